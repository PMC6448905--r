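#' Read GWAS summary statistics
#'
#' @param path TSV with header `snp_id`, `chrom`, `pos`, `p_value`.
#' @return A validated data.frame (`pos` integer, `p_value` numeric in
#'   (0, 1], `snp_id` unique).
#' @export
read_gwas <- function(path) {
  df <- read_tsv(path, "gwas")
  if (is.null(df)) fail("gwas: %s has no header row", path)
  check_columns(df, c("snp_id", "chrom", "pos", "p_value"), "gwas")
  df$pos <- as.integer(df$pos)
  df$p_value <- as.numeric(df$p_value)
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup) > 0L) fail("gwas: duplicate snp_id: %s",
                             paste(dup, collapse = ", "))
  if (any(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)) {
    fail("gwas: p_value must lie in (0, 1]")
  }
  if (any(is.na(df$pos) | df$pos < 1L)) fail("gwas: invalid position")
  df
}

#' Read gene models from a BED-like TSV
#'
#' Six columns without header: `chrom`, `start`, `end`, `gene_id`, a score
#' placeholder, `strand`. Unlike BED proper, coordinates in this dialect
#' are 1-based and inclusive.
#'
#' @param path Path to the gene-model file.
#' @return A data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv(path, "gene models", header = FALSE,
                 col.names = c("chrom", "start", "end", "gene_id", "score",
                               "strand"))
  if (is.null(df)) df <- data.frame(chrom = character(0), start = character(0),
                                    end = character(0), gene_id = character(0),
                                    score = character(0), strand = character(0))
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    start = as.integer(df$start), end = as.integer(df$end),
                    strand = df$strand)
  validate_gene_models(out)
}

validate_gene_models <- function(models) {
  check_columns(models, c("gene_id", "chrom", "start", "end", "strand"),
                "gene models")
  if (nrow(models) == 0L) return(models)
  dup <- unique(models$gene_id[duplicated(models$gene_id)])
  if (length(dup) > 0L) fail("gene models: duplicate gene_id: %s",
                             paste(dup, collapse = ", "))
  if (any(models$start < 1L | models$end < models$start)) {
    fail("gene models: coordinates must be positive with start <= end")
  }
  if (any(!models$strand %in% c("+", "-"))) {
    fail("gene models: strand must be '+' or '-'")
  }
  models
}

#' Write gene models as BED-like TSV
#'
#' @param models Gene-model data.frame (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  validate_gene_models(models)
  out <- data.frame(chrom = models$chrom, start = models$start,
                    end = models$end, gene_id = models$gene_id, score = 0L,
                    strand = models$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign SNPs to genes with strand-aware boundary extension
#'
#' Each gene interval is extended by `upstream_kb` on its 5' side and
#' `downstream_kb` on its 3' side (so the upstream flank lies leftward of a
#' `+`-strand gene and rightward of a `-`-strand gene). A SNP belongs to
#' every gene whose extended interval contains its position (inclusive at
#' both bounds); genes catching no SNP are dropped.
#'
#' @param snps GWAS summary data.frame (see [read_gwas()]).
#' @param gene_models Gene-model data.frame.
#' @param upstream_kb,downstream_kb Flank sizes in kb (defaults 110 and 40,
#'   the conventional enrichment boundaries).
#' @return A data.frame with one row per (gene, SNP) assignment: `gene_id`,
#'   `snp_id`, `chrom`, `pos`, `p_value`, plus the gene's unextended
#'   `start`, `end`, `strand`.
#' @export
map_snps_to_genes <- function(snps, gene_models, upstream_kb = 110,
                              downstream_kb = 40) {
  if (upstream_kb < 0 || downstream_kb < 0) {
    fail("map_snps_to_genes: boundary extensions must be >= 0")
  }
  validate_gene_models(gene_models)
  empty <- data.frame(gene_id = character(0), snp_id = character(0),
                      chrom = character(0), pos = integer(0),
                      p_value = numeric(0), start = integer(0),
                      end = integer(0), strand = character(0))
  if (nrow(gene_models) == 0L || nrow(snps) == 0L) return(empty)
  up <- as.integer(round(upstream_kb * 1000))
  down <- as.integer(round(downstream_kb * 1000))
  plus <- gene_models$strand == "+"
  ext_start <- ifelse(plus, gene_models$start - up, gene_models$start - down)
  ext_end <- ifelse(plus, gene_models$end + down, gene_models$end + up)
  ext_start <- pmax(ext_start, 1L)
  genes <- GenomicRanges::GRanges(gene_models$chrom,
                                  IRanges::IRanges(ext_start, ext_end))
  sites <- GenomicRanges::GRanges(snps$chrom,
                                  IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(sites, genes)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(empty)
  out <- data.frame(gene_id = gene_models$gene_id[si],
                    snp_id = snps$snp_id[qi], chrom = snps$chrom[qi],
                    pos = snps$pos[qi], p_value = snps$p_value[qi],
                    start = gene_models$start[si], end = gene_models$end[si],
                    strand = gene_models$strand[si])
  out <- out[order(out$gene_id, out$pos, out$snp_id), ]
  rownames(out) <- NULL
  out
}

#' Best-SNP gene scores
#'
#' Each gene is scored by its most significant assigned SNP:
#' `raw_score = -log10(best_p)`. Ties in the minimum p-value resolve to the
#' lexicographically smallest SNP id.
#'
#' @param mapping Gene-SNP assignment from [map_snps_to_genes()].
#' @return A data.frame with one row per gene: `gene_id`, `n_snps`,
#'   `best_snp_id`, `best_p`, `best_pos`, `raw_score`, `size_kb`,
#'   `midpoint`.
#' @export
score_genes <- function(mapping) {
  if (nrow(mapping) == 0L) fail("score_genes: empty gene-SNP mapping")
  rows <- lapply(split(mapping, mapping$gene_id), function(d) {
    best <- which(d$p_value == min(d$p_value))
    best <- best[order(d$snp_id[best])][1L]
    data.frame(gene_id = d$gene_id[1L], n_snps = nrow(d),
               best_snp_id = d$snp_id[best], best_p = d$p_value[best],
               best_pos = d$pos[best],
               raw_score = -log10(d$p_value[best]),
               size_kb = (d$end[1L] - d$start[1L] + 1L) / 1000,
               midpoint = (d$start[1L] + d$end[1L]) / 2)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Confounder-corrected gene significance ranks
#'
#' Best-SNP scores favour long, SNP-dense genes. The raw score is regressed
#' on gene size (kb) and log SNP count by least squares; residuals are
#' ranked in descending order and `corrected_p = rank / n_genes` (the best
#' residual scores 1/n). Genes sharing an identical best SNP are then
#' deduplicated, keeping the gene whose unextended midpoint lies nearest
#' the SNP (ties to the smaller gene id). With fewer than 10 genes the
#' regression is skipped with a warning and ranks come from the raw score.
#'
#' @param scores Gene scores from [score_genes()].
#' @return `scores` with a `corrected_p` column, deduplicated by best SNP.
#' @export
correct_confounders <- function(scores) {
  n <- nrow(scores)
  if (n < 10L) {
    warning("fewer than 10 genes; confounder correction skipped, ",
            "ranks taken from raw scores")
    resid <- scores$raw_score
  } else {
    fit <- stats::lm(raw_score ~ size_kb + log(n_snps), data = scores)
    resid <- stats::residuals(fit)
  }
  ord <- order(-resid, scores$gene_id)
  rank_pos <- integer(n)
  rank_pos[ord] <- seq_len(n)
  scores$corrected_p <- rank_pos / n
  # one association signal can span several overlapping gene regions; keep
  # the nearest gene so a single SNP is not counted repeatedly
  keep <- unlist(lapply(split(seq_len(n), scores$best_snp_id), function(idx) {
    if (length(idx) == 1L) return(idx)
    d <- abs(scores$midpoint[idx] - scores$best_pos[idx])
    idx[order(d, scores$gene_id[idx])][1L]
  }), use.names = FALSE)
  out <- scores[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analytic expectation for the above-cutoff count
#'
#' Under the null a fraction `1 - percentile/100` of genes lies above the
#' significance cutoff, so a set of `n` genes expects
#' `n * (1 - percentile/100)` members there. The reporting layer rounds
#' this to an integer.
#'
#' @param n_genes_in_set Number of scored genes in the set.
#' @param percentile Cutoff percentile in (0, 100); default 75.
#' @return The expected count (numeric).
#' @examples
#' expected_above_cutoff(43, 75) # 10.75, reported as 11
#' @export
expected_above_cutoff <- function(n_genes_in_set, percentile = 75) {
  if (percentile <= 0 || percentile >= 100) {
    fail("expected_above_cutoff: percentile must lie in (0, 100)")
  }
  n_genes_in_set * (1 - percentile / 100)
}

#' Percentile-cutoff gene-set enrichment test
#'
#' Tests whether a gene set is over-represented among the most significant
#' genes: the cutoff is the corrected-p value below which the top
#' `100 - percentile` percent of all scored genes fall (type-1 empirical
#' quantile), the observed statistic is the number of set genes at or below
#' the cutoff, and the null is the same count for `n_perm` random gene sets
#' of equal size drawn without replacement from all scored genes.
#' `nominal_p = (1 + #\{null >= observed\}) / (n_perm + 1)`, never zero.
#'
#' @param scores Corrected gene scores from [correct_confounders()].
#' @param gene_set Character vector of gene ids (set genes missing from the
#'   scored table are logged and excluded).
#' @param set_name Label carried into the result.
#' @param percentile Cutoff percentile (default 75: the top quartile of
#'   genes counts as above cutoff).
#' @param n_perm Number of random sets (>= 100; default 10000).
#' @param seed Optional seed giving bit-reproducible permutations without
#'   disturbing the caller's RNG stream.
#' @return A `metamine_enrichment` object: list with `set_name`,
#'   `n_genes_scored`, `cutoff_percentile`, `cutoff_value`, `observed`,
#'   `expected` (permutation mean), `excess`, `fold`, `nominal_p`,
#'   `null_sd`, `n_perm`, `seed`, `missing_genes`.
#' @export
gsea <- function(scores, gene_set, set_name = "set", percentile = 75,
                 n_perm = 10000L, seed = NULL) {
  if (n_perm < 100L) fail("gsea: n_perm must be >= 100")
  if (percentile <= 0 || percentile >= 100) {
    fail("gsea: percentile must lie in (0, 100)")
  }
  gene_set <- unique(gene_set)
  in_scores <- gene_set %in% scores$gene_id
  missing <- gene_set[!in_scores]
  present <- gene_set[in_scores]
  if (length(present) == 0L) {
    fail("gsea: no scored genes in set '%s'; missing: %s", set_name,
         paste(missing, collapse = ", "))
  }
  if (length(missing) > 0L) {
    message(sprintf("gsea: %d gene(s) in set '%s' not scored, excluded: %s",
                    length(missing), set_name,
                    paste(missing, collapse = ", ")))
  }
  cutoff <- stats::quantile(scores$corrected_p, 1 - percentile / 100,
                            type = 1, names = FALSE)
  above <- scores$corrected_p <= cutoff
  observed <- sum(above[match(present, scores$gene_id)])
  k <- length(present)
  n <- nrow(scores)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(above[sample.int(n, k)]), integer(1))
  })
  expected <- mean(null_counts)
  structure(list(set_name = set_name, n_genes_scored = k,
                 cutoff_percentile = percentile, cutoff_value = cutoff,
                 observed = as.integer(observed), expected = expected,
                 excess = observed - expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 nominal_p = (1 + sum(null_counts >= observed)) / (n_perm + 1),
                 null_sd = stats::sd(null_counts),
                 n_perm = as.integer(n_perm), seed = seed,
                 missing_genes = missing),
            class = "metamine_enrichment")
}

#' @export
print.metamine_enrichment <- function(x, ...) {
  cat(sprintf("<metamine_enrichment> set %s (%d scored genes)\n",
              x$set_name, x$n_genes_scored))
  cat(sprintf("  observed above %g%% cutoff: %d  (expected %.2f, fold %.2f)\n",
              x$cutoff_percentile, x$observed, x$expected, x$fold))
  cat(sprintf("  nominal p = %.4g  (%d permutations)\n", x$nominal_p,
              x$n_perm))
  invisible(x)
}

#' Tabulate enrichment results in reporting style
#'
#' One row per gene set with the expected count rounded to an integer and
#' excess/fold recomputed from the rounded value, matching the conventional
#' presentation of percentile-cutoff enrichment tables.
#'
#' @param results A list of `metamine_enrichment` objects.
#' @return A data.frame with columns `set_name`, `nominal_p`, `observed`,
#'   `expected`, `excess`, `fold`, `n_genes_scored`.
#' @export
enrichment_report <- function(results) {
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "metamine_enrichment"))
    exp_int <- round(r$expected)
    data.frame(set_name = r$set_name,
               nominal_p = round(r$nominal_p, 2),
               observed = r$observed,
               expected = exp_int,
               excess = r$observed - exp_int,
               fold = if (exp_int > 0) round(r$observed / exp_int, 2)
                      else NA_real_,
               n_genes_scored = r$n_genes_scored)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
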