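#' Mine a corpus for annotated gene-drug dyads
#'
#' End-to-end literature stage: load the corpus and dictionaries, extract
#' dyad sentences, annotate them with the cue rules, apply any manual
#' overrides, and report the screening funnel (articles, sentences,
#' co-occurrences, direct-explicit co-occurrences) on stderr.
#'
#' @param corpus Corpus data.frame or path (see [load_corpus()]).
#' @param gene_lexicon,drug_lexicon Lexicons or dictionary paths; default to
#'   the packaged fixture dictionaries.
#' @param cues Cue lexicon or path.
#' @param overrides Optional manual-override table or path.
#' @param out_dir Optional directory; when given, writes
#'   `annotated_dyads.tsv` with a provenance header.
#' @param include_ambiguous Passed to the tagger.
#' @return A list with `dyads` (annotated), `kept` (the direct-explicit
#'   subset) and `summary` (named funnel counts).
#' @export
run_mine <- function(corpus, gene_lexicon = NULL, drug_lexicon = NULL,
                     cues = NULL, overrides = NULL, out_dir = NULL,
                     include_ambiguous = FALSE) {
  if (is.character(corpus)) corpus <- load_corpus(corpus)
  if (is.null(gene_lexicon)) {
    gene_lexicon <- metamine_extdata("gene_dictionary.tsv")
  }
  if (is.character(gene_lexicon)) {
    gene_lexicon <- load_lexicon(gene_lexicon, "gene")
  }
  if (is.null(drug_lexicon)) {
    drug_lexicon <- metamine_extdata("drug_dictionary.tsv")
  }
  if (is.character(drug_lexicon)) {
    drug_lexicon <- load_lexicon(drug_lexicon, "drug")
  }
  lexes <- harmonize_lexicons(gene_lexicon, drug_lexicon)
  if (is.null(cues)) cues <- default_cues()
  if (is.character(cues)) cues <- load_cues(cues)

  n_sentences <- sum(vapply(seq_len(nrow(corpus)), function(i) {
    nrow(segment_sentences(corpus[i, ]))
  }, integer(1)))
  dyads <- extract_dyads(corpus, lexes$gene, lexes$drug,
                         include_ambiguous = include_ambiguous)
  annotated <- annotate_dyads(dyads, cues)
  if (!is.null(overrides)) annotated <- apply_overrides(annotated, overrides)
  kept <- filter_direct_explicit(annotated)
  summary <- c(n_articles = nrow(corpus), n_sentences = n_sentences,
               n_dyad_sentences = length(unique(paste(dyads$article_id,
                                                      dyads$sentence_index))),
               n_cooccurrences = nrow(dyads),
               n_direct_explicit = nrow(kept))
  message(sprintf(paste("mine: %d articles, %d sentences, %d dyad sentences,",
                        "%d co-occurrences, %d direct-explicit"),
                  summary[["n_articles"]], summary[["n_sentences"]],
                  summary[["n_dyad_sentences"]], summary[["n_cooccurrences"]],
                  summary[["n_direct_explicit"]]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dyads(annotated, file.path(out_dir, "annotated_dyads.tsv"),
                meta = list(stage = "mine",
                            config = config_hash(list(
                              n_articles = nrow(corpus),
                              include_ambiguous = include_ambiguous))))
  }
  list(dyads = annotated, kept = kept, summary = summary)
}

#' Score curated evidence and build the gene-set catalogue
#'
#' @param evidence Evidence-record data.frame or TSV path (see
#'   [read_evidence()]).
#' @param min_studies Passed to the consistency assessment.
#' @param out_dir Optional directory; writes `evidence_codes.tsv` and
#'   `gene_sets.tsv`.
#' @return A list with `codes` (per-gene evidence codes and category
#'   states) and `sets` (the `metamine_gene_sets` catalogue).
#' @export
run_score <- function(evidence, min_studies = 1L, out_dir = NULL) {
  if (is.character(evidence)) evidence <- read_evidence(evidence)
  codes <- assign_evidence_codes(evidence, min_studies)
  sets <- build_gene_sets(codes)
  message(sprintf("score: %d genes coded; set sizes %s", nrow(codes),
                  paste(sprintf("%s=%d", names(sets),
                                vapply(sets, length, integer(1))),
                        collapse = ", ")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_tsv(codes, file.path(out_dir, "evidence_codes.tsv"),
                     meta = list(stage = "score",
                                 config = config_hash(list(
                                   min_studies = min_studies))))
    write_gene_sets(sets, file.path(out_dir, "gene_sets.tsv"))
  }
  list(codes = codes, sets = sets)
}

#' Run the gene-set enrichment stage
#'
#' SNP-to-gene mapping, best-SNP scoring, confounder correction and the
#' percentile-cutoff permutation test for each gene set in the catalogue.
#'
#' @param gwas GWAS summary data.frame or TSV path.
#' @param gene_models Gene-model data.frame or BED-like path.
#' @param gene_sets A `metamine_gene_sets` object, named list, or gene-set
#'   TSV path.
#' @param percentile Enrichment cutoff percentile (default 75).
#' @param upstream_kb,downstream_kb Gene boundary extensions.
#' @param n_perm Permutations per set.
#' @param seed Base seed; set `i` uses `seed + i` so results are
#'   reproducible per set and independent across sets.
#' @param out_dir Optional directory; writes `enrichment.tsv` with seed and
#'   permutation count in the header.
#' @return A list with `scores` (corrected gene scores), `results` (list of
#'   `metamine_enrichment`) and `table` (the [enrichment_report()]).
#' @export
run_gsea <- function(gwas, gene_models, gene_sets, percentile = 75,
                     upstream_kb = 110, downstream_kb = 40,
                     n_perm = 10000L, seed = 1L, out_dir = NULL) {
  if (is.character(gwas)) gwas <- read_gwas(gwas)
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  mapping <- map_snps_to_genes(gwas, gene_models, upstream_kb, downstream_kb)
  scores <- correct_confounders(score_genes(mapping))
  usable <- vapply(gene_sets,
                   function(s) any(s %in% scores$gene_id), logical(1))
  if (!any(usable)) fail("run_gsea: no gene set overlaps the scored genes")
  results <- lapply(seq_along(gene_sets), function(i) {
    gsea(scores, gene_sets[[i]], set_name = names(gene_sets)[i],
         percentile = percentile, n_perm = n_perm, seed = seed + i)
  })
  table <- enrichment_report(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_tsv(table, file.path(out_dir, "enrichment.tsv"),
                     meta = list(stage = "gsea", seed = seed, n_perm = n_perm,
                                 config = config_hash(list(
                                   percentile = percentile,
                                   upstream_kb = upstream_kb,
                                   downstream_kb = downstream_kb,
                                   n_perm = n_perm, seed = seed))))
  }
  list(scores = scores, results = results, table = table)
}

#' Demonstration run of the full pipeline on simulated data
#'
#' Simulates a gold-annotated corpus and mines it; scores the packaged
#' curated-evidence fixture into the five gene sets; simulates a GWAS over
#' synthetic gene models covering the catalogue genes with an association
#' planted in the expression set; and runs the enrichment test on all five
#' sets.
#'
#' @param out_dir Optional output directory for the stage files.
#' @param seed Seed controlling every stage.
#' @param n_background Background genes added beside the catalogue genes.
#' @param n_perm Permutations per set.
#' @return A list with the `mine`, `score` and `gsea` stage results.
#' @export
run_demo <- function(out_dir = NULL, seed = 1L, n_background = 330L,
                     n_perm = 2000L) {
  mine <- run_mine(generate_corpus(corpus_sim_config(seed = seed))$articles,
                   out_dir = out_dir)
  score <- run_score(metamine_extdata("curated_evidence.tsv"),
                     out_dir = out_dir)
  catalogue_genes <- sort(unique(unlist(score$sets)))
  ids <- c(catalogue_genes, sprintf("bg%04d", seq_len(n_background)))
  models <- generate_gene_models(length(ids), gene_ids = ids,
                                 seed = seed + 1L)
  sim <- generate_gwas(gwas_sim_config(mode = "direct_p", seed = seed + 2L),
                       models, enriched_set = score$sets$C)
  enr <- run_gsea(sim$snps, models, score$sets, n_perm = n_perm, seed = seed,
                  out_dir = out_dir)
  list(mine = mine, score = score, gsea = enr)
}
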