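#' Configuration for the corpus simulator
#'
#' @param n_articles Number of articles to emit.
#' @param n_planted_dyads Number of planted gene-drug dyad sentences.
#' @param n_distractor_sentences Sentences containing no lexicon terms.
#' @param fraction_negated,fraction_hedged Fractions (of the planted dyads)
#'   built from negated resp. hedged cue templates; counts are rounded.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A validated list of class `corpus_sim_config`.
#' @export
corpus_sim_config <- function(n_articles = 4L, n_planted_dyads = 10L,
                              n_distractor_sentences = 20L,
                              fraction_negated = 0.2, fraction_hedged = 0.2,
                              seed = 1L) {
  stopifnot(n_articles >= 0, n_planted_dyads >= 0,
            n_distractor_sentences >= 0)
  if (fraction_negated < 0 || fraction_negated > 1 ||
      fraction_hedged < 0 || fraction_hedged > 1) {
    fail("corpus_sim_config: fractions must lie in [0, 1]")
  }
  structure(list(n_articles = as.integer(n_articles),
                 n_planted_dyads = as.integer(n_planted_dyads),
                 n_distractor_sentences = as.integer(n_distractor_sentences),
                 fraction_negated = fraction_negated,
                 fraction_hedged = fraction_hedged,
                 seed = as.integer(seed)),
            class = "corpus_sim_config")
}

PLAIN_TEMPLATES <- list(
  list(fmt = "%s increased %s expression.", modifier = "increased"),
  list(fmt = "%s decreased %s activity.", modifier = "decreased"),
  list(fmt = "%s reduced %s expression.", modifier = "decreased"))
NEGATED_TEMPLATE <- "%s did not alter %s activity."
HEDGED_TEMPLATE <- "%s may influence %s signalling."
DISTRACTOR_SENTENCES <- c(
  "The cohort was recruited from three regional clinics.",
  "Samples were processed in duplicate by blinded technicians.",
  "Participants returned for follow-up visits every quarter.",
  "Statistical analyses were performed with standard software.",
  "Baseline characteristics were balanced between the study arms.",
  "Written informed consent was obtained from all participants.")

#' Generate a gold-annotated mini-corpus
#'
#' Builds planted dyad sentences from cue templates over dictionary surface
#' forms ("<drug> increased <gene> expression.", a negated and a hedged
#' variant), mixes them with distractor sentences containing no lexicon
#' terms, and records the intended annotation of every planted dyad as a
#' gold standard. Output is byte-identical for a given config.
#'
#' @param config A [corpus_sim_config()].
#' @param gene_lex,drug_lex Lexicons supplying surface forms; default to the
#'   packaged fixture dictionaries. Only unambiguous forms are used, so
#'   extraction on the generated corpus is exact by construction.
#' @return A list with `articles` (corpus data.frame), `gold` (planted
#'   dyads with their true labels) and `config`.
#' @export
generate_corpus <- function(config, gene_lex = NULL, drug_lex = NULL) {
  stopifnot(inherits(config, "corpus_sim_config"))
  gene_lex <- gene_lex %||%
    load_lexicon(metamine_extdata("gene_dictionary.tsv"), "gene")
  drug_lex <- drug_lex %||%
    load_lexicon(metamine_extdata("drug_dictionary.tsv"), "drug")
  lexes <- harmonize_lexicons(gene_lex, drug_lex)
  gene_lex <- lexes$gene; drug_lex <- lexes$drug

  n_total <- config$n_planted_dyads + config$n_distractor_sentences
  if (n_total > 0L && config$n_articles == 0L) {
    fail("generate_corpus: planted sentences exceed capacity (0 articles)")
  }
  n_neg <- round(config$fraction_negated * config$n_planted_dyads)
  n_hedge <- round(config$fraction_hedged * config$n_planted_dyads)
  n_plain <- config$n_planted_dyads - n_neg - n_hedge
  if (n_plain < 0L) {
    fail("generate_corpus: fraction_negated + fraction_hedged exceed 1")
  }

  gene_pool <- unique(gene_lex$pairs[!gene_lex$pairs$ambiguous,
                                     c("canonical_id", "surface_form")])
  drug_pool <- unique(drug_lex$pairs[!drug_lex$pairs$ambiguous,
                                     c("canonical_id", "surface_form")])
  if (config$n_planted_dyads > 0L &&
      (nrow(gene_pool) == 0L || nrow(drug_pool) == 0L)) {
    fail("generate_corpus: no unambiguous surface forms to plant")
  }

  with_seed(config$seed, {
    kinds <- c(rep("plain", n_plain), rep("negated", n_neg),
               rep("hedged", n_hedge))
    kinds <- sample(kinds)
    planted <- lapply(seq_along(kinds), function(i) {
      g <- gene_pool[sample.int(nrow(gene_pool), 1L), ]
      d <- drug_pool[sample.int(nrow(drug_pool), 1L), ]
      dsurf <- d$surface_form
      substr(dsurf, 1L, 1L) <- toupper(substr(dsurf, 1L, 1L))
      if (kinds[i] == "plain") {
        tpl <- PLAIN_TEMPLATES[[sample.int(length(PLAIN_TEMPLATES), 1L)]]
        list(text = sprintf(tpl$fmt, dsurf, g$surface_form),
             gene_id = g$canonical_id, drug_id = d$canonical_id,
             relation = "interaction", directness = "direct",
             explicitness = "explicit", modifier = tpl$modifier)
      } else if (kinds[i] == "negated") {
        list(text = sprintf(NEGATED_TEMPLATE, dsurf, g$surface_form),
             gene_id = g$canonical_id, drug_id = d$canonical_id,
             relation = "no_interaction", directness = "direct",
             explicitness = "explicit", modifier = "negation")
      } else {
        list(text = sprintf(HEDGED_TEMPLATE, dsurf, g$surface_form),
             gene_id = g$canonical_id, drug_id = d$canonical_id,
             relation = "interaction", directness = "indirect",
             explicitness = "inferred", modifier = "none")
      }
    })
    distractors <- if (config$n_distractor_sentences > 0L) {
      DISTRACTOR_SENTENCES[1L + (seq_len(config$n_distractor_sentences) - 1L) %%
                             length(DISTRACTOR_SENTENCES)]
    } else character(0)

    ids <- sprintf("SIM%05d", seq_len(config$n_articles))
    # round-robin assignment keeps article sizes within one sentence
    sent_article <- if (n_total > 0L) {
      sample(rep_len(seq_len(config$n_articles), n_total))
    } else integer(0)
    is_planted <- c(rep(TRUE, length(planted)), rep(FALSE, length(distractors)))
    texts <- c(vapply(planted, `[[`, "", "text"), distractors)

    gold_rows <- list()
    article_text <- character(config$n_articles)
    for (a in seq_len(config$n_articles)) {
      sel <- which(sent_article == a)
      sel <- sample(sel) # shuffle order inside the article
      article_text[a] <- paste(texts[sel], collapse = " ")
      p_sel <- sel[is_planted[sel]]
      for (s in p_sel) {
        pl <- planted[[s]]
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          article_id = ids[a], sentence_index = match(s, sel) - 1L,
          gene_id = pl$gene_id, drug_id = pl$drug_id,
          relation = pl$relation, directness = pl$directness,
          explicitness = pl$explicitness, modifier = pl$modifier)
      }
    }
    articles <- data.frame(
      article_id = ids,
      year = if (config$n_articles > 0L)
        sample(1990:2014, config$n_articles, replace = TRUE) else integer(0),
      source_kind = ifelse(article_text == "", "abstract",
                           sample(c("full_text", "abstract"),
                                  max(config$n_articles, 1L), replace = TRUE,
                                  prob = c(0.6, 0.4))[seq_len(config$n_articles)]),
      text = article_text)
    gold <- if (length(gold_rows) == 0L) {
      data.frame(article_id = character(0), sentence_index = integer(0),
                 gene_id = character(0), drug_id = character(0),
                 relation = character(0), directness = character(0),
                 explicitness = character(0), modifier = character(0))
    } else do.call(rbind, gold_rows)
    ord <- order(match(gold$article_id, ids), gold$sentence_index,
                 gold$gene_id, gold$drug_id)
    gold <- gold[ord, , drop = FALSE]
    rownames(gold) <- NULL
    list(articles = articles, gold = gold, config = config)
  })
}

#' Generate non-overlapping synthetic gene models
#'
#' Places `n_genes` genes sequentially along one synthetic chromosome with
#' at least `min_gap_bp` between gene bodies (default 160 kb, so the
#' default 110/40 kb extended regions rarely overlap).
#'
#' @param n_genes Number of genes.
#' @param chrom_length_bp Chromosome length (error if the genes do not fit).
#' @param gene_length_range Min/max gene body length in bp.
#' @param min_gap_bp Minimum gap between consecutive gene bodies.
#' @param chrom Chromosome name.
#' @param gene_ids Optional ids (default `g0001`, ...).
#' @param seed RNG seed.
#' @return A gene-model data.frame (see [read_gene_models()]).
#' @export
generate_gene_models <- function(n_genes, chrom_length_bp = 1e9,
                                 gene_length_range = c(5e3, 5e4),
                                 min_gap_bp = 160e3, chrom = "chr1",
                                 gene_ids = NULL, seed = 1L) {
  n_genes <- as.integer(n_genes)
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  if (n_genes == 0L) return(empty)
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) {
    fail("generate_gene_models: need %d gene ids, got %d", n_genes,
         length(gene_ids))
  }
  with_seed(seed, {
    lens <- floor(stats::runif(n_genes, gene_length_range[1L],
                               gene_length_range[2L] + 1))
    gaps <- min_gap_bp + floor(stats::runif(n_genes, 0, 4e4))
    start <- cumsum(gaps) + cumsum(c(0, lens[-n_genes])) + 1
    end <- start + lens - 1
    if (end[n_genes] > chrom_length_bp) {
      fail("generate_gene_models: %d genes do not fit in %g bp", n_genes,
           chrom_length_bp)
    }
    validate_gene_models(data.frame(
      gene_id = gene_ids, chrom = chrom, start = as.integer(start),
      end = as.integer(end),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)))
  })
}

#' Configuration for the GWAS summary-statistic simulator
#'
#' @param mode `"direct_p"` draws SNP p-values directly (null SNPs uniform;
#'   one planted SNP per enriched gene with p ~ Beta(a, 1), a < 1 pushing
#'   mass toward zero). `"phenotype"` simulates individual-level data: a
#'   continuous glycaemic-response outcome (maximal HbA1c reduction) as a
#'   linear function of baseline HbA1c, creatinine clearance, adherence,
#'   average daily dose, drug group and baseline gap plus an additive
#'   genotype effect at causal SNPs, with per-SNP p-values from
#'   covariate-adjusted least squares.
#' @param n_snps_per_gene_range Min/max SNPs placed in each gene body.
#' @param enrichment_beta_a Beta shape `a` for planted p-values (in (0, 1]).
#' @param n_individuals Cohort size for phenotype mode.
#' @param effect_size_beta Causal allele effect in units of the residual SD.
#' @param maf_range Minor-allele-frequency range, in (0, 0.5].
#' @param covariate_sds Named SDs for the six covariates.
#' @param covariate_effects Named linear coefficients for the covariates
#'   (declared defaults; the outcome model's terms are fixed but its
#'   coefficients are configurable constants).
#' @param noise_sd Residual SD of the outcome.
#' @param seed RNG seed.
#' @return A validated list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(mode = c("direct_p", "phenotype"),
                            n_snps_per_gene_range = c(2L, 10L),
                            enrichment_beta_a = 0.1,
                            n_individuals = 2000L,
                            effect_size_beta = 0.5,
                            maf_range = c(0.05, 0.5),
                            covariate_sds = c(baseline_hba1c = 1.0,
                                              creatinine_clearance = 20,
                                              adherence = 0.1,
                                              avg_daily_dose = 500,
                                              drug_group = NA,
                                              baseline_gap = 15),
                            covariate_effects = c(baseline_hba1c = 0.8,
                                                  creatinine_clearance = 0.005,
                                                  adherence = 2.0,
                                                  avg_daily_dose = 4e-4,
                                                  drug_group = 0.2,
                                                  baseline_gap = -0.002),
                            noise_sd = 1.0,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (enrichment_beta_a <= 0 || enrichment_beta_a > 1) {
    fail("gwas_sim_config: enrichment_beta_a must lie in (0, 1]")
  }
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    fail("gwas_sim_config: maf_range must lie in (0, 0.5]")
  }
  stopifnot(n_snps_per_gene_range[1L] >= 1L,
            n_snps_per_gene_range[2L] >= n_snps_per_gene_range[1L])
  structure(list(mode = mode,
                 n_snps_per_gene_range = as.integer(n_snps_per_gene_range),
                 enrichment_beta_a = enrichment_beta_a,
                 n_individuals = as.integer(n_individuals),
                 effect_size_beta = effect_size_beta,
                 maf_range = maf_range, covariate_sds = covariate_sds,
                 covariate_effects = covariate_effects, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gwas_sim_config")
}

# Covariate-adjusted per-SNP OLS p-values via residualisation (equivalent
# to refitting the full model per SNP, but one QR for the shared part).
ols_snp_pvalues <- function(y, G, X) {
  n <- length(y)
  qx <- qr(cbind(1, X))
  yr <- qr.resid(qx, y)
  Gr <- qr.resid(qx, G)
  gg <- colSums(Gr^2)
  df <- n - qx$rank - 1L
  gy <- colSums(Gr * yr)
  beta <- ifelse(gg > 0, gy / gg, 0)
  rss <- sum(yr^2) - beta^2 * gg
  sigma2 <- rss / df
  tt <- ifelse(gg > 0, beta / sqrt(sigma2 / gg), 0)
  p <- 2 * stats::pt(-abs(tt), df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Simulate GWAS summary statistics over gene models
#'
#' @param config A [gwas_sim_config()].
#' @param gene_models Gene models (see [generate_gene_models()]).
#' @param enriched_set Gene ids carrying a planted association (must be a
#'   subset of the model ids); empty for a null simulation.
#' @return A list with `snps` (summary-statistic data.frame: `snp_id`,
#'   `chrom`, `pos`, `p_value`) and `gold` (per enriched gene: its causal
#'   `snp_id` and, in phenotype mode, the true allele effect).
#' @export
generate_gwas <- function(config, gene_models, enriched_set = character(0)) {
  stopifnot(inherits(config, "gwas_sim_config"))
  validate_gene_models(gene_models)
  bad <- setdiff(enriched_set, gene_models$gene_id)
  if (length(bad) > 0L) {
    fail("generate_gwas: enriched gene(s) not in gene models: %s",
         paste(bad, collapse = ", "))
  }
  with_seed(config$seed, {
    rng <- config$n_snps_per_gene_range
    n_genes <- nrow(gene_models)
    k <- if (rng[1L] == rng[2L]) rep(rng[1L], n_genes)
         else sample(seq.int(rng[1L], rng[2L]), n_genes, replace = TRUE)
    gene_of <- rep(seq_len(n_genes), k)
    pos <- unlist(lapply(seq_len(n_genes), function(i) {
      sort(sample(seq.int(gene_models$start[i], gene_models$end[i]), k[i]))
    }), use.names = FALSE)
    m <- length(pos)
    snp_id <- sprintf("snp%06d", seq_len(m))
    chrom <- gene_models$chrom[gene_of]
    enriched_idx <- which(gene_models$gene_id %in% enriched_set)
    causal <- vapply(enriched_idx, function(i) {
      cand <- which(gene_of == i)
      cand[sample.int(length(cand), 1L)]
    }, integer(1))

    if (config$mode == "direct_p") {
      p <- stats::runif(m)
      if (length(causal) > 0L) {
        p[causal] <- stats::rbeta(length(causal), config$enrichment_beta_a, 1)
      }
      p <- pmin(pmax(p, .Machine$double.xmin), 1)
      gold <- data.frame(gene_id = gene_models$gene_id[enriched_idx],
                         snp_id = snp_id[causal],
                         effect = rep(NA_real_, length(causal)))
    } else {
      n <- config$n_individuals
      sds <- config$covariate_sds
      X <- cbind(baseline_hba1c = stats::rnorm(n, 8.8, sds[["baseline_hba1c"]]),
                 creatinine_clearance =
                   stats::rnorm(n, 90, sds[["creatinine_clearance"]]),
                 adherence = stats::rnorm(n, 0.85, sds[["adherence"]]),
                 avg_daily_dose = stats::rnorm(n, 1500,
                                               sds[["avg_daily_dose"]]),
                 drug_group = stats::rbinom(n, 1L, 0.5),
                 baseline_gap = stats::rnorm(n, 30, sds[["baseline_gap"]]))
      maf <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
      G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
      eff <- config$effect_size_beta * config$noise_sd
      y <- drop(X %*% config$covariate_effects[colnames(X)]) +
        stats::rnorm(n, 0, config$noise_sd)
      if (length(causal) > 0L) {
        y <- y + G[, causal, drop = FALSE] %*% rep(eff, length(causal))
        y <- drop(y)
      }
      p <- ols_snp_pvalues(y, G, X)
      gold <- data.frame(gene_id = gene_models$gene_id[enriched_idx],
                         snp_id = snp_id[causal],
                         effect = rep(eff, length(causal)))
    }
    list(snps = data.frame(snp_id = snp_id, chrom = chrom,
                           pos = as.integer(pos), p_value = p),
         gold = gold)
  })
}
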