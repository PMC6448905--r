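mk_dyad <- function(text, gene_surface, drug_surface = "Metformin",
                    article_id = "a1", sentence_index = 0L,
                    gene_id = gene_surface, drug_id = "metformin") {
  data.frame(article_id = article_id, sentence_index = sentence_index,
             gene_id = gene_id, drug_id = drug_id,
             gene_surface = gene_surface, drug_surface = drug_surface,
             sentence_text = text)
}

test_that("cue rules produce the expected label for each annotation class", {
  cues <- default_cues()

  neg <- annotate_dyad(mk_dyad("Metformin did not alter SLC22A1 expression.",
                               "SLC22A1"), cues)
  expect_equal(neg$relation, "no_interaction")
  expect_equal(neg$modifier, "negation")
  expect_equal(neg$directness, "direct")
  expect_equal(neg$explicitness, "explicit")

  up <- annotate_dyad(mk_dyad("Metformin increased GLUT4 translocation.",
                              "GLUT4", gene_id = "SLC2A4"), cues)
  expect_equal(up[c("relation", "directness", "explicitness", "modifier")],
               list(relation = "interaction", directness = "direct",
                    explicitness = "explicit", modifier = "increased"))

  hedge <- annotate_dyad(mk_dyad("Metformin may influence ATM signalling.",
                                 "ATM"), cues)
  expect_equal(hedge$relation, "interaction")
  expect_equal(hedge$directness, "indirect")
  expect_equal(hedge$explicitness, "inferred")

  none <- annotate_dyad(mk_dyad("Metformin and SLC22A1 were both measured.",
                                "SLC22A1"), cues)
  expect_equal(none$relation, "unrelated")

  # negation outside the three-token scope window does not fire
  far <- annotate_dyad(mk_dyad(
    "Not one study found that metformin increased SLC22A1 expression.",
    "SLC22A1", drug_surface = "metformin"), cues)
  expect_equal(far$relation, "interaction")
  expect_equal(far$modifier, "increased")
})

test_that("rule annotation is deterministic and provenance is tracked", {
  d <- mk_dyad("Metformin decreased INSR expression.", "INSR")
  a1 <- annotate_dyads(d)
  a2 <- annotate_dyads(d)
  expect_identical(a1, a2)
  expect_equal(a1$provenance, "rule")
  expect_equal(a1$modifier, "decreased")
})

test_that("manual overrides replace rule labels and must reference real dyads", {
  d <- rbind(mk_dyad("Metformin increased GLUT4 expression.", "GLUT4",
                     gene_id = "SLC2A4"),
             mk_dyad("Metformin may influence ATM signalling.", "ATM",
                     sentence_index = 1L))
  ann <- annotate_dyads(d)

  expect_identical(apply_overrides(ann, ann[0, c("article_id",
                                                 "sentence_index", "gene_id",
                                                 "drug_id")]), ann)

  ov <- data.frame(article_id = "a1", sentence_index = 1L, gene_id = "ATM",
                   drug_id = "metformin", relation = "interaction",
                   directness = "direct", explicitness = "explicit",
                   modifier = "none")
  fixed <- apply_overrides(ann, ov)
  expect_equal(fixed$directness[2], "direct")
  expect_equal(fixed$provenance, c("rule", "manual"))
  expect_identical(fixed[1, ], ann[1, ])

  bad <- ov
  bad$gene_id <- "NOPE"
  expect_error(apply_overrides(ann, bad), "NOPE")
})

test_that("direct-explicit filtering keeps negations, drops hedged and unrelated", {
  d <- rbind(mk_dyad("Metformin increased GLUT4 expression.", "GLUT4",
                     gene_id = "SLC2A4"),
             mk_dyad("Metformin may influence ATM signalling.", "ATM",
                     sentence_index = 1L),
             mk_dyad("Metformin and SLC22A1 were both measured.", "SLC22A1",
                     sentence_index = 2L),
             mk_dyad("Metformin did not alter INSR expression.", "INSR",
                     sentence_index = 3L))
  ann <- annotate_dyads(d)
  kept <- filter_direct_explicit(ann)
  expect_equal(kept$gene_id, c("SLC2A4", "INSR"))
  expect_true(all(kept$relation %in% c("interaction", "no_interaction")))

  # idempotent, subset-of-input, order-preserving
  expect_identical(filter_direct_explicit(kept), kept)
  expect_true(all(dyad_key(kept) %in% dyad_key(ann)))

  expect_equal(nrow(filter_direct_explicit(
    annotate_dyads(mk_dyad("Metformin and SLC22A1 were both measured.",
                           "SLC22A1")))), 0L)

  expect_error(filter_direct_explicit(d), "not annotated")
})

test_that("rule labels reproduce the generator's gold labels on cue templates", {
  corp <- generate_corpus(corpus_sim_config(n_articles = 3L,
                                            n_planted_dyads = 12L,
                                            fraction_negated = 0.25,
                                            fraction_hedged = 0.25,
                                            seed = 11L))
  lx <- fixture_lexicons()
  ann <- annotate_dyads(extract_dyads(corp$articles, lx$gene, lx$drug))
  m <- merge(ann, corp$gold,
             by = c("article_id", "sentence_index", "gene_id", "drug_id"),
             suffixes = c("", ".gold"))
  expect_equal(nrow(m), nrow(corp$gold))
  expect_equal(m$relation, m$relation.gold)
  expect_equal(m$directness, m$directness.gold)
  expect_equal(m$explicitness, m$explicitness.gold)
  expect_equal(m$modifier, m$modifier.gold)

  # the kept set equals the planted direct-explicit subset
  kept <- filter_direct_explicit(ann)
  gold_de <- corp$gold[corp$gold$directness == "direct" &
                         corp$gold$explicitness == "explicit", ]
  expect_setequal(dyad_key(kept), dyad_key(gold_de))
})
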