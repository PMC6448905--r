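test_that("within-category consistency assessment covers all four states", {
  cons <- make_records("G", list(list("clinical_outcome", "effect", "increased"),
                                 list("clinical_outcome", "effect", "increased")))
  expect_equal(assess_consistency(cons), "consistent")

  mixed <- make_records("G", list(list("clinical_outcome", "effect", "increased"),
                                  list("clinical_outcome", "no_effect")))
  expect_equal(assess_consistency(mixed), "inconsistent")

  refut <- make_records("G", list(list("pk_pd", "no_effect"),
                                  list("pk_pd", "no_effect")))
  expect_equal(assess_consistency(refut), "refuted")

  expect_equal(assess_consistency(cons[0, ]), "absent")

  # opposing effect directions are inconsistent even without no-effect rows
  opp <- make_records("G", list(list("pk_pd", "effect", "increased"),
                                list("pk_pd", "effect", "decreased")))
  expect_equal(assess_consistency(opp), "inconsistent")

  # a single supporting study fails a stricter replication requirement
  one <- make_records("G", list(list("pk_pd", "effect", "increased")))
  expect_equal(assess_consistency(one), "consistent")
  expect_equal(assess_consistency(one, min_studies = 2L), "inconsistent")

  two_cat <- rbind(cons, refut)
  expect_error(assess_consistency(two_cat), "categories")
})

# Independent oracle for the code-assignment precedence: a direct rule-table
# lookup over category states, written without reference to the
# implementation's category loop.
oracle_code <- function(clin, pk, mol) {
  states <- c(clin, pk, mol)
  if (clin == "consistent") return(1L)
  if (pk == "consistent") return(2L)
  if (mol == "consistent") return(3L)
  if (clin == "inconsistent") return(4L)
  if (pk == "inconsistent") return(5L)
  if (mol == "inconsistent") return(6L)
  if (any(states == "refuted")) return(7L)
  NA_integer_ # no evidence at all
}

# Construct a record set realising a given state in a given category.
records_for_state <- function(cat, state) {
  switch(state,
         absent = NULL,
         consistent = list(list(cat, "effect", "increased"),
                           list(cat, "effect", "increased")),
         inconsistent = list(list(cat, "effect", "increased"),
                             list(cat, "no_effect")),
         refuted = list(list(cat, "no_effect")))
}

test_that("code assignment agrees with the brute-force precedence oracle on all 4^3 state combinations", {
  states <- c("absent", "consistent", "inconsistent", "refuted")
  grid <- expand.grid(clin = states, pk = states, mol = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    specs <- c(records_for_state("clinical_outcome", grid$clin[i]),
               records_for_state("pk_pd", grid$pk[i]),
               records_for_state("molecular_cellular", grid$mol[i]))
    expected <- oracle_code(grid$clin[i], grid$pk[i], grid$mol[i])
    if (is.na(expected)) {
      expect_error(assign_evidence_code("G", make_records("G", specs)),
                   "no evidence")
      next
    }
    got <- assign_evidence_code("G", make_records("G", specs))
    expect_equal(got$code, expected,
                 label = sprintf("code for states (%s, %s, %s)",
                                 grid$clin[i], grid$pk[i], grid$mol[i]))
    # the rule table is total and deterministic: re-evaluation is identical
    expect_identical(got,
                     assign_evidence_code("G", make_records("G", specs)))
  }
})

test_that("code-to-assessment mapping follows the seven-level scheme", {
  clin <- make_records("G", list(list("clinical_outcome", "effect", "increased"),
                                 list("clinical_outcome", "effect", "increased")))
  expect_equal(assign_evidence_code("G", clin)$assessment,
               "clinically_relevant")
  mol <- make_records("G", list(list("molecular_cellular", "effect", "increased")))
  got <- assign_evidence_code("G", mol)
  expect_equal(got$code, 3L)
  expect_equal(got$assessment, "potential_clinical_relevance")
  incon <- make_records("G", list(list("pk_pd", "effect", "increased"),
                                  list("pk_pd", "no_effect")))
  expect_equal(assign_evidence_code("G", incon)$assessment,
               "clinical_relevance_unknown")
  ref <- make_records("G", list(list("clinical_outcome", "no_effect"),
                                list("pk_pd", "no_effect")))
  got7 <- assign_evidence_code("G", ref)
  expect_equal(got7$code, 7L)
  expect_equal(got7$assessment, "clinical_relevance_unsupported")
})

test_that("code assignment is order-invariant and monotone under new evidence", {
  set.seed(42)
  cats <- c("clinical_outcome", "pk_pd", "molecular_cellular")
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    specs <- lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.6) {
        list(sample(cats, 1), "effect", sample(c("increased", "decreased"), 1))
      } else list(sample(cats, 1), "no_effect")
    })
    recs <- make_records("G", specs)
    base <- assign_evidence_code("G", recs)$code
    shuffled <- recs[sample(nrow(recs)), ]
    expect_equal(assign_evidence_code("G", shuffled)$code, base)

    # adding a no-effect record never strengthens (lowers) the code
    plus_null <- rbind(recs, make_records("G", list(list(sample(cats, 1),
                                                         "no_effect"))))
    expect_gte(assign_evidence_code("G", plus_null)$code, base)

    # reinforcing an already consistent category never weakens the code
    states <- assign_evidence_code("G", recs)$category_states
    consistent_cats <- names(states)[states == "consistent"]
    if (length(consistent_cats) > 0L) {
      cat0 <- consistent_cats[1]
      dir0 <- recs$direction[recs$study_category == cat0 &
                               recs$finding == "effect"][1]
      plus_eff <- rbind(recs, make_records("G", list(list(cat0, "effect",
                                                          dir0))))
      expect_lte(assign_evidence_code("G", plus_eff)$code, base)
    }

    # structural invariants of the scheme
    code <- base
    expect_equal(code <= 3L, any(states == "consistent"))
    present <- states[states != "absent"]
    expect_equal(code == 7L,
                 length(present) > 0L && all(present == "refuted"))
  }
})

test_that("the fixture evidence reproduces the published tier sizes", {
  codes <- assign_evidence_codes(
    read_evidence(metamine_extdata("curated_evidence.tsv")))
  sets <- build_gene_sets(codes)
  expect_length(sets$A, 7L)
  expect_length(sets$B, 15L)
  expect_length(sets$C, 51L)
  expect_length(sets$D, 22L)
  expect_length(sets$E, 70L)
  expect_setequal(sets$D, union(sets$A, sets$B))
  expect_setequal(sets$E, union(sets$D, sets$C))
  # the clinical tier is disjoint from the others; PK/PD and expression
  # tiers may share genes with evidence in both categories
  expect_length(intersect(sets$A, sets$B), 0L)
  expect_length(intersect(sets$A, sets$C), 0L)
  expect_setequal(intersect(sets$B, sets$C),
                  c("IRS2", "KLF15", "RPS6KB1"))
})

test_that("gene-set construction handles degenerate inputs", {
  all7 <- assign_evidence_codes(make_records("G1", list(
    list("clinical_outcome", "no_effect"))))
  sets <- build_gene_sets(all7)
  expect_true(all(vapply(sets, length, integer(1)) == 0L))

  dup <- data.frame(gene_id = c("G1", "G1"), code = c(1L, 2L))
  expect_error(build_gene_sets(dup), "duplicate")

  # without category states, the expression set falls back to code 3
  bare <- data.frame(gene_id = c("G1", "G2", "G3"), code = c(1L, 2L, 3L))
  sets2 <- build_gene_sets(bare)
  expect_equal(sets2$C, "G3")
  expect_equal(sets2$E, c("G1", "G2", "G3"))
})

test_that("gene-set catalogues round-trip through TSV", {
  codes <- assign_evidence_codes(
    read_evidence(metamine_extdata("curated_evidence.tsv")))
  sets <- build_gene_sets(codes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_sets(sets, path)
  expect_equal(length(readLines(path)) - 1L, 7L + 15L + 51L + 22L + 70L)
  again <- read_gene_sets(path)
  expect_equal(unclass(again)[names(sets)], unclass(sets)[names(sets)],
               ignore_attr = TRUE)

  empty <- withr::local_tempfile(fileext = ".tsv")
  write_gene_sets(list(), empty)
  expect_equal(readLines(empty), "set_name\tgene_id")
})

test_that("annotated dyads map to evidence records by keyword rules", {
  d <- rbind(
    data.frame(article_id = "a1", sentence_index = 0L, gene_id = "SLC2A4",
               drug_id = "metformin", gene_surface = "GLUT4",
               drug_surface = "Metformin",
               sentence_text = "Metformin increased GLUT4 expression."),
    data.frame(article_id = "a1", sentence_index = 1L, gene_id = "SLC22A1",
               drug_id = "metformin", gene_surface = "OCT1",
               drug_surface = "Metformin",
               sentence_text = "Metformin uptake was reduced by OCT1 loss."),
    data.frame(article_id = "a1", sentence_index = 2L, gene_id = "ATM",
               drug_id = "metformin", gene_surface = "ATM",
               drug_surface = "Metformin",
               sentence_text = "Metformin did not alter ATM activity."))
  ev <- evidence_from_annotations(annotate_dyads(d))
  expect_equal(ev$study_category,
               c("molecular_cellular", "pk_pd", "molecular_cellular"))
  expect_equal(ev$finding, c("effect", "effect", "no_effect"))
  expect_equal(ev$direction, c("increased", "decreased", ""))
})
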