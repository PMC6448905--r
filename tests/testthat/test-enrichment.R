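plus_gene <- data.frame(gene_id = "gA", chrom = "chr1", start = 200000L,
                        end = 210000L, strand = "+")
minus_gene <- data.frame(gene_id = "gB", chrom = "chr1", start = 200000L,
                         end = 210000L, strand = "-")
snp_at <- function(pos, id = "rs1") {
  data.frame(snp_id = id, chrom = "chr1", pos = as.integer(pos),
             p_value = 0.5)
}

test_that("SNP assignment extends gene boundaries by strand", {
  # + strand: 110 kb upstream reaches exactly to 90000
  expect_equal(nrow(map_snps_to_genes(snp_at(90000), plus_gene)), 1L)
  expect_equal(nrow(map_snps_to_genes(snp_at(89999), plus_gene)), 0L)
  # + strand: 40 kb downstream reaches exactly to 250000
  expect_equal(nrow(map_snps_to_genes(snp_at(250000), plus_gene)), 1L)
  expect_equal(nrow(map_snps_to_genes(snp_at(250001), plus_gene)), 0L)
  # - strand: the 110 kb upstream flank now lies rightward
  expect_equal(nrow(map_snps_to_genes(snp_at(320000), minus_gene)), 1L)
  expect_equal(nrow(map_snps_to_genes(snp_at(320001), minus_gene)), 0L)
  expect_equal(nrow(map_snps_to_genes(snp_at(160000), minus_gene)), 1L)
  expect_equal(nrow(map_snps_to_genes(snp_at(159999), minus_gene)), 0L)

  expect_error(map_snps_to_genes(snp_at(1), plus_gene, upstream_kb = -1),
               ">= 0")
})

test_that("gene scores take the best SNP with a lexicographic tie-break", {
  mapping <- map_snps_to_genes(
    data.frame(snp_id = c("rs2", "rs1"), chrom = "chr1",
               pos = c(201000L, 205000L), p_value = c(0.5, 0.01)),
    plus_gene)
  sc <- score_genes(mapping)
  expect_equal(sc$best_p, 0.01)
  expect_equal(sc$raw_score, 2)
  expect_equal(sc$n_snps, 2L)
  expect_equal(sc$best_snp_id, "rs1")

  one <- score_genes(map_snps_to_genes(
    data.frame(snp_id = "rs9", chrom = "chr1", pos = 201000L, p_value = 1),
    plus_gene))
  expect_equal(one$raw_score, 0)

  tie <- score_genes(map_snps_to_genes(
    data.frame(snp_id = c("rsB", "rsA"), chrom = "chr1",
               pos = c(201000L, 202000L), p_value = c(0.01, 0.01)),
    plus_gene))
  expect_equal(tie$best_snp_id, "rsA")
})

make_scores <- function(n, raw, size_kb = rep(10, n),
                        n_snps = rep(5L, n)) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), n_snps = n_snps,
             best_snp_id = sprintf("s%04d", seq_len(n)),
             best_p = 10^-raw, best_pos = seq_len(n) * 1000L,
             raw_score = raw, size_kb = size_kb,
             midpoint = seq_len(n) * 1000)
}

test_that("confounder correction ranks residuals and removes size bias", {
  # covariate-free scores: corrected ranking equals the raw ranking
  sc <- make_scores(20, raw = seq(2, 0.1, length.out = 20))
  cc <- correct_confounders(sc)
  expect_equal(order(cc$corrected_p), order(-sc$raw_score))
  expect_equal(min(cc$corrected_p), 1 / 20)
  expect_equal(max(cc$corrected_p), 1)

  # score driven by gene size: corrected ranks decorrelate from size
  set.seed(42)
  size <- stats::runif(500, 1, 200)
  sc2 <- make_scores(500, raw = 0.01 * size + stats::rnorm(500, 0, 0.05),
                     size_kb = size)
  cc2 <- correct_confounders(sc2)
  expect_lt(abs(stats::cor(cc2$corrected_p, cc2$size_kb)), 0.1)
  expect_gt(abs(stats::cor(sc2$raw_score, sc2$size_kb)), 0.9)

  expect_warning(correct_confounders(make_scores(5, raw = 5:1)),
                 "fewer than 10")
})

test_that("genes sharing a best SNP collapse to the nearest gene body", {
  sc <- make_scores(12, raw = seq(3, 0.2, length.out = 12))
  sc$best_snp_id[1:2] <- "shared"
  sc$best_pos[1:2] <- 10000L
  sc$midpoint[1] <- 11000   # 1 kb away: kept
  sc$midpoint[2] <- 60000   # 50 kb away: dropped
  cc <- correct_confounders(sc)
  expect_true("g0001" %in% cc$gene_id)
  expect_false("g0002" %in% cc$gene_id)
  expect_equal(nrow(cc), 11L)
})

test_that("the permutation test is calibrated on a flat score distribution", {
  sc <- make_scores(400, raw = rep(0, 400))
  sc$corrected_p <- seq_len(400) / 400
  set.seed(42)
  set40 <- sample(sc$gene_id, 40)
  res <- gsea(sc, set40, set_name = "random", n_perm = 2000L, seed = 42L)
  expect_equal(res$n_genes_scored, 40L)
  # analytic null expectation: a quarter of the set above the 75% cutoff
  expect_lt(abs(res$expected - 10), 3 * res$null_sd / sqrt(res$n_perm))
  expect_gt(res$nominal_p, 0)
  expect_true(res$fold > 0.5 && res$fold < 2)
  # bit-reproducible under the seed, without touching the caller's stream
  rng_before <- .Random.seed
  res2 <- gsea(sc, set40, set_name = "random", n_perm = 2000L, seed = 42L)
  expect_identical(.Random.seed, rng_before)
  expect_identical(res[names(res) != "set_name"],
                   res2[names(res2) != "set_name"])
})

test_that("unscored set genes are excluded with a message; empty overlap errors", {
  sc <- make_scores(50, raw = seq(2, 0.1, length.out = 50))
  sc$corrected_p <- seq_len(50) / 50
  expect_message(res <- gsea(sc, c("g0001", "g0002", "ghost"),
                             n_perm = 200L, seed = 1L), "ghost")
  expect_equal(res$n_genes_scored, 2L)
  expect_equal(res$missing_genes, "ghost")
  expect_error(gsea(sc, c("nope1", "nope2"), n_perm = 200L), "nope1")
  expect_error(gsea(sc, "g0001", n_perm = 10L), "n_perm")
})

test_that("reporting arithmetic matches the published table conventions", {
  # observed 17 against an analytic expectation of 10.75 (43 genes, 75%):
  # the report rounds the expectation to 11, giving excess 6, fold 1.55
  expect_equal(expected_above_cutoff(43, 75), 10.75)
  expect_equal(expected_above_cutoff(20, 75), 5)
  expect_equal(expected_above_cutoff(0, 75), 0)

  mock <- structure(list(set_name = "expression", n_genes_scored = 43L,
                         cutoff_percentile = 75, cutoff_value = 0.25,
                         observed = 17L, expected = 10.75,
                         excess = 17 - 10.75, fold = 17 / 10.75,
                         nominal_p = 0.03, null_sd = 2.6, n_perm = 10000L,
                         seed = 1L, missing_genes = character(0)),
                    class = "metamine_enrichment")
  row <- enrichment_report(list(mock))
  expect_equal(row$expected, 11)
  expect_equal(row$excess, 6)
  expect_equal(row$fold, 1.55)
  expect_equal(row$nominal_p, 0.03)
})
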