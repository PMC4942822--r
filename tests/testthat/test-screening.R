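test_that("screen keeps all polymorphic SNPs when top_m is large", {
  g <- sim_pop(n_lines = 40, n_chrom = 2, markers = 6, seed = 1)
  mono <- matrix(1, nrow = 40, ncol = 1, dimnames = list(NULL, "mono"))
  g2 <- toy_geno(cbind(g$calls, mono))
  ph <- toy_pheno(rnorm(40, 10), rownames(g2$calls))
  cand <- marginal_screen(g2, ph, "t", "E1", top_m = 1000)
  expect_setequal(cand$snps$snp_id, g$snps$snp_id)  # mono excluded
  expect_false("mono" %in% cand$snps$snp_id)
})

test_that("screening scores are invariant to affine phenotype transforms", {
  g <- sim_pop(n_lines = 50, n_chrom = 1, markers = 8, seed = 2)
  set.seed(3)
  ph <- toy_pheno(rnorm(50), rownames(g$calls))
  ph2 <- ph
  ph2$value <- 3 * ph$value + 7
  s1 <- marginal_screen(g, ph, "t", "E1", top_m = 8)
  s2 <- marginal_screen(g, ph2, "t", "E1", top_m = 8)
  expect_equal(s1$snps$score[order(s1$snps$snp_id)],
               s2$snps$score[order(s2$snps$snp_id)], tolerance = 1e-9)
})

test_that("a planted QTS ranks near the top of the marginal screen", {
  # single QTS with h2 ~ 0.3 among null SNPs at n = 138
  reps <- 40
  hits <- 0
  for (i in seq_len(reps)) {
    g <- sim_pop(n_lines = 138, n_chrom = 4, markers = 25, spacing_cM = 8,
                 seed = 100 + i)
    qts <- g$snps$snp_id[13]
    tm <- true_model(mu = 0, additive = setNames(1, qts),
                     residual_sd = sqrt(7 / 3), n_env = 1, n_rep = 1)
    ph <- simulate_phenotypes(g, tm, seed = 200 + i)
    cand <- marginal_screen(g, ph, "trait", "E1", top_m = 10)
    if (qts %in% cand$snps$snp_id) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("pairwise screen finds a planted interaction with no marginals", {
  reps <- 15
  first <- 0
  for (i in seq_len(reps)) {
    g <- sim_pop(n_lines = 500, n_chrom = 2, markers = 6, spacing_cM = 30,
                 seed = 300 + i)
    ids <- g$snps$snp_id
    pair <- c(ids[2], ids[9])  # different chromosomes
    tm <- true_model(mu = 0,
                     epistatic = data.frame(snp_i = pair[1], snp_j = pair[2],
                                            effect = 2.5),
                     residual_sd = 3, n_env = 1, n_rep = 1)
    ph <- simulate_phenotypes(g, tm, seed = 400 + i)
    cand <- pairwise_screen(g, ph, "trait", "E1", top_m = 5)
    top <- cand$pairs[1, ]
    if (setequal(c(top$snp_i, top$snp_j), pair)) first <- first + 1
  }
  expect_gte(first / reps, 0.9)
})

test_that("two SNPs give exactly one scored pair", {
  g <- toy_geno(cbind(a = c(1, 1, -1, -1, 1, -1),
                      b = c(1, -1, 1, -1, -1, 1)))
  ph <- toy_pheno(rnorm(6), rownames(g$calls))
  cand <- pairwise_screen(g, ph, "t", "E1", top_m = 10,
                          universe = c("a", "b"))
  expect_equal(nrow(cand$pairs), 1)
})

test_that("merging candidate sets is a union with provenance", {
  mk <- function(ids, env) {
    cs <- marginal_screen
    structure(list(
      snps = data.frame(snp_id = ids, score = seq_along(ids),
                        trait = "t", environment = env,
                        stringsAsFactors = FALSE),
      pairs = data.frame(snp_i = character(0), snp_j = character(0),
                         score = numeric(0), trait = character(0),
                         environment = character(0))),
      class = "candidate_set")
  }
  a <- mk(c("s1", "s2", "s3"), "E1")
  b <- mk(c("s3", "s4", "s5", "s6"), "E2")
  m <- merge_candidates(list(a, b))
  expect_equal(nrow(m$snps), 6)  # 3 + 4 - 1 overlap
  expect_setequal(m$snps$snp_id, paste0("s", 1:6))
  same <- merge_candidates(list(a, a))
  expect_equal(nrow(same$snps), 3)
})

test_that("constant phenotype warns and yields zero scores", {
  g <- sim_pop(n_lines = 20, n_chrom = 1, markers = 4, seed = 5)
  ph <- toy_pheno(rep(1, 20), rownames(g$calls))
  expect_warning(cand <- marginal_screen(g, ph, "t", "E1", top_m = 4),
                 "constant")
  expect_true(all(cand$snps$score == 0))
})

test_that("candidate sets round-trip through TSV", {
  g <- sim_pop(n_lines = 30, n_chrom = 1, markers = 5, seed = 6)
  ph <- toy_pheno(rnorm(30), rownames(g$calls))
  cand <- marginal_screen(g, ph, "t", "E1", top_m = 3)
  f <- tempfile()
  write_candidates(cand, f)
  back <- utils::read.delim(paste0(f, ".snps.tsv"), stringsAsFactors = FALSE)
  expect_equal(back$snp_id, cand$snps$snp_id)
})
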