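test_that("additive scan reproduces the one-way ANOVA F statistic", {
  g <- toy_geno(cbind(s1 = c(1, 1, -1, -1)))
  ph <- toy_pheno(c(2, 3, -2, -3), rownames(g$calls))
  sc <- scan_additive(g, ph, "t")
  expect_equal(sc$F, 50)  # MSB 25, MSW 0.5
  expect_equal(sc$df2, 2L)
})

test_that("degenerate scans: constant phenotype and perfect fit", {
  g <- toy_geno(cbind(s1 = c(1, -1, 1, -1), s2 = c(1, 1, -1, -1)))
  ph0 <- toy_pheno(rep(5, 4), rownames(g$calls))
  expect_warning(sc0 <- scan_additive(g, ph0, "t"), "constant")
  expect_true(all(sc0$F == 0))

  ph1 <- toy_pheno(c(1, -1, 1, -1), rownames(g$calls))
  sc1 <- scan_additive(g, ph1, "t")
  expect_true(is.infinite(sc1$F[1]))  # zero-residual sentinel
})

test_that("monomorphic SNPs scan to NA and scans respect invariances", {
  g <- sim_pop(n_lines = 60, n_chrom = 1, markers = 6, seed = 1)
  g2 <- toy_geno(cbind(g$calls, mono = rep(1, 60)))
  set.seed(2)
  tm <- true_model(mu = 10, additive = setNames(2, g$snps$snp_id[3]),
                   env_sd = 1, residual_sd = 4)
  ph <- simulate_phenotypes(g2, tm, seed = 3)
  sc <- scan_additive(g2, ph, "trait")
  expect_true(is.na(sc$F[sc$snp_id == "mono"]))

  ph_aff <- ph
  ph_aff$value <- -2.5 * ph$value + 100
  sc_aff <- scan_additive(g2, ph_aff, "trait")
  expect_equal(sc$F, sc_aff$F, tolerance = 1e-9)

  flip <- toy_geno(-g2$calls)
  sc_flip <- scan_additive(flip, ph, "trait")
  expect_equal(sc$F, sc_flip$F, tolerance = 1e-9)
})

test_that("permutation threshold honours quantile convention and seed", {
  g <- sim_pop(n_lines = 40, n_chrom = 1, markers = 8, seed = 4)
  set.seed(5)
  ph <- toy_pheno(rnorm(40), rownames(g$calls))
  thr <- permutation_threshold(g, ph, "t", n_permutations = 120, seed = 7)
  thr2 <- permutation_threshold(g, ph, "t", n_permutations = 120, seed = 7)
  expect_identical(thr, thr2)
  thr_min <- permutation_threshold(g, ph, "t", n_permutations = 120,
                                   alpha = 1, seed = 7)
  expect_equal(as.numeric(thr_min), min(attr(thr, "max_f")))
  expect_error(permutation_threshold(g, ph, "t", n_permutations = 50),
               "at least 100")
})

test_that("epistasis scan detects a planted pure interaction", {
  found_first <- 0
  reps <- 10
  for (i in seq_len(reps)) {
    g <- sim_pop(n_lines = 500, n_chrom = 2, markers = 4, spacing_cM = 40,
                 seed = 500 + i)
    ids <- g$snps$snp_id
    pair <- c(ids[1], ids[6])
    tm <- true_model(mu = 0,
                     epistatic = data.frame(snp_i = pair[1], snp_j = pair[2],
                                            effect = 2.5),
                     residual_sd = 4, n_env = 2, n_rep = 2)
    ph <- simulate_phenotypes(g, tm, seed = 600 + i)
    univ <- as.data.frame(t(utils::combn(ids, 2)), stringsAsFactors = FALSE)
    names(univ) <- c("snp_i", "snp_j")
    sc <- scan_epistasis(g, ph, "trait", character(0), univ)
    best <- sc[which.max(sc$F), ]
    if (setequal(c(best$snp_i, best$snp_j), pair)) found_first <- found_first + 1
  }
  expect_gte(found_first / reps, 0.9)
})

test_that("pairs with a monomorphic member or collinear product are skipped", {
  g <- toy_geno(cbind(a = c(1, 1, -1, -1, 1, -1),
                      b = rep(1, 6),
                      c = c(1, 1, -1, -1, 1, -1)))
  ph <- toy_pheno(rnorm(6), rownames(g$calls))
  sc <- scan_epistasis(g, ph, "t", character(0),
                       data.frame(snp_i = c("a", "a"), snp_j = c("b", "c")))
  expect_true(is.na(sc$F[1]))  # product collinear with marginal a
  expect_true(is.na(sc$F[2]))  # duplicate column: product constant
  expect_equal(attr(sc, "n_skipped"), 2L)
})

test_that("stepwise selects a lone significant candidate and breaks ties", {
  g <- sim_pop(n_lines = 100, n_chrom = 1, markers = 5, spacing_cM = 40,
               seed = 9)
  qts <- g$snps$snp_id[3]
  tm <- true_model(mu = 0, additive = setNames(2, qts), residual_sd = 2)
  ph <- simulate_phenotypes(g, tm, seed = 10)
  sc <- scan_additive(g, ph, "trait")
  cand <- sc[sc$snp_id == qts, ]
  sel <- stepwise_select(cand, NULL, g, ph, "trait")
  expect_equal(sel$loci, qts)

  # duplicate column (r2 = 1): exactly one survives
  g2 <- toy_geno(cbind(dup1 = g$calls[, 3], dup2 = g$calls[, 3]),
                 pos = c(100, 200))
  sc2 <- scan_additive(g2, ph, "trait")
  sel2 <- stepwise_select(sc2, NULL, g2, ph, "trait")
  expect_equal(length(sel2$loci), 1)
  expect_equal(sel2$loci, "dup1")  # tie broken by position
})

test_that("stepwise recovers a planted three-QTS architecture", {
  reps <- 25
  exact <- 0
  for (i in seq_len(reps)) {
    g <- sim_pop(n_lines = 138, n_chrom = 3, markers = 5, spacing_cM = 50,
                 seed = 700 + i)
    ids <- g$snps$snp_id
    qts <- ids[c(3, 8, 13)]
    tm <- true_model(mu = 80, additive = setNames(c(2.6, 3.0, 2.5), qts),
                     env_sd = 2, residual_sd = 8)
    ph <- simulate_phenotypes(g, tm, seed = 800 + i)
    sc <- scan_additive(g, ph, "trait")
    thr <- permutation_threshold(g, ph, "trait", n_permutations = 200,
                                 seed = 900 + i)
    cand <- sc[!is.na(sc$F) & sc$F > thr, ]
    sel <- stepwise_select(cand, NULL, g, ph, "trait")
    if (setequal(sel$loci, qts)) exact <- exact + 1
  }
  expect_gte(exact / reps, 0.8)
})

test_that("the Gibbs fit recovers a noise-free model almost exactly", {
  g <- sim_pop(n_lines = 100, n_chrom = 3, markers = 4, seed = 11)
  loci <- g$snps$snp_id[c(2, 6)]
  tm <- true_model(mu = 10, additive = setNames(c(2, -1.5), loci),
                   residual_sd = 0)
  ph <- simulate_phenotypes(g, tm, seed = 12)
  fit <- fit_full_model(g, ph, "trait", list(loci = loci),
                        mcmc_iter = 2000, seed = 13)
  expect_equal(fit$mu, 10, tolerance = 1e-3)
  expect_equal(fit$effects$estimate, c(2, -1.5), tolerance = 1e-3)
})

test_that("the Gibbs fit is bit-identical under a fixed seed", {
  g <- sim_pop(n_lines = 80, n_chrom = 2, markers = 4, seed = 14)
  loci <- g$snps$snp_id[c(1, 5)]
  tm <- true_model(mu = 5, additive = setNames(c(1.5, -1), loci),
                   env_sd = 1, residual_sd = 3)
  ph <- simulate_phenotypes(g, tm, seed = 15)
  f1 <- fit_full_model(g, ph, "trait", list(loci = loci),
                       mcmc_iter = 1500, seed = 16)
  f2 <- fit_full_model(g, ph, "trait", list(loci = loci),
                       mcmc_iter = 1500, seed = 16)
  expect_identical(f1$effects$estimate, f2$effects$estimate)
  expect_identical(f1$varcomp, f2$varcomp)
})

test_that("collinear fixed-effect columns are pruned with a warning", {
  g <- sim_pop(n_lines = 60, n_chrom = 1, markers = 4, seed = 17)
  g2 <- toy_geno(cbind(g$calls, twin = g$calls[, 2]))
  tm <- true_model(mu = 0, additive = setNames(2, g$snps$snp_id[2]),
                   residual_sd = 2)
  ph <- simulate_phenotypes(g2, tm, seed = 18)
  expect_warning(
    fit <- fit_full_model(g2, ph, "trait",
                          list(loci = c(g$snps$snp_id[2], "twin")),
                          mcmc_iter = 1000, seed = 19),
    "pruned")
  expect_equal(nrow(fit$effects), 1)
})

test_that("heritability follows a^2 var(x) / V_P with summed total", {
  g <- sim_pop(n_lines = 120, n_chrom = 2, markers = 4, seed = 20)
  loci <- g$snps$snp_id[c(2, 7)]
  tm <- true_model(mu = 50, additive = setNames(c(2.5, -2), loci),
                   env_sd = 2, residual_sd = 6)
  ph <- simulate_phenotypes(g, tm, seed = 21)
  fit <- fit_full_model(g, ph, "trait", list(loci = loci),
                        mcmc_iter = 2000, seed = 22)
  cm <- aggregate(value ~ line_id + environment, ph, mean)
  vp <- var(cm$value)
  expect_equal(fit$vp, vp)
  X <- impute_calls(g)
  for (i in 1:2) {
    expect_equal(fit$effects$h2[i],
                 100 * fit$effects$estimate[i]^2 * var(X[, loci[i]]) / vp)
  }
  expect_equal(fit$total_h2, sum(fit$effects$h2))
})

test_that("without simulated G-by-E the interaction variances stay small", {
  g <- sim_pop(n_lines = 138, n_chrom = 2, markers = 5, spacing_cM = 40,
               seed = 23)
  loci <- g$snps$snp_id[c(2, 8)]
  tm <- true_model(mu = 80, additive = setNames(c(2.6, -2.4), loci),
                   env_sd = 3, residual_sd = 8)
  ph <- simulate_phenotypes(g, tm, seed = 24)
  fit <- fit_full_model(g, ph, "trait", list(loci = loci),
                        mcmc_iter = 6000, seed = 25)
  expect_lt(fit$varcomp["ae"], 0.1 * fit$varcomp["residual"])
})

test_that("fit methods expose coefficients, predictions and residuals", {
  g <- sim_pop(n_lines = 60, n_chrom = 1, markers = 4, seed = 26)
  loci <- g$snps$snp_id[2]
  tm <- true_model(mu = 10, additive = setNames(2, loci), env_sd = 1,
                   residual_sd = 2)
  ph <- simulate_phenotypes(g, tm, seed = 27)
  fit <- fit_full_model(g, ph, "trait", list(loci = loci),
                        mcmc_iter = 1500, seed = 28)
  cf <- coef(fit)
  expect_equal(unname(cf[1]), fit$mu)
  pv <- predict(fit, g, type = "phenotype")
  expect_equal(length(pv), 60)
  expect_equal(unname(pv - predict(fit, g, type = "genetic")),
               rep(fit$mu, 60))
  expect_equal(length(residuals(fit)), nrow(ph))
  expect_lt(sd(residuals(fit)), sd(ph$value))
  sims <- simulate(fit, nsim = 2, seed = 29, geno = g)
  expect_equal(length(sims), 2)
  expect_equal(nrow(sims[[1]]), nrow(ph))
  expect_output(print(summary(fit)), "Variance components")
})
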