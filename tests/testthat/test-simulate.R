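test_that("markers at the same genetic position co-segregate exactly", {
  map <- genetic_map(c("m1", "m2", "m3"), rep("1", 3),
                     c(5, 5, 5), c(100, 200, 300))
  g <- simulate_ril_genotypes(map, 50, seed = 1)
  expect_identical(unname(g$calls[, 1]), unname(g$calls[, 2]))
  expect_identical(unname(g$calls[, 1]), unname(g$calls[, 3]))
})

test_that("markers on different chromosomes assort independently", {
  map <- genetic_map(c("m1", "m2"), c("1", "2"), c(0, 0), c(1, 1))
  g <- simulate_ril_genotypes(map, 5000, seed = 2)
  r2 <- cor(g$calls[, 1], g$calls[, 2])^2
  expect_lt(r2, 0.01)
})

test_that("adjacent-marker correlation matches the selfing-RIL closed form", {
  # genotype correlation for fully inbred selfing RILs: (1-2r)/(1+2r)
  r <- 0.25
  d <- -50 * log(1 - 2 * r)
  map <- genetic_map(c("m1", "m2"), c("1", "1"), c(0, d), c(1, 1000))
  g <- simulate_ril_genotypes(map, 20000, seed = 3)
  expect_equal(cor(g$calls[, 1], g$calls[, 2]),
               (1 - 2 * r) / (1 + 2 * r), tolerance = 0.02)
})

test_that("allele frequencies are near 1/2 at every locus", {
  g <- sim_pop(n_lines = 5000, n_chrom = 2, markers = 8, seed = 4)
  freq <- colMeans(g$calls == 1, na.rm = TRUE)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 5000)))
})

test_that("genotype simulation is reproducible and validates inputs", {
  map <- build_genetic_map(2, 5, 10, 1e5)
  g1 <- simulate_ril_genotypes(map, 30, seed = 9)
  g2 <- simulate_ril_genotypes(map, 30, seed = 9)
  expect_identical(g1$calls, g2$calls)
  expect_error(simulate_ril_genotypes(map[0, ], 30), "empty")
  expect_error(simulate_ril_genotypes(map, 1), "at least 2")
})

test_that("het policy and missing injection behave as configured", {
  map <- build_genetic_map(1, 6, 15, 1e5)
  # one selfing generation (F2): ~half the loci still heterozygous
  g_na <- simulate_ril_genotypes(map, 400, n_selfing_generations = 1,
                                 het_policy = "code-missing", seed = 5)
  expect_gt(mean(is.na(g_na$calls)), 0.3)
  g_hom <- simulate_ril_genotypes(map, 400, n_selfing_generations = 1,
                                  het_policy = "force-homozygous", seed = 5)
  expect_false(anyNA(g_hom$calls))
  g_miss <- simulate_ril_genotypes(map, 400, missing_rate = 0.05, seed = 6)
  expect_lt(abs(mean(is.na(g_miss$calls)) - 0.05), 0.02)
})

test_that("degenerate phenotype models reproduce exact values", {
  g <- sim_pop(n_lines = 20, n_chrom = 1, markers = 4, seed = 7)
  m0 <- true_model(mu = 7, residual_sd = 0)
  ph <- simulate_phenotypes(g, m0, seed = 1)
  expect_true(all(ph$value == 7))

  snp <- g$snps$snp_id[2]
  m1 <- true_model(mu = 10, additive = setNames(2, snp), residual_sd = 0)
  ph1 <- simulate_phenotypes(g, m1, seed = 1)
  x <- g$calls[ph1$line_id, snp]
  expect_true(all(ph1$value[x == 1] == 12))
  expect_true(all(ph1$value[x == -1] == 8))
})

test_that("environment effects are shared within environment", {
  g <- sim_pop(n_lines = 10, n_chrom = 1, markers = 3, seed = 8)
  m <- true_model(mu = 0, env_sd = 5, residual_sd = 0, n_env = 3, n_rep = 2)
  ph <- simulate_phenotypes(g, m, seed = 2)
  per_env <- tapply(ph$value, ph$environment, function(v) length(unique(v)))
  expect_true(all(per_env == 1))
  expect_gt(var(tapply(ph$value, ph$environment, mean)), 0)
})

test_that("phenotypic variance follows the model decomposition", {
  # single locus a = 2, residual sd 3: var(y) ~ 4 var(x) + 9 ~ 13
  map <- build_genetic_map(1, 1, 1, 1000)
  g <- simulate_ril_genotypes(map, 20000, seed = 3)
  m <- true_model(mu = 10, additive = c(c1_m1 = 2), residual_sd = 3,
                  n_env = 1, n_rep = 1)
  ph <- simulate_phenotypes(g, m, seed = 4)
  expect_equal(var(ph$value), 13, tolerance = 0.3)
})

test_that("phenotype simulation is seeded and validates QTS ids", {
  g <- sim_pop(n_lines = 12, n_chrom = 1, markers = 3, seed = 10)
  m <- true_model(mu = 1, additive = setNames(1, g$snps$snp_id[1]),
                  residual_sd = 2)
  expect_identical(simulate_phenotypes(g, m, seed = 5),
                   simulate_phenotypes(g, m, seed = 5))
  bad <- true_model(mu = 1, additive = c(nope = 1))
  expect_error(simulate_phenotypes(g, bad), "unknown QTS")
})

test_that("epistatic terms enter through the coded product", {
  g <- toy_geno(cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1)))
  m <- true_model(mu = 0,
                  epistatic = data.frame(snp_i = "a", snp_j = "b",
                                         effect = 1.5),
                  residual_sd = 0, n_env = 1, n_rep = 1)
  ph <- simulate_phenotypes(g, m, seed = 1)
  prod <- g$calls[ph$line_id, "a"] * g$calls[ph$line_id, "b"]
  expect_equal(ph$value, unname(1.5 * prod))
  expect_error(true_model(epistatic = data.frame(snp_i = "a", snp_j = "a",
                                                 effect = 1)),
               "distinct")
})

test_that("phenotype and model round-trip through their file formats", {
  g <- sim_pop(n_lines = 8, n_chrom = 1, markers = 3, seed = 11)
  m <- true_model(mu = 3, additive = setNames(1.1, g$snps$snp_id[1]),
                  env_sd = 1, residual_sd = 2)
  ph <- simulate_phenotypes(g, m, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_phenotypes_csv(ph, f)
  ph2 <- read_phenotypes_csv(f)
  expect_equal(ph2$value, ph$value, tolerance = 1e-12)
  fy <- tempfile(fileext = ".yaml")
  write_true_model(m, fy)
  y <- yaml::read_yaml(fy)
  expect_equal(y$mu, 3)
  expect_equal(y$additive[[g$snps$snp_id[1]]], 1.1)
})
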