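test_that("VCF writing and reading round-trip the parental coding", {
  g <- sim_pop(n_lines = 10, n_chrom = 2, markers = 4, seed = 1)
  g$calls[1, 2] <- NA
  f <- tempfile(fileext = ".vcf")
  write_geno_vcf(g, f)
  g2 <- read_genotypes(f, format = "vcf")
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$snps$snp_id, g$snps$snp_id)
  expect_equal(g2$snps$pos, g$snps$pos)
})

test_that("VCF calls are coded against the paternal allele", {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", "L3", sep = "\t"),
    paste("chr1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "1/1", "./.", sep = "\t"),
    paste("chr1", "200", "snp2", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "0/0", "1/1", sep = "\t")
  )
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  g <- read_genotypes(f, format = "vcf")  # REF is paternal by default
  expect_equal(unname(g$calls[, "snp1"]), c(1, -1, NA))
  expect_equal(unname(g$calls[, "snp2"]), c(NA, 1, -1))  # het -> missing
  expect_error(read_genotypes(f, format = "vcf", het_policy = "error"),
               "heterozygous")
  gm <- read_genotypes(f, format = "vcf", parent_assignment = "ref-maternal")
  expect_equal(unname(gm$calls[, "snp1"]), c(-1, 1, NA))
})

test_that("multiallelic VCF records are rejected with their rows", {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", sep = "\t"),
    paste("chr1", "100", "bad", "A", "T,G", ".", "PASS", ".", "GT",
          "0/0", "1/1", sep = "\t")
  )
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  expect_error(read_genotypes(f, format = "vcf"), "multiallelic")
})

test_that("coded TSV round-trips", {
  g <- sim_pop(n_lines = 6, n_chrom = 1, markers = 5, seed = 2)
  g$calls[2, 3] <- NA
  f <- tempfile(fileext = ".tsv")
  write_geno_tsv(g, f)
  g2 <- read_genotypes(f, format = "tsv")
  expect_equal(g2$calls, g$calls)
  expect_equal(g2$snps$chrom, g$snps$chrom)
})

test_that("missing-rate filter uses a strict 5% threshold", {
  # 138 lines: 7 missing (5.07%) is excluded, 6 missing (4.35%) retained
  g <- count_geno(list(c(131, 0), c(66, 66), c(69, 69)), n_lines = 138)
  res <- filter_missing_rate(g, 0.05)
  expect_equal(res$geno$snps$snp_id, c("s2", "s3"))
  expect_equal(res$report$removed_ids, "s1")
  g_none <- count_geno(list(c(69, 69), c(70, 68)), n_lines = 138)
  expect_equal(ncol(filter_missing_rate(g_none)$geno$calls), 2)
})

test_that("segregation filter applies the 1:1 Pearson chi-square at 1 df", {
  g <- count_geno(list(c(69, 69), c(50, 88), c(60, 78)), n_lines = 138)
  res <- filter_segregation_distortion(g, alpha = 0.01)
  # chi-square: 0, 10.46 (> 6.635, removed), 2.35 (retained)
  expect_equal(unname(res$report$chisq),
               c(0, (50 - 69)^2 / 69 + (88 - 69)^2 / 69,
                 (60 - 69)^2 / 69 + (78 - 69)^2 / 69))
  expect_equal(res$geno$snps$snp_id, c("s1", "s3"))
  expect_equal(res$report$removed_ids, "s2")
})

test_that("a SNP with zero informative calls is removed and flagged", {
  g <- count_geno(list(c(0, 0), c(69, 69)), n_lines = 138)
  res <- filter_segregation_distortion(g)
  expect_equal(res$geno$snps$snp_id, "s2")
  expect_equal(res$report$no_calls_ids, "s1")
})

test_that("MAF filter thresholds on non-missing frequency", {
  g <- count_geno(list(c(20, 118), c(60, 78)), n_lines = 138)
  res <- filter_maf(g, min_maf = 0.39)
  expect_equal(res$geno$snps$snp_id, "s2")  # MAF 0.145 out, 0.435 in
  expect_equal(ncol(filter_maf(g, min_maf = 0)$geno$calls), 2)  # identity
})

test_that("filters are idempotent and remove exactly the planted violations", {
  set.seed(42)
  calls <- cbind(replicate(8, sample(c(rep(1, 70), rep(-1, 68)))),
                 c(sample(c(rep(1, 60), rep(-1, 60))), rep(NA, 18)),
                 sample(c(rep(1, 115), rep(-1, 23))))
  planted <- c("bad_miss", "bad_seg")
  colnames(calls) <- c(paste0("good", 1:8), planted)
  g <- toy_geno(calls)

  res <- run_qc(g)
  expect_setequal(setdiff(g$snps$snp_id, res$geno$snps$snp_id), planted)
  again <- run_qc(res$geno)
  expect_identical(again$geno$calls, res$geno$calls)
})

test_that("parent swap negates calls and is an involution", {
  g <- sim_pop(n_lines = 12, n_chrom = 1, markers = 6, seed = 3)
  g$calls[3, 2] <- NA
  sw <- swap_parents(g)
  expect_equal(sw$calls, -g$calls)
  expect_equal(sw$snps$paternal, g$snps$maternal)
  expect_equal(swap_parents(sw)$calls, g$calls)
})

test_that("QC reports are written as TSV and JSON", {
  g <- count_geno(list(c(69, 69), c(50, 88)), n_lines = 138)
  res <- run_qc(g)
  d <- tempfile()
  write_qc_report(res$reports, d)
  expect_true(file.exists(file.path(d, "qc_summary.tsv")))
  js <- jsonlite::read_json(file.path(d, "qc_summary.json"))
  expect_equal(js$summary[[2]]$n_removed, 1)
})
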