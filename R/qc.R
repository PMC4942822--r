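#' SNP quality-control filters for a biparental RIL panel
#'
#' Three per-SNP filters, each returning the filtered genotype matrix plus a
#' report of what was removed:
#'
#' * `filter_missing_rate()` drops SNPs whose missing-call fraction is
#'   *strictly greater* than `max_rate` (default 5%).
#' * `filter_segregation_distortion()` drops SNPs whose +1/-1 counts
#'   deviate from the 1:1 expectation of a biparental RIL by a Pearson
#'   chi-square goodness-of-fit test (1 df, no continuity correction) at
#'   significance level `alpha` (default 0.01). SNPs with zero non-missing
#'   calls are removed and flagged.
#' * `filter_maf()` drops SNPs whose minor allele frequency over
#'   non-missing calls is below `min_maf`. In a RIL panel MAF is a reported
#'   property rather than a routine filter, so the pipeline leaves it off
#'   by default.
#'
#' @param geno A [ril_geno()].
#' @param max_rate Maximum tolerated missing fraction (default 0.05).
#' @param alpha Significance level of the segregation test (default 0.01).
#' @param min_maf Minimum minor allele frequency.
#' @return A list with elements `geno` (filtered [ril_geno()], SNP order
#'   preserved) and `report` (a `qc_report`).
#' @name qc_filters
NULL

qc_result <- function(geno, keep, filter, extra = list()) {
  removed <- geno$snps$snp_id[!keep]
  out <- ril_geno(geno$calls[, keep, drop = FALSE],
                  geno$snps[keep, , drop = FALSE], rownames(geno$calls))
  report <- structure(c(list(
    filter = filter,
    n_input = ncol(geno$calls),
    n_removed = length(removed),
    n_retained = sum(keep),
    removed_ids = removed
  ), extra), class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC filter '%s': %d SNPs in, %d removed, %d retained\n",
              x$filter, x$n_input, x$n_removed, x$n_retained))
  invisible(x)
}

#' @rdname qc_filters
#' @export
filter_missing_rate <- function(geno, max_rate = 0.05) {
  stopifnot(max_rate >= 0, max_rate <= 1)
  rate <- colMeans(is.na(geno$calls))
  qc_result(geno, rate <= max_rate, "missing_rate",
            list(max_rate = max_rate))
}

#' @rdname qc_filters
#' @export
filter_segregation_distortion <- function(geno, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  n_pat <- colSums(geno$calls == 1, na.rm = TRUE)
  n_mat <- colSums(geno$calls == -1, na.rm = TRUE)
  n <- n_pat + n_mat
  # Pearson GOF against 1:1 on non-missing calls, 1 df
  chisq <- ifelse(n > 0, (n_pat - n / 2)^2 / (n / 2) + (n_mat - n / 2)^2 / (n / 2),
                  Inf)
  crit <- stats::qchisq(1 - alpha, df = 1)
  keep <- chisq <= crit & n > 0
  qc_result(geno, keep, "segregation_distortion",
            list(alpha = alpha, critical_value = crit, chisq = chisq,
                 no_calls_ids = geno$snps$snp_id[n == 0]))
}

#' @rdname qc_filters
#' @export
filter_maf <- function(geno, min_maf = 0) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  n_pat <- colSums(geno$calls == 1, na.rm = TRUE)
  n <- n_pat + colSums(geno$calls == -1, na.rm = TRUE)
  p <- ifelse(n > 0, n_pat / n, NA)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf
  if (min_maf == 0) keep <- keep | is.na(maf)  # identity when filter is off
  qc_result(geno, keep, "maf", list(min_maf = min_maf))
}

#' Run the standard QC sequence
#'
#' Applies the missing-rate filter, then the 1:1 segregation filter, then
#' (optionally) the MAF filter — the order used throughout the pipeline.
#'
#' @param geno A [ril_geno()].
#' @param max_missing Missing-rate threshold (default 0.05).
#' @param seg_alpha Segregation-test alpha (default 0.01).
#' @param min_maf MAF threshold; `NULL` (default) skips the MAF filter.
#' @return List with `geno` (filtered) and `reports` (list of `qc_report`s).
#' @export
run_qc <- function(geno, max_missing = 0.05, seg_alpha = 0.01, min_maf = NULL) {
  r1 <- filter_missing_rate(geno, max_missing)
  r2 <- filter_segregation_distortion(r1$geno, seg_alpha)
  reports <- list(missing = r1$report, segregation = r2$report)
  out <- r2$geno
  if (!is.null(min_maf)) {
    r3 <- filter_maf(out, min_maf)
    out <- r3$geno
    reports$maf <- r3$report
  }
  list(geno = out, reports = reports)
}

#' Write QC reports as TSV + JSON summary
#' @param reports List of `qc_report` objects (see [run_qc()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(filter = r$filter, n_input = r$n_input,
               n_removed = r$n_removed, n_retained = r$n_retained,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file.path(dir, "qc_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  removed <- lapply(reports, function(r) r$removed_ids)
  jsonlite::write_json(list(summary = tab, removed = removed),
                       file.path(dir, "qc_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
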