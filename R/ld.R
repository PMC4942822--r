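#' Pairwise linkage disequilibrium within chromosomes
#'
#' For every pair of SNPs on the same chromosome separated by at most
#' `max_dist_bp`, computes r^2 as the squared Pearson correlation of the
#' +/-1 codes over the lines that are non-missing at both SNPs. Pairs with
#' a monomorphic member (zero variance over the shared lines) are skipped
#' and counted.
#'
#' @param geno A [ril_geno()].
#' @param max_dist_bp Maximum pair distance in bp (default 1 Mb).
#' @return An object of class `ld_pairs`: a data frame with columns
#'   `snp_i`, `snp_j`, `dist_bp`, `r2`, with attribute `n_skipped`
#'   (monomorphic pairs).
#' @export
pairwise_r2 <- function(geno, max_dist_bp = 1e6) {
  res <- list()
  n_skipped <- 0L
  for (ch in unique(geno$snps$chrom)) {
    idx <- which(geno$snps$chrom == ch)
    if (length(idx) < 2) next
    pos <- geno$snps$pos[idx]
    x <- geno$calls[, idx, drop = FALSE]
    cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- abs(pos[pr[, 2]] - pos[pr[, 1]])
    keep <- d <= max_dist_bp
    pr <- pr[keep, , drop = FALSE]
    d <- d[keep]
    r <- cc[pr]
    mono <- is.na(r)
    n_skipped <- n_skipped + sum(mono)
    res[[ch]] <- data.frame(
      snp_i = geno$snps$snp_id[idx[pr[!mono, 1]]],
      snp_j = geno$snps$snp_id[idx[pr[!mono, 2]]],
      dist_bp = d[!mono],
      r2 = r[!mono]^2,
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) stop("need at least 2 SNPs on some chromosome")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, n_skipped = n_skipped, class = c("ld_pairs", "data.frame"))
}

#' Binned LD decay curve
#'
#' Pools pairs (already restricted to within-chromosome comparisons) and
#' averages r^2 in half-open distance bins \[k w, (k+1) w) of width `w`
#' (default 1 kb). A distance exactly on a boundary belongs to the upper
#' bin. Only non-empty bins are reported.
#'
#' @param pairs An `ld_pairs` object from [pairwise_r2()].
#' @param bin_width_bp Bin width in bp (default 1000).
#' @return An object of class `ld_decay`: data frame with columns
#'   `bin_start_bp`, `mean_r2`, `n_pairs`, ordered by distance.
#' @export
ld_decay_curve <- function(pairs, bin_width_bp = 1000) {
  if (!nrow(pairs)) stop("no LD pairs to bin")
  bin <- floor(pairs$dist_bp / bin_width_bp)
  agg <- stats::aggregate(pairs$r2, by = list(bin = bin),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(bin_start_bp = agg$bin * bin_width_bp,
                    mean_r2 = agg$x[, 1],
                    n_pairs = as.integer(agg$x[, 2]))
  out <- out[order(out$bin_start_bp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bin_width_bp = bin_width_bp,
            class = c("ld_decay", "data.frame"))
}

#' Half-maximum LD decay distance
#'
#' The start distance of the first bin (in increasing distance) whose mean
#' r^2 is at most half the maximum bin mean of the empirical curve. If no
#' bin ever falls to half-maximum, `NA` is returned with attribute
#' `defined = FALSE`.
#'
#' @param curve An `ld_decay` object from [ld_decay_curve()].
#' @return Distance in bp (scalar), or `NA` flagged with
#'   `attr(, "defined") = FALSE`.
#' @export
half_decay_distance <- function(curve) {
  if (!nrow(curve)) stop("empty decay curve")
  half <- max(curve$mean_r2) / 2
  hit <- which(curve$mean_r2 <= half)
  if (!length(hit)) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(curve$bin_start_bp[hit[1]], defined = TRUE)
}

#' Write LD tables
#' @param pairs `ld_pairs` object; `curve` an `ld_decay` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_pairs
#' @param curve An `ld_decay` object.
#' @export
write_ld_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot an LD decay curve
#' @param x An `ld_decay` object.
#' @param ... Passed to [plot()].
#' @export
plot.ld_decay <- function(x, ...) {
  plot(x$bin_start_bp / 1000, x$mean_r2, type = "l",
       xlab = "distance (kb)", ylab = expression(mean ~ r^2), ...)
  graphics::abline(h = max(x$mean_r2) / 2, lty = 2, col = "grey")
  invisible(x)
}
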