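#' F-statistic candidate screening before mixed-model mapping
#'
#' A fast pre-filter that reduces a large SNP set to the `top_m`
#' highest-scoring candidates per trait and environment before the
#' (expensive) mixed-model scan — the same role the original analysis
#' delegates to a GPU-accelerated multifactor screen, here implemented as
#' plain one-way/interaction F-statistic ranking so that screening with
#' `top_m = n_snps` is exactly a no-op (a pure filter: the downstream
#' mapping result is unchanged).
#'
#' `marginal_screen()` scores each SNP by the one-way F statistic of the
#' within-environment line means on the +/-1 codes; monomorphic SNPs are
#' excluded. `pairwise_screen()` scores each SNP pair by the F statistic
#' of the product term added to a model with both marginal terms.
#' `merge_candidates()` unions candidate sets across traits/environments,
#' preserving provenance.
#'
#' @param geno A [ril_geno()].
#' @param pheno Phenotype table.
#' @param trait Trait name.
#' @param environment Environment to screen in (its line means are used).
#' @param top_m Number of candidates retained (default 1000).
#' @return A `candidate_set`: list with `snps` (data frame `snp_id`,
#'   `score`, `trait`, `environment`) and `pairs` (data frame `snp_i`,
#'   `snp_j`, `score`, `trait`, `environment`).
#' @name screening
NULL

line_means_env <- function(pheno, trait, environment) {
  ph <- pheno[pheno$trait == trait & pheno$environment == environment, ,
              drop = FALSE]
  if (!nrow(ph)) stop("no observations for trait/environment: ",
                      trait, "/", environment)
  stats::aggregate(value ~ line_id, data = ph, FUN = mean)
}

candidate_set <- function(snps = NULL, pairs = NULL) {
  if (is.null(snps)) {
    snps <- data.frame(snp_id = character(0), score = numeric(0),
                       trait = character(0), environment = character(0),
                       stringsAsFactors = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- data.frame(snp_i = character(0), snp_j = character(0),
                        score = numeric(0), trait = character(0),
                        environment = character(0), stringsAsFactors = FALSE)
  }
  structure(list(snps = snps, pairs = pairs), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", nrow(x$snps), "SNPs,", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' @rdname screening
#' @export
marginal_screen <- function(geno, pheno, trait, environment, top_m = 1000) {
  lm_df <- line_means_env(pheno, trait, environment)
  li <- match(lm_df$line_id, rownames(geno$calls))
  if (anyNA(li)) stop("phenotyped lines absent from genotype matrix")
  X <- impute_calls(geno)[li, , drop = FALSE]
  y <- lm_df$value
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(yc^2) < 1e-12) warning("phenotype is constant; all scores 0")
  f <- scan_f_stats(Xc, yc, dfres = n - 2L)
  keep <- which(!is.na(f))
  ord <- keep[order(-f[keep])]
  ord <- utils::head(ord, top_m)
  candidate_set(snps = data.frame(
    snp_id = geno$snps$snp_id[ord], score = f[ord],
    trait = trait, environment = environment, stringsAsFactors = FALSE))
}

#' @rdname screening
#' @param universe Optional character vector of SNP ids restricting the
#'   pair universe (default: the top 2000 marginal SNPs).
#' @export
pairwise_screen <- function(geno, pheno, trait, environment, top_m = 1000,
                            universe = NULL) {
  if (is.null(universe)) {
    ms <- marginal_screen(geno, pheno, trait, environment,
                          top_m = min(2000, ncol(geno$calls)))
    universe <- ms$snps$snp_id
  }
  universe <- universe[order(match(universe, geno$snps$snp_id))]
  if (length(universe) < 2) stop("pair universe needs at least 2 SNPs")
  lm_df <- line_means_env(pheno, trait, environment)
  li <- match(lm_df$line_id, rownames(geno$calls))
  X <- impute_calls(geno)[li, universe, drop = FALSE]
  y <- lm_df$value
  n <- length(y)
  cmb <- utils::combn(length(universe), 2)
  nP <- ncol(cmb)
  f <- rep(NA_real_, nP)
  for (k in seq_len(nP)) {
    xi <- X[, cmb[1, k]]
    xj <- X[, cmb[2, k]]
    if (abs(suppressWarnings(stats::cor(xi, xj))) >= 1 - 1e-12 ||
        stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # collinear pair
    M <- cbind(1, xi, xj)
    qM <- qr(M)
    pres <- qr.resid(qM, xi * xj)
    if (sum(pres^2) < 1e-10) next
    yres <- qr.resid(qM, y)
    dfr <- n - qM$rank - 1L
    rho2 <- sum(pres * yres)^2 / (sum(pres^2) * sum(yres^2))
    f[k] <- dfr * rho2 / (1 - rho2)
  }
  keep <- which(!is.na(f))
  ord <- keep[order(-f[keep])]
  ord <- utils::head(ord, top_m)
  candidate_set(pairs = data.frame(
    snp_i = universe[cmb[1, ord]], snp_j = universe[cmb[2, ord]],
    score = f[ord], trait = trait, environment = environment,
    stringsAsFactors = FALSE))
}

#' @rdname screening
#' @param sets List of `candidate_set` objects to union.
#' @export
merge_candidates <- function(sets) {
  snps <- do.call(rbind, lapply(sets, function(s) s$snps))
  pairs <- do.call(rbind, lapply(sets, function(s) s$pairs))
  if (!is.null(pairs) && nrow(pairs)) {
    key <- paste(pmin(pairs$snp_i, pairs$snp_j),
                 pmax(pairs$snp_i, pairs$snp_j))
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  out <- candidate_set(snps = snps, pairs = pairs)
  out$snps <- out$snps[!duplicated(out$snps$snp_id), , drop = FALSE]
  rownames(out$snps) <- rownames(out$pairs) <- NULL
  out
}

#' Write a candidate set as TSV
#' @param cand A `candidate_set`.
#' @param path Output path prefix; writes `<path>.snps.tsv` and, when
#'   pairs are present, `<path>.pairs.tsv`.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cand, path) {
  utils::write.table(cand$snps, paste0(path, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(cand$pairs)) {
    utils::write.table(cand$pairs, paste0(path, ".pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
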