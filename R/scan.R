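# Environment-block dummy columns (reference coding, empty for one level).
env_design <- function(env) {
  if (nlevels(env) <= 1) return(matrix(numeric(0), nrow = length(env), ncol = 0))
  stats::model.matrix(~ env, data.frame(env = env))[, -1, drop = FALSE]
}

# Shared scan preparation: replicate-level response and within-environment
# centered design. With environment as the only nuisance fixed block, the
# partial F for a SNP reduces to F = dfres * rho^2 / (1 - rho^2) where rho is
# the correlation of the environment-centered response and genotype columns.
prep_scan <- function(geno, pheno, trait) {
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(ph)) stop("trait not present in phenotype table: ", trait)
  li <- match(ph$line_id, rownames(geno$calls))
  if (anyNA(li)) {
    stop("phenotyped lines absent from genotype matrix: ",
         paste(unique(ph$line_id[is.na(li)]), collapse = ", "))
  }
  env <- factor(ph$environment)
  y <- ph$value
  X <- impute_calls(geno)
  Xobs <- X[li, , drop = FALSE]
  cnt <- tabulate(env)
  env_i <- as.integer(env)
  Xc <- Xobs - (rowsum(Xobs, env_i) / cnt)[env_i, , drop = FALSE]
  yc <- y - stats::ave(y, env_i)
  list(ph = ph, env = env, env_i = env_i, line_idx = li, X = X,
       Xobs = Xobs, Xc = Xc, y = y, yc = yc,
       dfres = length(y) - nlevels(env) - 1L)
}

# Vectorized per-column partial F statistics given centered design/response.
scan_f_stats <- function(Xc, yc, dfres, eps = 1e-12) {
  Sxx <- colSums(Xc^2)
  Syy <- sum(yc^2)
  if (Syy < eps) {
    f <- rep(0, length(Sxx))
    f[Sxx < eps] <- NA_real_
    return(f)
  }
  Sxy <- drop(crossprod(Xc, yc))
  r2 <- Sxy^2 / (Sxx * Syy)
  f <- dfres * r2 / (1 - r2)
  f[Sxx < eps] <- NA_real_              # monomorphic: no test
  f[!is.na(r2) & r2 >= 1 - eps] <- Inf  # zero-residual sentinel
  f
}

#' One-dimensional additive genome scan
#'
#' For every SNP, the F statistic of the additive term in the fixed-effects
#' model y = mu + environment block + a x + error, fitted on replicate-level
#' observations with per-SNP mean-imputed genotypes. Monomorphic SNPs get
#' `NA`; a zero-residual (perfect) fit is reported as `Inf`. A constant
#' phenotype yields F = 0 everywhere with a warning.
#'
#' @param geno A [ril_geno()].
#' @param pheno Replicated phenotype table (see [simulate_phenotypes()]).
#' @param trait Trait name to scan.
#' @return A `qts_scan` data frame: `snp_id`, `chrom`, `pos`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
scan_additive <- function(geno, pheno, trait) {
  pr <- prep_scan(geno, pheno, trait)
  if (sum(pr$yc^2) < 1e-12) warning("phenotype is constant; all F = 0")
  f <- scan_f_stats(pr$Xc, pr$yc, pr$dfres)
  out <- data.frame(snp_id = geno$snps$snp_id, chrom = geno$snps$chrom,
                    pos = geno$snps$pos, F = f,
                    df1 = 1L, df2 = pr$dfres,
                    p = stats::pf(f, 1, pr$dfres, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("qts_scan", "data.frame")
  out
}

# Permute environment-centered responses by shuffling line labels within
# each environment (replicates travel with their line). Returns an
# N x n_perm matrix of permuted centered responses.
permute_within_env <- function(pr, n_perm) {
  groups <- split(seq_along(pr$y), list(pr$env_i, pr$ph$line_id), drop = TRUE)
  env_of_group <- vapply(groups, function(ix) pr$env_i[ix[1]], integer(1))
  Y <- matrix(0, nrow = length(pr$y), ncol = n_perm)
  by_env <- split(seq_along(groups), env_of_group)
  for (p in seq_len(n_perm)) {
    newy <- pr$yc
    for (ge in by_env) {
      perm <- sample(length(ge))
      for (j in seq_along(ge)) {
        src <- groups[[ge[perm[j]]]]
        dst <- groups[[ge[j]]]
        if (length(src) == length(dst)) {
          newy[dst] <- pr$yc[src]
        } else {  # unbalanced replicates: fall back to resampled assignment
          newy[dst] <- pr$yc[sample(src, length(dst), replace = TRUE)]
        }
      }
    }
    Y[, p] <- newy
  }
  Y
}

#' Permutation threshold for the experiment-wise F statistic
#'
#' For each permutation, line labels of the phenotypes are shuffled within
#' each environment (preserving environment and replicate structure), the
#' scan is rerun, and the maximum F over the scanned units is recorded;
#' the threshold F* is the empirical (1 - alpha) quantile (type-1, so
#' `alpha = 1` returns the minimum of the max-F sample) of that null
#' distribution. Non-finite per-unit F values are dropped within each
#' permutation before the maximum is taken.
#'
#' @param geno A [ril_geno()].
#' @param pheno Phenotype table.
#' @param trait Trait name.
#' @param n_permutations Number of permutations (>= 100; default 1000).
#' @param alpha Experiment-wise significance level (default 0.05).
#' @param seed Integer seed (optional).
#' @param scan_kind `"1D"` (additive scan) or `"2D"` (epistasis scan).
#' @param covariate_snps Covariate SNP ids for the 2D scan.
#' @param pair_universe Data frame `snp_i`, `snp_j` of pairs for the 2D scan.
#' @return Threshold F* (scalar) with attribute `max_f` (the permutation
#'   max-F sample).
#' @export
permutation_threshold <- function(geno, pheno, trait,
                                  n_permutations = 1000, alpha = 0.05,
                                  seed = NULL, scan_kind = c("1D", "2D"),
                                  covariate_snps = NULL, pair_universe = NULL) {
  scan_kind <- match.arg(scan_kind)
  if (n_permutations < 100) {
    stop("need at least 100 permutations for a stable threshold")
  }
  stopifnot(alpha > 0, alpha <= 1)
  pr <- prep_scan(geno, pheno, trait)
  with_seed(seed, {
    if (scan_kind == "1D") {
      Y <- permute_within_env(pr, n_permutations)
      Sxx <- colSums(pr$Xc^2)
      poly <- Sxx > 1e-12
      Sxy <- crossprod(pr$Xc[, poly, drop = FALSE], Y)  # m x P
      Syy <- colSums(Y^2)
      R2 <- sweep(Sxy^2 / Sxx[poly], 2, Syy, "/")
      Fm <- pr$dfres * R2 / (1 - R2)
      max_f <- apply(Fm, 2, function(v) {
        v <- v[is.finite(v)]
        if (length(v)) max(v) else 0
      })
    } else {
      if (is.null(pair_universe) || !nrow(pair_universe)) {
        stop("2D permutation threshold needs a pair universe")
      }
      # For each pair precompute an orthonormal basis Q of the nuisance
      # model [env block, covariates, marginals] and the unit-norm residual
      # v of the product column; then for permuted responses y the product
      # term's F needs only v'y and ||y - QQ'y||^2.
      Y <- permute_within_env(pr, n_permutations)
      N <- length(pr$y)
      B <- cbind(1, env_design(pr$env))
      if (length(covariate_snps)) {
        B <- cbind(B, pr$Xobs[, covariate_snps, drop = FALSE])
      }
      max_f <- rep(0, n_permutations)
      Ysq <- colSums(Y^2)
      for (k in seq_len(nrow(pair_universe))) {
        xi <- pr$Xobs[, pair_universe$snp_i[k]]
        xj <- pr$Xobs[, pair_universe$snp_j[k]]
        qM <- qr(cbind(B, xi, xj))
        v <- qr.resid(qM, xi * xj)
        ssv <- sum(v^2)
        if (ssv < 1e-10) next
        v <- v / sqrt(ssv)
        Q <- qr.Q(qM)[, seq_len(qM$rank), drop = FALSE]
        dfr <- N - qM$rank - 1L
        QtY <- crossprod(Q, Y)
        ss_res <- Ysq - colSums(QtY^2)
        num2 <- drop(crossprod(v, Y))^2
        rho2 <- num2 / ss_res
        fk <- dfr * rho2 / (1 - rho2)
        fk[!is.finite(fk)] <- 0
        max_f <- pmax(max_f, fk)
      }
    }
    f_star <- unname(stats::quantile(max_f, 1 - alpha, type = 1))
    structure(f_star, max_f = max_f)
  })
}

#' Two-dimensional epistasis scan
#'
#' For each SNP pair, the F statistic for the product term x_i x_j in a
#' fixed-effects model containing the environment block, all covariate SNP
#' additive terms (the step-1 hits), and the pair's two marginal terms.
#' Pairs whose product column is collinear with the rest of the model are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param geno A [ril_geno()].
#' @param pheno Phenotype table.
#' @param trait Trait name.
#' @param covariate_snps Character vector of covariate SNP ids (may be empty).
#' @param pairs Data frame with columns `snp_i`, `snp_j`.
#' @return A `qts_scan` data frame with `snp_i`, `snp_j`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
scan_epistasis <- function(geno, pheno, trait, covariate_snps = character(0),
                           pairs) {
  stopifnot(all(c("snp_i", "snp_j") %in% names(pairs)))
  pr <- prep_scan(geno, pheno, trait)
  ids <- geno$snps$snp_id
  unknown <- setdiff(unique(c(pairs$snp_i, pairs$snp_j, covariate_snps)), ids)
  if (length(unknown)) stop("unknown SNP id(s): ", paste(unknown, collapse = ", "))
  N <- length(pr$y)
  B <- cbind(1, env_design(pr$env))
  if (length(covariate_snps)) {
    B <- cbind(B, pr$Xobs[, covariate_snps, drop = FALSE])
  }
  nP <- nrow(pairs)
  f <- rep(NA_real_, nP)
  df2 <- rep(NA_integer_, nP)
  skipped <- logical(nP)
  for (k in seq_len(nP)) {
    xi <- pr$Xobs[, pairs$snp_i[k]]
    xj <- pr$Xobs[, pairs$snp_j[k]]
    M <- cbind(B, xi, xj)
    qM <- qr(M)
    prod_res <- qr.resid(qM, xi * xj)
    if (sum(prod_res^2) < 1e-10) {
      skipped[k] <- TRUE
      next
    }
    y_res <- qr.resid(qM, pr$y)
    dfr <- N - qM$rank - 1L
    rho2 <- sum(prod_res * y_res)^2 / (sum(prod_res^2) * sum(y_res^2))
    fk <- dfr * rho2 / (1 - rho2)
    if (!is.na(rho2) && rho2 >= 1 - 1e-12) fk <- Inf
    f[k] <- fk
    df2[k] <- dfr
  }
  out <- data.frame(snp_i = pairs$snp_i, snp_j = pairs$snp_j,
                    F = f, df1 = 1L, df2 = df2,
                    p = stats::pf(f, 1, df2, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(skipped)
  class(out) <- c("qts_scan", "data.frame")
  out
}
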