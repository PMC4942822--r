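# Design matrix pieces for model fitting: intercept + environment dummies,
# additive columns for loci, product columns for pairs.
base_design <- function(pr) {
  cbind(`(Intercept)` = 1, env_design(pr$env))
}

unit_columns <- function(pr, loci, pairs) {
  cols <- NULL
  marg <- unique(c(loci, pairs$snp_i, pairs$snp_j))
  if (length(marg)) {
    cols <- pr$Xobs[, marg, drop = FALSE]
  }
  if (!is.null(pairs) && nrow(pairs)) {
    prod_cols <- pr$Xobs[, pairs$snp_i, drop = FALSE] *
      pr$Xobs[, pairs$snp_j, drop = FALSE]
    colnames(prod_cols) <- paste0(pairs$snp_i, ":", pairs$snp_j)
    cols <- cbind(cols, prod_cols)
  }
  cols
}

#' Stepwise selection over candidate loci and epistatic pairs
#'
#' Forward-backward stepwise regression at the replicate level with the
#' environment block always in the model. Selection units are a single
#' locus (its additive column) or an epistatic pair (its two marginal
#' columns plus the product column, added as a block). At each forward
#' step the unit with the smallest partial-F p-value below `entry_alpha`
#' enters; backward steps remove any unit whose partial-F p-value given
#' the rest exceeds `stay_alpha`; iteration continues until stable.
#' A unit collinear with the current model (zero rank gain) can never
#' enter, so of two perfectly correlated loci exactly one is selected;
#' remaining ties go to the larger F, then the smaller chromosome and
#' position.
#'
#' @param candidates A `qts_scan` from [scan_additive()] (or any data frame
#'   with `snp_id`, `chrom`, `pos`, `F`), usually restricted to the units
#'   exceeding the permutation threshold.
#' @param candidate_pairs Optional `qts_scan` from [scan_epistasis()]
#'   (columns `snp_i`, `snp_j`, `F`).
#' @param geno A [ril_geno()].
#' @param pheno Phenotype table.
#' @param trait Trait name.
#' @param entry_alpha,stay_alpha Entry / stay significance levels
#'   (defaults 0.05).
#' @return List with `loci` (character vector of selected SNP ids),
#'   `pairs` (data frame `snp_i`, `snp_j`), and `trace` (step log).
#' @export
stepwise_select <- function(candidates, candidate_pairs = NULL,
                            geno, pheno, trait,
                            entry_alpha = 0.05, stay_alpha = 0.05) {
  if (is.null(candidates) || !nrow(candidates)) stop("no candidate units")
  pr <- prep_scan(geno, pheno, trait)
  B0 <- base_design(pr)
  N <- length(pr$y)
  cand_loci <- candidates[is.finite(candidates$F) | is.na(candidates$F), ,
                          drop = FALSE]
  cand_pairs <- if (!is.null(candidate_pairs) && nrow(candidate_pairs)) {
    candidate_pairs
  } else {
    data.frame(snp_i = character(0), snp_j = character(0), F = numeric(0),
               stringsAsFactors = FALSE)
  }

  units <- c(
    lapply(seq_len(nrow(cand_loci)), function(i) {
      list(kind = "locus", id = cand_loci$snp_id[i],
           scan_f = cand_loci$F[i],
           chrom = cand_loci$chrom[i], pos = cand_loci$pos[i])
    }),
    lapply(seq_len(nrow(cand_pairs)), function(i) {
      si <- cand_pairs$snp_i[i]
      ki <- match(si, geno$snps$snp_id)
      list(kind = "pair", id = paste0(si, ":", cand_pairs$snp_j[i]),
           snp_i = si, snp_j = cand_pairs$snp_j[i],
           scan_f = if ("F" %in% names(cand_pairs)) cand_pairs$F[i] else NA,
           chrom = geno$snps$chrom[ki], pos = geno$snps$pos[ki])
    })
  )
  in_model <- logical(length(units))

  design_for <- function(sel) {
    loci <- vapply(units[sel], function(u) if (u$kind == "locus") u$id else NA_character_,
                   character(1))
    loci <- loci[!is.na(loci)]
    pl <- units[sel][vapply(units[sel], function(u) u$kind == "pair", logical(1))]
    pairs <- data.frame(snp_i = vapply(pl, `[[`, "", "snp_i"),
                        snp_j = vapply(pl, `[[`, "", "snp_j"),
                        stringsAsFactors = FALSE)
    uc <- unit_columns(pr, loci, pairs)
    if (is.null(uc)) B0 else cbind(B0, uc)
  }

  partial_f <- function(sel_without, sel_with) {
    D0 <- design_for(sel_without)
    D1 <- design_for(sel_with)
    q0 <- qr(D0); q1 <- qr(D1)
    dfn <- q1$rank - q0$rank
    if (dfn <= 0) return(c(f = NA_real_, p = 1))
    rss0 <- sum(qr.resid(q0, pr$y)^2)
    rss1 <- sum(qr.resid(q1, pr$y)^2)
    dfe <- N - q1$rank
    if (dfe <= 0) return(c(f = NA_real_, p = 1))
    if (rss1 < 1e-12) return(c(f = Inf, p = 0))
    f <- ((rss0 - rss1) / dfn) / (rss1 / dfe)
    c(f = f, p = stats::pf(f, dfn, dfe, lower.tail = FALSE))
  }

  trace <- list()
  for (iter in seq_len(100L)) {
    changed <- FALSE
    # forward
    out_idx <- which(!in_model)
    if (length(out_idx)) {
      stats_in <- t(vapply(out_idx, function(i) {
        sel <- in_model; sel[i] <- TRUE
        partial_f(in_model, sel)
      }, numeric(2)))
      pvals <- stats_in[, "p"]
      if (any(pvals < entry_alpha)) {
        best <- order(pvals, -stats_in[, "f"],
                      vapply(units[out_idx], function(u) u$chrom, character(1)),
                      vapply(units[out_idx], function(u) u$pos, numeric(1)))[1]
        pick <- out_idx[best]
        in_model[pick] <- TRUE
        changed <- TRUE
        trace[[length(trace) + 1]] <- list(step = "add", unit = units[[pick]]$id,
                                           p = pvals[best])
      }
    }
    # backward
    sel_idx <- which(in_model)
    if (length(sel_idx) > 1 || (length(sel_idx) == 1 && !changed)) {
      pv <- vapply(sel_idx, function(i) {
        sel <- in_model; sel[i] <- FALSE
        partial_f(sel, in_model)[["p"]]
      }, numeric(1))
      worst <- which.max(pv)
      if (length(pv) && pv[worst] > stay_alpha) {
        drop_i <- sel_idx[worst]
        in_model[drop_i] <- FALSE
        changed <- TRUE
        trace[[length(trace) + 1]] <- list(step = "drop",
                                           unit = units[[drop_i]]$id,
                                           p = pv[worst])
      }
    }
    if (!changed) break
  }

  sel <- units[in_model]
  loci <- vapply(sel[vapply(sel, function(u) u$kind == "locus", logical(1))],
                 `[[`, "", "id")
  pl <- sel[vapply(sel, function(u) u$kind == "pair", logical(1))]
  pairs <- data.frame(snp_i = vapply(pl, `[[`, "", "snp_i"),
                      snp_j = vapply(pl, `[[`, "", "snp_j"),
                      stringsAsFactors = FALSE)
  list(loci = loci, pairs = pairs, trace = trace)
}

#' Fit the full mixed model by Gibbs sampling
#'
#' Fits the saturated model for the selected terms: fixed population mean,
#' additive effects a_i and epistatic effects aa_ij; random environment
#' main effects, QTS-by-environment (ae) and epistasis-by-environment
#' (aae) interactions, and residual. Point estimates are posterior means
#' over the post-burn-in Gibbs draws, standard errors are posterior
#' standard deviations, and p-values come from a Wald-type normal
#' approximation on the posterior mean/sd. Per-QTS heritabilities are
#' filled in by [compute_heritability()].
#'
#' @param geno A [ril_geno()].
#' @param pheno Phenotype table.
#' @param trait Trait name.
#' @param terms List with `loci` (SNP ids) and optionally `pairs`
#'   (data frame `snp_i`, `snp_j`), as returned by [stepwise_select()].
#' @param mcmc_iter Total Gibbs iterations (default 20000).
#' @param burn_in Fraction of iterations discarded as burn-in
#'   (default 0.25).
#' @param seed Integer seed (optional; fixed seed gives bit-identical
#'   posterior summaries).
#' @param keep_draws Keep the posterior draws in the fit (default FALSE).
#' @return An object of class `qts_fit`.
#' @export
fit_full_model <- function(geno, pheno, trait, terms,
                           mcmc_iter = 20000, burn_in = 0.25, seed = NULL,
                           keep_draws = FALSE) {
  loci <- terms$loci %||% character(0)
  pairs <- terms$pairs %||% data.frame(snp_i = character(0),
                                       snp_j = character(0))
  if (!length(loci) && !nrow(pairs)) stop("no selected terms to fit")
  pr <- prep_scan(geno, pheno, trait)
  N <- length(pr$y)
  H <- nlevels(pr$env)
  A <- length(loci)
  P <- nrow(pairs)

  Xa <- pr$Xobs[, loci, drop = FALSE]
  XP <- if (P) {
    pp <- pr$Xobs[, pairs$snp_i, drop = FALSE] *
      pr$Xobs[, pairs$snp_j, drop = FALSE]
    colnames(pp) <- paste0(pairs$snp_i, ":", pairs$snp_j)
    pp
  } else {
    matrix(0, N, 0)
  }
  W <- cbind(`(Intercept)` = 1, Xa, XP)
  qW <- qr(W)
  if (qW$rank < ncol(W)) {
    keep <- qW$pivot[seq_len(qW$rank)]
    dropped <- colnames(W)[-keep]
    warning("collinear fixed-effect columns pruned: ",
            paste(dropped, collapse = ", "))
    keep_names <- colnames(W)[sort(keep)]
    loci <- intersect(loci, keep_names)
    pairs <- pairs[paste0(pairs$snp_i, ":", pairs$snp_j) %in% keep_names, ,
                   drop = FALSE]
    A <- length(loci); P <- nrow(pairs)
    Xa <- pr$Xobs[, loci, drop = FALSE]
    XP <- if (P) {
      pp <- pr$Xobs[, pairs$snp_i, drop = FALSE] *
        pr$Xobs[, pairs$snp_j, drop = FALSE]
      colnames(pp) <- paste0(pairs$snp_i, ":", pairs$snp_j)
      pp
    } else matrix(0, N, 0)
    W <- cbind(`(Intercept)` = 1, Xa, XP)
  }

  Zenv <- stats::model.matrix(~ 0 + env, data.frame(env = pr$env))
  Zae <- if (A) {
    do.call(cbind, lapply(seq_len(H), function(h) Xa * Zenv[, h]))
  } else matrix(0, N, 0)
  Zaae <- if (P) {
    do.call(cbind, lapply(seq_len(H), function(h) XP * Zenv[, h]))
  } else matrix(0, N, 0)
  Zlist <- list(env = Zenv)
  if (ncol(Zae)) Zlist$ae <- Zae
  if (ncol(Zaae)) Zlist$aae <- Zaae
  # Identification: each random block is fitted on the orthogonal complement
  # of the fixed design (sum-to-zero style), so mu is not confounded with the
  # environment means nor a_i (aa_ij) with the environment-average of its
  # interaction effects.
  qWfix <- qr(W)
  Zlist <- lapply(Zlist, function(Z) Z - qr.fitted(qWfix, Z))

  n_burn <- as.integer(round(mcmc_iter * burn_in))
  lower <- 1e-10 * max(stats::var(pr$y), 1)
  res <- with_seed(seed,
    gibbs_mixed(pr$y, W, unname(Zlist), as.integer(mcmc_iter), n_burn,
                0, 0, lower))

  bm <- colMeans(res$beta)
  bs <- apply(res$beta, 2, stats::sd)
  z <- abs(bm) / bs
  neglog10p <- -(log(2) + stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)) /
    log(10)
  sig <- colMeans(res$sigma2)
  names(sig) <- c(names(Zlist), "residual")
  vc <- c(env = unname(sig["env"]),
          ae = if ("ae" %in% names(sig)) unname(sig["ae"]) else NA_real_,
          aae = if ("aae" %in% names(sig)) unname(sig["aae"]) else NA_real_,
          residual = unname(sig["residual"]))

  eff_names <- colnames(W)[-1]
  ki <- match(loci, geno$snps$snp_id)
  kp <- match(pairs$snp_i, geno$snps$snp_id)
  effects <- data.frame(
    term = eff_names,
    type = c(rep("a", A), rep("aa", P)),
    snp_i = c(loci, pairs$snp_i),
    snp_j = c(rep(NA_character_, A), pairs$snp_j),
    chrom = c(geno$snps$chrom[ki], geno$snps$chrom[kp]),
    pos = c(geno$snps$pos[ki], geno$snps$pos[kp]),
    estimate = bm[-1],
    se = bs[-1],
    neglog10p = neglog10p[-1],
    h2 = NA_real_,
    stringsAsFactors = FALSE
  )

  u_mean <- res$u_mean
  zu_hat <- Reduce(`+`, lapply(seq_along(Zlist),
                               function(b) drop(Zlist[[b]] %*% u_mean[[b]])),
                   accumulate = FALSE)
  fitted_vals <- drop(W %*% bm) + zu_hat

  fit <- structure(list(
    mu = unname(bm[1]), mu_se = unname(bs[1]),
    effects = effects,
    varcomp = vc,
    total_h2 = NA_real_, vp = NA_real_,
    trait = trait,
    n_lines = nrow(geno$calls),
    n_obs = N,
    environments = levels(pr$env),
    selected = list(loci = loci, pairs = pairs),
    fitted = fitted_vals,
    observed = pr$y,
    obs_index = pr$ph[, c("line_id", "environment", "replicate")],
    mcmc = list(iterations = mcmc_iter, burn_in = n_burn, seed = seed),
    draws = if (keep_draws) res else NULL
  ), class = "qts_fit")
  compute_heritability(fit, geno, pheno)
}

#' Per-QTS heritability and the phenotypic variance convention
#'
#' Fills h2_i (%) = 100 a_i^2 var(x_i) / V_P for additive terms and
#' 100 aa_ij^2 var(x_i x_j) / V_P for epistatic terms, where var() is the
#' sample variance of the (mean-imputed) codes over lines and V_P is the
#' sample variance of line-by-environment mean phenotypes. The total
#' heritability is the sum of the individual values.
#'
#' @param fit A `qts_fit`.
#' @param geno The [ril_geno()] used for fitting.
#' @param pheno The phenotype table used for fitting.
#' @return The `qts_fit` with `effects$h2`, `total_h2` and `vp` filled.
#' @export
compute_heritability <- function(fit, geno, pheno) {
  ph <- pheno[pheno$trait == fit$trait, , drop = FALSE]
  cellmeans <- stats::aggregate(value ~ line_id + environment, data = ph,
                                FUN = mean)
  vp <- stats::var(cellmeans$value)
  if (!is.finite(vp) || vp <= 0) stop("phenotypic variance V_P is zero")
  X <- impute_calls(geno)
  h2 <- vapply(seq_len(nrow(fit$effects)), function(i) {
    e <- fit$effects[i, ]
    xv <- if (e$type == "a") {
      stats::var(X[, e$snp_i])
    } else {
      stats::var(X[, e$snp_i] * X[, e$snp_j])
    }
    100 * e$estimate^2 * xv / vp
  }, numeric(1))
  fit$effects$h2 <- h2
  fit$total_h2 <- sum(h2)
  fit$vp <- vp
  fit
}
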