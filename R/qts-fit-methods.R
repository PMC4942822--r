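#' Construct a QTS model from known effect estimates
#'
#' Builds a minimal `qts_fit` from a population mean and effect estimates
#' (for example, a published QTS table), suitable for the prediction
#' functions [genetic_value()], [best_line()] and [superior_line()].
#'
#' @param mu Population mean.
#' @param additive Named numeric vector of additive effects (names = SNP ids).
#' @param epistatic Optional data frame `snp_i`, `snp_j`, `effect`.
#' @param h2 Optional per-term heritabilities (%) aligned with
#'   `c(additive, epistatic)`.
#' @return A `qts_fit` with estimates only (no posterior summaries).
#' @export
qts_model <- function(mu, additive = numeric(0), epistatic = NULL, h2 = NULL) {
  if (length(additive) && is.null(names(additive))) {
    stop("additive effects must be named by SNP id")
  }
  if (is.null(epistatic)) {
    epistatic <- data.frame(snp_i = character(0), snp_j = character(0),
                            effect = numeric(0), stringsAsFactors = FALSE)
  }
  A <- length(additive); P <- nrow(epistatic)
  pair_terms <- if (P) paste0(epistatic$snp_i, ":", epistatic$snp_j) else character(0)
  effects <- data.frame(
    term = c(names(additive), pair_terms),
    type = c(rep("a", A), rep("aa", P)),
    snp_i = c(names(additive), epistatic$snp_i),
    snp_j = c(rep(NA_character_, A), epistatic$snp_j),
    chrom = NA_character_, pos = NA_real_,
    estimate = c(unname(additive), epistatic$effect),
    se = NA_real_, neglog10p = NA_real_,
    h2 = if (is.null(h2)) NA_real_ else h2,
    stringsAsFactors = FALSE
  )
  structure(list(mu = mu, mu_se = NA_real_, effects = effects,
                 varcomp = c(env = NA, ae = NA, aae = NA, residual = NA),
                 total_h2 = if (is.null(h2)) NA_real_ else sum(h2),
                 vp = NA_real_, trait = NA_character_,
                 selected = list(loci = names(additive), pairs = epistatic[,
                   c("snp_i", "snp_j"), drop = FALSE])),
            class = "qts_fit")
}

#' @export
print.qts_fit <- function(x, digits = 3, ...) {
  cat("QTS mixed-model fit", if (!is.na(x$trait)) paste0("for trait '", x$trait, "'"),
      "\n")
  cat(sprintf("Population mean: %.*f", digits, x$mu))
  if (!is.na(x$mu_se)) cat(sprintf(" (SE %.*f)", digits, x$mu_se))
  cat("\n")
  eff <- x$effects
  show <- eff[, c("term", "type", "estimate", "se", "neglog10p", "h2")]
  print(format(show, digits = digits), row.names = FALSE)
  if (!is.na(x$total_h2)) {
    cat(sprintf("Total heritability: %.2f%%\n", x$total_h2))
  }
  invisible(x)
}

#' @export
summary.qts_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.qts_fit")
}

#' @export
print.summary.qts_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!all(is.na(f$varcomp))) {
    cat("Variance components (posterior means):\n")
    print(round(f$varcomp, 4))
  }
  if (!is.null(f$mcmc)) {
    cat(sprintf("MCMC: %d iterations, %d burn-in\n",
                f$mcmc$iterations, f$mcmc$burn_in))
  }
  invisible(x)
}

#' @export
coef.qts_fit <- function(object, ...) {
  c(`(Intercept)` = object$mu,
    stats::setNames(object$effects$estimate, object$effects$term))
}

#' Predict genetic values or phenotypes for genotypes
#'
#' @param object A `qts_fit`.
#' @param newdata A [ril_geno()], or a matrix/vector of +/-1 codes with
#'   columns (or names) covering the selected QTSs.
#' @param type `"genetic"` (total genetic value G, excluding the mean) or
#'   `"phenotype"` (mu + G).
#' @param ... Unused.
#' @return Named numeric vector of predicted values.
#' @export
predict.qts_fit <- function(object, newdata,
                            type = c("genetic", "phenotype"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "ril_geno")) {
    impute_calls(newdata)
  } else if (is.matrix(newdata)) {
    newdata
  } else {
    matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  }
  need <- unique(object$effects$snp_i[object$effects$type == "a"])
  need <- unique(c(need, object$effects$snp_i[object$effects$type == "aa"],
                   object$effects$snp_j[object$effects$type == "aa"]))
  need <- need[!is.na(need)]
  absent <- setdiff(need, colnames(X))
  if (length(absent)) {
    stop("genotype lacks selected QTS(s): ", paste(absent, collapse = ", "))
  }
  g <- rep(0, nrow(X))
  for (i in seq_len(nrow(object$effects))) {
    e <- object$effects[i, ]
    g <- g + if (e$type == "a") {
      e$estimate * X[, e$snp_i]
    } else {
      e$estimate * X[, e$snp_i] * X[, e$snp_j]
    }
  }
  out <- if (type == "genetic") g else object$mu + g
  stats::setNames(out, rownames(X))
}

#' @export
residuals.qts_fit <- function(object, ...) {
  if (is.null(object$fitted)) {
    stop("residuals are only available for models fitted from data")
  }
  object$observed - object$fitted
}

#' Simulate phenotypes from a fitted QTS model
#'
#' Draws new replicated multi-environment phenotypes under the fitted
#' fixed effects and variance components (a parametric-bootstrap style
#' `simulate` method).
#'
#' @param object A `qts_fit` fitted from data.
#' @param nsim Number of simulated phenotype tables.
#' @param seed Integer seed (optional).
#' @param geno The [ril_geno()] to simulate for (defaults require one).
#' @param n_rep Replicates per line and environment (default 2).
#' @param ... Unused.
#' @return A list of `nsim` phenotype data frames.
#' @export
simulate.qts_fit <- function(object, nsim = 1, seed = NULL, geno,
                             n_rep = 2, ...) {
  vc <- object$varcomp
  add <- object$effects[object$effects$type == "a", ]
  epi <- object$effects[object$effects$type == "aa", ]
  tm <- true_model(
    mu = object$mu,
    additive = stats::setNames(add$estimate, add$snp_i),
    epistatic = if (nrow(epi)) {
      data.frame(snp_i = epi$snp_i, snp_j = epi$snp_j, effect = epi$estimate)
    } else NULL,
    env_sd = sqrt(max(vc["env"], 0, na.rm = TRUE)),
    ae_sd = if (is.na(vc["ae"])) 0 else sqrt(max(vc["ae"], 0)),
    aae_sd = if (is.na(vc["aae"])) 0 else sqrt(max(vc["aae"], 0)),
    residual_sd = sqrt(max(vc["residual"], 0, na.rm = TRUE)),
    n_env = length(object$environments %||% c("E1", "E2")),
    n_rep = n_rep
  )
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      simulate_phenotypes(geno, tm, trait = object$trait %||% "trait")
    })
  })
}

#' Write a fitted model as a TSV effect table
#'
#' Columns mirror the standard QTS report layout: term, type, chromosome,
#' position, effect size, SE, -log10(P), h2 (%), total h2 (%).
#'
#' @param fit A `qts_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qts_table <- function(fit, path) {
  eff <- fit$effects
  out <- data.frame(QTS = eff$term, Chr = eff$chrom, Pos = eff$pos,
                    Effect_type = eff$type, Effect_size = eff$estimate,
                    SE = eff$se, neglog10P = eff$neglog10p,
                    h2_pct = eff$h2, total_h2_pct = fit$total_h2,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
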