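#' Two-step QTS association mapping with permutation thresholds
#'
#' The central fitting function. Runs the full mapping procedure for one
#' trait on a (possibly strategy-subsetted) genotype matrix:
#'
#' 1. optional F-statistic candidate screening ([marginal_screen()],
#'    [pairwise_screen()]) per environment, merged by union;
#' 2. one-dimensional additive scan ([scan_additive()]) with an
#'    experiment-wise permutation threshold ([permutation_threshold()]);
#' 3. two-dimensional epistasis scan ([scan_epistasis()]) over pairs of
#'    top-ranked SNPs, conditioned on the step-1 hits as covariates, with
#'    its own permutation threshold;
#' 4. forward-backward stepwise selection over significant loci and pairs
#'    ([stepwise_select()]);
#' 5. Gibbs-sampler estimation of the saturated mixed model with
#'    per-QTS heritability partitioning ([fit_full_model()]).
#'
#' @param geno A [ril_geno()] (after QC / strategy subsetting).
#' @param pheno Replicated multi-environment phenotype table.
#' @param trait Trait to map.
#' @param screen_top_m If non-`NULL`, screen to this many top candidates
#'   per environment before scanning (`top_m = n_snps` makes screening a
#'   no-op).
#' @param screen_pairs Also run the 2D candidate screen (default FALSE).
#' @param n_permutations Permutations for each threshold (default 1000).
#' @param alpha Experiment-wise significance level (default 0.05).
#' @param epistasis Run the 2D step (default TRUE).
#' @param pair_top Pair universe: all pairs among this many top-F SNPs
#'   from the 1D scan (default 20), plus any screened pairs.
#' @param entry_alpha,stay_alpha Stepwise entry/stay levels (default 0.05).
#' @param mcmc_iter,burn_in Gibbs sampler control (defaults 20000, 0.25).
#' @param seed Integer seed driving all stochastic stages.
#' @return A `qts_fit` (with `scan1`, `threshold1`, `scan2`, `threshold2`
#'   attached), or `NULL` if no unit exceeds its permutation threshold.
#' @export
qts_map <- function(geno, pheno, trait,
                    screen_top_m = NULL, screen_pairs = FALSE,
                    n_permutations = 1000, alpha = 0.05,
                    epistasis = TRUE, pair_top = 20,
                    entry_alpha = 0.05, stay_alpha = 0.05,
                    mcmc_iter = 20000, burn_in = 0.25, seed = NULL) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, 4))
  if (is.null(seed)) seeds <- rep(list(NULL), 4)

  screened_pairs <- NULL
  if (!is.null(screen_top_m)) {
    envs <- unique(pheno$environment[pheno$trait == trait])
    sets <- lapply(envs, function(e) {
      s <- marginal_screen(geno, pheno, trait, e, top_m = screen_top_m)
      if (screen_pairs) {
        ps <- pairwise_screen(geno, pheno, trait, e, top_m = screen_top_m)
        s$pairs <- ps$pairs
      }
      s
    })
    cand <- merge_candidates(sets)
    keep <- geno$snps$snp_id %in% cand$snps$snp_id
    geno <- ril_geno(geno$calls[, keep, drop = FALSE],
                     geno$snps[keep, , drop = FALSE], rownames(geno$calls))
    if (nrow(cand$pairs)) screened_pairs <- cand$pairs
  }

  scan1 <- scan_additive(geno, pheno, trait)
  thr1 <- permutation_threshold(geno, pheno, trait,
                                n_permutations = n_permutations,
                                alpha = alpha, seed = seeds[[1]],
                                scan_kind = "1D")
  sig1 <- scan1[!is.na(scan1$F) & scan1$F > thr1, , drop = FALSE]

  scan2 <- NULL
  thr2 <- NULL
  sig2 <- NULL
  if (epistasis) {
    ranked <- scan1[!is.na(scan1$F) & is.finite(scan1$F), , drop = FALSE]
    ranked <- ranked[order(-ranked$F), , drop = FALSE]
    top_ids <- utils::head(ranked$snp_id, pair_top)
    pairs <- if (length(top_ids) >= 2) {
      cmb <- utils::combn(top_ids, 2)
      data.frame(snp_i = cmb[1, ], snp_j = cmb[2, ], stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(screened_pairs) && nrow(screened_pairs)) {
      pairs <- unique(rbind(pairs,
                            screened_pairs[, c("snp_i", "snp_j")]))
    }
    if (!is.null(pairs) && nrow(pairs)) {
      covs <- sig1$snp_id
      scan2 <- scan_epistasis(geno, pheno, trait, covs, pairs)
      thr2 <- permutation_threshold(geno, pheno, trait,
                                    n_permutations = n_permutations,
                                    alpha = alpha, seed = seeds[[2]],
                                    scan_kind = "2D",
                                    covariate_snps = covs,
                                    pair_universe = pairs)
      sig2 <- scan2[!is.na(scan2$F) & scan2$F > thr2, , drop = FALSE]
    }
  }

  if (!nrow(sig1) && (is.null(sig2) || !nrow(sig2))) {
    message("no QTS exceeded the permutation threshold")
    return(invisible(NULL))
  }

  sel <- stepwise_select(if (nrow(sig1)) sig1 else scan1[0, ], sig2,
                         geno, pheno, trait,
                         entry_alpha = entry_alpha, stay_alpha = stay_alpha)
  if (!length(sel$loci) && !nrow(sel$pairs)) {
    message("stepwise selection retained no terms")
    return(invisible(NULL))
  }
  fit <- fit_full_model(geno, pheno, trait, sel,
                        mcmc_iter = mcmc_iter, burn_in = burn_in,
                        seed = seeds[[3]])
  fit$scan1 <- scan1
  fit$threshold1 <- thr1
  fit$scan2 <- scan2
  fit$threshold2 <- thr2
  fit
}
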