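#' Simulate RIL genotypes by single seed descent
#'
#' Forward simulation of a biparental recombinant-inbred-line population:
#' the F1 carries one intact paternal and one intact maternal haplotype at
#' every marker; each line is then advanced by `n_selfing_generations`
#' rounds of selfing with one offspring kept per generation (single seed
#' descent). Each meiosis draws crossovers independently between adjacent
#' markers with Haldane recombination fractions ([haldane_r()]) — no
#' interference — so markers on different chromosomes assort independently.
#' The default of 12 selfing generations yields an F13 population in which
#' residual heterozygosity is negligible (~0.02% per locus).
#'
#' @param map A [genetic_map()] (or [build_genetic_map()] output).
#' @param n_lines Number of RILs to produce (>= 2).
#' @param n_selfing_generations Selfing rounds after the F1 (default 12,
#'   i.e. an F13 population).
#' @param het_policy What to do with loci still heterozygous after selfing:
#'   `"force-homozygous"` (default; resolved by a fair coin flip) or
#'   `"code-missing"`.
#' @param missing_rate Fraction of calls set missing uniformly at random
#'   after coding (default 0).
#' @param seed Integer seed for reproducibility (optional).
#' @return A [ril_geno()] with calls in \{+1, -1, NA\}; +1 is the paternal
#'   homozygote.
#' @export
simulate_ril_genotypes <- function(map, n_lines,
                                   n_selfing_generations = 12,
                                   het_policy = c("force-homozygous", "code-missing"),
                                   missing_rate = 0,
                                   seed = NULL) {
  het_policy <- match.arg(het_policy)
  if (nrow(map) < 1) stop("genetic map is empty")
  if (n_lines < 2) stop("need at least 2 lines")
  if (n_selfing_generations < 1) stop("need at least 1 selfing generation")
  n_lines <- as.integer(n_lines)
  with_seed(seed, {
    chrom_levels <- unique(map$chrom)
    geno_cols <- vector("list", length(chrom_levels))
    for (ci in seq_along(chrom_levels)) {
      sub <- map[map$chrom == chrom_levels[ci], , drop = FALSE]
      geno_cols[[ci]] <- ssd_chromosome(sub$pos_cM, n_lines, n_selfing_generations)
    }
    dose <- do.call(cbind, geno_cols)  # lines x markers, paternal allele dose 0/1/2
    calls <- matrix(NA_real_, nrow = n_lines, ncol = ncol(dose))
    calls[dose == 2] <- 1
    calls[dose == 0] <- -1
    het <- dose == 1
    if (any(het)) {
      if (het_policy == "force-homozygous") {
        calls[het] <- sample(c(-1, 1), sum(het), replace = TRUE)
      } # else stays NA
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(calls)) < missing_rate
      calls[drop] <- NA
    }
    snps <- data.frame(snp_id = map$marker_id, chrom = map$chrom,
                       pos = map$pos_bp,
                       paternal = "A", maternal = "G",
                       stringsAsFactors = FALSE)
    ril_geno(calls, snps, paste0("RIL", seq_len(n_lines)))
  })
}

# One chromosome of SSD descent: returns lines x markers paternal-dose matrix.
# Haplotypes are stored markers x lines with 1 = paternal origin.
ssd_chromosome <- function(pos_cM, n_lines, n_gen) {
  m <- length(pos_cM)
  r <- if (m > 1) haldane_r(diff(pos_cM)) else numeric(0)
  h1 <- matrix(1L, nrow = m, ncol = n_lines)
  h2 <- matrix(0L, nrow = m, ncol = n_lines)
  for (g in seq_len(n_gen)) {
    g1 <- meiosis_gametes(h1, h2, r)
    g2 <- meiosis_gametes(h1, h2, r)
    h1 <- g1
    h2 <- g2
  }
  t(h1 + h2)
}

# One gamete per line from parental haplotype pair (markers x lines).
meiosis_gametes <- function(h1, h2, r) {
  m <- nrow(h1); n <- ncol(h1)
  phase <- matrix(0L, nrow = m, ncol = n)
  phase[1, ] <- as.integer(stats::runif(n) < 0.5)
  if (m > 1) {
    sw <- matrix(as.integer(stats::runif((m - 1) * n) < r), nrow = m - 1, ncol = n)
    for (j in 2:m) phase[j, ] <- bitwXor(phase[j - 1, ], sw[j - 1, ])
  }
  h1 * (1L - phase) + h2 * phase
}

#' Specify a true genetic model for phenotype simulation
#'
#' The saturated model for a replicated multi-environment RIL trial:
#' y_hk = mu + sum_i a_i x_ik + sum_(i<j) aa_ij x_ik x_jk
#'        + e_h + sum_i ae_hi x_ik + sum_(i<j) aae_hij x_ik x_jk + eps_hk,
#' with additive (a) and additive-by-additive epistatic (aa) fixed effects,
#' random environment main effects e_h ~ N(0, env_sd^2) drawn once per
#' environment and shared by all lines in it, random QTS-by-environment
#' interactions ae_hi ~ N(0, ae_sd^2) and aae_hij ~ N(0, aae_sd^2), and an
#' independent residual eps ~ N(0, residual_sd^2) per observation.
#'
#' @param mu Population mean (trait units).
#' @param additive Named numeric vector of additive effects a_i, names are
#'   SNP ids.
#' @param epistatic Optional data frame with columns `snp_i`, `snp_j`,
#'   `effect` (aa_ij); the paired loci must be distinct.
#' @param env_sd,ae_sd,aae_sd,residual_sd Standard deviations (>= 0) of the
#'   random terms.
#' @param n_env Number of environments, `n_rep` replicates per line and
#'   environment.
#' @return An object of class `qts_true_model`.
#' @export
true_model <- function(mu = 0, additive = numeric(0), epistatic = NULL,
                       env_sd = 0, ae_sd = 0, aae_sd = 0, residual_sd = 1,
                       n_env = 2, n_rep = 2) {
  if (any(c(env_sd, ae_sd, aae_sd, residual_sd) < 0)) stop("sds must be >= 0")
  if (length(additive) && is.null(names(additive))) {
    stop("additive effects must be named by SNP id")
  }
  if (!is.null(epistatic) && nrow(epistatic)) {
    stopifnot(all(c("snp_i", "snp_j", "effect") %in% names(epistatic)))
    if (any(epistatic$snp_i == epistatic$snp_j)) {
      stop("epistatic pairs must reference distinct loci")
    }
  } else {
    epistatic <- data.frame(snp_i = character(0), snp_j = character(0),
                            effect = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(mu = mu, additive = additive, epistatic = epistatic,
                 env_sd = env_sd, ae_sd = ae_sd, aae_sd = aae_sd,
                 residual_sd = residual_sd,
                 n_env = as.integer(n_env), n_rep = as.integer(n_rep)),
            class = "qts_true_model")
}

#' Simulate replicated multi-environment phenotypes
#'
#' Draws phenotypes for every line under a [true_model()]. Missing
#' genotypes at model loci are mean-imputed before use.
#'
#' @param geno A [ril_geno()] containing every SNP named in `model`.
#' @param model A [true_model()].
#' @param trait Trait name recorded in the output (default `"trait"`).
#' @param seed Integer seed (optional).
#' @return A data frame with columns `line_id`, `environment`,
#'   `replicate`, `trait`, `value` — one row per observation y_hk.
#' @export
simulate_phenotypes <- function(geno, model, trait = "trait", seed = NULL) {
  stopifnot(inherits(model, "qts_true_model"))
  qts <- union(names(model$additive),
               c(model$epistatic$snp_i, model$epistatic$snp_j))
  missing_ids <- setdiff(qts, geno$snps$snp_id)
  if (length(missing_ids)) {
    stop("unknown QTS id(s): ", paste(missing_ids, collapse = ", "))
  }
  n <- nrow(geno$calls)
  X <- if (length(qts)) {
    impute_calls(geno)[, qts, drop = FALSE]
  } else {
    matrix(0, nrow = n, ncol = 0)
  }
  g_fixed <- rep(model$mu, n)
  if (length(model$additive)) {
    g_fixed <- g_fixed + drop(X[, names(model$additive), drop = FALSE] %*%
                                model$additive)
  }
  P <- nrow(model$epistatic)
  XP <- if (P) {
    X[, model$epistatic$snp_i, drop = FALSE] *
      X[, model$epistatic$snp_j, drop = FALSE]
  } else {
    matrix(0, nrow = n, ncol = 0)
  }
  if (P) g_fixed <- g_fixed + drop(XP %*% model$epistatic$effect)
  H <- model$n_env; R <- model$n_rep
  A <- length(model$additive)
  with_seed(seed, {
    e_h <- stats::rnorm(H, 0, model$env_sd)
    ae <- matrix(stats::rnorm(H * A, 0, model$ae_sd), nrow = H)   # env x QTS
    aae <- matrix(stats::rnorm(H * P, 0, model$aae_sd), nrow = H) # env x pair
    out <- vector("list", H)
    Xa <- X[, names(model$additive), drop = FALSE]
    for (h in seq_len(H)) {
      cell <- g_fixed + e_h[h]
      if (A) cell <- cell + drop(Xa %*% ae[h, ])
      if (P) cell <- cell + drop(XP %*% aae[h, ])
      vals <- rep(cell, times = R) +
        stats::rnorm(n * R, 0, model$residual_sd)
      out[[h]] <- data.frame(
        line_id = rep(rownames(geno$calls), times = R),
        environment = paste0("E", h),
        replicate = rep(seq_len(R), each = n),
        trait = trait,
        value = vals,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Write / read phenotype tables
#'
#' CSV layout with header `line_id,environment,replicate,trait,value`.
#'
#' @param pheno Phenotype data frame as from [simulate_phenotypes()].
#' @param path File path.
#' @return `path` invisibly (writer); the phenotype data frame (reader).
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno[, c("line_id", "environment", "replicate",
                             "trait", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "environment", "replicate", "trait", "value")
  if (!all(need %in% names(ph))) {
    stop("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(ph$value))) stop("phenotype values must be finite")
  ph
}

#' Write the ground-truth model as a YAML sidecar
#' @param model A [true_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_true_model <- function(model, path) {
  yaml::write_yaml(list(
    mu = model$mu,
    additive = as.list(model$additive),
    epistatic = if (nrow(model$epistatic)) model$epistatic else NULL,
    env_sd = model$env_sd, ae_sd = model$ae_sd, aae_sd = model$aae_sd,
    residual_sd = model$residual_sd,
    n_env = model$n_env, n_rep = model$n_rep
  ), path)
  invisible(path)
}
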