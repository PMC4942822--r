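#' Total genetic value of a genotype
#'
#' G = sum_i a_i x_i + sum_(i<j) aa_ij x_i x_j over the model's selected
#' QTSs; the predicted phenotype is mu + G. With no selected
#' environment-interaction terms the genetic value is constant across
#' environments.
#'
#' @param model A `qts_fit` (fitted, or built via [qts_model()]).
#' @param genotype Named vector of +/-1 codes covering all selected QTSs,
#'   or a single-row matrix.
#' @return Scalar genetic value G.
#' @export
genetic_value <- function(model, genotype) {
  unname(predict(model, genotype, type = "genetic"))[1]
}

#' Best observed line by genetic value
#'
#' Evaluates the total genetic value of every line in the population
#' (mean-imputing missing calls at selected QTSs) and returns the highest;
#' ties are broken by input order and reported via the `tied` attribute.
#'
#' @param model A `qts_fit`.
#' @param geno A [ril_geno()] containing the selected QTSs.
#' @return List with `line_id`, `G`, and all per-line values in `values`.
#' @export
best_line <- function(model, geno) {
  if (nrow(geno$calls) < 1) stop("no lines to evaluate")
  g <- predict(model, geno, type = "genetic")
  best <- which(g == max(g))
  out <- list(line_id = rownames(geno$calls)[best[1]], G = unname(g[best[1]]),
              values = g)
  attr(out, "tied") <- if (length(best) > 1) rownames(geno$calls)[best] else NULL
  out
}

#' Predicted superior line (optimal homozygous genotype)
#'
#' Finds the +/-1 genotype over the selected QTSs maximizing the total
#' genetic value — the "superior pure line". With k <= 20 loci the search
#' is exhaustive over all 2^k homozygous genotypes; for larger k a seeded
#' simulated-annealing search with restarts is used. For a purely additive
#' model the optimum is x_i = sign(a_i) with G = sum |a_i|.
#'
#' @param model A `qts_fit`.
#' @param method `"exhaustive"` (k <= 20 only) or `"anneal"`.
#' @param restarts Annealing restarts (default 50).
#' @param n_steps Annealing steps per restart (default 2000).
#' @param seed Integer seed for the annealing search.
#' @return List with `genotype` (named +/-1 vector) and `G`.
#' @export
superior_line <- function(model, method = c("exhaustive", "anneal"),
                          restarts = 50, n_steps = 2000, seed = NULL) {
  method <- match.arg(method)
  eff <- model$effects
  loci <- unique(c(eff$snp_i, eff$snp_j))
  loci <- loci[!is.na(loci)]
  k <- length(loci)
  if (k < 1) stop("model has no selected QTSs")

  a <- stats::setNames(rep(0, k), loci)
  add <- eff[eff$type == "a", ]
  a[add$snp_i] <- a[add$snp_i] + add$estimate
  epi <- eff[eff$type == "aa", , drop = FALSE]

  if (method == "exhaustive" && k > 20) {
    stop("exhaustive search refused for k > 20 loci; use method = \"anneal\"")
  }

  if (!nrow(epi)) {  # additive closed form
    x <- sign(a)
    x[x == 0] <- 1
    return(list(genotype = x, G = sum(abs(a))))
  }

  ei <- match(epi$snp_i, loci)
  ej <- match(epi$snp_j, loci)
  ea <- epi$estimate
  a <- unname(a)

  if (method == "exhaustive") {
    codes <- 0:(2^k - 1)
    X <- matrix(0L, nrow = length(codes), ncol = k)
    for (j in seq_len(k)) X[, j] <- 2L * bitwAnd(bitwShiftR(codes, j - 1L), 1L) - 1L
    G <- drop(X %*% a)
    for (p in seq_along(ea)) G <- G + ea[p] * X[, ei[p]] * X[, ej[p]]
    best <- which.max(G)
    return(list(genotype = stats::setNames(X[best, ], loci), G = G[best]))
  }

  # annealing with incremental single-flip deltas
  partners <- lapply(seq_len(k), function(j) {
    w <- which(ei == j | ej == j)
    cbind(other = ifelse(ei[w] == j, ej[w], ei[w]), eff = ea[w])
  })
  with_seed(seed, {
    best_g <- -Inf
    best_x <- NULL
    temps <- max(abs(c(a, ea))) *
      exp(seq(log(2), log(1e-3), length.out = n_steps))
    for (r in seq_len(restarts)) {
      x <- sample(c(-1, 1), k, replace = TRUE)
      g <- sum(a * x) + sum(ea * x[ei] * x[ej])
      if (g > best_g) {
        best_g <- g
        best_x <- x
      }
      js <- sample.int(k, n_steps, replace = TRUE)
      us <- stats::runif(n_steps)
      for (s in seq_len(n_steps)) {
        j <- js[s]
        pw <- partners[[j]]
        delta <- -2 * x[j] * (a[j] +
          if (nrow(pw)) sum(pw[, "eff"] * x[pw[, "other"]]) else 0)
        if (delta >= 0 || us[s] < exp(delta / temps[s])) {
          x[j] <- -x[j]
          g <- g + delta
          if (g > best_g) {
            best_g <- g
            best_x <- x
          }
        }
      }
    }
    list(genotype = stats::setNames(best_x, loci), G = best_g)
  })
}

#' Genetic-value report for parents, best line and superior line
#'
#' Computes the total genetic values of the paternal-type parent (all +1),
#' the maternal-type parent (all -1), the best observed line (BL) and the
#' predicted superior line (SL), together with the predicted phenotypes
#' mu + G.
#'
#' @param model A `qts_fit`.
#' @param geno A [ril_geno()] of observed lines (for BL); optional.
#' @param parent_names Names for the +1-type and -1-type parents.
#' @return A data frame with one row per entry (`mean`, parents, `BL`,
#'   `SL`) and columns `entry`, `G`, `predicted` (mu + G), `detail`.
#' @export
genetic_value_report <- function(model, geno = NULL,
                                 parent_names = c("ZH9308", "XQZB")) {
  loci <- unique(c(model$effects$snp_i, model$effects$snp_j))
  loci <- loci[!is.na(loci)]
  plus <- stats::setNames(rep(1, length(loci)), loci)
  gp <- genetic_value(model, plus)
  gm <- genetic_value(model, -plus)
  sl <- superior_line(model,
                      method = if (length(loci) <= 20) "exhaustive" else "anneal")
  rows <- list(
    data.frame(entry = "mean", G = 0, predicted = model$mu, detail = "",
               stringsAsFactors = FALSE),
    data.frame(entry = parent_names[1], G = gp, predicted = model$mu + gp,
               detail = "all +1", stringsAsFactors = FALSE),
    data.frame(entry = parent_names[2], G = gm, predicted = model$mu + gm,
               detail = "all -1", stringsAsFactors = FALSE)
  )
  if (!is.null(geno)) {
    bl <- best_line(model, geno)
    rows <- c(rows, list(
      data.frame(entry = "BL", G = bl$G, predicted = model$mu + bl$G,
                 detail = bl$line_id, stringsAsFactors = FALSE)))
  }
  rows <- c(rows, list(
    data.frame(entry = "SL", G = sl$G, predicted = model$mu + sl$G,
               detail = paste(ifelse(sl$genotype > 0, "+", "-"),
                              collapse = ""),
               stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}
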