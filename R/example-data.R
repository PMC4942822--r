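#' Bundled QTS effect estimates for a rice RIL population
#'
#' Per-QTS additive effect estimates, significance and heritability for
#' plant height (PH, cm) and heading date (HD, days) in a 138-line F13
#' recombinant-inbred population from the rice cross XieqingzaoB (XQZB,
#' maternal) x Zhonghui9308 (ZH9308, paternal), mapped under three SNP-set
#' strategies (GWA, QBA, GBA); effects are for the paternal homozygote
#' under +/-1 coding. `rice_qts_means()` gives the matching estimated
#' population means per trait and strategy. These tables serve as worked
#' examples for the prediction module.
#'
#' @return `rice_qts_effects()`: data frame with columns `trait`, `qts`,
#'   `chrom`, `allele`, `strategy`, `effect_type`, `effect`, `neglog10p`,
#'   `h2`, `total_h2`. `rice_qts_means()`: data frame `trait`, `strategy`,
#'   `mean`.
#' @export
rice_qts_effects <- function() {
  utils::read.delim(system.file("extdata", "rice_qts_effects.tsv",
                                package = "qtsmap"),
                    stringsAsFactors = FALSE)
}

#' @rdname rice_qts_effects
#' @export
rice_qts_means <- function() {
  utils::read.delim(system.file("extdata", "rice_qts_means.tsv",
                                package = "qtsmap"),
                    stringsAsFactors = FALSE)
}

#' Build prediction-ready models from an effect table
#'
#' Converts an effect table in the [rice_qts_effects()] layout (plus
#' matching population means) into one [qts_model()] per trait and
#' strategy.
#'
#' @param effects Effect table (defaults to [rice_qts_effects()]).
#' @param means Population-mean table (defaults to [rice_qts_means()]).
#' @return Named list of `qts_fit` objects, names `"<trait>.<strategy>"`.
#' @export
qts_models_from_table <- function(effects = rice_qts_effects(),
                                  means = rice_qts_means()) {
  keys <- unique(effects[, c("trait", "strategy")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    tr <- keys$trait[i]; st <- keys$strategy[i]
    sub <- effects[effects$trait == tr & effects$strategy == st, ]
    add <- sub[sub$effect_type == "a", ]
    epi <- sub[sub$effect_type == "aa", ]
    mu <- means$mean[means$trait == tr & means$strategy == st]
    if (!length(mu)) mu <- 0
    m <- qts_model(
      mu = mu,
      additive = stats::setNames(add$effect, add$qts),
      epistatic = if (nrow(epi)) {
        ij <- do.call(rbind, strsplit(epi$qts, ":", fixed = TRUE))
        data.frame(snp_i = ij[, 1], snp_j = ij[, 2], effect = epi$effect,
                   stringsAsFactors = FALSE)
      } else NULL,
      h2 = sub$h2
    )
    m$trait <- tr
    out[[paste(tr, st, sep = ".")]] <- m
  }
  out
}
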