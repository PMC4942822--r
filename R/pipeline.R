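#' Assemble and validate a pipeline configuration
#'
#' A configuration holds either input paths (`genotypes` +
#' `phenotypes`, with `format` `"vcf"` or `"tsv"`) or a `simulation`
#' spec (a list with `map` arguments for [build_genetic_map()],
#' `n_lines`, optional `n_selfing_generations`/`het_policy`/
#' `missing_rate`, and a `model` list of [true_model()] arguments) —
#' exactly one of the two. The strategy decides the SNP set: `"GWA"`
#' uses everything after QC, `"QBA"` needs `qtl_bed`, `"GBA"` needs
#' `gene_gff`.
#'
#' @param ... Configuration fields: `genotypes`, `phenotypes`, `format`,
#'   `simulation`, `strategy`, `qtl_bed`, `gene_gff`, `trait`,
#'   `qc` (list: `max_missing`, `seg_alpha`, `min_maf`),
#'   `screen_top_m`, `n_permutations`, `alpha`, `pair_top`,
#'   `mcmc_iter`, `burn_in`, `out_dir`, `seed`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  defaults <- list(strategy = "GWA", trait = "trait", format = "tsv",
                   qc = list(max_missing = 0.05, seg_alpha = 0.01,
                             min_maf = NULL),
                   screen_top_m = NULL, n_permutations = 1000, alpha = 0.05,
                   epistasis = TRUE, pair_top = 20,
                   mcmc_iter = 20000, burn_in = 0.25,
                   out_dir = NULL, seed = NULL)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  has_paths <- !is.null(cfg$genotypes) || !is.null(cfg$phenotypes)
  has_sim <- !is.null(cfg$simulation)
  if (has_paths == has_sim) {
    stop("config needs exactly one of input paths or a simulation spec")
  }
  if (has_paths && (is.null(cfg$genotypes) || is.null(cfg$phenotypes))) {
    stop("both genotype and phenotype paths are required")
  }
  cfg$strategy <- match.arg(cfg$strategy, c("GWA", "QBA", "GBA"))
  if (cfg$strategy == "QBA" && is.null(cfg$qtl_bed)) {
    stop("QBA strategy requires a QTL interval BED file ('qtl_bed')")
  }
  if (cfg$strategy == "GBA" && is.null(cfg$gene_gff)) {
    stop("GBA strategy requires a gene-model GFF3 file ('gene_gff')")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end mapping pipeline
#'
#' Simulate (or load) -> QC -> LD decay -> strategy subset -> screen ->
#' two-step mapping with permutation thresholds and Gibbs estimation ->
#' breeding-value prediction. Deterministic given `seed`; when `out_dir`
#' is set, every stage's tables plus a JSON run manifest are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @return List with `geno` (post-QC, post-subset), `qc` reports, `ld`
#'   (decay curve and half-decay distance), `fit` (a `qts_fit`, or `NULL`
#'   if nothing was declared), `prediction` (genetic-value report) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- list()
  tryCatch({
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      map <- do.call(build_genetic_map, sim$map)
      geno <- simulate_ril_genotypes(
        map, n_lines = sim$n_lines,
        n_selfing_generations = sim$n_selfing_generations %||% 12,
        het_policy = sim$het_policy %||% "force-homozygous",
        missing_rate = sim$missing_rate %||% 0,
        seed = config$seed)
      model <- do.call(true_model, sim$model)
      pheno <- simulate_phenotypes(geno, model, trait = config$trait,
                                   seed = (config$seed %||% 0) + 1)
      result$true_model <- model
    } else {
      geno <- read_genotypes(config$genotypes, format = config$format)
      pheno <- read_phenotypes_csv(config$phenotypes)
    }

    stage <- "qc"
    qc <- run_qc(geno, max_missing = config$qc$max_missing %||% 0.05,
                 seg_alpha = config$qc$seg_alpha %||% 0.01,
                 min_maf = config$qc$min_maf)
    geno <- qc$geno
    result$qc <- qc$reports

    stage <- "ld"
    ld <- tryCatch({
      pairs <- pairwise_r2(geno)
      curve <- ld_decay_curve(pairs)
      list(curve = curve, half_decay_bp = half_decay_distance(curve))
    }, error = function(e) NULL)
    result$ld <- ld

    stage <- "subset"
    if (config$strategy == "QBA") {
      intervals <- if (inherits(config$qtl_bed, "GRanges")) config$qtl_bed
                   else read_qtl_bed(config$qtl_bed)
      geno <- subset_by_intervals(geno, intervals)
    } else if (config$strategy == "GBA") {
      genes <- if (inherits(config$gene_gff, "GRanges")) config$gene_gff
               else read_gene_models(config$gene_gff)
      geno <- subset_by_gene_models(geno, genes)
    }
    if (!ncol(geno$calls)) stop("strategy subset removed every SNP")
    result$geno <- geno

    stage <- "map"
    fit <- qts_map(geno, pheno, config$trait,
                   screen_top_m = config$screen_top_m,
                   n_permutations = config$n_permutations,
                   alpha = config$alpha,
                   epistasis = config$epistasis,
                   pair_top = config$pair_top,
                   mcmc_iter = config$mcmc_iter,
                   burn_in = config$burn_in,
                   seed = config$seed)
    result$fit <- fit

    stage <- "predict"
    if (!is.null(fit)) {
      result$prediction <- genetic_value_report(fit, geno)
    }

    stage <- "report"
    result$manifest <- list(
      strategy = config$strategy, trait = config$trait,
      seed = config$seed, n_permutations = config$n_permutations,
      alpha = config$alpha, mcmc_iter = config$mcmc_iter,
      n_lines = nrow(geno$calls), n_snps = ncol(geno$calls),
      declared = if (is.null(fit)) 0L else nrow(fit$effects),
      package_version = as.character(utils::packageVersion("qtsmap"))
    )
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_qc_report(result$qc, file.path(config$out_dir, "qc"))
      if (!is.null(ld)) {
        write_ld_curve(ld$curve, file.path(config$out_dir, "ld_decay.tsv"))
      }
      if (!is.null(fit)) {
        write_qts_table(fit, file.path(config$out_dir, "qts_effects.tsv"))
        utils::write.table(result$prediction,
                           file.path(config$out_dir, "genetic_values.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(result$manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    result
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
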