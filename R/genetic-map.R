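#' Build an evenly spaced genetic map
#'
#' Constructs a marker map for simulation: `n_chrom` chromosomes, each with
#' `markers_per_chrom` markers spaced `spacing_cM` apart, physical positions
#' derived from the genetic positions at a constant `bp_per_cM` scale (the
#' first marker of every chromosome sits at 0 cM / 1 bp).
#'
#' @param n_chrom Number of chromosomes (positive integer).
#' @param markers_per_chrom Markers per chromosome (positive integer).
#' @param spacing_cM Genetic distance between adjacent markers, centimorgans.
#' @param bp_per_cM Physical scale, base pairs per centimorgan.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `marker_id`, `chrom`, `pos_cM`, `pos_bp`.
#' @examples
#' gm <- build_genetic_map(2, 5, 10, 2.5e5)
#' @export
build_genetic_map <- function(n_chrom, markers_per_chrom, spacing_cM, bp_per_cM) {
  if (any(c(n_chrom, markers_per_chrom, spacing_cM, bp_per_cM) <= 0)) {
    stop("all genetic map parameters must be positive")
  }
  n_chrom <- as.integer(n_chrom)
  m <- as.integer(markers_per_chrom)
  cm <- (seq_len(m) - 1L) * spacing_cM
  bp <- round(cm * bp_per_cM) + 1
  map <- data.frame(
    marker_id = paste0("c", rep(seq_len(n_chrom), each = m),
                       "_m", rep(seq_len(m), times = n_chrom)),
    chrom = paste0("chr", rep(seq_len(n_chrom), each = m)),
    pos_cM = rep(cm, times = n_chrom),
    pos_bp = rep(bp, times = n_chrom),
    stringsAsFactors = FALSE
  )
  validate_genetic_map(map)
}

#' Create a genetic map from explicit marker positions
#'
#' @param marker_id Character vector of unique marker names.
#' @param chrom Chromosome identifier per marker.
#' @param pos_cM Genetic position (cM), non-decreasing within chromosome.
#' @param pos_bp Physical position (bp, 1-based), increasing within chromosome.
#' @return A `genetic_map` data frame.
#' @export
genetic_map <- function(marker_id, chrom, pos_cM, pos_bp) {
  map <- data.frame(marker_id = as.character(marker_id),
                    chrom = as.character(chrom),
                    pos_cM = as.numeric(pos_cM),
                    pos_bp = as.numeric(pos_bp),
                    stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  stopifnot(nrow(map) >= 1)
  if (anyDuplicated(map$marker_id)) stop("marker ids must be unique")
  if (any(map$pos_cM < 0)) stop("genetic positions must be >= 0")
  if (any(map$pos_bp < 1)) stop("physical positions must be >= 1 (1-based)")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$pos_cM)) {
      stop("genetic positions must be non-decreasing within chromosome ", ch)
    }
    if (is.unsorted(sub$pos_bp, strictly = TRUE) && nrow(sub) > 1) {
      stop("physical positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans into a per-meiosis
#' recombination fraction assuming no crossover interference
#' (Poisson crossovers): r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM Genetic distance in centimorgans.
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2
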