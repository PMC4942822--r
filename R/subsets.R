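#' SNP-set strategies: interval and gene-model subsetting
#'
#' The three analysis strategies differ only in which SNPs enter the scan:
#' genome-wide (all SNPs after QC), QTL-based (SNPs inside previously
#' mapped QTL intervals, supplied as BED), and gene-based (SNPs inside
#' annotated gene spans, supplied as GFF3). BED input is 0-based
#' half-open; GFF3 is 1-based inclusive; internal SNP positions are
#' 1-based, matching VCF.
#'
#' @name strategy_subsets
NULL

#' Read QTL intervals from a BED file
#'
#' @param path BED file (0-based half-open); the optional 4th column is
#'   kept as the interval label.
#' @return A `GRanges` (1-based closed, as `rtracklayer` converts).
#' @export
read_qtl_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of `feature_type` (default `"gene"`) and uses their full
#' span — UTRs, exons and introns all included — as the membership region.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return A `GRanges` of gene spans with a `gene_id` metadata column.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == feature_type]
  ids <- gr$ID
  if (is.null(ids) || all(is.na(ids))) ids <- paste0("gene", seq_along(gr))
  gr$gene_id <- ids
  if (anyDuplicated(gr$gene_id)) stop("gene ids must be unique")
  gr
}

snp_granges <- function(geno) {
  GenomicRanges::GRanges(geno$snps$chrom,
                         IRanges::IRanges(geno$snps$pos, geno$snps$pos))
}

#' Subset SNPs by genomic intervals
#'
#' Retains SNPs whose 1-based position falls inside any interval; a SNP
#' hit by several intervals is retained once, with all hit labels recorded
#' in the result's `hits` attribute. Intervals on chromosomes absent from
#' the genotype matrix are skipped with a warning.
#'
#' @param geno A [ril_geno()].
#' @param intervals A `GRanges` (e.g. from [read_qtl_bed()]).
#' @return A [ril_geno()] with the retained SNPs, order preserved.
#' @export
subset_by_intervals <- function(geno, intervals) {
  if (!length(intervals)) {
    return(ril_geno(geno$calls[, 0, drop = FALSE], geno$snps[0, , drop = FALSE],
                    rownames(geno$calls)))
  }
  unknown <- !(as.character(GenomicRanges::seqnames(intervals)) %in%
                 unique(geno$snps$chrom))
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " interval(s) on unknown chromosomes")
    intervals <- intervals[!unknown]
  }
  ov <- suppressWarnings(GenomicRanges::findOverlaps(snp_granges(geno),
                                                     intervals))
  keep_idx <- sort(unique(S4Vectors::queryHits(ov)))
  out <- ril_geno(geno$calls[, keep_idx, drop = FALSE],
                  geno$snps[keep_idx, , drop = FALSE], rownames(geno$calls))
  labels <- if (!is.null(intervals$name)) {
    intervals$name
  } else {
    as.character(seq_along(intervals))
  }
  hits <- split(labels[S4Vectors::subjectHits(ov)],
                geno$snps$snp_id[S4Vectors::queryHits(ov)])
  attr(out, "hits") <- hits
  out
}

#' Subset SNPs by gene-model membership
#'
#' Retains SNPs within any gene span (introns and UTRs inclusive); the
#' GFF3 end coordinate is inclusive, so a SNP exactly at a span end is
#' retained.
#'
#' @param geno A [ril_geno()].
#' @param genes A `GRanges` of gene spans (from [read_gene_models()]).
#' @return A [ril_geno()] with the retained SNPs; hit gene ids in the
#'   `hits` attribute.
#' @export
subset_by_gene_models <- function(geno, genes) {
  if (length(genes) && !is.null(genes$gene_id)) genes$name <- genes$gene_id
  subset_by_intervals(geno, genes)
}
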