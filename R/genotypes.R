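#' Genotype matrix for a biparental inbred-line population
#'
#' The central genotype container: a lines x SNPs matrix of additive codes,
#' +1 for the paternal homozygote, -1 for the maternal homozygote, `NA` for
#' missing, together with per-SNP metadata (chromosome, 1-based physical
#' position, parental alleles).
#'
#' @param calls Numeric matrix, lines in rows, SNPs in columns, values in
#'   \{+1, -1, NA\}.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based bp) and optionally `paternal`, `maternal` alleles.
#' @param line_ids Character vector of line names (defaults to rownames).
#' @return An object of class `ril_geno`.
#' @export
ril_geno <- function(calls, snps, line_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(calls)))
  if (nrow(calls) < 2) stop("a population needs at least 2 lines")
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    stop("snps must have columns snp_id, chrom, pos")
  }
  if (ncol(calls) != nrow(snps)) stop("calls/snps dimension mismatch")
  if (anyDuplicated(snps$snp_id)) stop("SNP ids must be unique")
  if (any(snps$pos < 1)) stop("positions are 1-based and must be >= 1")
  ok <- calls %in% c(1, -1) | is.na(calls)
  if (!all(ok)) stop("genotype codes must be +1, -1 or NA")
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  rownames(snps) <- NULL
  dimnames(calls) <- list(as.character(line_ids), snps$snp_id)
  structure(list(calls = calls, snps = snps), class = "ril_geno")
}

#' @export
print.ril_geno <- function(x, ...) {
  cat("RIL genotype matrix:", nrow(x$calls), "lines x", ncol(x$calls), "SNPs\n")
  cat("Chromosomes:", length(unique(x$snps$chrom)), "  missing rate:",
      format(mean(is.na(x$calls)), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.ril_geno <- function(x) dim(x$calls)

#' Subset a genotype matrix by SNP ids (order preserved)
#' @param geno A [ril_geno()].
#' @param snp_ids SNP ids to keep; kept in the matrix's original order.
#' @return A `ril_geno` with the retained SNPs.
#' @export
subset_snps <- function(geno, snp_ids) {
  keep <- geno$snps$snp_id %in% snp_ids
  ril_geno(geno$calls[, keep, drop = FALSE], geno$snps[keep, , drop = FALSE],
           rownames(geno$calls))
}

#' Mean-impute missing genotype calls per SNP
#'
#' Missing codes are replaced by the SNP's mean code over non-missing lines
#' (an all-missing SNP is imputed to 0). Used before any model fitting so
#' design matrices are complete.
#'
#' @param geno A [ril_geno()].
#' @return Numeric matrix of imputed codes (lines x SNPs).
#' @export
impute_calls <- function(geno) {
  x <- geno$calls
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x))
    x[idx] <- mu[(idx - 1L) %/% nrow(x) + 1L]
  }
  x
}

#' Read genotypes from VCF or coded TSV
#'
#' For VCF input every record must be a biallelic SNP and every call
#' homozygous or missing; calls matching the paternal allele code +1,
#' the maternal allele -1. Heterozygous calls are handled per
#' `het_policy` (default: set missing). `parent_assignment` fixes which
#' allele is paternal: `"ref-paternal"` (REF allele is the paternal,
#' ZH9308-type allele) or `"ref-maternal"`.
#'
#' For TSV input the file is the coded layout written by
#' [write_geno_tsv()]: rows = lines, columns = SNP ids, values in
#' \{1, -1, NA\}, with a sidecar of SNP metadata.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`.
#' @param parent_assignment `"ref-paternal"` or `"ref-maternal"` (VCF only).
#' @param het_policy `"missing"` (default) or `"error"` for heterozygous calls.
#' @param snp_meta For TSV input, path to the SNP metadata TSV
#'   (columns snp_id, chrom, pos, paternal, maternal); defaults to
#'   `paste0(path, ".snps")`.
#' @return A [ril_geno()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"),
                           parent_assignment = c("ref-paternal", "ref-maternal"),
                           het_policy = c("missing", "error"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (format == "tsv") {
    return(read_geno_tsv(path, snp_meta))
  }
  parent_assignment <- match.arg(parent_assignment)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 | grepl(",", fix$ALT))) {
    bad <- which(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 | grepl(",", fix$ALT))
    stop("multiallelic or non-SNP records at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  code <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  hom_ref <- t(gt == "0/0")
  hom_alt <- t(gt == "1/1")
  het <- t(gt %in% c("0/1", "1/0"))
  if (any(het, na.rm = TRUE) && het_policy == "error") {
    stop("heterozygous calls present (het_policy = \"error\")")
  }
  unknown <- t(!(gt %in% c("0/0", "1/1", "0/1", "1/0", "./.", ".")) & !is.na(gt))
  if (any(unknown)) {
    idx <- which(unknown, arr.ind = TRUE)
    stop("unrecognised genotype calls at (line, snp): ",
         paste(apply(utils::head(idx, 5), 1, paste, collapse = ","), collapse = "; "))
  }
  ref_code <- if (parent_assignment == "ref-paternal") 1 else -1
  code[hom_ref & !is.na(hom_ref)] <- ref_code
  code[hom_alt & !is.na(hom_alt)] <- -ref_code
  pat <- if (parent_assignment == "ref-paternal") fix$REF else fix$ALT
  mat <- if (parent_assignment == "ref-paternal") fix$ALT else fix$REF
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- paste0(fix$CHROM, "_", fix$POS)
  }
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS),
                     paternal = pat, maternal = mat,
                     stringsAsFactors = FALSE)
  ril_geno(code, snps, line_ids = colnames(gt))
}

#' Write genotypes as a plain-text VCF 4.2 file
#'
#' Paternal (+1) codes become homozygous REF (`0/0`), maternal (-1)
#' homozygous ALT (`1/1`), missing `./.`; samples are the lines.
#'
#' @param geno A [ril_geno()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  snps <- geno$snps
  ref <- if ("paternal" %in% names(snps)) snps$paternal else rep("A", nrow(snps))
  alt <- if ("maternal" %in% names(snps)) snps$maternal else rep("T", nrow(snps))
  gt <- t(geno$calls)
  body <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  body[!is.na(gt) & gt == 1] <- "0/0"
  body[!is.na(gt) & gt == -1] <- "1/1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=qtsmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$calls)), collapse = "\t"),
    paste(snps$chrom, format(snps$pos, scientific = FALSE, trim = TRUE),
          snps$snp_id, ref, alt, ".", "PASS", ".", "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the coded-TSV genotype layout
#'
#' `write_geno_tsv()` writes rows = lines, columns = SNP ids, values in
#' \{1, -1, NA\}, plus a SNP metadata sidecar at `paste0(path, ".snps")`.
#'
#' @param geno A [ril_geno()].
#' @param path Output path for the coded matrix.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(geno, path) {
  df <- data.frame(line_id = rownames(geno$calls), geno$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(geno$snps, paste0(path, ".snps"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_geno_tsv <- function(path, snp_meta = NULL) {
  if (is.null(snp_meta)) snp_meta <- paste0(path, ".snps")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$line_id
  snps <- utils::read.delim(snp_meta, stringsAsFactors = FALSE)
  snps <- snps[match(colnames(calls), snps$snp_id), , drop = FALSE]
  ril_geno(calls, snps, df$line_id)
}

#' Swap the parental-allele assignment of every SNP
#'
#' Negates every non-missing code and exchanges the recorded parental
#' alleles; recoding is an involution.
#'
#' @param geno A [ril_geno()].
#' @return A `ril_geno` with swapped coding.
#' @export
swap_parents <- function(geno) {
  snps <- geno$snps
  if (all(c("paternal", "maternal") %in% names(snps))) {
    tmp <- snps$paternal
    snps$paternal <- snps$maternal
    snps$maternal <- tmp
  }
  ril_geno(-geno$calls, snps, rownames(geno$calls))
}
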