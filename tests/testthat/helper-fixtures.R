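# Shared fixture builders. Everything is generated in code; no stored data.

# A ril_geno with explicitly chosen call columns.
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(colnames(calls))) colnames(calls) <- paste0("s", seq_len(m))
  snps <- data.frame(
    snp_id = colnames(calls),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% (seq_len(m) * 100),
    paternal = "A", maternal = "G",
    stringsAsFactors = FALSE
  )
  qtsmap::ril_geno(calls, snps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-environment single-replicate phenotype table for given line values.
toy_pheno <- function(values, line_ids, trait = "t", environment = "E1",
                      replicate = 1) {
  data.frame(line_id = line_ids, environment = environment,
             replicate = replicate, trait = trait, value = values,
             stringsAsFactors = FALSE)
}

# A geno matrix with prescribed +1 / -1 / NA counts per SNP (rows shuffled
# deterministically so filters cannot rely on ordering).
count_geno <- function(counts, n_lines) {
  cols <- lapply(counts, function(ct) {
    v <- c(rep(1, ct[1]), rep(-1, ct[2]), rep(NA, n_lines - ct[1] - ct[2]))
    v
  })
  toy_geno(do.call(cbind, cols))
}

# Standard small simulated population used across tests.
sim_pop <- function(n_lines = 138, n_chrom = 3, markers = 12,
                    spacing_cM = 20, seed = 1) {
  map <- qtsmap::build_genetic_map(n_chrom, markers, spacing_cM, 2.5e5)
  qtsmap::simulate_ril_genotypes(map, n_lines, seed = seed)
}
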