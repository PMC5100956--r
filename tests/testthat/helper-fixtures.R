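# small in-code fixtures shared across tests

# uniform 1 cM/Mb map on one chromosome
toy_map <- function(chrom = "chr1", length_mb = 20) {
  genetic_map(chrom = rep(chrom, 2), pos = c(0, length_mb * 1e6),
              cM = c(0, length_mb))
}

# exons at given midpoint megabases, fixed length
toy_exons <- function(mid_mb, len = 1000, chrom = "chr1") {
  start <- round(mid_mb * 1e6 - len / 2)
  exon_annotation(rep(chrom, length(mid_mb)), start, start + len)
}

toy_calls <- function(pos_mb, pn, chrom = "chr1", map = NULL) {
  call_table(rep(chrom, length(pos_mb)), round(pos_mb * 1e6), pn, map = map)
}

# small synthetic genome for fast end-to-end tests
small_genome <- function(seed = 1, n_chrom = 2, chrom_cM = 40, ...) {
  synthetic_genome(n_chrom = n_chrom, chrom_cM = chrom_cM,
                   chrom_Mb = chrom_cM, seed = seed, ...)
}

# grid that contains the given values exactly (for grid-point recovery)
grid_with <- function(value, lo, hi, n = 9) {
  sort(unique(c(value, exp(seq(log(lo), log(hi), length.out = n)))))
}
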