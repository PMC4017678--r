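# shared helpers: tiny genomes and single-origin landscapes built in code

tiny_genome <- function(n_bins = 10, w = 500, chrom = "chrT") {
  genome_index(chrom, n_bins * w, bin_width = w)
}

# zero-background landscape with a single competent origin (1-based bin)
lone_ipls <- function(n_bins, origin, w = 500, chrom = "chrT") {
  v <- rep(0, n_bins)
  v[origin] <- 1
  build_ipls(binned_track(genome_index(chrom, n_bins * w, w), v),
             background = 0)
}

# S length of a single zero-background origin at 1-based bin m0 on B bins:
# one initiation step plus the longer one-bin-per-step fork travel
lone_origin_s_length <- function(B, m0) 1 + max(m0 - 1, B - m0)

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
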