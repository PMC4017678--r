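# Initiation probability landscapes (IPLS): construction from score
# tracks, TSS annotations and sequence features, plus reduced, subsampled
# and translocated landscapes.

#' Build an initiation probability landscape from a raw track
#'
#' Scales the raw per-bin values to `x / max(x)` (so the landscape is
#' invariant to the overall scale of the input), applies an amplitude map,
#' and floors at a background initiation probability. Missing bins are
#' treated as zero before flooring.
#'
#' Amplitude maps, applied to the scaled value in `[0, 1]`:
#' \describe{
#'   \item{linear}{identity (initiation probability proportional to the
#'     raw amplitude)}
#'   \item{square}{`x^2`}
#'   \item{sqrt}{`sqrt(x)`}
#'   \item{constant}{1 for every bin with positive raw value, 0 otherwise
#'     (amplitude information discarded; only site location retained)}
#' }
#'
#' @param raw A [binned_track()] of non-negative raw amplitudes with at
#'   least one positive value.
#' @param amplitude_map `"linear"` (default), `"square"`, `"sqrt"` or
#'   `"constant"`.
#' @param background Background initiation probability floor in `[0, 1)`
#'   (default `1e-4`; `0` restricts initiation to the annotated sites).
#' @return An `ipls` object (a [binned_track()] with values in `[0, 1]`).
#' @examples
#' g <- genome_index("chrT", 1500)
#' build_ipls(binned_track(g, c(2, 4, 0)))
#' @export
build_ipls <- function(raw, amplitude_map = c("linear", "square", "sqrt",
                                              "constant"),
                       background = 1e-4) {
  amplitude_map <- match.arg(amplitude_map)
  stopifnot(inherits(raw, "binned_track"))
  if (!is.numeric(background) || background < 0 || background >= 1)
    stop("background must lie in [0, 1)")
  x <- lapply(raw$values, function(v) {
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("raw landscape values must be non-negative")
    v
  })
  mx <- max(unlist(x, use.names = FALSE))
  if (mx <= 0) stop("empty landscape: no positive values in raw track")
  f <- switch(amplitude_map,
              linear = identity,
              square = function(z) z^2,
              sqrt = sqrt,
              constant = function(z) as.numeric(z > 0))
  vals <- lapply(x, function(v) pmax(f(v / mx), background))
  out <- binned_track(raw$genome, vals)
  class(out) <- c("ipls", class(out))
  attr(out, "background") <- background
  attr(out, "amplitude_map") <- amplitude_map
  out
}

#' @export
print.ipls <- function(x, ...) {
  cat("<ipls> background ", format(attr(x, "background")), ", amplitude map '",
      attr(x, "amplitude_map"), "'\n", sep = "")
  NextMethod()
}

#' Landscape from scored intervals
#'
#' Convenience wrapper: [bin_intervals()] then [build_ipls()]. This is the
#' standard route for ENCODE-style peak calls where the BED score is the
#' amplitude.
#'
#' @inheritParams build_ipls
#' @inheritParams bin_intervals
#' @param mode Within-bin aggregation of interval scores (default `"max"`:
#'   a peak score is a site property, not a density).
#' @return An `ipls`.
#' @export
ipls_from_scores <- function(intervals, genome, amplitude_map = "linear",
                             background = 1e-4, mode = "max") {
  build_ipls(bin_intervals(intervals, genome, mode = mode),
             amplitude_map = amplitude_map, background = background)
}

#' Landscape from transcription start sites
#'
#' Every bin containing at least one TSS receives initiation probability
#' 1.0; all other bins receive the background (idempotent in the number of
#' TSS per bin).
#'
#' @param tss An [interval_set()] of TSS records (1-base intervals are
#'   acceptable).
#' @inheritParams build_ipls
#' @inheritParams bin_intervals
#' @return An `ipls`.
#' @export
ipls_from_tss <- function(tss, genome, background = 1e-4) {
  build_ipls(bin_intervals(tss, genome, mode = "count"),
             amplitude_map = "constant", background = background)
}

# load sequences for a genome index; names truncated at first whitespace
.load_seqs <- function(fasta, genome) {
  seqs <- if (is.character(fasta)) {
    if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
    Biostrings::readDNAStringSet(fasta)
  } else if (is(fasta, "DNAStringSet")) fasta
  else stop("fasta must be a file path or a DNAStringSet")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(genome$chromosomes, names(seqs))
  if (length(missing))
    stop("chromosome(s) in genome index absent from FASTA: ",
         paste(missing, collapse = ", "))
  seqs[genome$chromosomes]
}

.bin_views <- function(seq, genome, ch) {
  w <- genome$bin_width
  nb <- n_bins(genome, ch)[[1]]
  len <- min(genome$lengths[[ch]], length(seq))
  nb_seq <- as.integer(ceiling(len / w))
  widths <- rep(w, nb_seq)
  if (len %% w) widths[nb_seq] <- len %% w
  list(views = IRanges::successiveViews(seq, widths), nb = nb,
       nb_seq = nb_seq)
}

#' GC-content landscape
#'
#' Per-bin fraction of G+C bases, scaled and floored by [build_ipls()].
#'
#' @param fasta FASTA path or `DNAStringSet` covering every chromosome of
#'   `genome`.
#' @inheritParams build_ipls
#' @param genome A [genome_index()].
#' @return An `ipls`.
#' @export
ipls_from_gc <- function(fasta, genome, amplitude_map = "linear",
                         background = 1e-4) {
  seqs <- .load_seqs(fasta, genome)
  vals <- lapply(genome$chromosomes, function(ch) {
    bv <- .bin_views(seqs[[ch]], genome, ch)
    lf <- Biostrings::letterFrequency(bv$views, letters = c("G", "C"))
    v <- numeric(bv$nb)
    v[seq_len(bv$nb_seq)] <- rowSums(lf) / BiocGenerics::width(bv$views)
    v
  })
  names(vals) <- genome$chromosomes
  build_ipls(binned_track(genome, vals), amplitude_map = amplitude_map,
             background = background)
}

#' CpG observed/expected landscape
#'
#' Per-bin CpG observed/expected ratio,
#' `(#CG dinucleotides * bin length) / (#C * #G)`, zero where `#C * #G = 0`,
#' then scaled and floored by [build_ipls()].
#'
#' @inheritParams ipls_from_gc
#' @return An `ipls`.
#' @export
ipls_from_cpg <- function(fasta, genome, amplitude_map = "linear",
                          background = 1e-4) {
  seqs <- .load_seqs(fasta, genome)
  vals <- lapply(genome$chromosomes, function(ch) {
    bv <- .bin_views(seqs[[ch]], genome, ch)
    vs <- as(bv$views, "DNAStringSet")
    cg <- Biostrings::vcountPattern("CG", vs)
    nc <- as.numeric(Biostrings::letterFrequency(vs, "C"))
    ng <- as.numeric(Biostrings::letterFrequency(vs, "G"))
    wd <- BiocGenerics::width(vs)
    oe <- ifelse(nc * ng > 0, cg * wd / (nc * ng), 0)
    v <- numeric(bv$nb)
    v[seq_len(bv$nb_seq)] <- oe
    v
  })
  names(vals) <- genome$chromosomes
  build_ipls(binned_track(genome, vals), amplitude_map = amplitude_map,
             background = background)
}

#' G-quadruplex motif landscape
#'
#' Scans both strands with the canonical quadruplex pattern (four runs of
#' at least `g_run` G separated by loops of `loop_min`--`loop_max` bases;
#' the C-run mirror detects minus-strand motifs), non-overlapping greedy
#' scan per strand. The per-bin raw value is the maximum motif length
#' overlapping the bin, so initiation probability scales with motif length.
#'
#' @inheritParams ipls_from_gc
#' @param g_run Minimum G-run length (default 3).
#' @param loop_min,loop_max Loop length bounds in bases (defaults 1 and 7).
#' @return An `ipls`.
#' @export
ipls_from_g4 <- function(fasta, genome, g_run = 3, loop_min = 1,
                         loop_max = 7, amplitude_map = "linear",
                         background = 1e-4) {
  seqs <- .load_seqs(fasta, genome)
  loop <- sprintf("[ACGTN]{%d,%d}", loop_min, loop_max)
  pat <- function(base) paste0(rep(sprintf("%s{%d,}", base, g_run), 4),
                               c(loop, loop, loop, ""), collapse = "")
  pats <- c(pat("G"), pat("C"))
  w <- genome$bin_width
  vals <- lapply(genome$chromosomes, function(ch) {
    s <- as.character(seqs[[ch]])
    nbc <- n_bins(genome, ch)[[1]]
    v <- numeric(nbc)
    for (p in pats) {
      m <- gregexpr(p, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m) - 1L            # to 0-based
      lens <- attr(m, "match.length")
      b0 <- starts %/% w + 1
      b1 <- (starts + lens - 1) %/% w + 1
      nper <- b1 - b0 + 1
      bins <- unlist(Map(seq.int, b0, b1), use.names = FALSE)
      lrep <- rep(lens, nper)
      agg <- tapply(lrep, bins, max)
      idx <- as.integer(names(agg))
      keep <- idx <= nbc
      v[idx[keep]] <- pmax(v[idx[keep]], as.numeric(agg)[keep])
    }
    v
  })
  names(vals) <- genome$chromosomes
  build_ipls(binned_track(genome, vals), amplitude_map = amplitude_map,
             background = background)
}

# ---------------------------------------------------------------------------
# reduced landscapes

#' Remove intervals co-localized with another annotation
#'
#' Drops every record of `a` that overlaps at least one base of any record
#' of `b` ("Subtract Overlap" reduced landscape). `slop` symmetrically
#' widens the records of `b` before the overlap test.
#'
#' @param a,b [interval_set()]s.
#' @param slop Bases added on each side of `b` records (default 0).
#' @return The reduced [interval_set()].
#' @export
subtract_overlap <- function(a, b, slop = 0) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  if (!nrow(a) || !nrow(b)) return(a)
  gra <- .as_granges(a)
  grb <- .as_granges(b)
  if (slop > 0) grb <- grb + slop
  ov <- IRanges::overlapsAny(gra, grb)
  a[!ov, , drop = FALSE]
}

#' Remove a fixed number of randomly chosen intervals
#'
#' Size-matched control for [subtract_overlap()] ("Subtract Random"): the
#' removed records are chosen uniformly without replacement, so the
#' reduced set has the same size as the overlap-subtracted one when `k`
#' equals the number of overlapping records.
#'
#' @param a An [interval_set()].
#' @param k Number of records to remove (`0 <= k <= nrow(a)`).
#' @param seed Integer seed.
#' @return The reduced [interval_set()].
#' @export
subtract_random <- function(a, k, seed = 1) {
  stopifnot(inherits(a, "interval_set"))
  k <- as.integer(k)
  if (k < 0 || k > nrow(a))
    stop("k must lie between 0 and the number of records (", nrow(a), ")")
  set.seed(seed)
  drop <- sample.int(nrow(a), k)
  if (length(drop)) a[-drop, , drop = FALSE] else a
}

#' Subsample an interval set
#'
#' Retains `round(keep_fraction * n)` records uniformly without
#' replacement; used to probe robustness to incomplete annotations.
#'
#' @param a An [interval_set()].
#' @param keep_fraction Fraction of records to keep, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The subsampled [interval_set()].
#' @export
subsample_intervals <- function(a, keep_fraction, seed = 1) {
  stopifnot(inherits(a, "interval_set"))
  if (keep_fraction < 0 || keep_fraction > 1)
    stop("keep_fraction must lie in [0, 1]")
  n_keep <- round(keep_fraction * nrow(a))
  if (n_keep == nrow(a)) return(a)
  set.seed(seed)
  a[sort(sample.int(nrow(a), n_keep)), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# in-silico translocation

#' Fuse two chromosome landscapes at a translocation breakpoint
#'
#' Builds the landscape of a derivative chromosome: for
#' `orientation = "AB"`, `a[0, breakpoint_a)` concatenated with
#' `b[breakpoint_b, end)`; `orientation = "BA"` gives the reciprocal
#' product `b[0, breakpoint_b)` + `a[breakpoint_a, end)`. The bin grid is
#' re-derived from the fused length. A breakpoint bin that straddles the
#' junction takes the landscape value of the donor segment covering the
#' majority of the bin, so no probabilities are fabricated. A mapping table
#' from fused bins back to source coordinates is returned alongside.
#'
#' @param ipls_a,ipls_b Source `ipls` objects.
#' @param chrom_a,chrom_b Source chromosome names.
#' @param breakpoint_a,breakpoint_b Breakpoints in bases (0-based), within
#'   the respective chromosomes.
#' @param orientation `"AB"` (default) or `"BA"`.
#' @param name Name of the derivative chromosome.
#' @return A list with components `ipls` (single-chromosome landscape of
#'   the fusion) and `map` (data frame: fused bin, source chromosome,
#'   source start/end in bases).
#' @export
fuse_translocation <- function(ipls_a, ipls_b, chrom_a, chrom_b,
                               breakpoint_a, breakpoint_b,
                               orientation = c("AB", "BA"), name = "der") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(ipls_a, "ipls"), inherits(ipls_b, "ipls"))
  if (ipls_a$genome$bin_width != ipls_b$genome$bin_width)
    stop("landscapes must share a bin width")
  if (!chrom_a %in% ipls_a$genome$chromosomes)
    stop("unknown chromosome: ", chrom_a)
  if (!chrom_b %in% ipls_b$genome$chromosomes)
    stop("unknown chromosome: ", chrom_b)
  len_a <- ipls_a$genome$lengths[[chrom_a]]
  len_b <- ipls_b$genome$lengths[[chrom_b]]
  if (breakpoint_a < 0 || breakpoint_a > len_a)
    stop("breakpoint_a beyond chromosome end")
  if (breakpoint_b < 0 || breakpoint_b > len_b)
    stop("breakpoint_b beyond chromosome end")
  if (orientation == "BA")
    return(fuse_translocation(ipls_b, ipls_a, chrom_b, chrom_a,
                              breakpoint_b, breakpoint_a,
                              orientation = "AB", name = name))

  w <- ipls_a$genome$bin_width
  fused_len <- breakpoint_a + (len_b - breakpoint_b)
  if (fused_len < 1) stop("fused chromosome would be empty")
  g <- genome_index(name, fused_len, bin_width = w)
  nbf <- n_bins(g)[[1]]
  va <- ipls_a$values[[chrom_a]]
  vb <- ipls_b$values[[chrom_b]]

  bins <- seq_len(nbf)
  mid <- pmin((bins - 1) * w + w / 2, fused_len)
  from_a <- mid <= breakpoint_a
  src_coord <- ifelse(from_a, mid, breakpoint_b + (mid - breakpoint_a))
  src_bin <- pmin(floor(src_coord / w) + 1,
                  ifelse(from_a, length(va), length(vb)))
  v <- ifelse(from_a, va[pmin(src_bin, length(va))],
              vb[pmin(src_bin, length(vb))])

  out <- binned_track(g, v)
  class(out) <- c("ipls", class(out))
  attr(out, "background") <- min(attr(ipls_a, "background"),
                                 attr(ipls_b, "background"))
  attr(out, "amplitude_map") <- attr(ipls_a, "amplitude_map")
  map <- data.frame(
    fused_bin = bins,
    source = ifelse(from_a, chrom_a, chrom_b),
    source_start = ifelse(from_a, (bins - 1) * w,
                          breakpoint_b + ((bins - 1) * w - breakpoint_a)),
    stringsAsFactors = FALSE)
  map$source_end <- map$source_start + pmin(w, fused_len - (bins - 1) * w)
  list(ipls = out, map = map)
}
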