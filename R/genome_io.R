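# Genome grid, binned tracks, interval sets and standard track formats.
#
# All genomic inputs follow the BED convention: 0-based, half-open
# coordinates. Bin k (1-based in R) covers bases [(k-1)*w, k*w) for bin
# width w; an interval ending exactly at a bin boundary does not touch the
# next bin.

#' Genome index on a fixed bin grid
#'
#' Describes the chromosomes of the simulated territory and the fixed-width
#' bin grid (default 500 bp, the resolution at which landscapes and timing
#' profiles are represented) onto which all tracks are projected.
#'
#' @param chromosomes Character vector of unique chromosome names.
#' @param lengths Positive chromosome lengths in bases, one per chromosome.
#' @param bin_width Bin width in bases (default 500).
#' @return A `genome_index` object.
#' @examples
#' genome_index("chrT", 5000)
#' @export
genome_index <- function(chromosomes, lengths, bin_width = 500) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have the same length")
  if (length(chromosomes) < 1) stop("at least one chromosome is required")
  if (anyDuplicated(chromosomes))
    stop("duplicate chromosome name: ",
         paste(unique(chromosomes[duplicated(chromosomes)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1) stop("bin_width must be >= 1")
  structure(list(chromosomes = chromosomes,
                 lengths = setNames(lengths, chromosomes),
                 bin_width = bin_width),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", length(x$chromosomes), " chromosome(s), bin width ",
      x$bin_width, " bp, ", sum(n_bins(x)), " bins\n", sep = "")
  invisible(x)
}

#' Number of bins per chromosome
#'
#' @param genome A [genome_index()].
#' @param chrom Optional chromosome name(s); default all.
#' @return Named integer vector, `ceiling(length / bin_width)` per chromosome.
#' @export
n_bins <- function(genome, chrom = NULL) {
  stopifnot(inherits(genome, "genome_index"))
  len <- if (is.null(chrom)) genome$lengths else genome$lengths[chrom]
  if (anyNA(len)) stop("unknown chromosome: ", paste(chrom[!chrom %in%
    genome$chromosomes], collapse = ", "))
  setNames(as.integer(ceiling(len / genome$bin_width)), names(len))
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-delimited text, chromosome name then length in
#' bases (UCSC chrom.sizes style). Extra columns are ignored.
#'
#' @inheritParams genome_index
#' @param path Path to the file.
#' @return A [genome_index()].
#' @export
read_chrom_sizes <- function(path, bin_width = 500) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes needs two columns (name, length): ", path)
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len)) stop("non-numeric length at line ", which(is.na(len))[1],
                       " of ", path)
  genome_index(df[[1]], len, bin_width = bin_width)
}

# ---------------------------------------------------------------------------
# binned tracks

#' Per-bin numeric track on a genome grid
#'
#' Carrier for landscapes, timing profiles and difference profiles: one
#' numeric value per bin per chromosome. `NA` marks bins with no data.
#'
#' @param genome A [genome_index()].
#' @param values Named list (one numeric vector per chromosome, lengths
#'   matching [n_bins()]), a single numeric vector (single-chromosome
#'   genome), or `NULL` to fill with `fill`.
#' @param fill Value used when `values` is `NULL` (default `NA`).
#' @return A `binned_track` object.
#' @export
binned_track <- function(genome, values = NULL, fill = NA_real_) {
  stopifnot(inherits(genome, "genome_index"))
  nb <- n_bins(genome)
  if (is.null(values)) {
    values <- lapply(nb, function(n) rep(as.numeric(fill), n))
  } else if (is.numeric(values) && length(genome$chromosomes) == 1L) {
    values <- setNames(list(as.numeric(values)), genome$chromosomes)
  }
  if (!is.list(values) || is.null(names(values)))
    stop("values must be a named list of per-chromosome numeric vectors")
  if (!setequal(names(values), genome$chromosomes))
    stop("values must cover exactly the chromosomes of the genome index")
  values <- lapply(values[genome$chromosomes], as.numeric)
  ok <- vapply(genome$chromosomes,
               function(ch) length(values[[ch]]) == nb[[ch]], logical(1))
  if (!all(ok))
    stop("value vector length mismatch on: ",
         paste(genome$chromosomes[!ok], collapse = ", "))
  structure(list(genome = genome, values = values), class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat("<", class(x)[1], "> ", length(v), " bins on ",
      length(x$genome$chromosomes), " chromosome(s); ",
      sum(is.na(v)), " missing\n", sep = "")
  if (any(!is.na(v)))
    cat("  value range: [", format(min(v, na.rm = TRUE)), ", ",
        format(max(v, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Flatten a binned track to a single numeric vector
#'
#' Concatenates per-chromosome values in genome order; used for genome-wide
#' comparisons.
#' @param track A [binned_track()].
#' @return Numeric vector.
#' @export
track_values <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  unlist(track$values[track$genome$chromosomes], use.names = FALSE)
}

#' Restrict a binned track to a subset of chromosomes
#'
#' @param track A [binned_track()].
#' @param chrom Chromosome name(s) to keep.
#' @return A [binned_track()] on the reduced genome; other attributes
#'   (class, background) are preserved.
#' @export
subset_track <- function(track, chrom) {
  stopifnot(inherits(track, "binned_track"))
  g <- track$genome
  if (!all(chrom %in% g$chromosomes))
    stop("unknown chromosome: ", paste(setdiff(chrom, g$chromosomes),
                                       collapse = ", "))
  g2 <- genome_index(chrom, g$lengths[chrom], g$bin_width)
  out <- binned_track(g2, track$values[chrom])
  attributes(out) <- c(attributes(out),
                       attributes(track)[setdiff(names(attributes(track)),
                                                 c("names", "class"))])
  class(out) <- class(track)
  out
}

.same_grid <- function(a, b) {
  identical(a$genome$chromosomes, b$genome$chromosomes) &&
    identical(as.numeric(a$genome$lengths), as.numeric(b$genome$lengths)) &&
    a$genome$bin_width == b$genome$bin_width
}

# ---------------------------------------------------------------------------
# interval sets

#' Genomic interval set (BED convention)
#'
#' Records of (chromosome, start, end, score) with 0-based, half-open
#' coordinates. Scores are non-negative amplitudes (ENCODE-style peak
#' scores, motif lengths, ...).
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param score Non-negative scores, recycled (default 1).
#' @return An `interval_set` (a data frame).
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), score = 1) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   score = rep(as.numeric(score),
                               length.out = length(chrom)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0)) stop("interval start must be >= 0")
    if (any(df$end <= df$start)) stop("interval end must exceed start")
    if (any(!is.finite(df$score)) || any(df$score < 0))
      stop("scores must be finite and non-negative")
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

.as_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

#' Read intervals from a BED file
#'
#' Uses `rtracklayer` to parse BED (>= 4 columns when scores are used); the
#' score column is taken as the amplitude, defaulting to 1 when absent.
#'
#' @param path Path to a BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("failed to parse BED ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  sc <- gr$score
  if (is.null(sc)) sc <- rep(1, length(gr))
  sc[is.na(sc)] <- 1
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               BiocGenerics::start(gr) - 1, BiocGenerics::end(gr), sc)
}

#' Write an interval set as BED
#'
#' @param intervals An [interval_set()].
#' @param path Output path.
#' @param names Optional feature names (default `feature_i`).
#' @export
write_bed <- function(intervals, path, names = NULL) {
  n <- nrow(intervals)
  if (is.null(names)) names <- paste0("feature_", seq_len(n))
  df <- data.frame(intervals$chrom, format_coord(intervals$start),
                   format_coord(intervals$end), names,
                   formatC(intervals$score, digits = 15, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) formatC(x, format = "d")

#' Aggregate interval scores onto the bin grid
#'
#' Each interval contributes its score to every bin it overlaps (for
#' `mode = "max"` the full score, treating the score as a site property);
#' bins untouched by any interval carry 0. Intervals are clipped to the
#' chromosome; intervals on chromosomes absent from the index are skipped
#' with a warning reporting their count.
#'
#' @param intervals An [interval_set()].
#' @param genome A [genome_index()].
#' @param mode Aggregation within a bin: `"max"` (default), `"sum"`,
#'   `"mean"` or `"count"` (number of overlapping intervals, ignoring
#'   scores).
#' @return A [binned_track()] (no missing bins; untouched bins are 0).
#' @export
bin_intervals <- function(intervals, genome,
                          mode = c("max", "sum", "mean", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "genome_index"))
  w <- genome$bin_width
  nb <- n_bins(genome)
  vals <- lapply(nb, function(n) numeric(n))
  unknown <- !(intervals$chrom %in% genome$chromosomes)
  if (any(unknown))
    warning(sum(unknown), " interval(s) on chromosomes absent from the ",
            "genome index were skipped")
  iv <- intervals[!unknown, , drop = FALSE]
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    len <- genome$lengths[[ch]]
    s <- pmax(0, sub$start)
    e <- pmin(len, sub$end)
    keep <- e > s
    s <- s[keep]; e <- e[keep]; sc <- sub$score[keep]
    if (!length(s)) next
    b0 <- s %/% w + 1
    b1 <- (e - 1) %/% w + 1
    nper <- b1 - b0 + 1
    bins <- unlist(Map(seq.int, b0, b1), use.names = FALSE)
    x <- if (mode == "count") rep(1, length(bins)) else rep(sc, nper)
    agg <- switch(mode,
                  max = tapply(x, bins, max),
                  sum = ,
                  count = tapply(x, bins, sum),
                  mean = tapply(x, bins, mean))
    vals[[ch]][as.integer(names(agg))] <- as.numeric(agg)
  }
  binned_track(genome, vals)
}

# ---------------------------------------------------------------------------
# track reading / writing

.guess_track_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bedgraph = , bg = "bedGraph",
         wig = "wig",
         tsv = , txt = , tab = "tsv",
         stop("cannot infer track format from extension: ", path))
}

#' Read a value track and project it onto the bin grid
#'
#' Supports bedGraph, fixed-step wiggle (both via `rtracklayer`) and
#' headerless 4-column TSV (chrom, start, end, value; BED-style
#' coordinates). When the source resolution differs from the bin grid,
#' values are averaged into bins weighted by overlap width. Bins with no
#' data are `NA`.
#'
#' @param path Path to the track file.
#' @param genome A [genome_index()].
#' @param format `"bedGraph"`, `"wig"` or `"tsv"`; inferred from the file
#'   extension when `NULL`.
#' @return A [binned_track()].
#' @export
read_track <- function(path, genome, format = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (is.null(format)) format <- .guess_track_format(path)
  format <- match.arg(format, c("bedGraph", "wig", "tsv"))
  if (format == "tsv") {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (ncol(df) < 4) stop("TSV track needs 4 columns: ", path)
    num <- lapply(df[2:4], function(col) suppressWarnings(as.numeric(col)))
    bad <- which(is.na(num[[1]]) | is.na(num[[2]]) | is.na(num[[3]]))
    if (length(bad)) stop("malformed line ", bad[1], " in ", path)
    iv <- data.frame(chrom = df[[1]], start = num[[1]], end = num[[2]],
                     value = num[[3]], stringsAsFactors = FALSE)
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = format),
                   error = function(e)
                     stop("failed to parse ", format, " ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1,
                     end = BiocGenerics::end(gr),
                     value = as.numeric(gr$score), stringsAsFactors = FALSE)
  }
  .project_weighted_mean(iv, genome)
}

# overlap-width-weighted mean of source interval values per bin
.project_weighted_mean <- function(iv, genome) {
  w <- genome$bin_width
  nb <- n_bins(genome)
  vals <- lapply(nb, function(n) rep(NA_real_, n))
  unknown <- !(iv$chrom %in% genome$chromosomes)
  if (any(unknown))
    warning(sum(unknown), " record(s) on chromosomes absent from the ",
            "genome index were skipped")
  iv <- iv[!unknown, , drop = FALSE]
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    len <- genome$lengths[[ch]]
    s <- pmax(0, sub$start)
    e <- pmin(len, sub$end)
    keep <- e > s
    s <- s[keep]; e <- e[keep]; v <- sub$value[keep]
    if (!length(s)) next
    b0 <- s %/% w + 1
    b1 <- (e - 1) %/% w + 1
    nper <- b1 - b0 + 1
    bins <- unlist(Map(seq.int, b0, b1), use.names = FALSE)
    srep <- rep(s, nper); erep <- rep(e, nper); vrep <- rep(v, nper)
    ow <- pmin(erep, bins * w) - pmax(srep, (bins - 1) * w)
    num <- tapply(vrep * ow, bins, sum)
    den <- tapply(ow, bins, sum)
    idx <- as.integer(names(num))
    out <- as.numeric(num) / as.numeric(den)
    # bins fed by a single source record take its value verbatim, so
    # write-then-read round-trips are exact
    cnt <- as.numeric(tapply(ow, bins, length))
    if (any(cnt == 1)) {
      first <- as.numeric(tapply(vrep, bins, function(z) z[1]))
      out[cnt == 1] <- first[cnt == 1]
    }
    vals[[ch]][idx] <- out
  }
  binned_track(genome, vals)
}

#' Write a binned track
#'
#' Writes one record per non-missing bin, full precision (round-trips
#' through [read_track()] within 1e-9).
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @param format `"bedGraph"` (4 columns) or `"tsv"` (identical layout,
#'   tab-separated).
#' @return The path, invisibly.
#' @export
write_track <- function(track, path, format = c("bedGraph", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(track, "binned_track"))
  g <- track$genome
  w <- g$bin_width
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in g$chromosomes) {
    v <- track$values[[ch]]
    idx <- which(!is.na(v))
    if (!length(idx)) next
    start <- (idx - 1) * w
    end <- pmin(idx * w, g$lengths[[ch]])
    writeLines(paste(ch, format_coord(start), format_coord(end),
                     formatC(v[idx], digits = 17, format = "g"),
                     sep = "\t"), con)
  }
  invisible(path)
}
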