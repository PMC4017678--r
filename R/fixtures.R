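# Deterministic generators of synthetic genomes, site landscapes,
# sequences and pseudo-empirical timing profiles. Everything here is a
# pure function of (spec, seed), so every stage of the pipeline is
# testable without downloads.

#' Specification of a synthetic landscape fixture
#'
#' Site models:
#' \describe{
#'   \item{clustered}{`n_clusters` clusters at known, evenly spaced
#'     centers, `sites_per_cluster` sites each within `cluster_width`
#'     bins — distance-to-nearest-site is computable from the returned
#'     centers.}
#'   \item{uniform}{`n_sites` sites at uniformly random bins.}
#'   \item{lone}{a single site at `lone_bin` (the closed-form single
#'     origin oracle input).}
#' }
#' Site amplitudes are gamma-distributed (shape 2, scale 1, mimicking
#' right-skewed peak scores) or constant 1.
#'
#' @param n_bins Bins per chromosome (recycled over chromosomes).
#' @param bin_width Bin width in bases (default 500).
#' @param sites Site model: `"clustered"`, `"uniform"` or `"lone"`.
#' @param n_clusters,cluster_width,sites_per_cluster Clustered-model
#'   parameters (defaults 5 clusters of 10 sites within 20 bins).
#' @param n_sites Uniform-model site count (default 100).
#' @param lone_bin Lone-model site bin (1-based, default 1).
#' @param amplitude `"gamma"` or `"constant"`.
#' @param background Landscape background floor (default 1e-4).
#' @param chromosomes Chromosome name(s) (default "chrF").
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_bins = 2000, bin_width = 500,
                         sites = c("clustered", "uniform", "lone"),
                         n_clusters = 5, cluster_width = 20,
                         sites_per_cluster = 10, n_sites = 100,
                         lone_bin = 1, amplitude = c("gamma", "constant"),
                         background = 1e-4, chromosomes = "chrF",
                         seed = 1) {
  sites <- match.arg(sites)
  amplitude <- match.arg(amplitude)
  stopifnot(all(n_bins >= 1), bin_width >= 1, n_clusters >= 1,
            cluster_width >= 1, sites_per_cluster >= 1, n_sites >= 1)
  structure(list(n_bins = rep(as.integer(n_bins),
                              length.out = length(chromosomes)),
                 bin_width = as.integer(bin_width), sites = sites,
                 n_clusters = as.integer(n_clusters),
                 cluster_width = as.integer(cluster_width),
                 sites_per_cluster = as.integer(sites_per_cluster),
                 n_sites = as.integer(n_sites),
                 lone_bin = as.integer(lone_bin), amplitude = amplitude,
                 background = background, chromosomes = chromosomes,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic landscape with known ground truth
#'
#' @param spec A [fixture_spec()].
#' @return List: `ipls`, `genome`, `sites` (named list of site bins per
#'   chromosome), `centers` (cluster centers, clustered model only),
#'   `intervals` (an [interval_set()] of the sites, 100-bp features inside
#'   their bins).
#' @export
make_ipls_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  w <- spec$bin_width
  genome <- genome_index(spec$chromosomes,
                         as.numeric(spec$n_bins) * w, bin_width = w)
  set.seed(spec$seed)
  site_bins <- list()
  centers <- list()
  iv_rows <- list()
  for (i in seq_along(spec$chromosomes)) {
    ch <- spec$chromosomes[i]
    B <- spec$n_bins[i]
    bins <- switch(spec$sites,
      lone = spec$lone_bin,
      uniform = sample.int(B, min(spec$n_sites, B)),
      clustered = {
        k <- spec$n_clusters
        ctr <- round((seq_len(k) - 0.5) * B / k)
        centers[[ch]] <- ctr
        half <- max(1L, spec$cluster_width %/% 2L)
        unlist(lapply(ctr, function(c0)
          pmax(1L, pmin(B, c0 + sample(seq(-half, half),
                                       spec$sites_per_cluster,
                                       replace = TRUE)))))
      })
    if (any(bins < 1 | bins > B)) stop("site bin outside territory")
    amp <- switch(spec$amplitude,
                  gamma = rgamma(length(bins), shape = 2, scale = 1) + 0.05,
                  constant = rep(1, length(bins)))
    site_bins[[ch]] <- bins
    start <- (bins - 1) * w + round(0.4 * w)
    iv_rows[[ch]] <- data.frame(chrom = ch, start = start,
                                end = start + max(1, round(0.2 * w)),
                                score = amp, stringsAsFactors = FALSE)
  }
  iv <- do.call(rbind, iv_rows)
  rownames(iv) <- NULL
  intervals <- interval_set(iv$chrom, iv$start, iv$end, iv$score)
  ip <- ipls_from_scores(intervals, genome, background = spec$background)
  list(ipls = ip, genome = genome, sites = site_bins, centers = centers,
       intervals = intervals, spec = spec)
}

#' Pseudo-empirical timing profile
#'
#' Runs the real engine at a fixed seed and gates the population with the
#' given (possibly non-equidistant) gate boundaries; the result serves as
#' a reference profile for gate-recovery and comparison tests.
#'
#' @param ipls An `ipls`.
#' @param n_factors,n_cycles,snapshot_period,seed Engine settings.
#' @param gates A [gate_spec()].
#' @return A `timing_profile`.
#' @export
make_pseudo_empirical <- function(ipls, n_factors = "auto", n_cycles = 500,
                                  gates = equidistant_gates(6), seed = 1,
                                  snapshot_period = 10) {
  st <- simulate_replication(ipls, n_factors = n_factors,
                             n_cycles = n_cycles,
                             snapshot_period = snapshot_period, seed = seed)
  timing_profile(st, gates)
}

#' Synthetic sequence with planted features
#'
#' Generates an A/T background and plants, at known bins, literal
#' G-quadruplex motifs (plus strand), their reverse complements (minus
#' strand) and GC-rich stretches, for testing the sequence-based landscape
#' builders.
#'
#' @param n_bins Bins on the single synthetic chromosome.
#' @param bin_width Bin width (default 500).
#' @param g4_bins Bins receiving a plus-strand `GGGTGGGTGGGTGGG` motif.
#' @param g4_revcomp_bins Bins receiving the reverse complement motif.
#' @param gc_rich_bins Bins filled with `GC` repeats.
#' @param chromosome Chromosome name.
#' @param seed Integer seed.
#' @param fasta Optional path; when given, the sequence is written there.
#' @return List: `seqs` (`DNAStringSet`), `genome`, `motif`, and `fasta`
#'   (path or `NULL`).
#' @export
make_sequence_fixture <- function(n_bins = 20, bin_width = 500,
                                  g4_bins = integer(),
                                  g4_revcomp_bins = integer(),
                                  gc_rich_bins = integer(),
                                  chromosome = "chrS", seed = 1,
                                  fasta = NULL) {
  set.seed(seed)
  len <- n_bins * bin_width
  base <- sample(c("A", "T"), len, replace = TRUE)
  motif <- "GGGTGGGTGGGTGGG"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  plant <- function(seq, bins, what) {
    for (b in bins) {
      at <- (b - 1) * bin_width + max(1, bin_width %/% 2 -
                                        nchar(what) %/% 2)
      seq[at:(at + nchar(what) - 1)] <- strsplit(what, "")[[1]]
    }
    seq
  }
  base <- plant(base, g4_bins, motif)
  base <- plant(base, g4_revcomp_bins, rc)
  for (b in gc_rich_bins) {
    at <- (b - 1) * bin_width + 1
    base[at:(at + bin_width - 1)] <- rep(c("G", "C"),
                                         length.out = bin_width)
  }
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- chromosome
  if (!is.null(fasta)) Biostrings::writeXStringSet(seqs, fasta)
  list(seqs = seqs,
       genome = genome_index(chromosome, len, bin_width = bin_width),
       motif = motif, fasta = fasta)
}
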