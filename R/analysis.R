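# Downstream statistics: profile comparison, plasticity-region calling,
# fork-count scanning with the linear length fit, S-phase statistics,
# robustness curves, the global initiation rate and all-pairs profile
# correlation.

#' Compare two timing profiles
#'
#' Pearson correlation per chromosome over pairwise-complete bins, their
#' unweighted mean across chromosomes and the standard error of that mean.
#'
#' @param a,b [binned_track()]s on the same bin grid.
#' @param flip Negate `b` before correlating, for empirical tracks whose
#'   convention is higher = earlier (the simulator emits lower = earlier).
#' @return A `profile_comparison` list: `per_chromosome` (named vector of
#'   r), `mean`, `sem`, `n_bins` (shared defined bins used).
#' @export
compare_profiles <- function(a, b, flip = FALSE) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  if (!.same_grid(a, b)) stop("profiles must share a bin grid")
  rs <- c()
  n_total <- 0
  for (ch in a$genome$chromosomes) {
    x <- a$values[[ch]]
    y <- b$values[[ch]]
    if (flip) y <- -y
    ok <- !is.na(x) & !is.na(y)
    n_total <- n_total + sum(ok)
    r <- if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0)
      cor(x[ok], y[ok]) else NA_real_
    rs[ch] <- r
  }
  if (n_total < 3) stop("fewer than 3 shared defined bins")
  m <- mean(rs, na.rm = TRUE)
  nn <- sum(!is.na(rs))
  sem <- if (nn > 1) sd(rs, na.rm = TRUE) / sqrt(nn) else NA_real_
  structure(list(per_chromosome = rs, mean = m, sem = sem,
                 n_bins = n_total),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("<profile_comparison> mean r = ", format(x$mean, digits = 4),
      " (sem ", format(x$sem, digits = 3), ") over ",
      length(x$per_chromosome), " chromosome(s), ", x$n_bins, " bins\n",
      sep = "")
  invisible(x)
}

#' Call replication plasticity regions
#'
#' Subtracts profile `b` from profile `a` bin-wise, fits a normal null to
#' the full distribution of differences (moment estimates over all defined
#' bins; `robust = TRUE` uses median/MAD instead), assigns a two-sided
#' p-value to every bin, and reports maximal runs of at least `min_run`
#' consecutive bins at `p <= alpha` (missing bins break runs).
#'
#' @param a,b [binned_track()]s on the same grid.
#' @param alpha Per-bin significance level (default 0.001).
#' @param min_run Minimum run length in bins (default 3).
#' @param robust Use median/MAD null parameters (default `FALSE`).
#' @return A `plasticity_regions` data frame: chrom, start_bin, end_bin
#'   (inclusive), start, end (bases), n_bins, min_p, direction (sign of
#'   the mean difference). Attributes `mu` and `sigma` carry the fitted
#'   null.
#' @export
call_plasticity_regions <- function(a, b, alpha = 0.001, min_run = 3,
                                    robust = FALSE) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  if (!.same_grid(a, b)) stop("profiles must share a bin grid")
  d <- lapply(a$genome$chromosomes,
              function(ch) a$values[[ch]] - b$values[[ch]])
  names(d) <- a$genome$chromosomes
  all_d <- unlist(d, use.names = FALSE)
  all_d <- all_d[!is.na(all_d)]
  if (length(all_d) < 2) stop("too few defined difference bins")
  if (robust) {
    mu <- median(all_d)
    sigma <- mad(all_d)
  } else {
    mu <- mean(all_d)
    sigma <- sd(all_d)
  }
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate difference profile (zero variance)")
  w <- a$genome$bin_width
  rows <- list()
  for (ch in a$genome$chromosomes) {
    dv <- d[[ch]]
    p <- 2 * pnorm(-abs((dv - mu) / sigma))
    sig <- !is.na(p) & p <= alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= min_run)) {
      bins <- starts[i]:ends[i]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start_bin = starts[i], end_bin = ends[i],
        start = (starts[i] - 1) * w,
        end = min(ends[i] * w, a$genome$lengths[[ch]]),
        n_bins = length(bins), min_p = min(p[bins]),
        direction = sign(mean(dv[bins])), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), start = numeric(), end = numeric(),
               n_bins = integer(), min_p = numeric(), direction = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("plasticity_regions", "data.frame")
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Write plasticity regions as BED5
#'
#' Score column is `-log10(min p)`, capped at 1000.
#'
#' @param regions A `plasticity_regions` data frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(inherits(regions, "plasticity_regions"))
  if (!nrow(regions)) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-log10(pmax(regions$min_p, 1e-300)), 2))
  df <- data.frame(regions$chrom, format_coord(regions$start),
                   format_coord(regions$end),
                   paste0("plasticity_", seq_len(nrow(regions))), score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Ordinary least squares fit of fork counts on chromosome length
#'
#' @param lengths Chromosome lengths in bases.
#' @param optima Optimal fork counts.
#' @return List with `intercept`, `slope` (forks per base) and `r`
#'   (Pearson correlation of the fit).
#' @export
fit_fork_scaling <- function(lengths, optima) {
  if (length(lengths) < 2) stop("need at least 2 chromosomes for the fit")
  fit <- lm(optima ~ lengths)
  r <- if (sd(optima) > 0) cor(lengths, optima) else NA_real_
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r = r)
}

#' Scan fork counts per chromosome and fit the length scaling
#'
#' For each chromosome, simulates the landscape at every candidate fork
#' count, correlates the resulting timing profile with the empirical one,
#' and picks the count maximizing the correlation (ties broken towards
#' the smallest count). With at least two chromosomes, ordinary least
#' squares of the optima on chromosome length gives the linear fork
#' scaling.
#'
#' @param ipls An `ipls`.
#' @param empirical Timing profile on the same grid.
#' @param candidate_n Fork counts to test (sorted ascending internally).
#' @param n_cycles Cycles per simulation (default 100).
#' @param gates Gate specification for profiling.
#' @param seed Master seed.
#' @param snapshot_period Snapshot cadence.
#' @return A `fork_scan` list: `per_chromosome` (data frame chrom, length,
#'   optimal_n, best_r), `correlations` (chromosome x candidate matrix),
#'   `intercept`, `slope`, `fit_r` (NA with a single chromosome).
#' @export
scan_fork_count <- function(ipls, empirical, candidate_n = 2:16,
                            n_cycles = 100, gates = equidistant_gates(6),
                            seed = 1, snapshot_period = 10) {
  stopifnot(inherits(ipls, "ipls"))
  candidate_n <- sort(unique(as.integer(candidate_n)))
  g <- ipls$genome
  cors <- matrix(NA_real_, length(g$chromosomes), length(candidate_n),
                 dimnames = list(g$chromosomes, candidate_n))
  for (i in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[i]
    sub_ipls <- subset_track(ipls, ch)
    sub_emp <- subset_track(empirical, ch)
    for (j in seq_along(candidate_n)) {
      st <- simulate_replication(sub_ipls, n_factors = candidate_n[j],
                                 n_cycles = n_cycles,
                                 snapshot_period = snapshot_period,
                                 seed = seed + 131 * candidate_n[j] +
                                   7 * i)
      prof <- timing_profile(st, gates)
      cors[i, j] <- compare_profiles(prof, sub_emp)$mean
    }
  }
  opt_idx <- apply(cors, 1, which.max)
  per_chrom <- data.frame(chrom = g$chromosomes,
                          length = as.numeric(g$lengths),
                          optimal_n = candidate_n[opt_idx],
                          best_r = cors[cbind(seq_along(opt_idx), opt_idx)],
                          stringsAsFactors = FALSE)
  fit <- if (nrow(per_chrom) >= 2)
    fit_fork_scaling(per_chrom$length, per_chrom$optimal_n)
  else list(intercept = NA_real_, slope = NA_real_, r = NA_real_)
  structure(list(per_chromosome = per_chrom, correlations = cors,
                 intercept = fit$intercept, slope = fit$slope,
                 fit_r = fit$r),
            class = "fork_scan")
}

#' S-phase length statistics and wall-clock conversion
#'
#' Converts simulation steps to hours: each step moves every unblocked
#' fork edge one bin (two forks per bubble in opposite directions), so
#' `hours = steps * bin_width / (fork_speed * 2) / 3600`.
#'
#' @param s_lengths S-phase lengths in steps (vector, or the list from
#'   [s_lengths()]).
#' @param bin_width Bin width in bases (default 500).
#' @param fork_speed Fork speed in bases per second (default 50).
#' @return A `sphase_stats` list: `median_steps`, `mean_steps`,
#'   `median_hours`, `mean_hours`.
#' @examples
#' sphase_stats(5965)  # ~8.3 h at 500 bp and 50 b/s
#' @export
sphase_stats <- function(s_lengths, bin_width = 500, fork_speed = 50) {
  s <- unlist(s_lengths, use.names = FALSE)
  if (!length(s)) stop("empty S-phase length vector")
  to_hours <- function(steps) steps * bin_width / (fork_speed * 2) / 3600
  structure(list(median_steps = median(s), mean_steps = mean(s),
                 median_hours = to_hours(median(s)),
                 mean_hours = to_hours(mean(s)), n = length(s)),
            class = "sphase_stats")
}

#' @export
print.sphase_stats <- function(x, ...) {
  cat("<sphase_stats> median ", format(x$median_steps), " steps (",
      format(round(x$median_hours, 1), nsmall = 1), " h), mean ",
      format(x$mean_steps), " steps, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Robustness of the timing prediction to site deletion
#'
#' For each keep-fraction, subsamples the site annotation, rebuilds the
#' landscape, re-simulates and correlates the resulting profile with a
#' reference profile.
#'
#' @param sites An [interval_set()] of initiation-site annotations.
#' @param genome A [genome_index()].
#' @param reference Reference timing profile (same grid).
#' @param fractions Keep-fractions to test.
#' @param n_factors,n_cycles,gates,snapshot_period Simulation settings.
#' @param amplitude_map,background,mode Landscape settings
#'   (see [ipls_from_scores()]).
#' @param seed Master seed.
#' @return Data frame: fraction, n_sites, r (mean per-chromosome Pearson
#'   correlation with the reference).
#' @export
robustness_curve <- function(sites, genome, reference,
                             fractions = c(1, 0.75, 0.5, 0.25, 0.1, 0.01),
                             n_factors = "auto", n_cycles = 200,
                             gates = equidistant_gates(6), seed = 1,
                             snapshot_period = 10, amplitude_map = "linear",
                             background = 1e-4, mode = "max") {
  rows <- lapply(fractions, function(f) {
    sub <- subsample_intervals(sites, f, seed = seed + round(1e4 * f))
    ip <- ipls_from_scores(sub, genome, amplitude_map = amplitude_map,
                           background = background, mode = mode)
    st <- simulate_replication(ip, n_factors = n_factors,
                               n_cycles = n_cycles,
                               snapshot_period = snapshot_period,
                               seed = seed + round(1e5 * f) + 13)
    prof <- timing_profile(st, gates)
    data.frame(fraction = f, n_sites = nrow(sub),
               r = compare_profiles(prof, reference)$mean)
  })
  do.call(rbind, rows)
}

#' Global initiation rate through S phase
#'
#' `I(t)` is the number of initiation events at S-age `t` divided by the
#' number of unreplicated bins at the start of step `t`, averaged over
#' cycles still replicating at `t`.
#'
#' @param stream A `snapshot_stream`.
#' @return Data frame: chrom, step, rate, cycles (number of cycles
#'   contributing at that step).
#' @export
initiation_rate <- function(stream) {
  stopifnot(inherits(stream, "snapshot_stream"))
  rows <- lapply(names(stream$chromosomes), function(ch) {
    r <- stream$chromosomes[[ch]]
    keep <- which(r$irate_n > 0)
    if (!length(keep)) return(NULL)
    data.frame(chrom = ch, step = keep,
               rate = r$irate_sum[keep] / r$irate_n[keep],
               cycles = r$irate_n[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All-pairs profile correlation with clustering order
#'
#' Genome-wide pairwise-complete Pearson correlations between profiles,
#' plus an average-linkage hierarchical clustering on `1 - r`.
#'
#' @param profiles Named list of [binned_track()]s on a common grid.
#' @return A `profile_cor` list: `r` (symmetric matrix, unit diagonal),
#'   `order` (dendrogram leaf order), `hclust`.
#' @export
correlation_matrix <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile_", seq_along(profiles))
  for (p in profiles[-1])
    if (!.same_grid(profiles[[1]], p))
      stop("profiles must share a bin grid")
  vals <- vapply(profiles, track_values,
                 numeric(length(track_values(profiles[[1]]))))
  m <- cor(vals, use = "pairwise.complete.obs")
  diag(m) <- 1
  hc <- hclust(as.dist(1 - m), method = "average")
  structure(list(r = m, order = hc$order, hclust = hc),
            class = "profile_cor")
}
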