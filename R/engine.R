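# Replication engine: configuration, the compiled population simulator,
# the fork-count scaling rule, and a pure-R reference single-cell stepper
# used as an independent cross-check of the compiled path.

#' Simulation configuration
#'
#' Bundles the inputs of a population simulation. Each chromosome is
#' simulated as an independent territory with its own factor pool (the
#' fork-count scaling was fitted per chromosome); `n_factors = "auto"`
#' draws N from [estimate_forks()] per chromosome.
#'
#' @param ipls An `ipls` (see [build_ipls()]).
#' @param n_factors `"auto"`, a single count, or one count per chromosome.
#' @param n_cycles Number of simulated cell cycles per chromosome.
#' @param snapshot_period Steps between population progress queries
#'   (default 10).
#' @param g_to_s_prob Per-step probability of the random G-to-S transition
#'   (default 1/500; the geometric G wait desynchronizes the population).
#' @param max_steps Safety cap on S-phase steps per cycle; default
#'   `50 * ceiling(B / (2 N))` per chromosome. Cycles hitting the cap are
#'   flagged incomplete and excluded from timing profiles.
#' @param seed Master integer seed; per-cycle generator seeds are derived
#'   from it so populations are reproducible and order-independent.
#' @param diagnostics Record per-step free-factor/bubble/throughput
#'   diagnostics (testing aid; default `FALSE`).
#' @return A `sim_config` object.
#' @export
sim_config <- function(ipls, n_factors = "auto", n_cycles = 200,
                       snapshot_period = 10, g_to_s_prob = 1 / 500,
                       max_steps = NULL, seed = 1, diagnostics = FALSE) {
  stopifnot(inherits(ipls, "ipls"))
  if (!(identical(n_factors, "auto") || (is.numeric(n_factors) &&
        all(n_factors >= 1))))
    stop("n_factors must be 'auto' or counts >= 1")
  if (snapshot_period < 1) stop("snapshot_period must be >= 1")
  if (g_to_s_prob <= 0 || g_to_s_prob > 1)
    stop("g_to_s_prob must lie in (0, 1]")
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  structure(list(ipls = ipls, n_factors = n_factors,
                 n_cycles = as.integer(n_cycles),
                 snapshot_period = as.integer(snapshot_period),
                 g_to_s_prob = g_to_s_prob, max_steps = max_steps,
                 seed = as.integer(seed), diagnostics = diagnostics),
            class = "sim_config")
}

#' Fork count from chromosome length
#'
#' Linear scaling of the optimal number of simultaneously active
#' replication forks with chromosome length,
#' `N = round(intercept + slope * length)`, clamped to at least 1. The
#' default coefficients (10.24, 7.9e-7) correspond to about one fork per
#' 1.3 Mb; see [fork_density_mb()].
#'
#' @param length Chromosome length(s) in bases, positive.
#' @param intercept,slope Scaling coefficients.
#' @return Integer fork count(s).
#' @examples
#' estimate_forks(1e8)
#' @export
estimate_forks <- function(length, intercept = 10.24, slope = 7.9e-7) {
  if (any(length <= 0)) stop("chromosome length must be positive")
  pmax(1L, as.integer(round(intercept + slope * length)))
}

#' Megabases per fork implied by the fork-count scaling slope
#'
#' @param slope Forks per base (default 7.9e-7).
#' @return Mb of chromosome per additional fork (`1 / slope / 1e6`).
#' @export
fork_density_mb <- function(slope = 7.9e-7) 1 / (slope * 1e6)

# per-cycle seeds derived from (master seed, chromosome index); kept
# strictly below 2^31
.cycle_seeds <- function(seed, chrom_idx, n) {
  base <- (as.numeric(seed) %% 1e6) * 1e6 + chrom_idx * 97561
  as.integer((base + seq_len(max(n, 1)) * 10007) %% 2147483647)[seq_len(n)]
}

.resolve_forks <- function(n_factors, genome) {
  nc <- length(genome$chromosomes)
  if (identical(n_factors, "auto")) {
    estimate_forks(as.numeric(genome$lengths))
  } else {
    nf <- as.integer(n_factors)
    if (length(nf) == 1L) rep(nf, nc)
    else if (length(nf) == nc) nf
    else stop("n_factors must be length 1 or one per chromosome")
  }
}

#' Simulate a cell population
#'
#' Runs `n_cycles` independent cell cycles per chromosome through the
#' compiled engine: a geometric G wait, then S-phase steps in which
#' engaged bubbles elongate bidirectionally (edges block on collision with
#' replicated territory or chromosome ends; fully blocked bubbles release
#' their factor) and each free factor makes one initiation attempt per
#' step, selecting one unreplicated competent bin (positive IPLS value)
#' uniformly at random and engaging there with the probability the IPLS
#' assigns to that bin. The probability of initiating at bin x is thus the
#' product of the uniform site-selection probability, IPLS(x) and the
#' number of free factors. Progress snapshots are recorded on a fixed
#' absolute-time cadence.
#'
#' @param ipls An `ipls`, or a [sim_config()] (in which case the remaining
#'   arguments are ignored).
#' @inheritParams sim_config
#' @return A `snapshot_stream`: per-chromosome cycle outcomes (S lengths,
#'   completion flags, per-bin replication steps, snapshot records,
#'   initiation events, initiation-rate accumulators).
#' @seealso [accumulate_gates()], [timing_profile()], [s_lengths()]
#' @export
simulate_replication <- function(ipls, n_factors = "auto", n_cycles = 200,
                                 snapshot_period = 10, g_to_s_prob = 1 / 500,
                                 max_steps = NULL, seed = 1,
                                 diagnostics = FALSE) {
  cfg <- if (inherits(ipls, "sim_config")) ipls
         else sim_config(ipls, n_factors, n_cycles, snapshot_period,
                         g_to_s_prob, max_steps, seed, diagnostics)
  g <- cfg$ipls$genome
  forks <- .resolve_forks(cfg$n_factors, g)
  chroms <- vector("list", length(g$chromosomes))
  names(chroms) <- g$chromosomes
  for (i in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[i]
    v <- cfg$ipls$values[[ch]]
    B <- length(v)
    ms <- cfg$max_steps
    if (is.null(ms)) ms <- 50L * as.integer(ceiling(B / (2 * forks[i])))
    res <- if (cfg$n_cycles > 0) {
      .run_cycles_cpp(v, forks[i], cfg$n_cycles, cfg$snapshot_period,
                      cfg$g_to_s_prob, ms,
                      .cycle_seeds(cfg$seed, i, cfg$n_cycles),
                      cfg$diagnostics)
    } else {
      list(s_length = integer(), completed = logical(),
           rep_step = matrix(NA_integer_, B, 0), snap_cycle = integer(),
           snap_step = integer(), snap_count = integer(),
           init_cycle = integer(), init_step = integer(),
           init_bin = integer(), irate_sum = numeric(), irate_n = integer())
    }
    res$n_factors <- forks[i]
    res$n_bins <- B
    res$max_steps <- ms
    chroms[[i]] <- res
  }
  structure(list(genome = g, chromosomes = chroms, n_cycles = cfg$n_cycles,
                 seed = cfg$seed, snapshot_period = cfg$snapshot_period,
                 g_to_s_prob = cfg$g_to_s_prob, forks = setNames(forks,
                 g$chromosomes)),
            class = "snapshot_stream")
}

#' @rdname simulate_replication
#' @param config A [sim_config()].
#' @export
run_population <- function(config) simulate_replication(config)

#' Run a single cell cycle
#'
#' Convenience wrapper around the population engine with `n_cycles = 1`;
#' returns the S length in steps and the snapshot records of that cycle.
#'
#' @inheritParams run_population
#' @return List with `s_length` (named per chromosome), `completed`, and
#'   `snapshots` (data frame: chrom, step, replicated bins, fraction).
#' @export
run_cycle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_cycles <- 1L
  st <- simulate_replication(config)
  snaps <- do.call(rbind, lapply(names(st$chromosomes), function(ch) {
    r <- st$chromosomes[[ch]]
    if (!length(r$snap_step)) return(NULL)
    data.frame(chrom = ch, step = r$snap_step, replicated = r$snap_count,
               fraction = r$snap_count / r$n_bins, stringsAsFactors = FALSE)
  }))
  list(s_length = vapply(st$chromosomes, function(r) r$s_length[1],
                         numeric(1)),
       completed = vapply(st$chromosomes, function(r) r$completed[1],
                          logical(1)),
       snapshots = snaps)
}

#' @export
print.snapshot_stream <- function(x, ...) {
  nsnap <- sum(vapply(x$chromosomes, function(r) length(r$snap_step),
                      numeric(1)))
  ninc <- sum(vapply(x$chromosomes, function(r) sum(!r$completed),
                     numeric(1)))
  cat("<snapshot_stream> ", x$n_cycles, " cycle(s) x ",
      length(x$chromosomes), " chromosome(s); ", nsnap, " snapshots; ",
      ninc, " incomplete cycle(s)\n", sep = "")
  invisible(x)
}

#' S-phase lengths of a simulated population
#'
#' @param stream A `snapshot_stream`.
#' @param complete_only Drop cycles that hit the step cap (default `TRUE`).
#' @return Named list of per-chromosome integer vectors of S lengths in
#'   simulation steps.
#' @export
s_lengths <- function(stream, complete_only = TRUE) {
  stopifnot(inherits(stream, "snapshot_stream"))
  lapply(stream$chromosomes, function(r) {
    if (complete_only) r$s_length[r$completed] else r$s_length
  })
}

# ---------------------------------------------------------------------------
# pure-R reference stepper (independent cross-check of the compiled core)

#' Create a single-cell replication state
#'
#' Reference R implementation of the engine's cell bookkeeping, exposed for
#' testing and didactic use; [simulate_replication()] is the production
#' path.
#'
#' @param n_bins Number of bins of the territory.
#' @param n_factors Factor pool size N.
#' @return A `cell_state`: replicated mask, bubble table, free factor
#'   count, phase and step counter.
#' @export
cell_state <- function(n_bins, n_factors) {
  structure(list(replicated = logical(n_bins),
                 bubbles = data.frame(left = integer(), right = integer(),
                                      left_blocked = logical(),
                                      right_blocked = logical()),
                 free_factors = as.integer(n_factors),
                 n_factors = as.integer(n_factors),
                 phase = "S", s_step = 0L),
            class = "cell_state")
}

#' Advance a cell by one S-phase step (reference implementation)
#'
#' Bubble edges advance first (one bin per unblocked edge; edges block on
#' replicated territory or chromosome ends; doubly blocked bubbles
#' dissolve, returning their factor), then each factor free at the start
#' of the step makes one initiation attempt on a uniformly selected
#' unreplicated competent bin. Initiation replicates the chosen bin in the
#' same step; elongation starts the following step.
#'
#' @param cell A [cell_state()].
#' @param ipls_values Numeric vector of per-bin initiation probabilities.
#' @return The advanced `cell_state`.
#' @export
step_cell <- function(cell, ipls_values) {
  stopifnot(inherits(cell, "cell_state"))
  B <- length(cell$replicated)
  stopifnot(length(ipls_values) == B)
  bub <- cell$bubbles
  # 1. elongation
  keep <- rep(TRUE, nrow(bub))
  for (i in seq_len(nrow(bub))) {
    if (!bub$left_blocked[i]) {
      nb <- bub$left[i] - 1L
      if (nb < 1L || cell$replicated[nb]) bub$left_blocked[i] <- TRUE
      else { cell$replicated[nb] <- TRUE; bub$left[i] <- nb }
    }
    if (!bub$right_blocked[i]) {
      nb <- bub$right[i] + 1L
      if (nb > B || cell$replicated[nb]) bub$right_blocked[i] <- TRUE
      else { cell$replicated[nb] <- TRUE; bub$right[i] <- nb }
    }
    if (bub$left_blocked[i] && bub$right_blocked[i]) {
      keep[i] <- FALSE
      cell$free_factors <- cell$free_factors + 1L
    }
  }
  bub <- bub[keep, , drop = FALSE]
  # 2. initiation attempts
  attempts <- cell$free_factors
  for (a in seq_len(attempts)) {
    competent <- which(ipls_values > 0 & !cell$replicated)
    if (!length(competent)) break
    bin <- competent[sample.int(length(competent), 1L)]
    if (runif(1) < ipls_values[bin]) {
      cell$replicated[bin] <- TRUE
      bub <- rbind(bub, data.frame(left = bin, right = bin,
                                   left_blocked = FALSE,
                                   right_blocked = FALSE))
      cell$free_factors <- cell$free_factors - 1L
    }
  }
  cell$bubbles <- bub
  cell$s_step <- cell$s_step + 1L
  cell
}

#' Run one cycle with the reference stepper
#'
#' @inheritParams step_cell
#' @param n_factors Factor pool size.
#' @param max_steps Step cap.
#' @return List with `s_length` and the final `cell_state`.
#' @export
run_cycle_r <- function(ipls_values, n_factors, max_steps = 10000L) {
  cell <- cell_state(length(ipls_values), n_factors)
  while (!all(cell$replicated) && cell$s_step < max_steps)
    cell <- step_cell(cell, ipls_values)
  list(s_length = cell$s_step, cell = cell,
       completed = all(cell$replicated))
}
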