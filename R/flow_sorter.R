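# Flow-sorter emulation: DNA-content gating of population snapshots into
# per-bin gate counts, the weighted-average timing profile, and simulated
# annealing optimization of gate boundaries against an empirical profile.

#' Flow-sorter gate specification
#'
#' Gates partition S-phase cells by replicated fraction (DNA content maps
#' affinely onto it): G gates are defined by G-1 strictly increasing cut
#' points in (0, 1); gate g is the half-open interval (b[g-1], b[g]] with
#' b[0] = 0 and b[G] = 1.
#'
#' @param boundaries Strictly increasing numeric vector in (0, 1).
#' @return A `gate_spec`.
#' @export
gate_spec <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (!length(boundaries)) stop("at least one boundary is required")
  if (any(boundaries <= 0) || any(boundaries >= 1) ||
      any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing within (0, 1)")
  structure(boundaries, class = "gate_spec", n_gates = length(boundaries) + 1L)
}

#' @rdname gate_spec
#' @param n_gates Number of gates (default 6).
#' @export
equidistant_gates <- function(n_gates = 6) {
  if (n_gates < 2) stop("need at least 2 gates")
  gate_spec(seq_len(n_gates - 1) / n_gates)
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("<gate_spec> ", attr(x, "n_gates"), " gates; boundaries: ",
      paste(format(unclass(x), digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gate index of a replicated fraction
#'
#' @param fraction Replicated fraction(s) in (0, 1]; G-phase cells
#'   (fraction 0) must be filtered by the caller and raise an error.
#' @param gates A [gate_spec()].
#' @return Integer gate index in 1..G.
#' @examples
#' gate_of(0.1, equidistant_gates(6))
#' @export
gate_of <- function(fraction, gates) {
  stopifnot(inherits(gates, "gate_spec"))
  if (any(fraction <= 0))
    stop("replicated fraction must be positive (filter G-phase cells)")
  if (any(fraction > 1)) stop("replicated fraction cannot exceed 1")
  b <- unclass(gates)
  vapply(fraction, function(f) 1L + sum(f > b), integer(1))
}

#' Accumulate gate counts over a snapshot stream
#'
#' For every snapshot of a complete cycle, the snapshot's gate is computed
#' once from the cell's replicated fraction; every bin replicated at that
#' snapshot then increments its count in that gate. Incomplete cycles are
#' excluded.
#'
#' @param stream A `snapshot_stream` from [simulate_replication()].
#' @param gates A [gate_spec()] (default 6 equidistant gates).
#' @return A `gate_counts` object (per-chromosome bins x gates matrices).
#' @export
accumulate_gates <- function(stream, gates = equidistant_gates(6)) {
  stopifnot(inherits(stream, "snapshot_stream"),
            inherits(gates, "gate_spec"))
  counts <- lapply(stream$chromosomes, function(r) {
    .count_by_gate_cpp(r$rep_step, r$snap_cycle, r$snap_step, r$snap_count,
                       r$completed, as.numeric(gates))
  })
  structure(list(genome = stream$genome, counts = counts, gates = gates),
            class = "gate_counts")
}

#' Replication timing profile from gate counts
#'
#' Per bin, the count-weighted average gate index,
#' `T = sum(g * c_g) / sum(c_g)`; bins never observed replicated are
#' missing. Values lie in `[1, G]`; smaller means earlier replication.
#'
#' @param x A `gate_counts`, or a `snapshot_stream` (gated on the fly with
#'   `gates`).
#' @param gates Gate specification used when `x` is a stream.
#' @return A `timing_profile` (a [binned_track()] with attribute
#'   `n_gates`).
#' @export
timing_profile <- function(x, gates = equidistant_gates(6)) {
  if (inherits(x, "snapshot_stream")) x <- accumulate_gates(x, gates)
  stopifnot(inherits(x, "gate_counts"))
  G <- attr(x$gates, "n_gates")
  vals <- lapply(x$counts, function(cm) {
    tot <- rowSums(cm)
    t_ <- as.numeric(cm %*% seq_len(G)) / tot
    t_[tot == 0] <- NA_real_
    t_
  })
  out <- binned_track(x$genome, vals)
  class(out) <- c("timing_profile", class(out))
  attr(out, "n_gates") <- G
  out
}

# ---------------------------------------------------------------------------
# gate-boundary optimization

# cumulative replicated-count histograms per chromosome, restricted to
# bins defined in both the simulation and the empirical profile
.gate_opt_precompute <- function(stream, empirical) {
  if (!.same_grid(stream, empirical))
    stop("empirical profile and simulation must share a bin grid")
  pre <- lapply(names(stream$chromosomes), function(ch) {
    r <- stream$chromosomes[[ch]]
    H <- .count_hist_cpp(r$rep_step, r$snap_cycle, r$snap_step,
                         r$snap_count, r$completed)
    Hc <- cbind(0, t(apply(H, 1, cumsum)))
    total <- Hc[, ncol(Hc)]
    emp <- empirical$values[[ch]]
    mask <- total > 0 & !is.na(emp)
    list(Hc = Hc[mask, , drop = FALSE], total = total[mask],
         emp = emp[mask], B = r$n_bins)
  })
  if (sum(vapply(pre, function(p) length(p$emp), numeric(1))) == 0)
    stop("no bins defined in both the simulated and empirical profiles")
  pre
}

.gate_objective <- function(boundaries, pre, n_gates) {
  ss <- 0
  for (p in pre) {
    if (!length(p$emp)) next
    idx <- pmax(0, pmin(p$B, floor(p$B * c(boundaries, 1) + 1e-9)))
    cum <- p$Hc[, idx + 1, drop = FALSE]
    counts <- cum - cbind(0, cum[, -n_gates, drop = FALSE])
    t_ <- as.numeric(counts %*% seq_len(n_gates)) / p$total
    ss <- ss + sum((t_ - p$emp)^2)
  }
  sqrt(ss)
}

#' Optimize flow-sorter gate boundaries by simulated annealing
#'
#' Searches gate boundary vectors to minimize the Euclidean distance
#' between the gated simulation's timing profile and an empirical profile
#' (bins undefined in either are dropped pairwise; the set of defined bins
#' does not depend on the boundaries). Each move perturbs one uniformly
#' chosen boundary with a Normal(old value, `sigma`) proposal on the
#' replicated-fraction scale (default `sigma = 0.01`, i.e. one percentage
#' point of DNA content); proposals violating ordering or range are
#' rejected outright; otherwise the Metropolis criterion under a geometric
#' temperature schedule decides. The best-ever boundary vector is
#' returned.
#'
#' @param stream A `snapshot_stream`.
#' @param empirical A timing profile on the same bin grid.
#' @param init Initial [gate_spec()] (default 6 equidistant gates).
#' @param n_iter Number of annealing iterations (default 1000; 0 returns
#'   `init`).
#' @param sigma Proposal standard deviation on the fraction scale.
#' @param t0 Initial temperature; default one tenth of the starting
#'   objective.
#' @param cooling Geometric cooling factor per iteration (default 0.995).
#' @param seed Integer seed (the search is deterministic given the seed).
#' @return A `gate_opt` list: `gates` (best [gate_spec()]), `objective`,
#'   `initial_objective`, `accepted`, `n_iter`.
#' @export
optimize_gates <- function(stream, empirical, init = equidistant_gates(6),
                           n_iter = 1000, sigma = 0.01, t0 = NULL,
                           cooling = 0.995, seed = 1) {
  stopifnot(inherits(stream, "snapshot_stream"),
            inherits(empirical, "binned_track"),
            inherits(init, "gate_spec"))
  G <- attr(init, "n_gates")
  pre <- .gate_opt_precompute(stream, empirical)
  cur <- as.numeric(init)
  d_cur <- .gate_objective(cur, pre, G)
  best <- cur
  d_best <- d_cur
  d_init <- d_cur
  if (is.null(t0)) t0 <- max(d_cur, 1e-8) / 10
  accepted <- 0L
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    temp <- t0 * cooling^(it - 1)
    j <- sample.int(G - 1, 1)
    prop <- cur
    prop[j] <- rnorm(1, cur[j], sigma)
    ok <- prop[j] > 0 && prop[j] < 1 &&
      (j == 1 || prop[j] > prop[j - 1]) &&
      (j == G - 1 || prop[j] < prop[j + 1])
    if (!ok) next
    d_new <- .gate_objective(prop, pre, G)
    if (d_new <= d_cur || runif(1) < exp(-(d_new - d_cur) / temp)) {
      cur <- prop
      d_cur <- d_new
      accepted <- accepted + 1L
      if (d_cur < d_best) {
        best <- cur
        d_best <- d_cur
      }
    }
  }
  structure(list(gates = gate_spec(best), objective = d_best,
                 initial_objective = d_init, accepted = accepted,
                 n_iter = as.integer(n_iter)),
            class = "gate_opt")
}

#' @export
print.gate_opt <- function(x, ...) {
  cat("<gate_opt> objective ", format(x$objective, digits = 6),
      " (from ", format(x$initial_objective, digits = 6), "), ",
      x$accepted, "/", x$n_iter, " moves accepted\n", sep = "")
  print(x$gates)
  invisible(x)
}
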