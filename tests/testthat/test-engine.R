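test_that("fork count scaling follows the linear length rule", {
  expect_equal(estimate_forks(1e8), 89L)        # round(10.24 + 79)
  expect_equal(estimate_forks(c(5e7, 2.4e8)),
               as.integer(round(10.24 + 7.9e-7 * c(5e7, 2.4e8))))
  expect_error(estimate_forks(0), "positive")
  # the clamp keeps degenerate coefficient choices at one fork minimum
  expect_equal(estimate_forks(1000, intercept = 0.1, slope = 0), 1L)
  # slope reciprocal ~ 1.3 Mb per fork
  expect_equal(round(fork_density_mb(7.9e-7), 1), 1.3)
})

test_that("a lone zero-background origin replicates in closed-form time", {
  for (B in c(10, 11, 101)) {
    for (m0 in unique(c(1, (B + 1) %/% 2, B))) {
      for (N in c(1, 3)) {
        st <- simulate_replication(lone_ipls(B, m0), n_factors = N,
                                   n_cycles = 5, seed = 100 + B + m0 + N)
        sl <- s_lengths(st)$chrT
        expect_length(sl, 5)
        expect_true(all(sl == lone_origin_s_length(B, m0)),
                    info = sprintf("B=%d m0=%d N=%d", B, m0, N))
      }
    }
  }
})

test_that("reference R stepper reproduces the compiled lone-origin dynamics", {
  for (B in c(10, 11)) {
    for (m0 in c(1, (B + 1) %/% 2, B)) {
      v <- rep(0, B)
      v[m0] <- 1
      set.seed(1)
      res <- run_cycle_r(v, n_factors = 2)
      expect_true(res$completed)
      expect_equal(res$s_length, lone_origin_s_length(B, m0))
      # factor conservation at the end of the cycle
      expect_equal(res$cell$free_factors + nrow(res$cell$bubbles), 2L)
    }
  }
})

test_that("colliding bubbles release their factor back to the pool mid-cycle", {
  # origins at bins 3 and 8 of 20: the left bubble blocks on the chromosome
  # start and on the right bubble's territory, dissolves, and frees its
  # factor while the right bubble is still elongating
  v <- rep(0, 20)
  v[c(3, 8)] <- 1
  set.seed(2)
  cell <- cell_state(20, 2)
  free_trace <- integer()
  while (!all(cell$replicated)) {
    cell <- step_cell(cell, v)
    free_trace <- c(free_trace, cell$free_factors)
    expect_equal(cell$free_factors + nrow(cell$bubbles), 2L)
  }
  expect_equal(cell$s_step, 1 + max(7, 20 - 8))  # rightmost travel dominates
  # the released factor shows up before the cycle ends
  expect_true(any(free_trace[-length(free_trace)] >= 1))
})

test_that("factor pool and replication mask obey conservation laws", {
  set.seed(42)
  for (rep_i in 1:10) {
    B <- sample(50:300, 1)
    N <- sample(1:8, 1)
    v <- runif(B) * (runif(B) > 0.6)
    if (!any(v > 0)) v[1] <- 1
    ip <- build_ipls(binned_track(tiny_genome(B), v), background = 1e-4)
    st <- simulate_replication(ip, n_factors = N, n_cycles = 4,
                               seed = 1000 + rep_i, diagnostics = TRUE)
    r <- st$chromosomes$chrT
    d <- r$diag
    # free + engaged = N at every step
    expect_true(all(d$free_factors + d$bubbles == N))
    # at most 2N bins replicated per step
    expect_true(all(d$new_replicated <= 2 * N))
    # complete cycles replicate every bin exactly once
    for (ci in which(r$completed)) {
      expect_false(anyNA(r$rep_step[, ci]))
      expect_equal(sum(d$new_replicated[d$cycle == ci]), B)
    }
    # snapshot replicated counts are monotone within each cycle
    for (ci in unique(r$snap_cycle)) {
      expect_true(all(diff(r$snap_count[r$snap_cycle == ci]) >= 0))
    }
  }
})

test_that("population runs are deterministic in the master seed", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = 300, seed = 6))
  a <- simulate_replication(fx$ipls, n_factors = 4, n_cycles = 10, seed = 11)
  b <- simulate_replication(fx$ipls, n_factors = 4, n_cycles = 10, seed = 11)
  expect_identical(a$chromosomes$chrF$rep_step, b$chromosomes$chrF$rep_step)
  expect_identical(a$chromosomes$chrF$snap_count,
                   b$chromosomes$chrF$snap_count)
  c_ <- simulate_replication(fx$ipls, n_factors = 4, n_cycles = 10, seed = 12)
  expect_false(identical(a$chromosomes$chrF$rep_step,
                         c_$chromosomes$chrF$rep_step))
})

test_that("S length respects the 2N-per-step throughput bound", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = 400, seed = 2))
  for (N in c(1, 4, 16)) {
    st <- simulate_replication(fx$ipls, n_factors = N, n_cycles = 10,
                               seed = 3)
    expect_true(all(s_lengths(st)$chrT >= ceiling(400 / (2 * N))))
  }
})

test_that("median S length is non-increasing in the factor count", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = 2000, seed = 17))
  med <- vapply(c(1, 2, 4, 8, 16), function(N) {
    st <- simulate_replication(fx$ipls, n_factors = N, n_cycles = 60,
                               seed = 99)
    as.numeric(median(s_lengths(st)$chrF))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("empty and growing populations behave additively", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = 200, seed = 8))
  st0 <- simulate_replication(fx$ipls, n_factors = 2, n_cycles = 0, seed = 1)
  expect_length(st0$chromosomes$chrF$snap_step, 0)
  n1 <- length(simulate_replication(fx$ipls, 2, n_cycles = 25,
                                    seed = 1)$chromosomes$chrF$snap_step)
  n2 <- length(simulate_replication(fx$ipls, 2, n_cycles = 50,
                                    seed = 1)$chromosomes$chrF$snap_step)
  expect_gt(n2, 1.6 * n1)
  expect_lt(n2, 2.4 * n1)
})

test_that("run_cycle reports per-chromosome S length and snapshots", {
  cfg <- sim_config(lone_ipls(10, 1), n_factors = 1, seed = 5)
  res <- run_cycle(cfg)
  expect_equal(unname(res$s_length["chrT"]), 10)
  expect_true(res$completed[["chrT"]])
  expect_true(all(res$snapshots$fraction > 0 & res$snapshots$fraction <= 1))
})

test_that("initiation events are logged per cycle with conserved totals", {
  st <- simulate_replication(lone_ipls(10, 3), n_factors = 1, n_cycles = 7,
                             seed = 2, diagnostics = TRUE)
  r <- st$chromosomes$chrT
  # lone origin: exactly one initiation per cycle, at step 1, at the origin
  expect_equal(length(r$init_step), 7)
  expect_true(all(r$init_step == 1))
  expect_true(all(r$init_bin == 3))
  # every logged initiation marks its bin replicated at that very step,
  # and all factors are free again once a cycle completes
  fx <- make_ipls_fixture(fixture_spec(n_bins = 300, seed = 4))
  st2 <- simulate_replication(fx$ipls, n_factors = 4, n_cycles = 5,
                              seed = 9, diagnostics = TRUE)
  r2 <- st2$chromosomes$chrF
  expect_true(all(r2$rep_step[cbind(r2$init_bin, r2$init_cycle)] ==
                    r2$init_step))
  d <- r2$diag
  for (ci in which(r2$completed)) {
    expect_gte(sum(r2$init_cycle == ci), 1)
    # factors released by mid-cycle collisions re-enter the pool: the free
    # count recovers after its first dip whenever more than one bubble
    # ever coexisted
    fr <- d$free_factors[d$cycle == ci]
    if (any(d$bubbles[d$cycle == ci] > 1))
      expect_gt(max(fr[-1]), min(fr))
  }
})

test_that("sim_config validates its parameters", {
  ip <- lone_ipls(10, 1)
  expect_error(sim_config(ip, n_factors = 0), "n_factors")
  expect_error(sim_config(ip, g_to_s_prob = 0), "g_to_s_prob")
  expect_error(sim_config(ip, snapshot_period = 0), "snapshot_period")
})
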