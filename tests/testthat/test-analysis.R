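test_that("profile comparison reproduces textbook Pearson correlation", {
  g <- genome_index("chrT", 4 * 500)
  a <- binned_track(g, c(1, 2, 3, 4))
  b <- binned_track(g, c(1, 2, 3, 5))
  # closed-form Pearson oracle computed from sums, not cor()
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cmp <- compare_profiles(a, b)
  expect_equal(unname(cmp$per_chromosome["chrT"]), r_oracle)
  # identity and inversion
  expect_equal(compare_profiles(a, a)$mean, 1)
  inv <- binned_track(g, -c(1, 2, 3, 4) + 10)
  expect_equal(compare_profiles(a, inv)$mean, -1)
  expect_equal(compare_profiles(a, inv, flip = TRUE)$mean, 1)
})

test_that("comparison demands shared bins and averages across chromosomes", {
  g2 <- genome_index(c("c1", "c2"), c(2000, 2000))
  a <- binned_track(g2, list(c1 = c(1, 2, 3, 4), c2 = c(4, 3, 2, 1)))
  b <- binned_track(g2, list(c1 = c(1, 2, 3, 4), c2 = c(8, 6, 4, 2)))
  cmp <- compare_profiles(a, b)
  expect_equal(unname(cmp$per_chromosome), c(1, 1))
  expect_equal(cmp$mean, 1)
  expect_equal(cmp$sem, 0)
  sparse <- binned_track(g2, list(c1 = c(1, NA, NA, NA),
                                  c2 = c(NA, NA, NA, NA)))
  expect_error(compare_profiles(a, sparse), "fewer than 3")
  g3 <- genome_index("c1", 2000)
  expect_error(compare_profiles(a, binned_track(g3, 1:4)), "share a bin grid")
})

test_that("plasticity caller finds injected shifts and nothing else", {
  set.seed(101)
  g <- genome_index("chrP", 10000 * 500)
  noise <- rnorm(10000)
  zero <- binned_track(g, rep(0, 10000))
  # identical profiles have a zero-variance difference: degenerate by design
  same <- binned_track(g, noise)
  expect_error(call_plasticity_regions(same, same), "degenerate")
  # equal-up-to-noise profiles yield no regions
  near <- binned_track(g, noise + rnorm(10000, sd = 0.1))
  expect_equal(nrow(call_plasticity_regions(same, near)), 0)
  # a 10-bin +6-sigma shift yields exactly one region over those bins
  shifted <- noise
  shifted[4001:4010] <- shifted[4001:4010] + 6
  regs <- call_plasticity_regions(binned_track(g, shifted), zero)
  expect_equal(nrow(regs), 1)
  expect_gte(regs$start_bin, 3998)
  expect_lte(regs$end_bin, 4013)
  expect_gte(sum(4001:4010 >= regs$start_bin & 4001:4010 <= regs$end_bin), 8)
  expect_equal(regs$direction, 1)
  # a run of two extreme bins is below the minimum run length
  short <- noise
  short[100:101] <- short[100:101] + 6
  expect_equal(nrow(call_plasticity_regions(binned_track(g, short), zero)), 0)
  # missing bins break runs
  gap <- shifted
  gap[4005] <- NA
  regs_gap <- call_plasticity_regions(binned_track(g, gap), zero)
  expect_equal(nrow(regs_gap), 2)
  # degenerate difference profile
  expect_error(call_plasticity_regions(zero, zero), "degenerate")
})

test_that("plasticity null is fit to the whole difference distribution", {
  set.seed(7)
  g <- genome_index("chrP", 5000 * 500)
  a <- binned_track(g, rnorm(5000, mean = 3, sd = 2))
  b <- binned_track(g, rep(0, 5000))
  regs <- call_plasticity_regions(a, b)
  expect_equal(attr(regs, "mu"), mean(track_values(a)))
  expect_equal(attr(regs, "sigma"), sd(track_values(a)))
  # a robust fit survives heavy outliers
  v <- rnorm(5000)
  v[1:50] <- 100
  rr <- call_plasticity_regions(binned_track(g, v), b, robust = TRUE)
  expect_lt(abs(attr(rr, "mu")), 0.1)
})

test_that("fork scaling fit is exact on collinear optima", {
  lengths <- c(5e7, 1e8, 1.5e8, 2e8)
  optima <- 10.24 + 7.9e-7 * lengths   # points exactly on the line
  fit <- fit_fork_scaling(lengths, optima)
  expect_equal(fit$intercept, 10.24, tolerance = 1e-12)
  expect_equal(fit$slope, 7.9e-7, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_error(fit_fork_scaling(1e8, 10), "at least 2")
})

test_that("fork scan degenerates correctly with a single candidate", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = c(200, 300),
                                       chromosomes = c("cA", "cB"),
                                       seed = 14))
  emp <- make_pseudo_empirical(fx$ipls, n_factors = 3, n_cycles = 60,
                               seed = 2)
  sc <- scan_fork_count(fx$ipls, emp, candidate_n = 4, n_cycles = 30,
                        seed = 3)
  expect_equal(sc$per_chromosome$optimal_n, c(4L, 4L))
  expect_true(is.na(sc$fit_r))  # constant optima: no meaningful correlation
})

test_that("S-phase statistics convert steps to wall-clock hours exactly", {
  st <- sphase_stats(5965, bin_width = 500, fork_speed = 50)
  expect_equal(round(st$median_hours, 1), 8.3)
  # unit inversion: 720 steps at 500 bp and 50 b/s is exactly one hour
  expect_equal(sphase_stats(720)$median_hours, 1)
  s3 <- sphase_stats(c(1, 2, 3))
  expect_equal(s3$median_steps, 2)
  expect_equal(s3$mean_steps, 2)
  # dimensional exactness: doubling fork speed halves the hours
  expect_equal(sphase_stats(5965, fork_speed = 100)$median_hours,
               sphase_stats(5965, fork_speed = 50)$median_hours / 2)
  expect_error(sphase_stats(numeric()), "empty")
})

test_that("global initiation rate has the expected structure", {
  # lone origin: a single nonzero entry at S-age 1, value 1/B
  st <- simulate_replication(lone_ipls(10, 1), n_factors = 1, n_cycles = 10,
                             seed = 3)
  ir <- initiation_rate(st)
  expect_equal(ir$rate[ir$step == 1], 1 / 10)
  expect_true(all(ir$rate[ir$step > 1] == 0))
  # homogeneous landscape, large pool: the rate rises then falls
  g <- genome_index("chrU", 500 * 500)
  v <- rep(0.05, 500)
  ip <- binned_track(g, v)
  class(ip) <- c("ipls", class(ip))
  attr(ip, "background") <- 0.05
  attr(ip, "amplitude_map") <- "linear"
  st2 <- simulate_replication(ip, n_factors = 16, n_cycles = 150, seed = 3)
  ir2 <- initiation_rate(st2)
  peak <- which.max(ir2$rate)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(ir2))
  expect_gt(ir2$rate[peak], ir2$rate[1])
  expect_gt(ir2$rate[peak], ir2$rate[nrow(ir2)])
})

test_that("correlation matrix clusters identical profiles first", {
  g <- genome_index("chrT", 50 * 500)
  set.seed(31)
  base <- rnorm(50)
  profs <- list(a = binned_track(g, base + rnorm(50, sd = 0.01)),
                b = binned_track(g, base + rnorm(50, sd = 0.01)),
                c = binned_track(g, -base))
  cm <- correlation_matrix(profs)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  first_merge <- cm$hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))  # a and b merge first
  # brute-force oracle for one off-diagonal entry
  expect_equal(cm$r["a", "c"],
               cor(track_values(profs$a), track_values(profs$c)))
})

test_that("robustness to site erasure degrades gracefully", {
  fx <- make_ipls_fixture(fixture_spec(n_bins = 800, sites_per_cluster = 30,
                                       seed = 31))
  ref <- make_pseudo_empirical(fx$ipls, n_factors = 6, n_cycles = 150,
                               seed = 100)
  rc <- robustness_curve(fx$intervals, fx$genome, ref,
                         fractions = c(1, 0.5, 0.02), n_factors = 6,
                         n_cycles = 120, seed = 7)
  expect_equal(rc$n_sites, c(150, 75, 3))
  expect_gt(rc$r[1], 0.95)          # full annotation reproduces the reference
  expect_gt(rc$r[2], rc$r[3])       # heavier erasure hurts more
})
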