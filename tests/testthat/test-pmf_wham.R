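# Window planning and WHAM reconstruction on known surfaces.

test_that("window plans are inclusive arithmetic ladders", {
  expect_length(window_plan(5.0, 0.0, 0.1), 51)
  expect_equal(window_plan(1.0, 0.0, 0.5), c(1.0, 0.5, 0.0))
  expect_error(window_plan(5.0, 5.0, 0.1), "degenerate")
  expect_warning(p <- window_plan(1.0, 0.0, 0.3), "clamped")
  expect_equal(p, c(1.0, 0.7, 0.4, 0.1, 0.0))
  ## ascending plans work too
  expect_equal(window_plan(0, 1, 0.5), c(0, 0.5, 1))
})

test_that("a single weak window on a flat surface gives a flat profile", {
  pmf <- pmf_flat(0, 5)
  w <- sample_umbrella_windows(pmf, 2.5, k_bias = 0.001,
                               n_samples = 50000, seed = 2)
  prof <- wham(w, bin_width = 0.25)
  occ <- !is.na(prof$G) & prof$count > 500
  expect_true(all(abs(prof$G[occ]) < 0.1))
})

test_that("WHAM recovers a double-well surface from biased windows", {
  pmf <- pmf_double_well(z_lo = 0.5, z_hi = 5.6)
  centers <- window_plan(5.5, 0.5, 0.1)
  wins <- sample_umbrella_windows(pmf, centers, k_bias = 2000,
                                  n_samples = 5000, seed = 5)
  prof <- wham(wins)
  ## adequately sampled bins (sparse edge bins are pure shot noise)
  occ <- !is.na(prof$G) & prof$count >= 10
  truth <- zero_on_reference(prof$z[occ], pmf$fn(prof$z[occ]))
  rmsd <- sqrt(mean((prof$G[occ] - truth)^2))
  expect_lt(rmsd, 0.3)
  ## minimum location and depth
  pm <- profile_minimum(prof)
  expect_equal(pm$z_min, 1.6, tolerance = 0.05)
  expect_false(pm$edge)
})

test_that("WHAM recovers the curvature of a harmonic surface", {
  kappa <- 500
  pmf <- pmf_harmonic(z0 = 2.5, kappa = kappa, z_lo = 1, z_hi = 4)
  wins <- sample_umbrella_windows(pmf, window_plan(4, 1, 0.1),
                                  k_bias = 2000, n_samples = 4000,
                                  seed = 8)
  prof <- wham(wins)
  keep <- !is.na(prof$G) & abs(prof$z - 2.5) < 0.8
  fit <- lm(G ~ poly(z, 2, raw = TRUE), data = prof[keep, ])
  kappa_hat <- kcal_to_kj(2 * coef(fit)[[3]])
  expect_lt(abs(kappa_hat - kappa) / kappa, 0.05)
})

test_that("the profile is invariant to window order and splitting", {
  pmf <- pmf_harmonic(z0 = 2, kappa = 300, z_lo = 1, z_hi = 3)
  wins <- sample_umbrella_windows(pmf, window_plan(3, 1, 0.2),
                                  k_bias = 1000, n_samples = 2000,
                                  seed = 13)
  p1 <- wham(wins)
  p2 <- wham(rev(wins))
  expect_equal(p1$G, p2$G, tolerance = 1e-6)
  ## split one window's samples into two windows at the same centre
  w5 <- wins[[5]]
  half <- length(w5$samples) %/% 2
  split_wins <- c(wins[-5],
                  list(umbrella_window(w5$center, w5$k_bias,
                                       w5$samples[1:half],
                                       w5$temperature),
                       umbrella_window(w5$center, w5$k_bias,
                                       w5$samples[(half + 1):length(w5$samples)],
                                       w5$temperature)))
  p3 <- wham(split_wins)
  expect_equal(p1$G, p3$G, tolerance = 1e-6)
})

test_that("WHAM matches the binless MBAR oracle", {
  pmf <- pmf_double_well(z_lo = 0.5, z_hi = 5.6)
  wins <- sample_umbrella_windows(pmf, window_plan(5.5, 0.5, 0.1),
                                  k_bias = 2000, n_samples = 1000,
                                  seed = 19)
  ## fine shared binning so discretisation does not mask the
  ## estimator comparison
  prof <- wham(wins, bin_width = 0.025)
  ref <- mbar_profile(wins, bin_width = 0.025)
  stopifnot(all(ref$z == prof$z))
  occ <- !is.na(prof$G) & !is.na(ref$G) & prof$count >= 10
  g1 <- prof$G[occ]
  g2 <- zero_on_reference(ref$z[occ], ref$G[occ])
  expect_lt(sqrt(mean((g1 - g2)^2)), 0.1)
})

test_that("non-overlapping windows raise a coverage error", {
  pmf <- pmf_flat(0, 10)
  wins <- sample_umbrella_windows(pmf, c(1, 9), k_bias = 5000,
                                  n_samples = 500, seed = 4)
  expect_error(wham(wins), "overlap")
})

test_that("windows at different temperatures are rejected", {
  w1 <- umbrella_window(1, 1000, rnorm(100, 1, 0.05), 310)
  w2 <- umbrella_window(1.1, 1000, rnorm(100, 1.1, 0.05), 300)
  expect_error(wham(list(w1, w2)), "temperature")
})

test_that("minimum extraction refines below the bin width", {
  pmf <- pmf_harmonic(z0 = 2.53, kappa = 800, z_lo = 1.5, z_hi = 3.5)
  wins <- sample_umbrella_windows(pmf, window_plan(3.5, 1.5, 0.1),
                                  k_bias = 2000, n_samples = 3000,
                                  seed = 23)
  pm <- profile_minimum(wham(wins))
  expect_lt(abs(pm$z_min - 2.53), 0.025)   # within bin_width / 2
  ## a noisy flat profile has a near-zero minimum
  flat <- wham(sample_umbrella_windows(pmf_flat(0, 5), 2.5,
                                       k_bias = 0.001,
                                       n_samples = 20000, seed = 2),
               bin_width = 0.25)
  pf <- profile_minimum(flat)
  expect_lt(abs(pf$delta_G), 0.2)
  ## a monotone profile flags its edge minimum
  mono <- structure(data.frame(z = seq(1, 2, 0.05),
                               G = seq(0, 5, length.out = 21),
                               count = 100),
                    class = c("free_energy_profile", "data.frame"))
  expect_warning(pe <- profile_minimum(mono), "edge")
  expect_true(pe$edge)
  expect_equal(pe$z_min, 1)
})
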