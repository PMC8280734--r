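# Trajectory metrics against their definitions and oracles.

sel_gas <- bead_selection(role = "water")

test_that("ideal gas gives g(r) = 1 beyond the first bins", {
  gas <- make_ideal_gas(5000, c(10, 10, 10), n_frames = 2, seed = 5)
  rdf <- radial_distribution(gas, sel_gas, sel_gas, bin_width = 0.1)
  expect_true(all(abs(rdf$g[rdf$r >= 1] - 1) <= 0.05))
})

test_that("two fixed beads occupy exactly one distance bin", {
  fr <- list(box = c(5, 5, 5),
             beads = data.frame(x = 1, y = 1, z = c(1, 2),
                                molecule = 1:2, role = "water",
                                residue = "GAS", leaflet = NA))
  fs <- frame_set(list(fr))
  rdf <- radial_distribution(fs, sel_gas, sel_gas, bin_width = 0.1,
                             r_max = 2)
  expect_equal(rdf$r[rdf$count > 0], 0.95)   # bin containing 1.0
  expect_equal(sum(rdf$count > 0), 1)
})

test_that("RDF counts are bin-exact against the brute-force oracle", {
  for (seed in 1:50) {
    gas <- make_ideal_gas(40, c(4, 5, 6), seed = seed)
    rdf <- radial_distribution(gas, sel_gas, sel_gas, bin_width = 0.2,
                               r_max = 2)
    oracle <- brute_force_rdf_counts(gas$frames[[1]], 1:40, 1:40, 0.2, 2)
    expect_equal(rdf$count, oracle)
  }
})

test_that("RDF rejects bad ranges and empty selections", {
  gas <- make_ideal_gas(10, c(4, 4, 4), seed = 1)
  expect_error(radial_distribution(gas, sel_gas, sel_gas, r_max = 3),
               "half")
  expect_error(radial_distribution(gas, bead_selection(role = "tail"),
                                   sel_gas), "selection")
})

test_that("order parameter hits its exact endpoints and magic angle", {
  p2_at <- function(tilt)
    order_parameter(make_flat_bilayer(bilayer_spec(tilt = tilt)))$mean
  expect_identical(p2_at(0), 1)
  expect_equal(p2_at(90), -0.5, tolerance = 1e-12)
  expect_lt(abs(p2_at(54.7356103)), 1e-4)
  ## bounds hold on noisy data
  noisy <- order_parameter(make_flat_bilayer(
    bilayer_spec(sigma = 0.3, seed = 8)))
  expect_true(all(noisy$values >= -0.5 - 1e-12 & noisy$values <= 1 + 1e-12))
})

test_that("short chains are rejected", {
  fs <- make_flat_bilayer(bilayer_spec(tail_beads = 2))
  expect_error(order_parameter(fs), "fewer than 3")
})

test_that("grid-aggregated P2 matches global P2 for homogeneous fields", {
  fs <- make_flat_bilayer(bilayer_spec(sigma = 0.05, seed = 2))
  of <- order_parameter(fs, grid = 10)
  w <- of$map$counts > 0
  grid_mean <- sum(of$map$values[w] * of$map$counts[w]) /
    sum(of$map$counts[w])
  expect_equal(grid_mean, mean(of$values), tolerance = 1e-12)
})

test_that("thickness map reproduces the generator separation", {
  ## noise-free: every cell exact
  tm <- thickness_map(make_flat_bilayer(bilayer_spec(separation = 4.0)),
                      grid = 50)
  expect_true(all(abs(tm$values - 4.0) < 1e-12))
  ## noisy: map mean within the propagated noise bound
  for (sep in c(3.6, 4.4)) {
    fs <- make_flat_bilayer(bilayer_spec(separation = sep, sigma = 0.05,
                                         n_frames = 4, seed = 31))
    tm <- thickness_map(fs, grid = 20)
    ## each surface averages 3 phosphates over 4 frames
    tol <- 3 * sqrt(2) * 0.05 / sqrt(3 * 4)
    expect_lt(abs(mean(tm$values) - sep), tol)
  }
})

test_that("thickness map agrees with a direct plane-fit oracle", {
  fs <- make_flat_bilayer(bilayer_spec(separation = 4.0, sigma = 0.03,
                                       seed = 12))
  tm <- thickness_map(fs, grid = 20)
  b <- fs$frames[[1]]$beads
  ph <- b[b$role == "phosphate", ]
  sep_direct <- mean(ph$z[ph$leaflet == "upper"]) -
    mean(ph$z[ph$leaflet == "lower"])
  expect_lt(abs(mean(tm$values) - sep_direct) / sep_direct, 0.01)
})

test_that("a leaflet with too few phosphates is an analysis error", {
  fr <- list(box = c(5, 5, 5),
             beads = data.frame(x = runif(4), y = runif(4),
                                z = c(2, 2, -2, -2), molecule = 1:4,
                                role = "phosphate", residue = "POPC",
                                leaflet = NA))
  expect_error(thickness_map(frame_set(list(fr)), grid = 5),
               "fewer than 3 phosphate")
})

test_that("lattice Voronoi cells are exact squares conserving box area", {
  fs <- make_flat_bilayer(bilayer_spec())
  apl <- area_per_lipid(fs)
  expect_true(all(abs(unlist(apl$areas) - 0.64) < 1e-9))
  expect_lt(abs(apl$total_area - apl$box_area) / apl$box_area, 1e-6)
})

test_that("carrier beads carve area without breaking conservation", {
  core <- build_core_bonds(place_beads_on_sphere(64, 2.0))
  tr <- make_binding_trace(data.frame(frame = 1, z = 1.0),
                           bilayer_spec(), core)
  apl <- area_per_lipid(tr)
  ref <- area_per_lipid(make_flat_bilayer(bilayer_spec()))
  expect_gt(apl$n_carrier, 0)
  expect_lt(apl$mean, ref$mean)
  expect_lt(max(abs(apl$total_area - apl$box_area)) / apl$box_area, 1e-6)
})

test_that("transversal density shows two symmetric phosphate peaks", {
  fs <- make_flat_bilayer(bilayer_spec(separation = 4.0, sigma = 0.05,
                                       seed = 6))
  prof <- transversal_density(fs, bin_width = 0.1)
  up <- prof[prof$z > 0, ]; lo <- prof[prof$z < 0, ]
  peak_up <- up$z[which.max(up$density)]
  peak_lo <- lo$z[which.max(lo$density)]
  expect_equal(peak_up, 2.0, tolerance = 0.1)
  expect_lt(abs(peak_up + peak_lo), 0.1)       # symmetry within a bin
  ## integral equals the mean phosphate count per frame
  expect_equal(sum(prof$density) * 0.1, 200, tolerance = 1e-9)
})

test_that("the COM separation CV matches its invariances", {
  core <- build_core_bonds(place_beads_on_sphere(64, 2.0))
  tr <- make_binding_trace(data.frame(frame = 1, z = 1.6),
                           bilayer_spec(), core)
  fr <- tr$frames[[1]]
  sel_np <- bead_selection(role = "core")
  sel_mem <- bead_selection(role = c("phosphate", "tail"))
  expect_equal(com_distance_z(fr, sel_np, sel_mem), 1.6,
               tolerance = 1e-9)
  expect_equal(com_distance_z(fr, sel_np, sel_np), 0)
  fr2 <- fr
  fr2$beads$z <- fr2$beads$z + 0.7
  expect_equal(com_distance_z(fr2, sel_np, sel_mem),
               com_distance_z(fr, sel_np, sel_mem), tolerance = 1e-12)
  expect_error(com_distance_z(fr, bead_selection(role = "nope"), sel_mem),
               "selection")
})

test_that("binding detection honours threshold and dwell", {
  trace <- c(rep(5, 99), rep(1.6, 51))
  expect_equal(detect_binding(trace, 2.0, dwell = 5), 100)
  expect_true(is.na(detect_binding(rep(5, 100), 2.0)))
  dip <- rep(5, 100); dip[50] <- 1.0
  expect_true(is.na(detect_binding(dip, 2.0, dwell = 5)))
  expect_equal(detect_binding(dip, 2.0, dwell = 1), 50)
})

test_that("metrics are invariant under periodic lateral translation", {
  fs <- make_flat_bilayer(bilayer_spec(sigma = 0.05, seed = 17))
  shift <- function(fs, dx, dy) {
    for (i in seq_along(fs$frames)) {
      b <- fs$frames[[i]]$beads
      b$x <- (b$x + dx) %% fs$frames[[i]]$box[1]
      b$y <- (b$y + dy) %% fs$frames[[i]]$box[2]
      fs$frames[[i]]$beads <- b
    }
    fs
  }
  fs2 <- shift(fs, 2.3, 5.1)
  sel_ph <- bead_selection(role = "phosphate")
  r1 <- radial_distribution(fs, sel_ph, sel_ph, bin_width = 0.2)
  r2 <- radial_distribution(fs2, sel_ph, sel_ph, bin_width = 0.2)
  expect_equal(r1$count, r2$count)
  a1 <- area_per_lipid(fs); a2 <- area_per_lipid(fs2)
  expect_equal(a1$mean, a2$mean, tolerance = 1e-9)
  ## thickness sampled on a fixed grid: shift by whole grid cells so
  ## the map is an exact permutation of cells
  fs3 <- shift(fs, 2.4, 4.0)          # box 8, grid 10 -> 0.8 nm cells
  t1 <- thickness_map(fs, 10); t3 <- thickness_map(fs3, 10)
  expect_equal(mean(t1$values), mean(t3$values), tolerance = 1e-9)
  expect_equal(sort(as.vector(t1$values)), sort(as.vector(t3$values)),
               tolerance = 1e-9)
})
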