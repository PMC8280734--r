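# Nanoparticle builder: sphere placement, bond network, surface
# charges, graft sites, elastic network, eccentricity.

test_that("beads land uniformly on the sphere at the requested radius", {
  core <- place_beads_on_sphere(187, 2.5)
  xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  expect_equal(nrow(xyz), 187)
  radii <- sqrt(rowSums(xyz^2))
  expect_true(all(abs(radii - 1.25) <= 1e-6))
  expect_lt(sqrt(sum(colMeans(xyz)^2)), 1e-3)
  ## near-uniform: minimum chord >= 80% of the equal-area ideal spacing
  D <- as.matrix(dist(xyz)); diag(D) <- Inf
  expect_gte(min(D), 0.8 * sqrt(4 * pi * 1.25^2 / 187))
})

test_that("two beads are antipodal; small cores are centred", {
  two <- place_beads_on_sphere(2, 1.0)
  xyz <- as.matrix(two$beads[, c("x", "y", "z")])
  expect_equal(sqrt(sum((xyz[1, ] - xyz[2, ])^2)), 1.0, tolerance = 1e-12)
  c64 <- place_beads_on_sphere(64, 2.0)
  expect_lt(sqrt(sum(colMeans(
    as.matrix(c64$beads[, c("x", "y", "z")]))^2)), 1e-3)
})

test_that("builder rejects invalid bead counts and diameters", {
  expect_error(place_beads_on_sphere(1, 2.5))
  expect_error(place_beads_on_sphere(187, -1))
  expect_error(place_beads_on_sphere(10.5, 2.5))
})

test_that("bond network bonds six neighbours plus the antipodal bead", {
  core <- build_core_bonds(place_beads_on_sphere(187, 2.5), k_b = 2250)
  deg <- table(c(core$bonds$i, core$bonds$j))
  expect_length(deg, 187)           # every bead bonded
  expect_gte(min(deg), 6)
  expect_true(all(core$bonds$i < core$bonds$j))      # canonical, deduped
  expect_false(any(duplicated(core$bonds[, c("i", "j")])))
  ## r0 is the build distance
  xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[core$bonds$i, ] - xyz[core$bonds$j, ])^2))
  expect_equal(core$bonds$r0, d, tolerance = 1e-12)
  expect_true(all(core$bonds$k_b == 2250))
})

test_that("two-bead core yields exactly the single antipodal bond", {
  core <- build_core_bonds(place_beads_on_sphere(2, 1.0), k_b = 2250)
  expect_equal(nrow(core$bonds), 1)
  expect_equal(core$bonds$r0, 1.0, tolerance = 1e-12)
})

test_that("bond graph is connected for a range of core sizes", {
  for (n in c(20, 64, 187)) {
    core <- build_core_bonds(place_beads_on_sphere(n, 2.5))
    adj <- matrix(FALSE, n, n)
    adj[cbind(core$bonds$i, core$bonds$j)] <- TRUE
    adj <- adj | t(adj)
    ## reachability by repeated neighbour expansion
    reach <- c(TRUE, rep(FALSE, n - 1))
    repeat {
      new <- reach | apply(adj[reach, , drop = FALSE], 2, any)
      if (all(new == reach)) break
      reach <- new
    }
    expect_true(all(reach), label = paste("connected at n =", n))
  }
})

test_that("citrate charging puts the site charge on a spread subset", {
  core <- assign_surface_charges(
    build_core_bonds(place_beads_on_sphere(187, 2.5)), 28, -2)
  expect_equal(sum(core$beads$charge != 0), 28)
  expect_true(all(core$beads$charge %in% c(0, -2)))
  expect_equal(sum(core$beads$charge), -56)
  ## spread: min pairwise distance beats the bulk of random subsets
  xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  sel <- which(core$beads$charge != 0)
  min_d <- function(s) {
    D <- as.matrix(dist(xyz[s, ])); diag(D) <- Inf; min(D)
  }
  set.seed(42)
  rand <- replicate(1000, min_d(sample(187, 28)))
  expect_gt(min_d(sel), quantile(rand, 0.05))
})

test_that("single charge site and bad site counts behave", {
  core <- assign_surface_charges(place_beads_on_sphere(20, 2), 1, -2)
  expect_equal(sum(core$beads$charge), -2)
  expect_equal(sum(core$beads$charge != 0), 1)
  expect_error(assign_surface_charges(place_beads_on_sphere(20, 2), 21, -2))
})

test_that("six graft sites sit at the cardinal points", {
  core <- place_beads_on_sphere(187, 2.5)
  sites <- select_graft_sites(core, 6)
  expect_length(unique(sites), 6)
  xyz <- as.matrix(core$beads[sites, c("x", "y", "z")])
  u <- xyz / sqrt(rowSums(xyz^2))
  ## pairwise angular separations cluster near 90 and 180 degrees
  ang <- acos(pmin(1, pmax(-1, tcrossprod(u)))) * 180 / pi
  ang <- ang[upper.tri(ang)]
  expect_true(all(abs(ang - 90) < 15 | abs(ang - 180) < 15))
  ## each site is the global angular minimiser for its axis point
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  all_xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  all_u <- all_xyz / sqrt(rowSums(all_xyz^2))
  for (a in 1:6) {
    best <- which.max(all_u %*% axes[a, ])
    expect_true(best %in% sites)
  }
  ## single-site convention: nearest +z
  expect_equal(select_graft_sites(core, 1),
               which.max(core$beads$z))
})

test_that("elastic network equals the brute-force all-pairs filter", {
  ## forced geometry: 3 collinear beads at 0.6 nm spacing
  pos <- rbind(c(0, 0, 0), c(0, 0, 0.6), c(0, 0, 1.2))
  en <- build_elastic_network(pos, k = 500, r_min = 0.5, r_max = 0.9)
  expect_equal(nrow(en), 2)
  expect_true(all(en$k_b == 500))
  ## far-apart beads: no bonds
  expect_equal(nrow(build_elastic_network(2 * pos, 500, 0.5, 0.9)), 0)
  ## property: match the O(n^2) oracle across random fixtures
  for (seed in 1:100) {
    set.seed(seed)
    p <- matrix(runif(3 * 12, 0, 2), ncol = 3)
    en <- build_elastic_network(p, 500, 0.5, 0.9)
    expect_equal(nrow(en), brute_force_pair_filter(p, 0.5, 0.9))
    if (nrow(en)) {
      d <- sqrt(rowSums((p[en$i, , drop = FALSE] -
                           p[en$j, , drop = FALSE])^2))
      expect_equal(en$r0, d, tolerance = 1e-12)
    }
  }
})

test_that("eccentricity matches a direct inertia-tensor oracle", {
  set.seed(7)
  for (rep in 1:5) {
    cloud <- matrix(rnorm(3 * 40), ncol = 3) %*% diag(c(1, 0.7, 0.4))
    expect_equal(compute_eccentricity(cloud), direct_eccentricity(cloud),
                 tolerance = 1e-10)
  }
  ## near-collinear cloud approaches the e -> 1 limit
  line <- cbind(seq(0, 1, length.out = 30), 0, 0) +
    matrix(rnorm(90, 0, 1e-4), ncol = 3)
  expect_gt(compute_eccentricity(line), 0.99)
  expect_error(compute_eccentricity(matrix(0, 4, 3)))
})

test_that("built core is near-spherical and rotation leaves e fixed", {
  core <- place_beads_on_sphere(187, 2.5)
  xyz <- as.matrix(core$beads[, c("x", "y", "z")])
  e0 <- compute_eccentricity(xyz)
  expect_lt(e0, 0.02)
  set.seed(3)
  for (rep in 1:5) {
    ax <- rnorm(3)
    R <- nanomem:::rotation_matrix(ax, runif(1, 0, 2 * pi))
    expect_lt(abs(compute_eccentricity(xyz %*% t(R)) - e0), 1e-9)
  }
})

test_that("grafting places one peptide per site with additive charge", {
  core <- build_core_bonds(place_beads_on_sphere(187, 2.5))
  pep <- synthetic_gh_model()
  np <- graft_peptides(core, pep, select_graft_sites(core, 6))
  expect_s3_class(np, "assembled_np")
  expect_length(np$peptides, 6)
  expect_equal(nrow(np$graft_bonds), 6)
  expect_length(unique(np$graft_bonds$i), 6)
  expect_equal(total_charge(np), total_charge(core) + 6 * pep$net_charge)
  ## no peptide bead inside the clash shell of the core
  cxyz <- as.matrix(core$beads[, c("x", "y", "z")])
  for (k in seq_along(np$peptides)) {
    p <- np$peptides[[k]]
    linker_global <- np$graft_bonds$j[k]
    for (b in seq_len(nrow(p))) {
      d <- sqrt(colSums((t(cxyz) - c(p$x[b], p$y[b], p$z[b]))^2))
      if (187 + (k - 1) * nrow(p) + b == linker_global)
        d[np$graft_bonds$i[k]] <- Inf
      expect_gte(min(d), 0.3 - 1e-9)
    }
  }
})

test_that("grafting zero sites reproduces the bare core", {
  core <- build_core_bonds(place_beads_on_sphere(64, 2.0))
  np <- graft_peptides(core, synthetic_gh_model(), integer())
  expect_length(np$peptides, 0)
  expect_equal(total_charge(np), total_charge(core))
  expect_equal(nrow(nanomem:::flatten_topology(np)), 64)
})

test_that("synthetic gH model carries its stated anchors and charge", {
  pep <- synthetic_gh_model()
  expect_equal(pep$net_charge, 5)
  expect_length(unique(pep$anchors), 6)
  expect_true(all(pep$beads$role[pep$anchors] == "backbone"))
  ## helix is rigid enough to have an elastic network
  expect_gt(nrow(pep$bonds), nrow(pep$beads))
})
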