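# Synthetic ground-truth generators. The analysis and free-energy
# stages are exercised on idealized systems whose true parameters are
# known by construction: lattice bilayers with prescribed thickness and
# tail tilt, ideal-gas bead fields, rigid helices at prescribed
# orientation angles, composite nanoparticle-plus-bilayer frames with a
# prescribed approach trace, and Boltzmann-exact umbrella-window
# samples from a known free-energy surface. Every generator is
# deterministic under its seed.

#' Synthetic bilayer specification
#'
#' Defaults describe an idealized fluid-phase phosphatidylcholine
#' bilayer: 100 lipids per leaflet on a 0.8 nm lattice (area per lipid
#' 0.64 nm^2), 4 nm phosphate-plane separation, four-bead tails, no
#' tilt, no sterol, no noise.
#'
#' @param lipids_per_leaflet lipids per leaflet; must be a perfect
#'   square (lattice construction)
#' @param spacing lateral lattice constant, nm
#' @param separation distance between the two phosphate planes
#'   (target bilayer thickness), nm
#' @param tail_beads beads per acyl chain
#' @param tilt tail tilt from the membrane normal, degrees
#' @param sterol_fraction fraction of leaflet sites occupied by a
#'   single-bead sterol analogue instead of a lipid, in `[0, 1]`
#' @param sigma isotropic Gaussian positional noise, nm
#' @param n_frames number of frames (independent noise realisations)
#' @param seed RNG seed
#' @return object of class `bilayer_spec`
#' @export
bilayer_spec <- function(lipids_per_leaflet = 100, spacing = 0.8,
                         separation = 4.0, tail_beads = 4, tilt = 0,
                         sterol_fraction = 0, sigma = 0, n_frames = 1,
                         seed = 1) {
  side <- sqrt(lipids_per_leaflet)
  if (side != round(side))
    stop("lipids_per_leaflet must be a perfect square")
  stopifnot(spacing > 0, separation > 0, tail_beads >= 1,
            sterol_fraction >= 0, sterol_fraction <= 1, sigma >= 0,
            n_frames >= 1)
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 spacing = spacing, separation = separation,
                 tail_beads = as.integer(tail_beads), tilt = tilt,
                 sterol_fraction = sterol_fraction, sigma = sigma,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "bilayer_spec")
}

#' Generate a flat two-leaflet bilayer
#'
#' Lipids sit on a jittered square lattice; phosphate beads at
#' z = +/- separation/2 (bilayer midplane at z = 0), tail chains
#' pointing inward at the prescribed tilt from the z axis (tilt azimuth
#' along +x). A prescribed fraction of sites carries a single-bead
#' sterol head (`ROH` analogue) just below the phosphate plane instead
#' of a lipid. The generated membrane is ground truth for the analysis
#' metrics, not a realistic conformational ensemble.
#'
#' @param spec `bilayer_spec`
#' @return `frame_set`; upper/lower leaflet hints are set
#' @export
make_flat_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  side <- as.integer(sqrt(spec$lipids_per_leaflet))
  a <- spec$spacing
  lx <- side * a
  box <- c(lx, lx, spec$separation + 6)
  xy <- as.matrix(expand.grid(x = (seq_len(side) - 0.5) * a,
                              y = (seq_len(side) - 0.5) * a))
  n_site <- nrow(xy)
  n_sterol <- round(spec$sterol_fraction * n_site)
  set.seed(spec$seed)
  sterol_sites <- list(
    upper = if (n_sterol) sample.int(n_site, n_sterol) else integer(),
    lower = if (n_sterol) sample.int(n_site, n_sterol) else integer())
  tilt <- deg2rad(spec$tilt)
  bond <- 0.47   # tail bead spacing along the chain director, nm

  template <- list()
  mol <- 0L
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    zp <- sgn * spec$separation / 2
    ## chain director: inward at the prescribed tilt, azimuth +x
    dir <- c(sin(tilt), 0, -sgn * cos(tilt))
    for (s in seq_len(n_site)) {
      mol <- mol + 1L
      if (s %in% sterol_sites[[leaf]]) {
        template[[length(template) + 1]] <- data.frame(
          x = xy[s, 1], y = xy[s, 2], z = zp - sgn * 0.3,
          molecule = mol, role = "sterol-head", residue = "CHOL",
          leaflet = leaf, stringsAsFactors = FALSE)
      } else {
        k <- seq_len(spec$tail_beads)
        template[[length(template) + 1]] <- data.frame(
          x = c(xy[s, 1], xy[s, 1] + k * bond * dir[1]),
          y = c(xy[s, 2], xy[s, 2] + k * bond * dir[2]),
          z = c(zp, zp + k * bond * dir[3]),
          molecule = mol,
          role = c("phosphate", rep("tail", spec$tail_beads)),
          residue = "POPC", leaflet = leaf, stringsAsFactors = FALSE)
      }
    }
  }
  template <- do.call(rbind, template)
  rownames(template) <- NULL

  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    beads <- template
    if (spec$sigma > 0) {
      beads$x <- beads$x + stats::rnorm(nrow(beads), 0, spec$sigma)
      beads$y <- beads$y + stats::rnorm(nrow(beads), 0, spec$sigma)
      beads$z <- beads$z + stats::rnorm(nrow(beads), 0, spec$sigma)
    }
    frames[[f]] <- list(box = box, beads = beads)
  }
  frame_set(frames, wrapped = FALSE)
}

#' Generate an ideal-gas bead field
#'
#' Uniform, uncorrelated bead positions in an orthorhombic box; the
#' null model for radial distribution functions (g(r) = 1).
#'
#' @param n beads per frame
#' @param box length-3 box, nm
#' @param n_frames frames
#' @param seed RNG seed
#' @param role bead role label
#' @return `frame_set` (wrapped coordinates)
#' @export
make_ideal_gas <- function(n, box = c(10, 10, 10), n_frames = 1, seed = 1,
                           role = "water") {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    beads <- data.frame(
      x = stats::runif(n, 0, box[1]), y = stats::runif(n, 0, box[2]),
      z = stats::runif(n, 0, box[3]), molecule = seq_len(n), role = role,
      residue = "GAS", leaflet = NA_character_, stringsAsFactors = FALSE)
    list(box = box, beads = beads)
  })
  frame_set(frames, wrapped = TRUE)
}

## torsion angle of the three-vector construction (b1, b2, b3) in
## degrees mapped to [0, 360); shared by the generator (inverse
## construction) and the measurement in peptide_geometry
torsion_deg <- function(b1, b2, b3) {
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  (ang + 360) %% 360
}

#' Build a rigid helix at prescribed orientation angles
#'
#' Places the synthetic gH helix so that the measured inclination
#' (Leu627 to Ala639 backbone vector versus +z) equals `theta_inc`
#' exactly and the measured rolling angle equals `phi_roll`. The roll is
#' set by inverse construction: the helix is rotated about its own
#' measured axis until the torsion-angle definition returns the target.
#'
#' @param theta_inc target inclination, degrees in `[0, 180]`
#' @param phi_roll target rolling angle, degrees in `[0, 360)`. The
#'   roll is fully controllable for intermediate inclinations (about
#'   30-150 degrees); toward the poles rotating the helix about its
#'   own axis barely moves the torsion-angle definition, and an
#'   unattainable request is honoured as closely as possible with a
#'   warning.
#' @param com centre-of-mass position of the placed helix, nm
#' @param box box lengths, nm
#' @param model peptide model (default the synthetic gH helix)
#' @return single-frame `frame_set`; ground-truth angles stored in
#'   attribute `truth`
#' @export
make_helix <- function(theta_inc, phi_roll = 90, com = c(5, 5, 1.5),
                       box = c(10, 10, 10),
                       model = synthetic_gh_model()) {
  stopifnot(theta_inc >= 0, theta_inc <= 180)
  phi_roll <- phi_roll %% 360
  xyz <- bead_xyz(model$beads)
  a <- model$anchors
  axis0 <- unit(xyz[a[["ala639"]], ] - xyz[a[["leu627"]], ])
  target_axis <- c(sin(deg2rad(theta_inc)), 0, cos(deg2rad(theta_inc)))
  R1 <- rotation_between(axis0, target_axis)
  xyz <- xyz %*% t(R1)

  measure_phi <- function(p) {
    torsion_deg(c(0, 0, 1),
                p[a[["thr630"]], ] - p[a[["trp634"]], ],
                p[a[["thr632"]], ] - p[a[["thr630"]], ])
  }
  roll_by <- function(delta) xyz %*% t(rotation_matrix(target_axis,
                                                       deg2rad(delta)))
  ## scan for the roll that realises the target torsion, then refine;
  ## the torsion winds once around as the helix rolls through 360
  deltas <- seq(0, 360, by = 0.5)
  err <- vapply(deltas, function(d) {
    e <- (measure_phi(roll_by(d)) - phi_roll) %% 360
    min(e, 360 - e)
  }, numeric(1))
  d0 <- deltas[which.min(err)]
  refine <- stats::optimize(function(d) {
    e <- (measure_phi(roll_by(d)) - phi_roll) %% 360
    min(e, 360 - e)
  }, interval = c(d0 - 1, d0 + 1), tol = 1e-10)
  xyz <- roll_by(refine$minimum)
  achieved <- measure_phi(xyz)
  miss <- abs((achieved - phi_roll) %% 360)
  if (min(miss, 360 - miss) > 1e-3)
    warning(sprintf(
      paste("rolling angle %.1f not attainable at inclination %.1f",
            "(the roll degenerates toward the poles); achieved %.1f"),
      phi_roll, theta_inc, achieved))

  xyz <- sweep(xyz, 2, com - colMeans(xyz), FUN = "+")
  beads <- data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], molecule = 1L,
    role = ifelse(model$beads$role == "backbone", "peptide-backbone",
                  "peptide-side"),
    residue = model$beads$residue_tag, leaflet = NA_character_,
    stringsAsFactors = FALSE)
  fs <- frame_set(list(list(box = box, beads = beads)), wrapped = FALSE)
  attr(fs, "truth") <- list(theta_inc = theta_inc, phi_roll = phi_roll)
  fs
}

#' Backbone anchor indices of a placed gH helix
#'
#' @param frame a frame containing one gH peptide
#' @return named integer vector (`leu627`, `thr630`, `thr632`,
#'   `trp634`, `ala639`)
#' @export
gh_anchors <- function(frame) {
  b <- frame$beads
  find <- function(res) {
    i <- which(b$residue == res & b$role == "peptide-backbone")
    if (length(i) != 1) stop("anchor ", res, " not found uniquely")
    i
  }
  c(leu627 = find("LEU627"), thr630 = find("THR630"),
    thr632 = find("THR632"), trp634 = find("TRP634"),
    ala639 = find("ALA639"))
}

#' One-dimensional model free-energy surface
#'
#' @param fn function of z (nm) returning free energy in kcal mol^-1
#' @param z_lo,z_hi domain, nm
#' @param temperature K
#' @return object of class `true_pmf` (callable)
#' @export
true_pmf <- function(fn, z_lo, z_hi, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.function(fn), z_lo < z_hi, temperature > 0)
  structure(list(fn = fn, z_lo = z_lo, z_hi = z_hi,
                 temperature = temperature), class = "true_pmf")
}

#' Gaussian double-well model free-energy surface
#'
#' Two attractive Gaussian wells separated by a Gaussian barrier,
#' flattening to zero at large separation; the default places wells at
#' 1.6 and 3.5 nm with a 5 kcal mol^-1 barrier between them, a
#' caricature of a carrier first contacting and then embedding into a
#' bilayer.
#'
#' @param z1,depth1,width1 inner well centre (nm), depth (kcal mol^-1,
#'   positive number = well), width (nm)
#' @param z2,depth2,width2 outer well
#' @param zb,barrier,widthb barrier centre, height, width
#' @param z_lo,z_hi domain, nm
#' @param temperature K
#' @return `true_pmf`
#' @export
pmf_double_well <- function(z1 = 1.6, depth1 = 8, width1 = 0.3,
                            z2 = 3.5, depth2 = 3, width2 = 0.35,
                            zb = 2.5, barrier = 5, widthb = 0.25,
                            z_lo = 0.8, z_hi = 5.5,
                            temperature = DEFAULT_TEMPERATURE) {
  fn <- function(z)
    -depth1 * exp(-(z - z1)^2 / (2 * width1^2)) -
      depth2 * exp(-(z - z2)^2 / (2 * width2^2)) +
      barrier * exp(-(z - zb)^2 / (2 * widthb^2))
  true_pmf(fn, z_lo, z_hi, temperature)
}

#' Harmonic model free-energy surface
#'
#' @param z0 minimum position, nm
#' @param kappa curvature, kJ mol^-1 nm^-2
#' @param z_lo,z_hi domain, nm
#' @param temperature K
#' @return `true_pmf`
#' @export
pmf_harmonic <- function(z0 = 2.5, kappa = 500, z_lo = 0.5, z_hi = 4.5,
                         temperature = DEFAULT_TEMPERATURE) {
  true_pmf(function(z) kj_to_kcal(0.5 * kappa * (z - z0)^2), z_lo, z_hi,
           temperature)
}

#' Flat model free-energy surface
#' @param z_lo,z_hi domain, nm
#' @param temperature K
#' @return `true_pmf`
#' @export
pmf_flat <- function(z_lo = 0, z_hi = 5,
                     temperature = DEFAULT_TEMPERATURE) {
  true_pmf(function(z) rep(0, length(z)), z_lo, z_hi, temperature)
}

#' Draw Boltzmann-exact umbrella-window samples
#'
#' For each window centre, samples the collective variable from the
#' density proportional to `exp(-(G(z) + k/2 (z - z_c)^2) / kT)` by
#' inverse-CDF interpolation on a fine grid — exact draws up to grid
#' resolution, with no autocorrelation, standing in for long biased
#' simulations.
#'
#' @param pmf `true_pmf` ground-truth surface
#' @param centers window centres, nm (see [window_plan()])
#' @param k_bias harmonic bias constant, kJ mol^-1 nm^-2
#' @param n_samples samples per window
#' @param seed RNG seed (one stream across all windows)
#' @param grid_n grid resolution for the inverse CDF
#' @return list of `umbrella_window` objects
#' @export
sample_umbrella_windows <- function(pmf, centers, k_bias = 2000,
                                    n_samples = 5000, seed = 1,
                                    grid_n = 8192) {
  stopifnot(inherits(pmf, "true_pmf"), k_bias > 0, n_samples > 0)
  if (any(centers < pmf$z_lo - 1e-9 | centers > pmf$z_hi + 1e-9))
    stop("window centers outside the PMF domain [", pmf$z_lo, ", ",
         pmf$z_hi, "]")
  kT <- kT_kJ(pmf$temperature)
  z <- seq(pmf$z_lo, pmf$z_hi, length.out = grid_n)
  g_kj <- kcal_to_kj(pmf$fn(z))
  set.seed(seed)
  lapply(centers, function(zc) {
    e <- g_kj + 0.5 * k_bias * (z - zc)^2
    w <- exp(-(e - min(e)) / kT)
    if (!any(is.finite(w)) || sum(w) <= 0)
      stop("zero normalisation in window at ", zc)
    ## trapezoidal cumulative density: a plain cumsum treats the grid
    ## as point masses and biases every draw by half a grid cell,
    ## which a stiff restraint amplifies into a visible profile tilt
    cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(n_samples)
    ## strictly increasing sub-grid for interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    samples <- stats::approx(cdf[keep], z[keep], xout = u, rule = 2)$y
    umbrella_window(center = zc, k_bias = k_bias, samples = samples,
                    temperature = pmf$temperature)
  })
}

#' Composite nanoparticle + bilayer frames with a prescribed approach
#'
#' Builds one frame per schedule row: the bilayer from `spec` plus the
#' nanoparticle placed with its centre of mass at the scheduled height
#' above the bilayer midplane (laterally centred). Ground truth for the
#' centre-of-mass separation metric and binding-event detection.
#'
#' @param schedule data frame with columns `frame` (strictly
#'   increasing) and `z` (COM height above the midplane, nm)
#' @param spec `bilayer_spec`
#' @param np `core_topology` or `assembled_np`
#' @return `frame_set`
#' @export
make_binding_trace <- function(schedule, spec, np) {
  stopifnot(is.data.frame(schedule),
            all(c("frame", "z") %in% names(schedule)),
            nrow(schedule) >= 1)
  if (is.unsorted(schedule$frame, strictly = TRUE))
    stop("schedule must be strictly increasing in frame index")
  spec$n_frames <- nrow(schedule)
  bilayer <- make_flat_bilayer(spec)
  np_beads <- flatten_topology(np)
  role <- rep("core", nrow(np_beads))
  if ("role" %in% names(np_beads))
    role <- ifelse(is.na(np_beads$role) | np_beads$role == "",
                   "core",
                   ifelse(np_beads$role == "backbone", "peptide-backbone",
                          ifelse(np_beads$role == "side", "peptide-side",
                                 "core")))
  np_xyz <- bead_xyz(np_beads)
  np_xyz <- sweep(np_xyz, 2, colMeans(np_xyz))   # COM at origin
  frames <- vector("list", nrow(schedule))
  for (f in seq_len(nrow(schedule))) {
    bf <- bilayer$frames[[f]]
    pos <- sweep(np_xyz, 2,
                 c(bf$box[1] / 2, bf$box[2] / 2, schedule$z[f]),
                 FUN = "+")
    np_df <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      molecule = max(bf$beads$molecule) + 1L, role = role,
      residue = np_beads$residue_tag, leaflet = NA_character_,
      stringsAsFactors = FALSE)
    frames[[f]] <- list(box = bf$box, beads = rbind(bf$beads, np_df))
  }
  out <- frame_set(frames, wrapped = FALSE)
  attr(out, "truth") <- list(schedule = schedule)
  out
}
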