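# Construction of coarse-grained metal nanoparticle topologies: a rigid
# spherical shell of hydrophobic beads held by a harmonic bond network,
# optionally carrying an implicit-citrate surface charge or a grafted
# monolayer of helical peptides.

#' Spherical nanoparticle core
#'
#' A `core_topology` holds the bead table and harmonic bond list of a
#' coarse-grained spherical nanoparticle. Beads are placed on a sphere
#' centred at the origin; bonds are built later by
#' [build_core_bonds()].
#'
#' @param beads data frame with columns `index`, `x`, `y`, `z` (nm),
#'   `bead_type`, `charge` (e), `residue_tag`
#' @param bonds data frame with columns `i`, `j`, `k_b`
#'   (kJ mol^-1 nm^-2), `r0` (nm)
#' @param diameter core diameter, nm
#' @param graft_sites integer bead indices reserved for peptide grafting
#' @return object of class `core_topology`
#' @export
core_topology <- function(beads, bonds = empty_bond_table(), diameter,
                          graft_sites = integer()) {
  stopifnot(is.data.frame(beads),
            all(c("index", "x", "y", "z", "bead_type", "charge",
                  "residue_tag") %in% names(beads)),
            all(is.finite(as.matrix(beads[, c("x", "y", "z")]))),
            diameter > 0)
  structure(list(beads = beads, bonds = bonds, diameter = diameter,
                 graft_sites = as.integer(graft_sites)),
            class = "core_topology")
}

empty_bond_table <- function() {
  data.frame(i = integer(), j = integer(), k_b = numeric(), r0 = numeric())
}

bead_xyz <- function(beads) as.matrix(beads[, c("x", "y", "z")])

#' @export
print.core_topology <- function(x, ...) {
  cat(sprintf(
    "core_topology: %d beads, %d bonds, diameter %.3f nm, total charge %+g e\n",
    nrow(x$beads), nrow(x$bonds), x$diameter, sum(x$beads$charge)))
  invisible(x)
}

#' Place beads uniformly on a sphere
#'
#' Distributes `n_beads` points on a sphere of the given diameter with a
#' deterministic Fibonacci (golden-spiral) lattice, the standard
#' quasi-uniform construction for bead-shell nanoparticle models. The
#' two-bead case returns the antipodal pair on the z axis.
#'
#' @param n_beads number of surface beads (>= 2)
#' @param diameter sphere diameter, nm
#' @param bead_type Martini bead type label assigned to every bead;
#'   hydrophobic `"C1"` reproduces the dispersion behaviour of bare
#'   noble-metal colloids
#' @return `core_topology` with beads only (no bonds)
#' @examples
#' core <- place_beads_on_sphere(187, 2.5)
#' range(sqrt(rowSums(core$beads[, c("x", "y", "z")]^2)))
#' @export
place_beads_on_sphere <- function(n_beads, diameter, bead_type = "C1") {
  if (!(is.numeric(n_beads) && length(n_beads) == 1 && n_beads >= 2 &&
        n_beads == round(n_beads)))
    stop("n_beads must be a single integer >= 2")
  if (!(is.numeric(diameter) && length(diameter) == 1 && diameter > 0))
    stop("diameter must be a single positive number")
  n <- as.integer(n_beads)
  r <- diameter / 2
  if (n == 2L) {
    xyz <- rbind(c(0, 0, r), c(0, 0, -r))
  } else {
    i <- seq_len(n) - 1
    ## golden-spiral lattice: equal-area latitudes, golden-angle azimuths
    z <- 1 - (2 * i + 1) / n
    phi <- i * pi * (3 - sqrt(5))
    s <- sqrt(pmax(0, 1 - z^2))
    xyz <- r * cbind(s * cos(phi), s * sin(phi), z)
    ## recentre so the centroid sits at the origin, then reproject:
    ## the spiral centroid is already O(1/n) from zero, a couple of
    ## Lloyd-style recentring passes push it below 1e-3 nm
    for (pass in 1:3) {
      xyz <- sweep(xyz, 2, colMeans(xyz))
      xyz <- r * xyz / sqrt(rowSums(xyz^2))
    }
  }
  beads <- data.frame(index = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], bead_type = bead_type, charge = 0,
                      residue_tag = "core", stringsAsFactors = FALSE)
  core_topology(beads, diameter = diameter)
}

pairwise_dist <- function(xyz) as.matrix(stats::dist(xyz))

#' Build the core bond network
#'
#' Bonds every bead to its six nearest neighbours and to its radially
#' opposing neighbour (the bead closest to its exact antipode), each with
#' a harmonic potential whose equilibrium length is the build-time
#' distance. Duplicate pairs arising from the symmetric neighbour search
#' are merged. The resulting network keeps the shell rigid and spherical.
#'
#' @param core `core_topology`
#' @param k_b harmonic force constant, kJ mol^-1 nm^-2
#' @return the core with its `bonds` table filled in
#' @export
build_core_bonds <- function(core, k_b = 2250) {
  stopifnot(inherits(core, "core_topology"), k_b > 0)
  xyz <- bead_xyz(core$beads)
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 beads to build bonds")
  D <- pairwise_dist(xyz)
  if (any(D[upper.tri(D)] < 1e-9))
    stop("degenerate geometry: coincident beads")
  pairs <- matrix(integer(), 0, 2)
  n_nn <- min(6L, n - 1L)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d)[seq_len(n_nn)]
    ## antipodal partner: bead nearest the exact reflection through the centre
    anti_d <- sqrt(colSums((t(xyz) + xyz[i, ])^2))
    anti_d[i] <- Inf
    partner <- which.min(anti_d)
    pairs <- rbind(pairs, cbind(i, c(nn, partner)))
  }
  ## canonical order then dedup
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  r0 <- D[pairs]
  core$bonds <- data.frame(i = as.integer(pairs[, 1]),
                           j = as.integer(pairs[, 2]),
                           k_b = k_b, r0 = r0)
  if (!bond_graph_connected(n, core$bonds))
    stop("bond network is not connected")
  core
}

## breadth-first connectivity check on the bond graph
bond_graph_connected <- function(n, bonds) {
  if (n == 1) return(TRUE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Assign implicit-citrate surface charges
#'
#' Marks `n_sites` beads as charge carriers with `site_charge` each,
#' representing citrate capping as fixed charges covalently held on the
#' metal surface rather than explicit ligands. The charged subset is
#' chosen by greedy farthest-point selection (seeded at the first bead)
#' so that like charges are maximally spread over the shell.
#'
#' @param core `core_topology`
#' @param n_sites number of charged beads
#' @param site_charge charge per site, e (citrate model: -2)
#' @return the core with charges assigned; charged beads are retagged
#'   `"citrate-site"`
#' @export
assign_surface_charges <- function(core, n_sites = 28, site_charge = -2) {
  stopifnot(inherits(core, "core_topology"))
  n <- nrow(core$beads)
  if (!(n_sites > 0 && n_sites <= n))
    stop("n_sites must be in 1..", n)
  sel <- farthest_point_subset(bead_xyz(core$beads), n_sites)
  core$beads$charge <- 0
  core$beads$charge[sel] <- site_charge
  core$beads$residue_tag[sel] <- "citrate-site"
  core
}

## greedy farthest-point selection, deterministically seeded at bead 1
farthest_point_subset <- function(xyz, k) {
  n <- nrow(xyz)
  k <- as.integer(k)
  if (k >= n) return(seq_len(n))
  sel <- 1L
  ## distance of every point to the selected set
  mind <- sqrt(colSums((t(xyz) - xyz[1, ])^2))
  while (length(sel) < k) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    d <- sqrt(colSums((t(xyz) - xyz[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sort(sel)
}

#' Select peptide graft sites
#'
#' For six sites returns the beads nearest the six cardinal points of the
#' build frame (the +/-x, +/-y, +/-z axis intersections with the sphere),
#' matching the experimentally resolved six-peptide coating geometry. For
#' any other count it falls back to greedy farthest-point spread.
#'
#' @param core `core_topology`
#' @param n_sites number of graft sites
#' @return integer vector of bead indices
#' @export
select_graft_sites <- function(core, n_sites = 6) {
  stopifnot(inherits(core, "core_topology"))
  n <- nrow(core$beads)
  if (!(n_sites >= 0 && n_sites <= n))
    stop("n_sites must be in 0..", n)
  if (n_sites == 0) return(integer())
  xyz <- bead_xyz(core$beads)
  if (n_sites == 6) {
    r <- core$diameter / 2
    axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * r
    sel <- integer(6)
    for (a in 1:6) {
      d <- sqrt(colSums((t(xyz) - axes[a, ])^2))
      d[sel[seq_len(a - 1)]] <- Inf   # keep sites distinct
      sel[a] <- which.min(d)
    }
    return(sel)
  }
  if (n_sites == 1) {
    ## convention: the bead nearest +z
    return(which.max(xyz[, 3]))
  }
  farthest_point_subset(xyz, n_sites)[seq_len(n_sites)]
}

#' Build an elastic network over backbone beads
#'
#' A harmonic bond for every unordered bead pair whose build-time
#' distance lies in `[r_min, r_max]`; the standard Martini device for
#' holding a mapped peptide's secondary structure rigid.
#'
#' @param positions n x 3 matrix of backbone positions, nm
#' @param k force constant, kJ mol^-1 nm^-2
#' @param r_min,r_max distance band, nm
#' @return bond data frame (`i`, `j`, `k_b`, `r0`)
#' @export
build_elastic_network <- function(positions, k = 500, r_min = 0.5,
                                  r_max = 0.9) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, r_min < r_max, k > 0)
  n <- nrow(positions)
  if (n < 2) return(empty_bond_table())
  D <- pairwise_dist(positions)
  idx <- which(upper.tri(D) & D >= r_min & D <= r_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_bond_table())
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
             k_b = k, r0 = D[idx])
}

#' Eccentricity of a bead cloud
#'
#' Deviation from spherical symmetry computed from the principal moments
#' of inertia of unit-mass beads: `e = 1 - I_min / I_avg`, zero for a
#' perfectly spherical shell and approaching one for a line.
#'
#' @param positions n x 3 matrix of positions
#' @return dimensionless eccentricity in `[0, 1)`
#' @export
compute_eccentricity <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 4) stop("need at least 4 points")
  x <- sweep(positions, 2, colMeans(positions))
  r2 <- rowSums(x^2)
  if (all(r2 < 1e-18)) stop("degenerate point set: all points coincide")
  ## inertia tensor of unit masses
  I <- diag(3) * sum(r2) - t(x) %*% x
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (mean(ev) < 1e-15) stop("degenerate point set")
  1 - min(ev) / mean(ev)
}

#' Graft peptides onto a nanoparticle core
#'
#' Places one rigid-body copy of the peptide model per graft site. The
#' peptide's C-terminal linker bead is set radially outward from its site
#' bead at the graft bond length, the helix axis points radially outward,
#' and a harmonic bond joins linker to site. The azimuthal orientation of
#' each copy is deterministic (fixed by the rotation taking the build
#' axis onto the site radial).
#'
#' @param core `core_topology` with bonds built
#' @param peptide `peptide_model` (see [synthetic_gh_model()])
#' @param sites integer bead indices from [select_graft_sites()]
#' @param graft_k graft bond force constant, kJ mol^-1 nm^-2 (defaults to
#'   the core bond constant)
#' @param graft_r0 graft bond length, nm; default is the nearest
#'   inter-bead spacing of the core shell
#' @param clash_distance minimum allowed distance between any peptide
#'   bead (other than the bonded linker) and any core bead, nm
#' @return object of class `assembled_np` with fields `core`, `peptides`
#'   (list of placed bead tables), `graft_bonds`
#' @export
graft_peptides <- function(core, peptide, sites, graft_k = 2250,
                           graft_r0 = NULL, clash_distance = 0.3) {
  stopifnot(inherits(core, "core_topology"),
            inherits(peptide, "peptide_model"))
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("graft sites must be distinct")
  core$graft_sites <- sites
  if (is.null(graft_r0)) {
    graft_r0 <- if (nrow(core$bonds)) min(core$bonds$r0) else 0.3
  }
  core_xyz <- bead_xyz(core$beads)
  peptides <- list()
  graft_bonds <- empty_bond_table()
  ## bead-index offset of the next peptide copy in the flattened topology
  offset <- nrow(core$beads)
  for (s in sites) {
    u <- unit(core_xyz[s, ])
    R <- rotation_between(c(0, 0, 1), u)
    pxyz <- bead_xyz(peptide$beads) %*% t(R)
    ## canonical model has its linker bead at the origin with the helix
    ## running along +z; translate the linker to the graft point
    anchor_pos <- core_xyz[s, ] + graft_r0 * u
    linker <- peptide$anchors[["linker"]]
    pxyz <- sweep(pxyz, 2, anchor_pos - pxyz[linker, ], FUN = "+")
    ## steric check against every core bead except the bonded site
    dmin <- Inf
    for (b in seq_len(nrow(pxyz))) {
      d <- sqrt(colSums((t(core_xyz) - pxyz[b, ])^2))
      if (b == linker) d[s] <- Inf
      dmin <- min(dmin, min(d))
    }
    if (dmin < clash_distance)
      stop(sprintf(
        "steric clash at site %d: peptide bead %.3f nm from core (< %.3f)",
        s, dmin, clash_distance))
    placed <- peptide$beads
    placed$x <- pxyz[, 1]; placed$y <- pxyz[, 2]; placed$z <- pxyz[, 3]
    peptides[[length(peptides) + 1]] <- placed
    ## graft bond indices refer to the flattened topology
    graft_bonds <- rbind(graft_bonds,
                         data.frame(i = s, j = offset + linker,
                                    k_b = graft_k, r0 = graft_r0))
    offset <- offset + nrow(placed)
  }
  structure(list(core = core, peptides = peptides,
                 peptide_bonds = peptide$bonds,
                 graft_bonds = graft_bonds),
            class = "assembled_np")
}

## all bonds of a topology with indices in the flattened bead table
flatten_bonds <- function(x) {
  if (inherits(x, "core_topology")) return(x$bonds)
  stopifnot(inherits(x, "assembled_np"))
  out <- list(x$core$bonds)
  offset <- nrow(x$core$beads)
  for (p in x$peptides) {
    b <- x$peptide_bonds
    if (nrow(b)) {
      b$i <- b$i + offset
      b$j <- b$j + offset
      out[[length(out) + 1]] <- b
    }
    offset <- offset + nrow(p)
  }
  out[[length(out) + 1]] <- x$graft_bonds
  do.call(rbind, out)
}

#' @export
print.assembled_np <- function(x, ...) {
  cat(sprintf("assembled_np: %d core beads + %d peptides, total charge %+g e\n",
              nrow(x$core$beads), length(x$peptides), total_charge(x)))
  invisible(x)
}

#' Total charge of a topology
#'
#' @param x `core_topology` or `assembled_np`
#' @return total charge, e
#' @export
total_charge <- function(x) {
  if (inherits(x, "core_topology")) return(sum(x$beads$charge))
  if (inherits(x, "assembled_np"))
    return(sum(x$core$beads$charge) +
             sum(vapply(x$peptides, function(p) sum(p$charge), numeric(1))))
  stop("unsupported topology class")
}

## flatten an assembled NP (or bare core) into one bead table, reindexed
flatten_topology <- function(x) {
  if (inherits(x, "core_topology")) return(x$beads)
  stopifnot(inherits(x, "assembled_np"))
  core_beads <- x$core$beads
  core_beads$role <- "core"
  tabs <- c(list(core_beads), x$peptides)
  out <- do.call(rbind, tabs)
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
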