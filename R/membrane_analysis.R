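# Trajectory metrics for bilayer / nanocarrier systems: radial
# distribution functions, acyl order parameters, gridded thickness
# maps, Voronoi area per lipid, transversal density, the
# centre-of-mass separation collective variable, and binding-event
# detection. All distances use the minimum-image convention in the
# orthorhombic box; lateral maps use a 50 x 50 grid by default.

#' Assign leaflets from the phosphate median
#'
#' Per-frame leaflet assignment: a head-group bead (phosphate or sterol
#' head) belongs to the upper leaflet when its z exceeds the median z
#' of the frame's phosphate beads. Existing `leaflet` hints are
#' ignored; the generator's hints and this rule agree on all synthetic
#' bilayers by construction.
#'
#' @param frame a single frame
#' @return character vector, `"upper"`/`"lower"` for head-group beads,
#'   `NA` otherwise
#' @export
assign_leaflets <- function(frame) {
  b <- frame$beads
  ph <- b$role == "phosphate"
  if (!any(ph)) stop("no phosphate beads in frame")
  zmid <- stats::median(b$z[ph])
  out <- rep(NA_character_, nrow(b))
  heads <- ph | b$role == "sterol-head"
  out[heads] <- ifelse(b$z[heads] > zmid, "upper", "lower")
  out
}

#' Radial distribution function
#'
#' g(r) of selection A with respect to selection B: a histogram of
#' minimum-image pair distances normalised by the spherical shell
#' volume and the mean B density, so an ideal gas gives g = 1. No
#' anisotropy correction is applied near a membrane, matching common
#' practice for first-shell structure around bilayers.
#'
#' @param frames `frame_set`
#' @param selection_A,selection_B `bead_selection`s
#' @param bin_width histogram bin width, nm
#' @param r_max maximum distance, nm; must not exceed half the smallest
#'   box length (default: exactly that bound)
#' @return object of class `rdf_curve`: data frame with `r` (bin
#'   centres), `g`, `count`
#' @export
radial_distribution <- function(frames, selection_A, selection_B,
                                bin_width = 0.05, r_max = NULL) {
  stopifnot(inherits(frames, "frame_set"))
  box1 <- frames$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box1) / 2
  if (r_max > min(box1) / 2 + 1e-9)
    stop("r_max exceeds half the minimal box length")
  n_bins <- floor(r_max / bin_width + 1e-9)
  edges <- (0:n_bins) * bin_width
  acc <- numeric(n_bins)
  counts <- numeric(n_bins)
  nf <- n_frames(frames)
  for (fr in frames$frames) {
    ia <- select_beads(fr, selection_A)
    ib <- select_beads(fr, selection_B)
    if (!length(ia) || !length(ib))
      stop("empty selection in radial_distribution")
    xyz <- as.matrix(fr$beads[, c("x", "y", "z")])
    V <- prod(fr$box)
    d2 <- matrix(0, length(ia), length(ib))
    for (k in 1:3)
      d2 <- d2 + min_image(outer(xyz[ia, k], xyz[ib, k], "-"),
                           fr$box[k])^2
    d <- sqrt(d2)
    ## drop self-pairs where the two selections share beads
    self <- outer(ia, ib, "==")
    d <- d[!self]
    n_pairs_per_a <- length(ib) - any(self)   # B partners available per A
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)$counts
    counts <- counts + h
    rho_b <- n_pairs_per_a / V
    acc <- acc + h / (length(ia) * rho_b)
  }
  vshell <- 4 / 3 * pi * diff(edges^3)
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                    g = acc / (nf * vshell), count = counts)
  class(out) <- c("rdf_curve", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Acyl-chain order parameter
#'
#' Second-Legendre order parameter
#' `P2 = <(3 cos^2 w - 1) / 2>` where `w` is the angle between the z
#' axis and the vector joining bead i-1 to bead i+1 of a chain; the
#' ensemble averages over time, molecules and beads. Values range from
#' 1 (chain parallel to the normal) through 0 (isotropic) to -0.5
#' (chain in the membrane plane).
#'
#' @param frames `frame_set`
#' @param selection chain beads (default: role `"tail"`); beads of one
#'   molecule are taken in their stored order as one chain
#' @param grid optional lateral grid size; if given, a [grid_map()] of
#'   per-lipid P2 (averaged over the molecule's beads) binned by the
#'   molecule's first-bead lateral position is attached
#' @return object of class `order_field`: list with `mean`,
#'   `per_position` (P2 by position along the chain), `values`
#'   (per-molecule per-frame means) and optional `map`
#' @export
order_parameter <- function(frames, selection = bead_selection(role = "tail"),
                            grid = NULL) {
  stopifnot(inherits(frames, "frame_set"))
  all_p2 <- list()     # per chain bead position
  mol_vals <- numeric() # per molecule-frame mean
  mol_xy <- NULL
  for (fr in frames$frames) {
    idx <- select_beads(fr, selection)
    if (!length(idx)) stop("empty selection in order_parameter")
    b <- fr$beads[idx, ]
    for (m in unique(b$molecule)) {
      chain <- b[b$molecule == m, ]
      n <- nrow(chain)
      if (n < 3)
        stop("chain of molecule ", m, " has fewer than 3 beads")
      v <- as.matrix(chain[3:n, c("x", "y", "z")]) -
        as.matrix(chain[1:(n - 2), c("x", "y", "z")])
      cosw <- v[, 3] / sqrt(rowSums(v^2))
      p2 <- (3 * cosw^2 - 1) / 2
      for (k in seq_along(p2)) {
        pos <- as.character(k + 1)   # bead index along the chain
        all_p2[[pos]] <- c(all_p2[[pos]], p2[k])
      }
      mol_vals <- c(mol_vals, mean(p2))
      mol_xy <- rbind(mol_xy, c(chain$x[1], chain$y[1]))
    }
  }
  out <- list(mean = mean(unlist(all_p2)),
              per_position = vapply(all_p2, mean, numeric(1)),
              values = mol_vals)
  if (!is.null(grid)) {
    box <- frames$frames[[1]]$box
    out$map <- grid_map(mol_xy[, 1], mol_xy[, 2], mol_vals,
                        nx = grid, ny = grid, box = box[1:2])
  }
  class(out) <- "order_field"
  out
}

#' @export
print.order_field <- function(x, ...) {
  cat(sprintf("order_field: mean P2 = %.4f over %d chain samples\n",
              x$mean, length(x$values)))
  invisible(x)
}

#' Lateral grid map
#'
#' Bins scattered lateral samples onto an `nx` x `ny` grid of cell
#' means. Cells with no samples hold `NA` (flagged, never
#' zero-filled or interpolated).
#'
#' @param x,y lateral coordinates, nm (wrapped into the box)
#' @param value sample values
#' @param nx,ny grid size
#' @param box lateral box lengths, nm
#' @return object of class `grid_map`: list with `values` and `counts`
#'   matrices and the box footprint
#' @export
grid_map <- function(x, y, value, nx = 50, ny = 50, box) {
  ix <- pmin(nx, pmax(1, floor((x %% box[1]) / box[1] * nx) + 1))
  iy <- pmin(ny, pmax(1, floor((y %% box[2]) / box[2] * ny) + 1))
  values <- matrix(NA_real_, nx, ny)
  counts <- matrix(0L, nx, ny)
  sums <- matrix(0, nx, ny)
  for (k in seq_along(value)) {
    sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + value[k]
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  }
  occ <- counts > 0
  values[occ] <- sums[occ] / counts[occ]
  structure(list(values = values, counts = counts, nx = nx, ny = ny,
                 box = box), class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map: %d x %d cells, %d empty, mean %.4f\n",
              x$nx, x$ny, sum(x$counts == 0),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Membrane thickness map
#'
#' Per grid point, the height of each leaflet surface is the mean z of
#' the three laterally nearest phosphate beads of that leaflet
#' (minimum-image lateral distances); thickness is the upper minus the
#' lower surface, averaged over frames.
#'
#' @param frames `frame_set`
#' @param grid grid size per side (default 50)
#' @return `grid_map` of thickness, nm
#' @export
thickness_map <- function(frames, grid = 50) {
  stopifnot(inherits(frames, "frame_set"))
  box <- frames$frames[[1]]$box
  gx <- (seq_len(grid) - 0.5) * box[1] / grid
  gy <- (seq_len(grid) - 0.5) * box[2] / grid
  gpts <- as.matrix(expand.grid(x = gx, y = gy))
  acc <- matrix(0, grid, grid)
  for (fr in frames$frames) {
    leaf <- assign_leaflets(fr)
    b <- fr$beads
    surf <- list()
    for (side in c("upper", "lower")) {
      sel <- which(b$role == "phosphate" & !is.na(leaf) & leaf == side)
      if (length(sel) < 3)
        stop("leaflet '", side, "' has fewer than 3 phosphate beads")
      dx <- min_image(outer(gpts[, 1], b$x[sel], "-"), box[1])
      dy <- min_image(outer(gpts[, 2], b$y[sel], "-"), box[2])
      d2 <- dx^2 + dy^2
      ## mean z of the 3 laterally nearest phosphates per grid point
      zsel <- b$z[sel]
      surf[[side]] <- apply(d2, 1, function(row)
        mean(zsel[order(row)[1:3]]))
    }
    acc <- acc + matrix(surf$upper - surf$lower, grid, grid)
  }
  structure(list(values = acc / n_frames(frames),
                 counts = matrix(n_frames(frames), grid, grid),
                 nx = grid, ny = grid, box = box[1:2]),
            class = "grid_map")
}

#' Voronoi area per lipid
#'
#' Per frame, a two-dimensional Voronoi tessellation of the x-y
#' coordinates of upper-leaflet phosphate beads, upper-leaflet sterol
#' head beads, and nanocarrier beads lying on the bilayer surface (z
#' between the frame's lowest and highest phosphate). Carrier beads
#' participate in the tessellation — so their footprint carves area out
#' of neighbouring lipids — but are excluded from the reported
#' averages. Lateral periodicity is handled by 8-neighbour ghost
#' replication, so the real cells tile the box exactly.
#'
#' @param frames `frame_set`
#' @param carrier_roles bead roles treated as nanocarrier
#' @return object of class `apl_result`: list with per-frame lipid
#'   `areas` (nm^2), overall `mean` and `sd`, `n_carrier` beads used,
#'   and `total_area` (sum of all real cells, per frame)
#' @export
area_per_lipid <- function(frames,
                           carrier_roles = c("core", "peptide-backbone",
                                             "peptide-side")) {
  stopifnot(inherits(frames, "frame_set"))
  areas <- list()
  total <- numeric()
  n_carrier <- 0L
  for (fr in frames$frames) {
    b <- fr$beads
    leaf <- assign_leaflets(fr)
    ph <- b$role == "phosphate"
    lipid_idx <- which((ph | b$role == "sterol-head") &
                         !is.na(leaf) & leaf == "upper")
    z_lo <- min(b$z[ph]); z_hi <- max(b$z[ph])
    car_idx <- which(b$role %in% carrier_roles &
                       b$z >= z_lo & b$z <= z_hi)
    gen <- c(lipid_idx, car_idx)
    if (length(gen) < 3) stop("fewer than 3 tessellation points")
    n_carrier <- n_carrier + length(car_idx)
    lx <- fr$box[1]; ly <- fr$box[2]
    x <- b$x[gen] %% lx
    y <- b$y[gen] %% ly
    ## 8-neighbour ghost replication for lateral periodicity
    sh <- as.matrix(expand.grid(dx = c(-1, 0, 1), dy = c(-1, 0, 1)))
    gx <- as.vector(outer(rep(1, length(x)), sh[, 1] * lx) + x)
    gy <- as.vector(outer(rep(1, length(y)), sh[, 2] * ly) + y)
    ## real points are the dx = dy = 0 replica (sh row 5)
    real <- seq_along(x) + (5 - 1) * length(x)
    dd <- deldir::deldir(gx, gy,
                         rw = c(-lx, 2 * lx, -ly, 2 * ly),
                         suppressMsge = TRUE)
    cell_area <- numeric(length(gx))
    kept <- if (!is.null(dd$ind.orig)) dd$ind.orig
            else seq_len(nrow(dd$summary))
    cell_area[kept] <- dd$summary$dir.area
    real_areas <- cell_area[real]
    is_lipid <- seq_along(gen) <= length(lipid_idx)
    areas[[length(areas) + 1]] <- real_areas[is_lipid]
    total <- c(total, sum(real_areas))
  }
  all_areas <- unlist(areas)
  structure(list(areas = areas, mean = mean(all_areas),
                 sd = stats::sd(all_areas), n_carrier = n_carrier,
                 total_area = total,
                 box_area = frames$frames[[1]]$box[1] *
                   frames$frames[[1]]$box[2]),
            class = "apl_result")
}

#' @export
print.apl_result <- function(x, ...) {
  cat(sprintf("apl_result: %.4f +/- %.4f nm^2 per lipid (%d carrier beads)\n",
              x$mean, x$sd, x$n_carrier))
  invisible(x)
}

#' Transversal density profile
#'
#' Histogram of selected bead z positions relative to the bilayer
#' midplane (the per-frame mean phosphate z), averaged over frames.
#' The profile integrates to the mean selected bead count per frame.
#'
#' @param frames `frame_set`
#' @param selection `bead_selection` (default: phosphate beads)
#' @param bin_width bin width, nm
#' @return data frame of class `density_profile` with `z` (bin centre,
#'   nm, midplane at 0) and `density` (beads nm^-1)
#' @export
transversal_density <- function(frames,
                                selection = bead_selection(role = "phosphate"),
                                bin_width = 0.1) {
  stopifnot(inherits(frames, "frame_set"))
  rel <- list()
  for (fr in frames$frames) {
    idx <- select_beads(fr, selection)
    if (!length(idx)) stop("empty selection in transversal_density")
    ph <- fr$beads$role == "phosphate"
    mid <- mean(fr$beads$z[ph])
    rel[[length(rel) + 1]] <- fr$beads$z[idx] - mid
  }
  rel <- unlist(rel)
  half <- (floor(max(abs(rel)) / bin_width) + 1) * bin_width
  edges <- seq(-half, half, by = bin_width)
  h <- graphics::hist(rel, breaks = edges, plot = FALSE)$counts
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                    density = h / (n_frames(frames) * bin_width))
  class(out) <- c("density_profile", "data.frame")
  out
}

#' z-component of the centre-of-mass separation
#'
#' The collective variable of the binding free-energy calculations:
#' `z(COM_A) - z(COM_B)` with equal bead masses.
#'
#' @param frame a single frame
#' @param selection_A,selection_B `bead_selection`s (carrier and
#'   bilayer)
#' @return signed separation, nm
#' @export
com_distance_z <- function(frame, selection_A, selection_B) {
  ia <- select_beads(frame, selection_A)
  ib <- select_beads(frame, selection_B)
  if (!length(ia) || !length(ib))
    stop("empty selection in com_distance_z")
  mean(frame$beads$z[ia]) - mean(frame$beads$z[ib])
}

#' Collective-variable trace over a trajectory
#'
#' @param frames `frame_set`
#' @param selection_A,selection_B as in [com_distance_z()]
#' @return numeric vector, one value per frame
#' @export
cv_trace <- function(frames, selection_A, selection_B) {
  vapply(frames$frames, com_distance_z, numeric(1),
         selection_A = selection_A, selection_B = selection_B)
}

#' Detect a binding event on a CV trace
#'
#' The binding frame is the earliest frame that starts a run of at
#' least `dwell` consecutive frames with the collective variable below
#' `threshold`.
#'
#' @param cv per-frame collective-variable values, nm
#' @param threshold binding threshold, nm
#' @param dwell minimum consecutive frames below threshold
#' @return first binding frame index, or `NA_integer_` if none
#' @export
detect_binding <- function(cv, threshold, dwell = 1) {
  stopifnot(dwell >= 1)
  below <- cv < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= dwell)
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[1]])
}
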