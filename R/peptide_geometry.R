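# Orientation observables of a membrane-bound helical peptide: the
# inclination (polar) angle of the helix axis with respect to the
# membrane normal, and the rolling angle of the helix about its own
# axis, both defined on labelled backbone beads.

#' Helix inclination angle
#'
#' Angle between the helix axis — the vector from the Leu627 backbone
#' bead to the Ala639 backbone bead — and the +z membrane normal.
#' With the membrane below the peptide, 0 degrees means the N-terminus
#' points at the membrane and 180 degrees the C-terminus; 90 degrees is
#' a helix lying flat on the bilayer.
#'
#' @param frame a single frame
#' @param leu627,ala639 backbone bead row indices (default: looked up
#'   from residue labels via [gh_anchors()])
#' @return inclination, degrees in `[0, 180]`
#' @export
theta_inc <- function(frame, leu627 = NULL, ala639 = NULL) {
  if (is.null(leu627) || is.null(ala639)) {
    a <- gh_anchors(frame)
    leu627 <- a[["leu627"]]; ala639 <- a[["ala639"]]
  }
  b <- frame$beads
  v <- c(b$x[ala639] - b$x[leu627], b$y[ala639] - b$y[leu627],
         b$z[ala639] - b$z[leu627])
  n <- vnorm(v)
  if (n < 1e-9) stop("zero-length helix axis")
  rad2deg(acos(pmin(1, pmax(-1, v[3] / n))))
}

#' Helix rolling angle
#'
#' Torsion angle between the plane spanned by the z axis and
#' v1 = Trp634 -> Thr630, and the plane spanned by v1 and
#' v2 = Thr630 -> Thr632, computed with the numerically stable atan2
#' torsion formulation and mapped to `[0, 360)`. With this convention a
#' rolling angle near 90 degrees points the Trp634 side chain at the
#' bilayer interior below the peptide.
#'
#' @param frame a single frame
#' @param trp634,thr630,thr632 backbone bead row indices (default:
#'   looked up from residue labels)
#' @return rolling angle, degrees in `[0, 360)`
#' @export
phi_roll <- function(frame, trp634 = NULL, thr630 = NULL, thr632 = NULL) {
  if (is.null(trp634) || is.null(thr630) || is.null(thr632)) {
    a <- gh_anchors(frame)
    trp634 <- a[["trp634"]]; thr630 <- a[["thr630"]]
    thr632 <- a[["thr632"]]
  }
  b <- frame$beads
  p <- function(i) c(b$x[i], b$y[i], b$z[i])
  v1 <- p(thr630) - p(trp634)
  v2 <- p(thr632) - p(thr630)
  if (vnorm(cross3(v1, v2)) < 1e-9)
    stop("collinear anchor beads: rolling angle undefined")
  torsion_deg(c(0, 0, 1), v1, v2)
}

#' Orientation angle trace over a trajectory
#'
#' @param frames `frame_set` containing one labelled gH peptide
#' @return data frame of class `angle_trace` with per-frame `theta_inc`
#'   and `phi_roll`, degrees
#' @export
angle_trace <- function(frames) {
  stopifnot(inherits(frames, "frame_set"))
  a <- gh_anchors(frames$frames[[1]])
  out <- data.frame(
    frame = seq_len(n_frames(frames)),
    theta_inc = vapply(frames$frames, theta_inc, numeric(1),
                       leu627 = a[["leu627"]], ala639 = a[["ala639"]]),
    phi_roll = vapply(frames$frames, phi_roll, numeric(1),
                      trp634 = a[["trp634"]], thr630 = a[["thr630"]],
                      thr632 = a[["thr632"]]))
  class(out) <- c("angle_trace", "data.frame")
  out
}

#' Circular summary of an angle distribution
#'
#' Circular mean and circular standard deviation; the appropriate
#' summary for periodic observables such as the rolling angle.
#'
#' @param x angles, degrees
#' @return named numeric vector `mean`, `sd` (degrees)
#' @export
angle_summary <- function(x) {
  c(mean = circ_mean(x), sd = circ_sd(x))
}
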