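# Small vector-geometry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector where a direction is required")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; rotates column vectors by `angle` radians about the
#' (not necessarily unit) axis through the origin.
#'
#' @param axis 3-vector rotation axis
#' @param angle rotation angle, radians
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## rotation taking unit vector a onto unit vector b (deterministic for a = -b)
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    ## pick any axis perpendicular to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit(cross3(a, ref))
    return(rotation_matrix(perp, pi))
  }
  rotation_matrix(cross3(a, b), acos(d))
}

## minimum-image displacement components for an orthorhombic box
min_image <- function(d, box_len) d - box_len * round(d / box_len)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles in degrees
#'
#' @param x angles, degrees
#' @return mean direction in `[0, 360)` degrees
#' @export
circ_mean <- function(x) {
  r <- deg2rad(x)
  m <- rad2deg(atan2(mean(sin(r)), mean(cos(r))))
  (m + 360) %% 360
}

#' Circular standard deviation of angles in degrees
#'
#' Mardia's definition `sqrt(-2 log R)` where `R` is the mean resultant
#' length; for tightly concentrated samples this converges to the linear
#' standard deviation.
#'
#' @param x angles, degrees
#' @return circular standard deviation, degrees
#' @export
circ_sd <- function(x) {
  r <- deg2rad(x)
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rad2deg(sqrt(-2 * log(max(R, .Machine$double.eps))))
}
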