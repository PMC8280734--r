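# Trajectory container: an ordered list of frames of typed, labelled
# bead coordinates in an orthorhombic box, the common currency between
# the synthetic generators and the analysis metrics.

#' Trajectory frame set
#'
#' @param frames list of frames; each frame is a list with `box`
#'   (length-3 box lengths, nm) and `beads` (data frame with `x`, `y`,
#'   `z` in nm, integer `molecule`, character `role`, `residue`, and
#'   optional `leaflet` hint)
#' @param wrapped logical: are coordinates wrapped into the box?
#'   Analyses always use minimum-image distances, so either convention
#'   is valid; the flag is carried for provenance.
#' @return object of class `frame_set`
#' @export
frame_set <- function(frames, wrapped = FALSE) {
  stopifnot(length(frames) >= 1)
  n0 <- nrow(frames[[1]]$beads)
  for (f in frames) {
    stopifnot(length(f$box) == 3, all(f$box > 0),
              is.data.frame(f$beads),
              all(c("x", "y", "z", "molecule", "role", "residue")
                  %in% names(f$beads)))
    if (nrow(f$beads) != n0)
      stop("inconsistent bead count across frames")
  }
  structure(list(frames = frames, wrapped = wrapped), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("frame_set: %d frames, %d beads, box %.2f x %.2f x %.2f nm\n",
              length(x$frames), nrow(f1$beads),
              f1$box[1], f1$box[2], f1$box[3]))
  invisible(x)
}

#' Number of frames
#' @param x `frame_set`
#' @return integer frame count
#' @export
n_frames <- function(x) length(x$frames)

#' Bead selection
#'
#' Declarative bead filter used by every analysis metric. `NULL` fields
#' match everything; character fields match any of the given values.
#'
#' @param role bead roles (e.g. `"phosphate"`, `"tail"`,
#'   `"sterol-head"`, `"core"`, `"peptide-backbone"`)
#' @param residue residue names
#' @param leaflet `"upper"` or `"lower"`
#' @param molecule integer molecule ids
#' @return object of class `bead_selection`
#' @export
bead_selection <- function(role = NULL, residue = NULL, leaflet = NULL,
                           molecule = NULL) {
  structure(list(role = role, residue = residue, leaflet = leaflet,
                 molecule = molecule), class = "bead_selection")
}

#' Row indices of beads matched by a selection
#'
#' @param frame a single frame from a `frame_set`
#' @param selection `bead_selection`
#' @return integer row indices into `frame$beads`
#' @export
select_beads <- function(frame, selection) {
  b <- frame$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(selection$role)) keep <- keep & b$role %in% selection$role
  if (!is.null(selection$residue))
    keep <- keep & b$residue %in% selection$residue
  if (!is.null(selection$leaflet) && "leaflet" %in% names(b))
    keep <- keep & !is.na(b$leaflet) & b$leaflet %in% selection$leaflet
  if (!is.null(selection$molecule))
    keep <- keep & b$molecule %in% selection$molecule
  which(keep)
}
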