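# Gromacs-dialect structure output: fixed-width GRO coordinate files
# (nm) and itp-style topology files with [atoms] charges and [bonds]
# harmonic parameters. The readers exist so written structures
# round-trip through the package at format precision.

#' Write a GRO coordinate file
#'
#' Fixed-column Gromacs format: title, atom count, one
#' `%5d%-5s%5s%5d%8.3f%8.3f%8.3f` line per bead (positions in nm, three
#' decimals), and an orthorhombic box line.
#'
#' @param beads bead data frame with `x`, `y`, `z`, `residue_tag`,
#'   `bead_type`
#' @param path output file
#' @param box length-3 box vector, nm; default is the bead bounding box
#'   plus a 2 nm margin
#' @param title title line
#' @return `path`, invisibly
#' @export
write_gro <- function(beads, path, box = NULL, title = "nanomem structure") {
  n <- nrow(beads)
  if (is.null(box)) {
    ext <- apply(bead_xyz(beads), 2, function(v) diff(range(v)))
    box <- ext + 2
  }
  res_id <- as.integer(factor(beads$residue_tag,
                              levels = unique(beads$residue_tag)))
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            res_id %% 100000L,
            substr(beads$residue_tag, 1, 5),
            substr(beads$bead_type, 1, 5),
            beads$index %% 100000L,
            beads$x, beads$y, beads$z),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  tryCatch(suppressWarnings(writeLines(lines, path)),
           error = function(e) stop("cannot write GRO file '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a GRO coordinate file
#'
#' @param path GRO file written by [write_gro()] or Gromacs
#' @return list with `title`, `beads` (data frame: `index`,
#'   `residue_tag`, `bead_type`, `x`, `y`, `z`) and `box` (length 3, nm)
#' @export
read_gro <- function(path) {
  lines <- tryCatch(suppressWarnings(readLines(path)),
                    error = function(e) stop("cannot read GRO file '", path,
                                             "': ", conditionMessage(e)))
  if (length(lines) < 3) stop("GRO file '", path, "' is truncated")
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < 2 + n + 1)
    stop("GRO file '", path, "' is truncated")
  at <- lines[3:(2 + n)]
  field <- function(from, to) trimws(substr(at, from, to))
  beads <- data.frame(
    index = as.integer(field(16, 20)),
    residue_tag = field(6, 10),
    bead_type = field(11, 15),
    x = as.numeric(field(21, 28)),
    y = as.numeric(field(29, 36)),
    z = as.numeric(field(37, 44)),
    stringsAsFactors = FALSE)
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(title = lines[1], beads = beads, box = box)
}

#' Write an itp-style topology file
#'
#' Emits `[moleculetype]`, `[atoms]` (with per-bead charges) and
#' `[bonds]` (harmonic, funct 1, r0 in nm and k in kJ mol^-1 nm^-2)
#' sections for a core or assembled nanoparticle.
#'
#' @param x `core_topology` or `assembled_np`
#' @param path output file
#' @param name moleculetype name
#' @return `path`, invisibly
#' @export
write_itp <- function(x, path, name = "NP") {
  beads <- flatten_topology(x)
  bonds <- flatten_bonds(x)
  res_id <- as.integer(factor(beads$residue_tag,
                              levels = unique(beads$residue_tag)))
  lines <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  1", name),
    "",
    "[ atoms ]",
    ";  nr  type  resnr  residue  atom  cgnr  charge",
    sprintf("%6d %5s %6d %8s %5s %6d %10.4f",
            beads$index, beads$bead_type, res_id, beads$residue_tag,
            beads$bead_type, beads$index, beads$charge))
  if (nrow(bonds)) {
    lines <- c(lines, "", "[ bonds ]", ";   i    j  funct      r0          k",
               sprintf("%6d %6d %5d %10.5f %12.2f",
                       bonds$i, bonds$j, 1L, bonds$r0, bonds$k_b))
  }
  tryCatch(suppressWarnings(writeLines(lines, path)),
           error = function(e) stop("cannot write topology file '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' Read an itp-style topology file
#'
#' @param path itp file written by [write_itp()]
#' @return list with `atoms` (data frame: `index`, `bead_type`,
#'   `residue_tag`, `charge`) and `bonds` (`i`, `j`, `r0`, `k_b`)
#' @export
read_itp <- function(path) {
  lines <- tryCatch(suppressWarnings(readLines(path)),
                    error = function(e) stop("cannot read topology file '",
                                             path, "': ",
                                             conditionMessage(e)))
  lines <- sub(";.*", "", lines)
  lines <- trimws(lines)
  section <- ""
  atoms <- list(); bonds <- list()
  for (ln in lines) {
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (section == "atoms") {
      atoms[[length(atoms) + 1]] <- data.frame(
        index = as.integer(f[1]), bead_type = f[2], residue_tag = f[4],
        charge = as.numeric(f[7]), stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      bonds[[length(bonds) + 1]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        r0 = as.numeric(f[4]), k_b = as.numeric(f[5]))
    }
  }
  list(atoms = if (length(atoms)) do.call(rbind, atoms) else NULL,
       bonds = if (length(bonds)) do.call(rbind, bonds)
               else empty_bond_table())
}

#' Write coordinate and topology files for a built nanoparticle
#'
#' @param x `core_topology` or `assembled_np`
#' @param gro_path coordinate file path
#' @param itp_path topology file path
#' @param name moleculetype name
#' @return named character vector of the two paths, invisibly
#' @export
write_structure <- function(x, gro_path, itp_path, name = "NP") {
  beads <- flatten_topology(x)
  write_gro(beads, gro_path, title = sprintf("%s (%d beads)", name,
                                             nrow(beads)))
  write_itp(x, itp_path, name = name)
  invisible(c(gro = gro_path, itp = itp_path))
}
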