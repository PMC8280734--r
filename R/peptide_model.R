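# Synthetic coarse-grained model of the membranotropic gH(625-644)
# peptide. The real model is a Martini mapping of the NMR structure of
# glycoprotein H residues 625-644 plus a C-terminal glycine linker; the
# mapping itself is outside this package, so a geometrically ideal
# alpha-helical stand-in with the same residue labels, anchor beads and
# net charge is constructed in code and used wherever a peptide bead
# model is required.

GH_SEQUENCE <- c(
  "625" = "HIS", "626" = "GLY", "627" = "LEU", "628" = "ALA",
  "629" = "SER", "630" = "THR", "631" = "LEU", "632" = "THR",
  "633" = "ARG", "634" = "TRP", "635" = "ALA", "636" = "HIS",
  "637" = "TYR", "638" = "ASN", "639" = "ALA", "640" = "LEU",
  "641" = "ILE", "642" = "ARG", "643" = "ALA", "644" = "PHE")

## residues represented with a single side-chain bead (Gly/Ala have none)
HAS_SIDE_BEAD <- c("HIS", "LEU", "SER", "THR", "ARG", "TRP", "TYR",
                   "ASN", "ILE", "PHE")

## azimuthal offset of side-chain beads from the radial direction,
## degrees; calibrated once so that a rolling angle of 90 degrees
## points the Trp634 side chain straight at the membrane normal
SC_AZIMUTH_OFFSET <- -69.5

#' Ideal coarse-grained alpha-helix backbone
#'
#' One backbone bead per residue on an ideal helix along +z:
#' 0.15 nm rise and 100 degrees of twist per residue on a 0.23 nm
#' radius, the canonical alpha-helical geometry at one-bead-per-residue
#' resolution.
#'
#' @param n_res number of residues
#' @param rise rise per residue, nm
#' @param radius helix radius, nm
#' @param twist twist per residue, degrees
#' @return n_res x 3 matrix of backbone positions
#' @export
ideal_helix_backbone <- function(n_res, rise = 0.15, radius = 0.23,
                                 twist = 100) {
  k <- seq_len(n_res) - 1
  ang <- deg2rad(twist) * k
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = rise * k)
}

#' Peptide bead model
#'
#' Container for a coarse-grained peptide: bead table with
#' backbone/side-chain roles, bond list, named backbone anchor indices
#' and net charge. In the canonical build frame the C-terminal linker
#' bead sits at the origin and the helix axis runs along +z toward the
#' N-terminus, the orientation assumed by [graft_peptides()].
#'
#' @param beads bead data frame (columns as in [core_topology()] plus
#'   `role`)
#' @param bonds bond data frame
#' @param anchors named integer vector with at least `leu627`, `thr630`,
#'   `thr632`, `trp634`, `ala639`, `linker`
#' @return object of class `peptide_model`
#' @export
peptide_model <- function(beads, bonds, anchors) {
  need <- c("leu627", "thr630", "thr632", "trp634", "ala639", "linker")
  if (!all(need %in% names(anchors)))
    stop("missing anchors: ", paste(setdiff(need, names(anchors)),
                                    collapse = ", "))
  if (anyDuplicated(anchors[need])) stop("anchor beads must be distinct")
  structure(list(beads = beads, bonds = bonds,
                 anchors = anchors[need],
                 net_charge = sum(beads$charge)),
            class = "peptide_model")
}

#' @export
print.peptide_model <- function(x, ...) {
  cat(sprintf("peptide_model: %d beads, %d bonds, net charge %+g e\n",
              nrow(x$beads), nrow(x$bonds), x$net_charge))
  invisible(x)
}

#' Synthetic gH(625-644) coarse-grained model
#'
#' Builds the peptide as an ideal alpha helix with one backbone bead per
#' residue, single side-chain beads for residues larger than Ala/Gly,
#' and a neutral C-terminal glycine linker used for conjugation to the
#' nanoparticle. Charges follow the amphipathic, cationic character of
#' the peptide: +1 on each arginine side chain (Arg633, Arg642), +1 on
#' each protonated histidine side chain (His625, His636) and +1 on the
#' free N-terminus, for a net charge of +5 e per peptide. Backbone
#' bonds, backbone-side bonds and an elastic network
#' (k = 500 kJ mol^-1 nm^-2 over backbone pairs 0.5-0.9 nm apart) hold
#' the helix rigid.
#'
#' @param n_linker number of glycine linker residues appended at the
#'   C-terminus (the last one is the graft anchor bead)
#' @param elastic_k,elastic_rmin,elastic_rmax elastic network parameters
#' @return `peptide_model` in the canonical build frame (linker bead at
#'   the origin, helix axis +z)
#' @export
synthetic_gh_model <- function(n_linker = 3, elastic_k = 500,
                               elastic_rmin = 0.5, elastic_rmax = 0.9) {
  res_names <- c(GH_SEQUENCE, rep("GLY", n_linker))
  res_ids <- c(as.integer(names(GH_SEQUENCE)), 644 + seq_len(n_linker))
  n_res <- length(res_names)
  bb <- ideal_helix_backbone(n_res)
  ## canonical frame: C-terminal linker lowest, N-terminus up (+z);
  ## rotate pi about x (not a z-mirror, which would flip handedness)
  bb <- cbind(bb[, 1], -bb[, 2], -bb[, 3])
  bb[, 3] <- bb[, 3] - min(bb[, 3])

  rows <- list()
  bb_index <- integer(n_res)
  idx <- 0L
  for (r in seq_len(n_res)) {
    idx <- idx + 1L
    bb_index[r] <- idx
    q_bb <- if (r == 1) 1 else 0   # charged free N-terminus
    rows[[length(rows) + 1]] <- data.frame(
      index = idx, x = bb[r, 1], y = bb[r, 2], z = bb[r, 3],
      bead_type = "BB", charge = q_bb,
      residue_tag = sprintf("%s%d", res_names[r], res_ids[r]),
      role = "backbone", stringsAsFactors = FALSE)
    if (res_names[r] %in% HAS_SIDE_BEAD && r <= length(GH_SEQUENCE)) {
      idx <- idx + 1L
      ## side bead outward from the helix axis, at a fixed azimuthal
      ## offset from radial chosen so the model reproduces the
      ## force-field property that a rolling angle of ~90 degrees
      ## points the Trp634 side chain at the membrane below
      radial <- unit(c(bb[r, 1], bb[r, 2], 0))
      psi <- deg2rad(SC_AZIMUTH_OFFSET)
      sc_dir <- c(cos(psi) * radial[1] - sin(psi) * radial[2],
                  sin(psi) * radial[1] + cos(psi) * radial[2], 0)
      sc <- bb[r, ] + 0.25 * sc_dir
      q_sc <- if (res_names[r] %in% c("ARG", "HIS")) 1 else 0
      rows[[length(rows) + 1]] <- data.frame(
        index = idx, x = sc[1], y = sc[2], z = sc[3],
        bead_type = "SC1", charge = q_sc,
        residue_tag = sprintf("%s%d", res_names[r], res_ids[r]),
        role = "side", stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, rows)
  xyz <- bead_xyz(beads)

  ## bonds: backbone chain, backbone-side, elastic network on backbone
  bonds <- empty_bond_table()
  for (r in seq_len(n_res - 1)) {
    i <- bb_index[r]; j <- bb_index[r + 1]
    bonds <- rbind(bonds, data.frame(
      i = i, j = j, k_b = 1250, r0 = vnorm(xyz[j, ] - xyz[i, ])))
  }
  side_rows <- which(beads$role == "side")
  for (s in side_rows) {
    b <- bb_index[match(beads$residue_tag[s],
                        beads$residue_tag[beads$role == "backbone"])]
    bonds <- rbind(bonds, data.frame(
      i = b, j = s, k_b = 1250, r0 = vnorm(xyz[s, ] - xyz[b, ])))
  }
  en <- build_elastic_network(xyz[bb_index, ], k = elastic_k,
                              r_min = elastic_rmin, r_max = elastic_rmax)
  if (nrow(en)) {
    en$i <- bb_index[en$i]
    en$j <- bb_index[en$j]
    ## drop elastic bonds duplicating chain bonds
    key <- paste(pmin(en$i, en$j), pmax(en$i, en$j))
    have <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bonds <- rbind(bonds, en[!(key %in% have), ])
  }

  ## translate canonical frame: linker backbone bead at the origin
  linker <- bb_index[n_res]
  shift <- xyz[linker, ]
  beads$x <- beads$x - shift[1]
  beads$y <- beads$y - shift[2]
  beads$z <- beads$z - shift[3]

  anchors <- c(leu627 = bb_index[res_ids == 627 & res_names == "LEU"],
               thr630 = bb_index[res_ids == 630],
               thr632 = bb_index[res_ids == 632],
               trp634 = bb_index[res_ids == 634],
               ala639 = bb_index[res_ids == 639],
               linker = linker)
  peptide_model(beads, bonds, anchors)
}
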