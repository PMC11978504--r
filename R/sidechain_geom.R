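# Ideal sidechain geometry: per-residue 14-atom naming, internal-coordinate
# build tables (bond length, bond angle, dihedral source), NeRF placement
# driven by chi angles, and chi measurement from coordinates.
#
# Dihedral sources: list(chi = k) places the atom at chi_k; an extra
# `offset` (degrees) places branch atoms relative to chi_k; `fixed` places
# ring atoms at a constant dihedral. Terminal rings are ideal-planar; proline
# ring closure is approximate (the CD-N bond is not re-closed).

.ATOM14 <- list(
  ALA = c("N","CA","C","O","CB"),
  ARG = c("N","CA","C","O","CB","CG","CD","NE","CZ","NH1","NH2"),
  ASN = c("N","CA","C","O","CB","CG","OD1","ND2"),
  ASP = c("N","CA","C","O","CB","CG","OD1","OD2"),
  CYS = c("N","CA","C","O","CB","SG"),
  GLN = c("N","CA","C","O","CB","CG","CD","OE1","NE2"),
  GLU = c("N","CA","C","O","CB","CG","CD","OE1","OE2"),
  GLY = c("N","CA","C","O"),
  HIS = c("N","CA","C","O","CB","CG","ND1","CD2","CE1","NE2"),
  ILE = c("N","CA","C","O","CB","CG1","CG2","CD1"),
  LEU = c("N","CA","C","O","CB","CG","CD1","CD2"),
  LYS = c("N","CA","C","O","CB","CG","CD","CE","NZ"),
  MET = c("N","CA","C","O","CB","CG","SD","CE"),
  PHE = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ"),
  PRO = c("N","CA","C","O","CB","CG","CD"),
  SER = c("N","CA","C","O","CB","OG"),
  THR = c("N","CA","C","O","CB","OG1","CG2"),
  TRP = c("N","CA","C","O","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
  TYR = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
  VAL = c("N","CA","C","O","CB","CG1","CG2"),
  UNK = c("N","CA","C","O","CB"))

# entry: name, refs (a, b, c), bond (A), angle (deg), dih = list(...)
.bld <- function(name, a, b, c, bond, angle, chi = NA, offset = 0, fixed = NA) {
  list(name = name, refs = c(a, b, c), bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

# CB improper: dihedral(C, N, CA, CB) = +122.6 deg places CB on the
# L-amino-acid side; validated against the virtual C-beta construction
.CB <- .bld("CB", "C", "N", "CA", 1.530, 110.4, fixed = 122.6)

.SIDECHAIN_BUILD <- list(
  ALA = list(.CB),
  SER = list(.CB, .bld("OG", "N","CA","CB", 1.417, 110.8, chi = 1)),
  CYS = list(.CB, .bld("SG", "N","CA","CB", 1.808, 113.8, chi = 1)),
  THR = list(.CB, .bld("OG1","N","CA","CB", 1.433, 109.5, chi = 1),
             .bld("CG2","N","CA","CB", 1.521, 110.5, chi = 1, offset = -120)),
  VAL = list(.CB, .bld("CG1","N","CA","CB", 1.527, 110.5, chi = 1),
             .bld("CG2","N","CA","CB", 1.527, 110.5, chi = 1, offset = 122.3)),
  ILE = list(.CB, .bld("CG1","N","CA","CB", 1.530, 110.4, chi = 1),
             .bld("CG2","N","CA","CB", 1.521, 110.5, chi = 1, offset = -122.3),
             .bld("CD1","CA","CB","CG1", 1.513, 113.8, chi = 2)),
  LEU = list(.CB, .bld("CG", "N","CA","CB", 1.530, 116.3, chi = 1),
             .bld("CD1","CA","CB","CG", 1.521, 110.7, chi = 2),
             .bld("CD2","CA","CB","CG", 1.521, 110.7, chi = 2, offset = 122.6)),
  PRO = list(.CB, .bld("CG", "N","CA","CB", 1.495, 104.5, chi = 1),
             .bld("CD", "CA","CB","CG", 1.507, 106.1, chi = 2)),
  MET = list(.CB, .bld("CG", "N","CA","CB", 1.520, 114.1, chi = 1),
             .bld("SD", "CA","CB","CG", 1.803, 112.7, chi = 2),
             .bld("CE", "CB","CG","SD", 1.791, 100.9, chi = 3)),
  ASP = list(.CB, .bld("CG", "N","CA","CB", 1.516, 112.6, chi = 1),
             .bld("OD1","CA","CB","CG", 1.249, 118.4, chi = 2),
             .bld("OD2","CA","CB","CG", 1.249, 118.4, chi = 2, offset = 180)),
  ASN = list(.CB, .bld("CG", "N","CA","CB", 1.516, 112.6, chi = 1),
             .bld("OD1","CA","CB","CG", 1.231, 120.8, chi = 2),
             .bld("ND2","CA","CB","CG", 1.328, 116.4, chi = 2, offset = 180)),
  GLU = list(.CB, .bld("CG", "N","CA","CB", 1.520, 114.1, chi = 1),
             .bld("CD", "CA","CB","CG", 1.516, 112.6, chi = 2),
             .bld("OE1","CB","CG","CD", 1.249, 118.4, chi = 3),
             .bld("OE2","CB","CG","CD", 1.249, 118.4, chi = 3, offset = 180)),
  GLN = list(.CB, .bld("CG", "N","CA","CB", 1.520, 114.1, chi = 1),
             .bld("CD", "CA","CB","CG", 1.516, 112.6, chi = 2),
             .bld("OE1","CB","CG","CD", 1.231, 120.8, chi = 3),
             .bld("NE2","CB","CG","CD", 1.328, 116.4, chi = 3, offset = 180)),
  LYS = list(.CB, .bld("CG", "N","CA","CB", 1.520, 114.1, chi = 1),
             .bld("CD", "CA","CB","CG", 1.520, 111.3, chi = 2),
             .bld("CE", "CB","CG","CD", 1.508, 111.3, chi = 3),
             .bld("NZ", "CG","CD","CE", 1.489, 111.9, chi = 4)),
  ARG = list(.CB, .bld("CG", "N","CA","CB", 1.520, 114.1, chi = 1),
             .bld("CD", "CA","CB","CG", 1.520, 111.3, chi = 2),
             .bld("NE", "CB","CG","CD", 1.461, 112.0, chi = 3),
             .bld("CZ", "CG","CD","NE", 1.329, 124.2, chi = 4),
             .bld("NH1","CD","NE","CZ", 1.326, 120.0, fixed = 0),
             .bld("NH2","CD","NE","CZ", 1.326, 120.0, fixed = 180)),
  HIS = list(.CB, .bld("CG", "N","CA","CB", 1.497, 113.8, chi = 1),
             .bld("ND1","CA","CB","CG", 1.378, 122.7, chi = 2),
             .bld("CD2","CA","CB","CG", 1.356, 129.7, chi = 2, offset = 180),
             .bld("CE1","CB","CG","ND1", 1.320, 109.0, fixed = 180),
             .bld("NE2","CG","ND1","CE1", 1.320, 108.5, fixed = 0)),
  PHE = list(.CB, .bld("CG", "N","CA","CB", 1.502, 113.8, chi = 1),
             .bld("CD1","CA","CB","CG", 1.384, 120.7, chi = 2),
             .bld("CD2","CA","CB","CG", 1.384, 120.7, chi = 2, offset = 180),
             .bld("CE1","CB","CG","CD1", 1.382, 120.7, fixed = 180),
             .bld("CE2","CB","CG","CD2", 1.382, 120.7, fixed = 180),
             .bld("CZ", "CG","CD1","CE1", 1.382, 120.0, fixed = 0)),
  TYR = list(.CB, .bld("CG", "N","CA","CB", 1.512, 113.9, chi = 1),
             .bld("CD1","CA","CB","CG", 1.389, 120.8, chi = 2),
             .bld("CD2","CA","CB","CG", 1.389, 120.8, chi = 2, offset = 180),
             .bld("CE1","CB","CG","CD1", 1.382, 121.1, fixed = 180),
             .bld("CE2","CB","CG","CD2", 1.382, 121.1, fixed = 180),
             .bld("CZ", "CG","CD1","CE1", 1.378, 119.6, fixed = 0),
             .bld("OH", "CD1","CE1","CZ", 1.376, 119.9, fixed = 180)),
  TRP = list(.CB, .bld("CG", "N","CA","CB", 1.498, 113.6, chi = 1),
             .bld("CD1","CA","CB","CG", 1.365, 126.9, chi = 2),
             .bld("CD2","CA","CB","CG", 1.433, 126.7, chi = 2, offset = 180),
             .bld("NE1","CB","CG","CD1", 1.374, 110.2, fixed = 180),
             .bld("CE2","CB","CG","CD2", 1.409, 107.3, fixed = 180),
             .bld("CE3","CB","CG","CD2", 1.398, 133.9, fixed = 0),
             .bld("CZ2","CG","CD2","CE2", 1.394, 122.4, fixed = 180),
             .bld("CZ3","CG","CD2","CE3", 1.382, 118.8, fixed = 180),
             .bld("CH2","CD2","CE2","CZ2", 1.368, 117.5, fixed = 0)))

# chi-defining atom quadruples by residue (names)
.CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")))

#' Per-residue 14-slot atom names
#' @param token integer token (1-21).
#' @return character vector (length <= 14) of atom names.
#' @export
atom14_names <- function(token) {
  .ATOM14[[tokens_to_three(token)]]
}

#' Build sidechain (and backbone-slot) coordinates from chi angles
#'
#' Places atoms sequentially from ideal bond lengths/angles and the supplied
#' chi dihedrals (NeRF); atoms whose governing chi is NA stay NA.
#'
#' @param token integer residue token.
#' @param backbone numeric `[4 x 3]` N, CA, C, O coordinates.
#' @param chis numeric chi angles in radians (length >= [chi_count()] of the
#'   token; NA entries leave dependent atoms unplaced).
#' @return numeric `[14 x 3]` matrix (rownames = atom names, NA rows for
#'   absent slots).
#' @export
chis_to_coords <- function(token, backbone, chis = numeric(0)) {
  three <- tokens_to_three(token)
  names14 <- .ATOM14[[three]]
  out <- matrix(NA_real_, 14, 3)
  rownames(out) <- c(names14, rep("", 14 - length(names14)))
  out[1:4, ] <- backbone
  pos <- list(N = backbone[1, ], CA = backbone[2, ], C = backbone[3, ],
              O = backbone[4, ])
  build <- .SIDECHAIN_BUILD[[three]]
  if (is.null(build)) return(out)    # GLY / UNK beyond CB
  for (b in build) {
    dih <- if (!is.na(b$fixed)) {
      b$fixed * pi / 180
    } else {
      k <- b$chi
      if (k > length(chis) || is.na(chis[k])) next
      chis[k] + b$offset * pi / 180
    }
    refs <- pos[b$refs]
    if (any(vapply(refs, is.null, logical(1)))) next
    p <- place_atom(refs[[1]], refs[[2]], refs[[3]], b$bond,
                    b$angle * pi / 180, dih)
    pos[[b$name]] <- p
    slot <- match(b$name, names14)
    if (!is.na(slot)) out[slot, ] <- p
  }
  out
}

#' Measure chi angles from a 14-slot coordinate matrix
#'
#' @param token integer residue token.
#' @param coords14 numeric `[14 x 3]` in the [atom14_names()] layout.
#' @return numeric length-4 vector of chi angles in radians (NA where the
#'   residue has no such chi or atoms are missing).
#' @export
measure_chis <- function(token, coords14) {
  three <- tokens_to_three(token)
  defs <- .CHI_ATOMS[[three]]
  out <- rep(NA_real_, 4)
  if (is.null(defs)) return(out)
  names14 <- .ATOM14[[three]]
  for (k in seq_along(defs)) {
    idx <- match(defs[[k]], names14)
    if (any(is.na(idx))) next
    pts <- coords14[idx, , drop = FALSE]
    if (any(!is.finite(pts))) next
    out[k] <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  }
  out
}

#' Ideal bond table for a residue's sidechain
#' @param token integer residue token.
#' @return data.frame with columns `atom`, `parent`, `length` (the bond each
#'   placed atom makes with its third reference atom).
#' @export
ideal_bond_table <- function(token) {
  build <- .SIDECHAIN_BUILD[[tokens_to_three(token)]]
  if (is.null(build)) return(data.frame(atom = character(0),
                                        parent = character(0),
                                        length = numeric(0)))
  data.frame(atom = vapply(build, `[[`, "", "name"),
             parent = vapply(build, function(b) b$refs[3], ""),
             length = vapply(build, `[[`, 0, "bond"),
             stringsAsFactors = FALSE)
}
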