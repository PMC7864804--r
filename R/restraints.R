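## Ideal-geometry restraint library for the 20 standard amino acids.
## Connectivity is exact; ideal values are Engh-Huber-style class ideals
## (backbone values are the standard ones; side-chain values come from a
## small bond-class table). The fixture builder draws its internal
## coordinates from this same library, so fixtures score zero geometry
## RMSD by construction.

## Side-chain connectivity (heavy atoms, beyond CB) per residue type.
SIDECHAIN_BONDS <- list(
  ALA = NULL,
  ARG = c("CB-CG", "CG-CD", "CD-NE", "NE-CZ", "CZ-NH1", "CZ-NH2"),
  ASN = c("CB-CG", "CG-OD1", "CG-ND2"),
  ASP = c("CB-CG", "CG-OD1", "CG-OD2"),
  CYS = c("CB-SG"),
  GLN = c("CB-CG", "CG-CD", "CD-OE1", "CD-NE2"),
  GLU = c("CB-CG", "CG-CD", "CD-OE1", "CD-OE2"),
  GLY = NULL,
  HIS = c("CB-CG", "CG-ND1", "ND1-CE1", "CE1-NE2", "NE2-CD2", "CD2-CG"),
  ILE = c("CB-CG1", "CB-CG2", "CG1-CD1"),
  LEU = c("CB-CG", "CG-CD1", "CG-CD2"),
  LYS = c("CB-CG", "CG-CD", "CD-CE", "CE-NZ"),
  MET = c("CB-CG", "CG-SD", "SD-CE"),
  PHE = c("CB-CG", "CG-CD1", "CD1-CE1", "CE1-CZ", "CZ-CE2", "CE2-CD2", "CD2-CG"),
  PRO = c("CB-CG", "CG-CD", "CD-N"),
  SER = c("CB-OG"),
  THR = c("CB-OG1", "CB-CG2"),
  TRP = c("CB-CG", "CG-CD1", "CD1-NE1", "NE1-CE2", "CE2-CD2", "CD2-CG",
          "CE2-CZ2", "CZ2-CH2", "CH2-CZ3", "CZ3-CE3", "CE3-CD2"),
  TYR = c("CB-CG", "CG-CD1", "CD1-CE1", "CE1-CZ", "CZ-CE2", "CE2-CD2",
          "CD2-CG", "CZ-OH"),
  VAL = c("CB-CG1", "CB-CG2")
)

## sp2 (planar, ~120 deg angle) atoms per residue type, beyond backbone C.
SP2_ATOMS <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"), ASP = c("CG", "OD1", "OD2"),
  GLN = c("CD", "OE1", "NE2"), GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TRP = c("CG", "CD1", "NE1", "CE2", "CD2", "CZ2", "CH2", "CZ3", "CE3"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH")
)

## Planar side-chain groups (least-squares-plane restraints).
PLANAR_GROUPS <- list(
  ARG = list(c("CD", "NE", "CZ", "NH1", "NH2")),
  ASN = list(c("CB", "CG", "OD1", "ND2")),
  ASP = list(c("CB", "CG", "OD1", "OD2")),
  GLN = list(c("CG", "CD", "OE1", "NE2")),
  GLU = list(c("CG", "CD", "OE1", "OE2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2", "CZ2", "CH2", "CZ3", "CE3")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH"))
)

AROMATIC_RES <- c("HIS", "PHE", "TRP", "TYR")

bond_class_length <- function(resid, a1, a2, el1, el2) {
  arom <- resid %in% AROMATIC_RES &&
    a1 %in% SP2_ATOMS[[resid]] && a2 %in% SP2_ATOMS[[resid]]
  pair <- paste(sort(c(el1, el2)), collapse = "-")
  if (arom && pair == "C-C") return(1.390)
  if (arom && pair == "C-N") return(1.370)
  sp2 <- !is.null(SP2_ATOMS[[resid]]) &&
    (a1 %in% SP2_ATOMS[[resid]] || a2 %in% SP2_ATOMS[[resid]])
  switch(pair,
    "C-C" = if (sp2) 1.510 else 1.530,
    "C-N" = if (sp2) 1.330 else 1.470,
    "C-O" = if (sp2) 1.250 else 1.420,
    "C-S" = 1.800,
    1.500)
}

atom_element_in_res <- function(name) substr(gsub("^[0-9]", "", name), 1, 1)

#' Ideal-geometry restraint library
#'
#' Bond-length, bond-angle, chirality and planarity targets for the 20
#' standard amino acids, with standard deviations, plus the peptide-link
#' ideals. Backbone ideals: N-CA 1.458, CA-C 1.525, C-O 1.231, C-N 1.329
#' Angstrom; N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8,
#' O-C-N 123.0, N-CA-CB 110.4, CB-CA-C 110.5 degrees; side-chain classes
#' default to 110.5 (sp3) / 120 (sp2) degrees. The L-configuration CA
#' chiral volume (substituent order N, C, CB) is derived from these
#' ideals.
#'
#' @return object of class `em_restraints` with per-residue `$bonds` and
#'   `$angles` tables, `$planar` groups, `$chiral_ca` ideal volume, and
#'   `$link` peptide-bond ideals
#' @export
default_restraints <- function() {
  bb_bonds <- data.frame(
    a1 = c("N", "CA", "C"), a2 = c("CA", "C", "O"),
    ideal = c(1.458, 1.525, 1.231), sigma = c(0.019, 0.021, 0.020))
  bb_angles <- data.frame(
    a1 = c("N", "N", "CB"), a2 = c("CA", "CA", "CA"), a3 = c("C", "CB", "C"),
    ideal = c(111.2, 110.4, 110.5), sigma = c(2.8, 1.5, 1.5))
  res <- list()
  for (rt in names(SIDECHAIN_BONDS)) {
    bonds <- bb_bonds
    if (rt != "GLY")
      bonds <- rbind(bonds, data.frame(a1 = "CA", a2 = "CB",
                                       ideal = 1.530, sigma = 0.020))
    sc <- SIDECHAIN_BONDS[[rt]]
    if (!is.null(sc)) {
      pr <- do.call(rbind, strsplit(sc, "-"))
      scb <- data.frame(a1 = pr[, 1], a2 = pr[, 2], ideal = NA_real_, sigma = 0.025)
      for (i in seq_len(nrow(scb)))
        scb$ideal[i] <- bond_class_length(rt, scb$a1[i], scb$a2[i],
                                          atom_element_in_res(scb$a1[i]),
                                          atom_element_in_res(scb$a2[i]))
      bonds <- rbind(bonds, scb)
    }
    ## derive angles from connectivity: all neighbor pairs at each center
    adj <- list()
    add_edge <- function(adj, u, v) {
      adj[[u]] <- union(adj[[u]], v); adj[[v]] <- union(adj[[v]], u); adj
    }
    for (i in seq_len(nrow(bonds))) adj <- add_edge(adj, bonds$a1[i], bonds$a2[i])
    angles <- bb_angles[if (rt == "GLY") 1 else 1:3, , drop = FALSE]
    sp2 <- SP2_ATOMS[[rt]]
    for (ctr in names(adj)) {
      if (ctr %in% c("N", "CA", "C", "O")) next
      nb <- sort(adj[[ctr]])
      if (length(nb) < 2) next
      cmb <- utils::combn(nb, 2)
      ideal <- if (!is.null(sp2) && ctr %in% sp2) 120 else 110.5
      angles <- rbind(angles, data.frame(
        a1 = cmb[1, ], a2 = ctr, a3 = cmb[2, ],
        ideal = ideal, sigma = if (ideal == 120) 1.2 else 2.0))
    }
    res[[rt]] <- list(bonds = bonds, angles = angles,
                      planar = PLANAR_GROUPS[[rt]], adj = adj)
  }
  ## CB improper torsion dihedral(C,N,CA,CB) consistent with the three
  ## ideal CA bond angles (N-CA-C, N-CA-CB, C-CA-CB), L-configuration,
  ## and the implied ideal CA chiral volume
  a_nc <- deg2rad(111.2); a_nb <- deg2rad(110.4); a_cb <- deg2rad(110.5)
  cb_tor <- -rad2deg(acos(max(-1, min(1,
    (cos(a_cb) - cos(a_nc) * cos(a_nb)) / (sin(a_nc) * sin(a_nb))))))
  n <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 1, 0), n, c(0, 0, 0), 1.525, 111.2, 0)  # any torsion
  ca <- c(0, 0, 0)
  cb <- place_atom(cc, n, ca, 1.530, 110.4, cb_tor)
  vol <- chiral_volume(ca, n, cc, cb)
  structure(list(
    residues = res,
    chiral_ca = list(ideal = vol, sigma = 0.2),
    link = list(bond = c(ideal = 1.329, sigma = 0.014),
                angle_cacn = c(ideal = 116.2, sigma = 2.0),
                angle_cnca = c(ideal = 121.7, sigma = 1.8),
                angle_ocn = c(ideal = 123.0, sigma = 1.6),
                angle_caco = c(ideal = 120.8, sigma = 1.7)),
    cb_torsion = cb_tor
  ), class = "em_restraints")
}

#' @export
print.em_restraints <- function(x, ...) {
  cat(sprintf("em_restraints: %d residue types, CA chiral volume %.3f A^3\n",
              length(x$residues), x$chiral_ca$ideal))
  invisible(x)
}
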