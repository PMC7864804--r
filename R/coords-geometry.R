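#' Restraint RMSDs (bonds, angles, chirality, planarity, dihedrals)
#'
#' Measures deviations of a model's internal coordinates from the ideal
#' values in a restraint library: covalent bond lengths and bond angles
#' (within residues plus the peptide link), the CA chiral volume
#' (substituents N, C, CB), planarity (RMS out-of-plane distance of
#' planar-group atoms from their least-squares plane, for side-chain
#' planar groups and the peptide group CA-C-O-N), and peptide-bond
#' dihedrals (omega deviation from the nearer of trans/cis). Residue
#' types not covered by the library are skipped and counted.
#'
#' @param model an [em_model()]
#' @param lib a restraint library from [default_restraints()]
#' @return list with `bond`, `angle`, `chiral`, `planar`, `dihedral`
#'   RMSDs (Angstrom / degrees / A^3 / Angstrom / degrees), deviation
#'   counts, and `skipped` residue-type count
#' @export
geometry_rmsd <- function(model, lib = default_restraints()) {
  ri <- residue_index(model)
  a <- model$atoms
  dev_bond <- c(); dev_angle <- c(); dev_chiral <- c(); dev_planar <- c()
  dev_dihedral <- c()
  skipped <- 0L
  get <- function(r, nm) atom_xyz(model, r, nm)
  for (i in seq_along(ri)) {
    r <- ri[[i]]
    rt <- a$resid[r[1]]
    tmpl <- lib$residues[[rt]]
    if (is.null(tmpl)) { skipped <- skipped + 1L; next }
    for (j in seq_len(nrow(tmpl$bonds))) {
      p1 <- get(r, tmpl$bonds$a1[j]); p2 <- get(r, tmpl$bonds$a2[j])
      if (is.null(p1) || is.null(p2)) next
      dev_bond <- c(dev_bond, vnorm(p2 - p1) - tmpl$bonds$ideal[j])
    }
    for (j in seq_len(nrow(tmpl$angles))) {
      p1 <- get(r, tmpl$angles$a1[j]); p2 <- get(r, tmpl$angles$a2[j])
      p3 <- get(r, tmpl$angles$a3[j])
      if (is.null(p1) || is.null(p2) || is.null(p3)) next
      dev_angle <- c(dev_angle, bond_angle(p1, p2, p3) - tmpl$angles$ideal[j])
    }
    nn <- get(r, "N"); ca <- get(r, "CA"); cc <- get(r, "C"); cb <- get(r, "CB")
    if (!is.null(nn) && !is.null(ca) && !is.null(cc) && !is.null(cb))
      dev_chiral <- c(dev_chiral,
                      chiral_volume(ca, nn, cc, cb) - lib$chiral_ca$ideal)
    if (!is.null(tmpl$planar))
      for (grp in tmpl$planar) {
        pts <- lapply(grp, function(nm) get(r, nm))
        if (any(vapply(pts, is.null, TRUE))) next
        dev_planar <- c(dev_planar, plane_rms(do.call(rbind, pts)))
      }
    ## peptide link to next residue in the same chain
    if (i < length(ri)) {
      r2 <- ri[[i + 1]]
      if (a$chain[r2[1]] == a$chain[r[1]]) {
        n2 <- get(r2, "N"); ca2 <- get(r2, "CA"); o1 <- get(r, "O")
        if (!is.null(cc) && !is.null(n2) && vnorm(n2 - cc) < 2.5) {
          lk <- lib$link
          dev_bond <- c(dev_bond, vnorm(n2 - cc) - lk$bond["ideal"])
          if (!is.null(ca))
            dev_angle <- c(dev_angle, bond_angle(ca, cc, n2) - lk$angle_cacn["ideal"])
          if (!is.null(ca2))
            dev_angle <- c(dev_angle, bond_angle(cc, n2, ca2) - lk$angle_cnca["ideal"])
          if (!is.null(o1)) {
            dev_angle <- c(dev_angle, bond_angle(o1, cc, n2) - lk$angle_ocn["ideal"])
            dev_angle <- c(dev_angle, bond_angle(ca, cc, o1) - lk$angle_caco["ideal"])
            if (!is.null(ca)) dev_planar <- c(dev_planar,
                                              plane_rms(rbind(ca, cc, o1, n2)))
          }
          if (!is.null(ca) && !is.null(ca2)) {
            om <- dihedral(ca, cc, n2, ca2)
            dev_dihedral <- c(dev_dihedral, min(abs(om), 180 - abs(om)) *
                                sign_or_one(om))
          }
        }
      }
    }
  }
  rmsd <- function(v) if (length(v)) sqrt(mean(v^2)) else NA_real_
  list(bond = rmsd(dev_bond), angle = rmsd(dev_angle),
       chiral = rmsd(dev_chiral), planar = rmsd(dev_planar),
       dihedral = rmsd(dev_dihedral),
       n = c(bond = length(dev_bond), angle = length(dev_angle),
             chiral = length(dev_chiral), planar = length(dev_planar),
             dihedral = length(dev_dihedral)),
       skipped = skipped)
}

sign_or_one <- function(x) if (x == 0) 1 else sign(x)

## RMS distance of points from their least-squares plane.
plane_rms <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  normal <- s$v[, 3]
  sqrt(mean((sweep(pts, 2, ctr) %*% normal)^2))
}

## Standard heavy-atom van der Waals radii (Angstrom).
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 SE = 1.90, H = 1.20)

#' Clashscore
#'
#' Steric overlaps per 1,000 atoms: a clash is an atom pair more than
#' three bonds apart (the Probe/MolProbity exclusion of 1-2, 1-3 and 1-4
#' pairs) whose van der Waals overlap `(r_i + r_j - d)` is at least
#' `overlap_cut` (0.4 Angstrom by convention). Connectivity comes from
#' the restraint library plus the peptide link.
#' Scores are intended to be computed on hydrogen-stripped models (see
#' [normalize_for_scoring()]).
#'
#' @param model an [em_model()]
#' @param vdw named vector of van der Waals radii by element
#' @param overlap_cut minimum overlap counted as a clash, Angstrom
#' @param lib restraint library for connectivity
#' @return list with `clashscore` (clashes per 1,000 atoms), `n_clashes`,
#'   `n_atoms` and the `clashes` pair table
#' @export
clashscore <- function(model, vdw = DEFAULT_VDW, overlap_cut = 0.4,
                       lib = default_restraints()) {
  a <- model$atoms
  n <- nrow(a)
  excl <- bonded_exclusions(model, lib)
  rad <- vdw[a$element]
  rad[is.na(rad)] <- 1.7
  xyz <- coords(model)
  max_r <- 2 * max(rad)
  pairs <- close_pairs(xyz, max_r)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (excl[[paste(i, j)]] %||% FALSE) next
    d <- vnorm(xyz[i, ] - xyz[j, ])
    ov <- rad[i] + rad[j] - d
    if (ov >= overlap_cut - 1e-9)
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j, overlap = ov,
        atom_i = paste(a$chain[i], a$resno[i], a$atom[i]),
        atom_j = paste(a$chain[j], a$resno[j], a$atom[j]))
  }
  clashes <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), overlap = numeric(),
               atom_i = character(), atom_j = character())
  list(clashscore = 1000 * nrow(clashes) / n, n_clashes = nrow(clashes),
       n_atoms = n, clashes = clashes)
}

## All atom pairs with distance below cutoff (simple cell-list binning).
close_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cell <- pmax(1L, as.integer(floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)) + 1L)
  dim(cell) <- dim(xyz)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(buckets), " "))
  storage.mode(coord) <- "integer"
  res <- list()
  bk <- stats::setNames(seq_along(buckets), names(buckets))
  for (b in seq_along(buckets)) {
    ids <- buckets[[b]]
    ## neighbors: cells with index >= this cell (avoid double counting)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nb_key <- paste(coord[b, 1] + dx, coord[b, 2] + dy, coord[b, 3] + dz)
      nb <- bk[nb_key]
      if (is.na(nb) || nb < b) next
      jds <- buckets[[nb]]
      cand <- if (nb == b) {
        if (length(ids) < 2) next
        t(utils::combn(ids, 2))
      } else as.matrix(expand.grid(ids, jds))
      dd <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                            xyz[cand[, 2], , drop = FALSE])^2))
      keep <- dd < cutoff
      if (any(keep)) res[[length(res) + 1]] <- cand[keep, , drop = FALSE]
    }
  }
  if (!length(res)) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, res)
  t(apply(m, 1, sort))
}

## Environment of excluded (1-2 and 1-3) pairs as a lookup keyed "i j".
bonded_exclusions <- function(model, lib) {
  a <- model$atoms
  ri <- residue_index(model)
  edges <- list()
  for (i in seq_along(ri)) {
    r <- ri[[i]]
    rt <- a$resid[r[1]]
    tmpl <- lib$residues[[rt]]
    nm <- a$atom[r]
    if (!is.null(tmpl)) {
      for (j in seq_len(nrow(tmpl$bonds))) {
        i1 <- r[nm == tmpl$bonds$a1[j]]; i2 <- r[nm == tmpl$bonds$a2[j]]
        if (length(i1) && length(i2))
          edges[[length(edges) + 1]] <- c(i1[1], i2[1])
      }
    }
    if (i < length(ri)) {
      r2 <- ri[[i + 1]]
      if (a$chain[r2[1]] == a$chain[r[1]]) {
        c1 <- r[nm == "C"]; n2 <- r2[a$atom[r2] == "N"]
        if (length(c1) && length(n2)) {
          p1 <- coords(model)[c1[1], ]; p2 <- coords(model)[n2[1], ]
          if (vnorm(p2 - p1) < 2.5)
            edges[[length(edges) + 1]] <- c(c1[1], n2[1])
        }
      }
    }
  }
  adj <- vector("list", nrow(a))
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) {
    if (i != j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  ## exclude pairs up to 3 bonds apart (1-2, 1-3 and 1-4), the Probe /
  ## MolProbity convention
  for (i in seq_along(adj)) {
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    for (j in unique(c(d1, d2, d3))) mark(i, j)
  }
  as.list(excl)
}

#' Cis-peptide detection
#'
#' Classifies every consecutive residue pair (with CA,C | N,CA atoms
#' present, same chain, peptide bond formed) by its omega torsion:
#' `|omega| <= 30` is cis, within 30 degrees of 180 is trans, anything
#' else is twisted. Cis peptides are split into cis-Pro and cis-nonPro.
#'
#' @param model an [em_model()]
#' @return data.frame with one row per peptide bond: residue pair,
#'   omega (degrees) and class (`trans` / `cis-Pro` / `cis-nonPro` /
#'   `twisted`)
#' @export
cis_peptides <- function(model) {
  ri <- residue_index(model)
  a <- model$atoms
  rows <- list()
  for (i in seq_len(length(ri) - 1)) {
    r1 <- ri[[i]]; r2 <- ri[[i + 1]]
    if (a$chain[r1[1]] != a$chain[r2[1]]) next
    ca1 <- atom_xyz(model, r1, "CA"); c1 <- atom_xyz(model, r1, "C")
    n2 <- atom_xyz(model, r2, "N"); ca2 <- atom_xyz(model, r2, "CA")
    if (is.null(ca1) || is.null(c1) || is.null(n2) || is.null(ca2)) next
    if (vnorm(n2 - c1) > 2.5) next
    om <- dihedral(ca1, c1, n2, ca2)
    cls <- if (abs(om) <= 30) {
      if (a$resid[r2[1]] == "PRO") "cis-Pro" else "cis-nonPro"
    } else if (angdiff(om, 180) <= 30) "trans" else "twisted"
    rows[[length(rows) + 1]] <- data.frame(
      chain = a$chain[r1[1]], resno1 = a$resno[r1[1]], resno2 = a$resno[r2[1]],
      resid2 = a$resid[r2[1]], omega = om, class = cls,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(chain = character(), resno1 = integer(),
                                       resno2 = integer(), resid2 = character(),
                                       omega = numeric(), class = character()))
  do.call(rbind, rows)
}
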