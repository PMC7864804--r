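#' Build an ideal-geometry test structure
#'
#' Constructs a single-chain polypeptide with ideal bond lengths/angles
#' drawn from [default_restraints()] and ideal backbone torsions: helix
#' phi = -57, psi = -47; strand phi = -120, psi = +120; `alpha_left` is
#' the mirrored helix basin (phi = +57, psi = +47); `two_segment` is a
#' helix followed by a spatially offset strand (a chain break), useful
#' for domain-level comparisons. All peptide bonds are trans
#' (omega = 180). The default sequence is poly-Ala with every fourth
#' residue Leu, so chi-angle-dependent metrics (rotamers, EMRinger) have
#' eligible residues; Leu side chains are built at `chi1`/`chi2`.
#'
#' @param kind one of `"helix"`, `"strand"`, `"alpha_left"`, `"two_segment"`
#' @param n_residues number of residues (>= 4)
#' @param sequence optional 1-letter sequence string (only A/G/L supported
#'   by the builder); default poly-Ala with periodic Leu
#' @param chain chain identifier
#' @param chi1,chi2 Leu side-chain torsions in degrees
#' @param phi,psi optional explicit backbone torsions (degrees), scalar
#'   or per-residue vectors (recycled), overriding the `kind` presets
#'   (used e.g. to sample conformational basins when building reference
#'   distributions)
#' @return an [em_model()]
#' @export
build_fixture <- function(kind = c("helix", "strand", "alpha_left", "two_segment"),
                          n_residues, sequence = NULL, chain = "A",
                          chi1 = 300, chi2 = 180, phi = NULL, psi = NULL) {
  kind <- match.arg(kind)
  if (n_residues < 4) stop_emvalid("fixtures need n_residues >= 4")
  if (kind == "two_segment") {
    n1 <- ceiling(n_residues / 2); n2 <- n_residues - n1
    if (n2 < 4) stop_emvalid("two_segment needs >= 8 residues")
    seq1 <- if (is.null(sequence)) NULL else substr(sequence, 1, n1)
    seq2 <- if (is.null(sequence)) NULL else substring(sequence, n1 + 1)
    m1 <- build_fixture("helix", n1, seq1, chain, chi1, chi2)
    m2 <- build_fixture("strand", n2, seq2, chain, chi1, chi2)
    m2$atoms$resno <- m2$atoms$resno + n1
    m2 <- transform_model(m2, diag(3), c(0, 14, 0))
    return(em_model(rbind(m1$atoms, m2$atoms)))
  }
  tor <- switch(kind,
    helix = c(phi = -57, psi = -47),
    strand = c(phi = -120, psi = 120),
    alpha_left = c(phi = 57, psi = 47))
  phi_v <- rep_len(if (is.null(phi)) tor["phi"] else phi, n_residues)
  psi_v <- rep_len(if (is.null(psi)) tor["psi"] else psi, n_residues)
  if (is.null(sequence)) {
    seq1 <- rep("A", n_residues)
    seq1[seq_len(n_residues) %% 4 == 2] <- "L"
  } else {
    seq1 <- strsplit(toupper(sequence), "")[[1]]
    if (length(seq1) != n_residues)
      stop_emvalid("sequence length %d != n_residues %d", length(seq1), n_residues)
  }
  three <- c(A = "ALA", G = "GLY", L = "LEU")[seq1]
  if (anyNA(three)) stop_emvalid("builder supports residues A/G/L only")
  lib <- default_restraints()
  ideal_bond <- function(rt, a1, a2) {
    b <- lib$residues[[rt]]$bonds
    i <- which((b$a1 == a1 & b$a2 == a2) | (b$a1 == a2 & b$a2 == a1))
    b$ideal[i[1]]
  }
  ideal_angle <- function(rt, a1, a2, a3) {
    an <- lib$residues[[rt]]$angles
    i <- which(an$a2 == a2 & ((an$a1 == a1 & an$a3 == a3) |
                                (an$a1 == a3 & an$a3 == a1)))
    an$ideal[i[1]]
  }
  lk <- lib$link
  rows <- list()
  add <- function(resno, resid, name, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, ins = "", resid = resid, atom = name,
      element = substr(gsub("^[0-9]", "", name), 1, 1),
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
      stringsAsFactors = FALSE)
  }
  ## backbone trace
  N <- CA <- C <- vector("list", n_residues)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(ideal_bond("ALA", "N", "CA"), 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]],
                       ideal_bond("ALA", "CA", "C"),
                       ideal_angle("ALA", "N", "CA", "C"), psi_v[1] - 120)
  for (i in seq_len(n_residues - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], lk$bond["ideal"],
                             lk$angle_cacn["ideal"], psi_v[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                              ideal_bond("ALA", "N", "CA"),
                              lk$angle_cnca["ideal"], 180)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                             ideal_bond("ALA", "CA", "C"),
                             ideal_angle("ALA", "N", "CA", "C"), phi_v[i + 1])
  }
  for (i in seq_len(n_residues)) {
    rt <- three[i]
    add(i, rt, "N", N[[i]])
    add(i, rt, "CA", CA[[i]])
    add(i, rt, "C", C[[i]])
    ## carbonyl O anti to the next N (or to ideal psi for the last residue)
    O <- if (i < n_residues)
      place_atom(N[[i + 1]], CA[[i]], C[[i]], ideal_bond(rt, "C", "O"),
                 lk$angle_caco["ideal"], 180)
    else
      place_atom(N[[i]], CA[[i]], C[[i]], ideal_bond(rt, "C", "O"),
                 lk$angle_caco["ideal"], psi_v[i] + 180)
    add(i, rt, "O", O)
    if (rt == "GLY") next
    CB <- place_atom(C[[i]], N[[i]], CA[[i]], ideal_bond(rt, "CA", "CB"),
                     ideal_angle(rt, "N", "CA", "CB"), lib$cb_torsion)
    add(i, rt, "CB", CB)
    if (rt == "LEU") {
      CG <- place_atom(N[[i]], CA[[i]], CB, ideal_bond(rt, "CB", "CG"),
                       ideal_angle(rt, "CA", "CB", "CG"), chi1)
      add(i, rt, "CG", CG)
      ang_d <- ideal_angle(rt, "CB", "CG", "CD1")
      ang_dd <- ideal_angle(rt, "CD1", "CG", "CD2")
      ## dihedral offset between the two delta branches that realizes the
      ## ideal CD1-CG-CD2 angle given both CB-CG-CD angles
      gam <- deg2rad(180 - ang_d)
      doff <- rad2deg(acos(max(-1, min(1,
        (cos(deg2rad(ang_dd)) - cos(gam)^2) / sin(gam)^2))))
      add(i, rt, "CD1", place_atom(CA[[i]], CB, CG,
                                   ideal_bond(rt, "CG", "CD1"), ang_d, chi2))
      add(i, rt, "CD2", place_atom(CA[[i]], CB, CG,
                                   ideal_bond(rt, "CG", "CD2"), ang_d, chi2 + doff))
    }
  }
  em_model(do.call(rbind, rows))
}
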