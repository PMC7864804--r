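#' Apply a controlled perturbation to a model
#'
#' Emulates the model-error classes seen in practice:
#' \describe{
#'   \item{jitter}{i.i.d. Gaussian displacement of every atom with the
#'     requested root-mean-square magnitude (Angstrom).}
#'   \item{peptide_flip}{rotates the peptide plane following residue
#'     `index` (atoms C and O of residue `index`, N of residue
#'     `index + 1`) by 180 degrees about the CA(i)-CA(i+1) axis: the
#'     carbonyl points the wrong way while the CA trace is untouched.}
#'   \item{misthread}{shifts residue-type assignments by `offset`
#'     residues along the chain while keeping backbone coordinates
#'     (local sequence misalignment); side-chain atoms beyond CB are
#'     dropped since they belong to the old identities, and CB is kept
#'     or removed according to the new type.}
#'   \item{rotamer_swap}{sets chi1 of every side-chain-bearing residue
#'     (or of residue `index` if given) to `target` degrees by rotating
#'     the atoms beyond CB about the CA-CB axis.}
#' }
#'
#' With `magnitude = 0` (jitter), `offset = 0` (misthread) the input is
#' returned unchanged; with a fixed `seed`, jitter is reproducible.
#'
#' @param model an [em_model()]
#' @param kind perturbation kind
#' @param magnitude jitter RMS displacement in Angstrom
#' @param index residue position (1-based along the chain) for
#'   `peptide_flip` / `rotamer_swap`
#' @param offset misthread shift in residues
#' @param target target chi1 in degrees for `rotamer_swap`
#' @param seed RNG seed (required for jitter with magnitude > 0)
#' @return perturbed [em_model()]
#' @export
perturb_model <- function(model,
                          kind = c("jitter", "peptide_flip", "misthread", "rotamer_swap"),
                          magnitude = 0, index = NULL, offset = 0,
                          target = NULL, seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    jitter = perturb_jitter(model, magnitude, seed),
    peptide_flip = perturb_flip(model, index),
    misthread = perturb_misthread(model, offset),
    rotamer_swap = perturb_rotamer(model, target, index))
}

perturb_jitter <- function(model, magnitude, seed) {
  if (magnitude < 0) stop_emvalid("jitter magnitude must be >= 0")
  if (magnitude == 0) return(model)
  if (is.null(seed)) stop_emvalid("jitter requires a seed")
  n <- nrow(model$atoms)
  disp <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, magnitude / sqrt(3)), ncol = 3))
  set_coords(model, coords(model) + disp)
}

perturb_flip <- function(model, index) {
  ri <- residue_index(model)
  if (is.null(index) || index < 1 || index >= length(ri))
    stop_emvalid("peptide_flip needs a residue index with a following residue")
  r1 <- ri[[index]]; r2 <- ri[[index + 1]]
  ca1 <- atom_xyz(model, r1, "CA"); ca2 <- atom_xyz(model, r2, "CA")
  if (is.null(ca1) || is.null(ca2)) stop_emvalid("missing CA atoms at flip site")
  if (vnorm(ca2 - ca1) > 4.5) stop_emvalid("flip site spans a chain break")
  R <- rotation_about_axis(ca2 - ca1, 180)
  sel <- c(r1[model$atoms$atom[r1] %in% c("C", "O")],
           r2[model$atoms$atom[r2] == "N"])
  xyz <- coords(model)[sel, , drop = FALSE]
  xyz <- sweep(sweep(xyz, 2, ca1, "-") %*% t(R), 2, ca1, "+")
  set_coords(model, xyz, sel)
}

perturb_misthread <- function(model, offset) {
  if (offset == 0) return(model)
  ri <- residue_index(model)
  n <- length(ri)
  if (abs(offset) >= n) stop_emvalid("misthread offset |%d| >= chain length %d", offset, n)
  types <- vapply(ri, function(r) model$atoms$resid[r[1]], "")
  new_types <- types[((seq_len(n) - 1 + offset) %% n) + 1]
  keep <- logical(nrow(model$atoms))
  a <- model$atoms
  for (i in seq_len(n)) {
    r <- ri[[i]]
    bb <- a$atom[r] %in% c("N", "CA", "C", "O")
    cb <- a$atom[r] == "CB" & new_types[i] != "GLY"
    keep[r[bb | cb]] <- TRUE
    a$resid[r] <- new_types[i]
  }
  em_model(a[keep, , drop = FALSE])
}

perturb_rotamer <- function(model, target, index = NULL) {
  if (is.null(target)) stop_emvalid("rotamer_swap needs a target chi1")
  ri <- residue_index(model)
  idx <- if (is.null(index)) seq_along(ri) else index
  a <- model$atoms
  for (i in idx) {
    r <- ri[[i]]
    nn <- atom_xyz(model, r, "N"); ca <- atom_xyz(model, r, "CA")
    cb <- atom_xyz(model, r, "CB")
    gamma <- intersect(c("CG", "CG1", "OG", "OG1", "SG"), a$atom[r])
    if (is.null(cb) || !length(gamma)) next
    cg <- atom_xyz(model, r, gamma[1])
    cur <- dihedral(nn, ca, cb, cg)
    R <- rotation_about_axis(cb - ca, target - cur)
    side <- r[!(a$atom[r] %in% c("N", "CA", "C", "O", "CB"))]
    if (!length(side)) next
    xyz <- coords(model)[side, , drop = FALSE]
    xyz <- sweep(sweep(xyz, 2, cb, "-") %*% t(R), 2, cb, "+")
    model <- set_coords(model, xyz, side)
  }
  model
}
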