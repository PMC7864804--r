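#' Atomic coordinate model
#'
#' An `em_model` is a flat atom table with the chain/residue/atom hierarchy
#' encoded in its columns, in the style of crystallographic atom records:
#' one row per atom with chain id, author residue number, insertion code,
#' 3-letter residue type, atom name, element, Cartesian coordinates
#' (Angstrom), occupancy, isotropic B factor (Angstrom^2) and a hydrogen
#' flag. Residues within a chain are kept strictly ordered by residue
#' number (then insertion code); atom names are unique within a residue.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resid`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ`, `b` (missing `ins`, `occ`,
#'   `b`, `element` are filled with defaults).
#' @return Object of class `em_model`.
#' @export
em_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_emvalid("missing atom columns: %s", paste(miss, collapse = ", "))
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$resno <- as.integer(atoms$resno)
  atoms$is_h <- atoms$element %in% c("H", "D")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop_emvalid("non-finite atom coordinates")
  ## strict residue ordering within chains, stable atom order within residues
  ord <- order(match(atoms$chain, unique(atoms$chain)), atoms$resno,
               atoms$ins, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|")
  if (anyDuplicated(key))
    stop_emvalid("duplicate atom name within a residue: %s", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "em_model")
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_name))
  el <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")]
  ## heuristic: in protein atom names a leading CA/NA etc. is carbon/nitrogen
  el[atom_name %in% c("CA", "CB", "CG", "CD", "CE", "CZ", "CH")] <- "C"
  el[atom_name %in% c("NA", "ND", "NE", "NZ", "NH")] <- "N"
  el
}

#' @export
print.em_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("em_model: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), nrow(unique(a[c("chain", "resno", "ins")])),
              length(unique(a$chain)), paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Atom coordinate matrix
#' @param model an `em_model`
#' @param sel optional logical/integer row selection on the atom table
#' @return numeric matrix n x 3
#' @export
coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

## Unique residue keys in model order.
residue_keys <- function(model) {
  a <- model$atoms
  unique(paste(a$chain, a$resno, a$ins, sep = "|"))
}

## Split atom-row indices by residue, preserving order.
residue_index <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = "|")
  split(seq_len(nrow(a)), factor(key, levels = unique(key)))
}

## Fetch one named atom's xyz within residue rows; NULL if absent.
atom_xyz <- function(model, rows, name) {
  i <- rows[model$atoms$atom[rows] == name]
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1], c("x", "y", "z")])
}

## Replace coordinates (n x 3) of selected rows.
set_coords <- function(model, xyz, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(model$atoms))
  model$atoms[sel, c("x", "y", "z")] <- xyz
  model
}

## Apply rigid transform x -> x R^T + t.
transform_model <- function(model, rotation, translation) {
  xyz <- coords(model) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(model, xyz)
}

#' Normalize a model for scoring
#'
#' Applies the standard pre-scoring control used when comparing models
#' produced under heterogeneous conventions: hydrogens are removed, all B
#' factors are set to zero and, when *every* occupancy in the input is
#' zero (a deposition artifact), occupancies are reset to one. Models with
#' mixed occupancies are left untouched in that respect.
#'
#' @param model an `em_model`
#' @return a normalized copy; the input is not modified
#' @export
normalize_for_scoring <- function(model) {
  a <- model$atoms
  a <- a[!a$is_h, , drop = FALSE]
  if (!nrow(a)) stop_emvalid("model has no heavy atoms after hydrogen removal")
  a$b <- 0
  if (all(a$occ == 0)) a$occ <- 1
  rownames(a) <- NULL
  em_model(a)
}
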