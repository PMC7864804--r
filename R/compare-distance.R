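#' Local difference distance test (LDDT)
#'
#' Superposition-free comparison of interatomic distance maps: over all
#' reference atom pairs within `inclusion_radius` and not in the same
#' residue, the fraction of pairs whose model distance matches the
#' reference within each threshold, averaged over thresholds, times 100.
#' Per-residue scores restrict to pairs touching the residue.
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @param inclusion_radius reference distance cutoff, Angstrom
#' @param thresholds agreement tolerances, Angstrom
#' @return list with `global` (0-100) and `per_residue` data.frame
#' @export
lddt <- function(model, reference, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  pr <- pair_atoms(model, reference, "all")
  n <- nrow(pr$ref_xyz)
  if (n < 2) stop_emvalid("no paired atoms")
  reskey <- paste(pr$chain, pr$resno)
  dref <- as.matrix(stats::dist(pr$ref_xyz))
  dmod <- as.matrix(stats::dist(pr$model_xyz))
  sel <- upper.tri(dref) & dref <= inclusion_radius &
    outer(reskey, reskey, "!=")
  ij <- which(sel, arr.ind = TRUE)
  if (!nrow(ij)) stop_emvalid("no reference pairs within the inclusion radius")
  dd <- abs(dref[sel] - dmod[sel])
  pass <- vapply(thresholds, function(th) dd <= th, logical(length(dd)))
  global <- 100 * mean(colMeans(pass))
  ukeys <- unique(reskey)
  per_res <- vapply(ukeys, function(k) {
    touch <- reskey[ij[, 1]] == k | reskey[ij[, 2]] == k
    if (!any(touch)) return(NA_real_)
    100 * mean(colMeans(pass[touch, , drop = FALSE]))
  }, 1)
  list(global = global,
       per_residue = data.frame(reskey = ukeys, lddt = unname(per_res),
                                stringsAsFactors = FALSE))
}

#' Contact area difference (CAD) score
#'
#' Superposition-free comparison of residue-residue contacts. Contact
#' areas are approximated analytically: for each atom pair closer than
#' the sum of their (vdW + slack) shell radii, the buried spherical-cap
#' area on both spheres is summed into the residue-pair contact area A.
#' The score is `1 - sum(min(|A_ref - A_model|, A_ref)) / sum(A_ref)`
#' over reference residue pairs (bounded difference, normalized by the
#' reference), in [0, 1].
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @param contact_radius_slack shell enlargement over vdW radii, Angstrom
#' @param vdw vdW radius table by element
#' @return CAD score in [0, 1]
#' @export
cad_score <- function(model, reference, contact_radius_slack = 0.5,
                      vdw = DEFAULT_VDW) {
  pr <- pair_atoms(model, reference, "all")
  if (!nrow(pr$ref_xyz)) stop_emvalid("no paired atoms")
  el <- vapply(strsplit(pr$keys, "|", fixed = TRUE), function(x)
    guess_element(x[4]), "")
  rad <- vdw[el] + contact_radius_slack
  rad[is.na(rad)] <- 1.7 + contact_radius_slack
  reskey <- paste(pr$chain, pr$resno)
  areas <- function(xyz) {
    cp <- close_pairs(xyz, 2 * max(rad))
    acc <- new.env(hash = TRUE)
    for (k in seq_len(nrow(cp))) {
      i <- cp[k, 1]; j <- cp[k, 2]
      if (reskey[i] == reskey[j]) next
      d <- vnorm(xyz[i, ] - xyz[j, ])
      A <- sphere_overlap_area(rad[i], rad[j], d)
      if (A <= 0) next
      key <- paste(sort(c(reskey[i], reskey[j])), collapse = "::")
      acc[[key]] <- (acc[[key]] %||% 0) + A
    }
    acc
  }
  a_ref <- areas(pr$ref_xyz)
  a_mod <- areas(pr$model_xyz)
  ref_keys <- ls(a_ref)
  if (!length(ref_keys)) stop_emvalid("reference has no residue contacts")
  tot <- 0; lost <- 0
  for (k in ref_keys) {
    Ar <- a_ref[[k]]; Am <- a_mod[[k]] %||% 0
    tot <- tot + Ar
    lost <- lost + min(abs(Ar - Am), Ar)
  }
  unname(1 - lost / tot)
}

## Total surface area buried in the overlap of two spheres (sum of both
## spherical caps); 0 when disjoint, full smaller-sphere area when
## engulfed.
sphere_overlap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    rs <- min(r1, r2)
    return(4 * pi * rs^2)
  }
  ## cap heights from the standard sphere-sphere intersection geometry
  h1 <- (r2 - r1 + d) * (r2 + r1 - d) / (2 * d)
  h2 <- (r1 - r2 + d) * (r1 + r2 - d) / (2 * d)
  2 * pi * r1 * h1 + 2 * pi * r2 * h2
}

#' Nonlocal hydrogen-bond precision (HBPR > 6)
#'
#' Detects hydrogen bonds on hydrogen-stripped models with a heavy-atom
#' criterion: donor N or O to acceptor O within `dist_cut`, sequence
#' separation > `min_sep` within a chain (cross-chain pairs count as
#' nonlocal). Bonds are identified by their (donor residue, acceptor
#' residue) pair; precision is the fraction of the model's nonlocal
#' bonds present in the reference. A model with zero nonlocal bonds
#' yields `NA` with `undefined = TRUE`, never a fake 0.
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @param dist_cut donor-acceptor distance cutoff, Angstrom
#' @param min_sep minimum sequence separation (exclusive)
#' @return list with `precision`, `n_model`, `n_matched`, bond tables,
#'   `undefined`
#' @export
hbond_precision <- function(model, reference, dist_cut = 3.5, min_sep = 6) {
  bonds <- function(m) {
    a <- m$atoms[!m$atoms$is_h, , drop = FALSE]
    don <- which(a$element %in% c("N", "O"))
    acc <- which(a$element == "O")
    xyz <- as.matrix(a[, c("x", "y", "z")])
    out <- list()
    for (i in don) {
      dd <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[i, ])^2))
      hit <- acc[dd <= dist_cut & dd > 0.1]
      for (j in hit) {
        same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j] &
          a$ins[i] == a$ins[j]
        if (same_res) next
        nonlocal <- a$chain[i] != a$chain[j] ||
          abs(a$resno[i] - a$resno[j]) > min_sep
        if (!nonlocal) next
        out[[length(out) + 1]] <- paste(
          a$chain[i], a$resno[i], a$ins[i], "->",
          a$chain[j], a$resno[j], a$ins[j])
      }
    }
    unique(unlist(out))
  }
  bm <- bonds(model); br <- bonds(reference)
  if (!length(bm))
    return(list(precision = NA_real_, n_model = 0L, n_matched = 0L,
                model_bonds = character(), reference_bonds = br,
                undefined = TRUE))
  matched <- sum(bm %in% br)
  list(precision = matched / length(bm), n_model = length(bm),
       n_matched = matched, model_bonds = bm, reference_bonds = br,
       undefined = FALSE)
}

#' Full model-versus-reference comparison report
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @return list of class `em_compare_report` with gdt/gdc, CA RMSD,
#'   LDDT, CAD and HBPR components
#' @export
compare_to_reference <- function(model, reference) {
  g <- gdt_scores(model, reference)
  l <- lddt(model, reference)
  structure(list(
    gdt_ts = g$gdt_ts, gdc_all = g$gdc_all, gdc_sc = g$gdc_sc,
    ca_rmsd = g$ca_rmsd, lddt = l$global,
    cad = cad_score(model, reference),
    hbpr = hbond_precision(model, reference),
    per_residue = g$per_residue, lddt_per_residue = l$per_residue
  ), class = "em_compare_report")
}

#' @export
print.em_compare_report <- function(x, ...) {
  cat(sprintf("gdt_ts %.1f, gdc_all %.1f, gdc_sc %s, ca_rmsd %.3f A\n",
              x$gdt_ts, x$gdc_all,
              if (is.na(x$gdc_sc)) "NA" else sprintf("%.1f", x$gdc_sc),
              x$ca_rmsd))
  cat(sprintf("lddt %.1f, cad %.3f, hbpr>6 %s\n", x$lddt, x$cad,
              if (x$hbpr$undefined) "undef" else sprintf("%.3f", x$hbpr$precision)))
  invisible(x)
}
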