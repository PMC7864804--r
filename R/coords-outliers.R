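#' Ramachandran and rotamer outliers
#'
#' A residue is a Ramachandran outlier iff its (phi, psi) falls in a bin
#' whose reference frequency is below the reference's outlier cutoff;
#' rotamer outliers are judged the same way on chi1. Terminal residues
#' (no phi or psi) and residues with missing backbone atoms are
#' unscored. Fractions are `NA` with an `undefined` flag when no residue
#' could be scored.
#'
#' @param model an [em_model()]
#' @param rama_ref,rotamer_ref reference distributions (see
#'   [build_reference()] / [reference_from_fixtures()])
#' @return list with `rama` and `rotamer` components, each holding
#'   `fraction`, `n_scored`, and an `outliers` table
#' @export
rama_rotamer_outliers <- function(model, rama_ref, rotamer_ref = NULL) {
  score_track <- function(o, ref) {
    if (!nrow(o$obs))
      return(list(fraction = NA_real_, n_scored = 0L,
                  outliers = data.frame(), undefined = TRUE))
    fr <- reference_frequency(ref, o$obs)
    out <- fr < ref$cutoff_values["outlier"]
    a <- model$atoms
    first <- vapply(residue_index(model), `[`, 1L, 1)
    tab <- data.frame(chain = a$chain[first[o$index]],
                      resno = a$resno[first[o$index]],
                      resid = a$resid[first[o$index]],
                      frequency = fr, outlier = out,
                      stringsAsFactors = FALSE)
    list(fraction = mean(out), n_scored = length(out),
         outliers = tab[out, , drop = FALSE], undefined = FALSE)
  }
  res <- list(rama = score_track(rama_observations(model), rama_ref))
  if (!is.null(rotamer_ref))
    res$rotamer <- score_track(chi1_observations(model), rotamer_ref)
  res
}

#' CaBLAM and CA-geometry outliers
#'
#' For each protein residue i with CA positions i-2..i+2 available
#' within one contiguous stretch (chain breaks, CA-CA > 4.5 A, terminate
#' stretches), evaluates two virtual-angle triplets: the CaBLAM triplet
#' (two CA virtual dihedrals plus the virtual dihedral of the CO groups
#' flanking i) and the CA-geometry triplet (the two CA virtual dihedrals
#' plus the CA virtual angle at i). A residue is flagged when its
#' triplet's reference frequency falls below the outlier cutoff. The
#' first/last two residues of every stretch are unscored.
#'
#' @param model an [em_model()]
#' @param cablam_ref,calpha_ref reference distributions over the two
#'   triplet spaces
#' @return list with `cablam` and `calpha` components (`fraction`,
#'   `n_scored`, `outliers` table with the marginal values logged)
#' @export
cablam <- function(model, cablam_ref, calpha_ref = NULL) {
  a <- model$atoms
  first <- vapply(residue_index(model), `[`, 1L, 1)
  score <- function(o, ref, label) {
    if (!nrow(o$obs))
      return(list(fraction = NA_real_, n_scored = 0L,
                  outliers = data.frame(), undefined = TRUE))
    fr <- reference_frequency(ref, o$obs)
    out <- fr < ref$cutoff_values["outlier"]
    tab <- data.frame(chain = a$chain[first[o$index]],
                      resno = a$resno[first[o$index]],
                      resid = a$resid[first[o$index]],
                      mu_in = o$obs[, 1], mu_out = o$obs[, 2],
                      third = o$obs[, 3], frequency = fr, outlier = out,
                      stringsAsFactors = FALSE)
    list(fraction = mean(out), n_scored = length(out),
         outliers = tab[out, , drop = FALSE], undefined = FALSE)
  }
  res <- list(cablam = score(cablam_observations(model, "cablam"), cablam_ref))
  if (!is.null(calpha_ref))
    res$calpha <- score(cablam_observations(model, "calpha"), calpha_ref)
  res
}

#' Full coordinates-only geometry report
#'
#' Convenience wrapper bundling restraint RMSDs, clashscore,
#' Ramachandran/rotamer outliers, CaBLAM/CA-geometry outliers and
#' cis-peptide detection into one report.
#'
#' @param model an [em_model()] (normalized with
#'   [normalize_for_scoring()] internally)
#' @param refs named list with elements `rama`, `rotamer`, `cablam`,
#'   `calpha` (defaults to [reference_from_fixtures()] grids)
#' @param lib restraint library
#' @return list of class `em_geometry_report`
#' @export
geometry_report <- function(model, refs = NULL, lib = default_restraints()) {
  model <- normalize_for_scoring(model)
  if (is.null(refs))
    refs <- list(rama = reference_from_fixtures("rama"),
                 rotamer = reference_from_fixtures("rotamer"),
                 cablam = reference_from_fixtures("cablam"),
                 calpha = reference_from_fixtures("calpha"))
  rr <- rama_rotamer_outliers(model, refs$rama, refs$rotamer)
  cb <- cablam(model, refs$cablam, refs$calpha)
  cis <- cis_peptides(model)
  structure(list(
    rmsd = geometry_rmsd(model, lib),
    clash = clashscore(model, lib = lib),
    rama = rr$rama, rotamer = rr$rotamer,
    cablam = cb$cablam, calpha = cb$calpha,
    cis_peptides = cis,
    n_cis_pro = sum(cis$class == "cis-Pro"),
    n_cis_nonpro = sum(cis$class == "cis-nonPro")
  ), class = "em_geometry_report")
}

#' @export
print.em_geometry_report <- function(x, ...) {
  cat(sprintf("bond rmsd %.4f A, angle rmsd %.2f deg, clashscore %.1f\n",
              x$rmsd$bond, x$rmsd$angle, x$clash$clashscore))
  cat(sprintf("rama outliers %s, rotamer %s, cablam %s, calpha %s\n",
              fmt_frac(x$rama$fraction), fmt_frac(x$rotamer$fraction),
              fmt_frac(x$cablam$fraction), fmt_frac(x$calpha$fraction)))
  cat(sprintf("cis-Pro %d, cis-nonPro %d\n", x$n_cis_pro, x$n_cis_nonpro))
  invisible(x)
}

fmt_frac <- function(f) if (is.na(f)) "undef" else sprintf("%.1f%%", 100 * f)
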