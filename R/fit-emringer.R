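## Residues whose C-gamma is a single unbranched heavy atom; ring-path
## analysis applies to these (not ALA/GLY/SER/THR/VAL/ILE/CYS/PRO).
EMRINGER_ELIGIBLE <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LEU",
                       "LYS", "MET", "PHE", "TRP", "TYR")

#' EMRinger-style side-chain ring-path score
#'
#' For every eligible residue (unbranched C-gamma), sweeps chi1 in
#' `step`-degree increments, placing the implied C-gamma position on the
#' circular path about the CA-CB axis and interpolating map density
#' there. The peak angle is the sweep argmax; a peak is rotameric iff it
#' falls within 30 degrees of a staggered center (60/180/300). The
#' global score is the binomial z-statistic of the rotameric peak count
#' among peaks whose density exceeds an acceptance threshold (null
#' p0 = 1/2: three 60-degree rotameric windows cover half the circle),
#' maximized over a sweep of thresholds and rescaled by
#' `10/sqrt(N_scored)`. A model at 100% rotameric peaks therefore scores
#' `10*(1 - p0)/sqrt(p0*(1 - p0)) = 10`. The per-residue profile is the
#' sliding-window rotameric fraction (`window` residues).
#'
#' @param map an [em_map()]
#' @param model an [em_model()]
#' @param step chi1 sweep step, degrees
#' @param window sliding window length (residues) for the profile
#' @param n_thresholds number of density acceptance thresholds swept
#' @return object of class `em_emringer`: list with `global` score,
#'   `residues` table (peak angle, peak density, rotameric flag) and
#'   `profile`
#' @export
emringer <- function(map, model, step = 5, window = 21, n_thresholds = 20) {
  ri <- residue_index(model)
  a <- model$atoms
  lib <- default_restraints()
  angles <- seq(0, 360 - step, by = step)
  res_rows <- list()
  for (i in seq_along(ri)) {
    r <- ri[[i]]
    rt <- a$resid[r[1]]
    if (!rt %in% EMRINGER_ELIGIBLE) next
    nn <- atom_xyz(model, r, "N"); ca <- atom_xyz(model, r, "CA")
    cb <- atom_xyz(model, r, "CB")
    if (is.null(nn) || is.null(ca) || is.null(cb)) next
    blen <- {
      b <- lib$residues[[rt]]$bonds
      j <- which(b$a1 == "CB" & b$a2 == "CG")
      if (length(j)) b$ideal[j[1]] else 1.52
    }
    bang <- {
      an <- lib$residues[[rt]]$angles
      j <- which(an$a2 == "CB" & ((an$a1 == "CA" & an$a3 == "CG") |
                                    (an$a1 == "CG" & an$a3 == "CA")))
      if (length(j)) an$ideal[j[1]] else 114
    }
    ring <- t(vapply(angles, function(chi)
      place_atom(nn, ca, cb, blen, bang, chi), numeric(3)))
    dens <- interpolate_density(map, ring)
    pk <- which.max(dens)
    peak_chi <- angles[pk]
    rot <- min(angdiff(peak_chi, c(60, 180, 300))) <= 30
    res_rows[[length(res_rows) + 1]] <- data.frame(
      chain = a$chain[r[1]], resno = a$resno[r[1]], ins = a$ins[r[1]],
      resid = rt, peak_chi = peak_chi, peak_density = dens[pk],
      rotameric = rot, stringsAsFactors = FALSE)
  }
  if (!length(res_rows))
    stop_emvalid("no residues eligible for ring-path analysis (unbranched C-gamma required)")
  tab <- do.call(rbind, res_rows)
  n_total <- nrow(tab)
  p0 <- 0.5
  thresholds <- stats::quantile(tab$peak_density,
                                probs = seq(0, 1 - 1 / n_thresholds,
                                            length.out = n_thresholds),
                                names = FALSE)
  z_best <- -Inf
  for (thr in unique(thresholds)) {
    sel <- tab$peak_density >= thr
    n <- sum(sel)
    if (n < 2) next
    z <- (sum(tab$rotameric[sel]) - n * p0) / sqrt(n * p0 * (1 - p0))
    if (z > z_best) z_best <- z
  }
  global <- 10 * z_best / sqrt(n_total)
  ## sliding-window rotameric fraction mapped back onto all residues
  half <- (window - 1) / 2
  all_keys <- residue_keys(model)
  tab_keys <- paste(tab$chain, tab$resno, tab$ins, sep = "|")
  pos <- match(tab_keys, all_keys)
  prof_scores <- rep(NA_real_, length(all_keys))
  for (i in seq_along(all_keys)) {
    sel <- which(pos >= i - half & pos <= i + half)
    if (length(sel)) prof_scores[i] <- mean(tab$rotameric[sel])
  }
  prof <- residue_profile(model, prof_scores, "emringer")
  attr(prof, "global") <- global
  structure(list(global = global, residues = tab, profile = prof,
                 n_scored = n_total, p0 = p0),
            class = "em_emringer")
}

#' @export
print.em_emringer <- function(x, ...) {
  cat(sprintf("em_emringer: score %.3f over %d residues (%.0f%% rotameric peaks)\n",
              x$global, x$n_scored, 100 * mean(x$residues$rotameric)))
  invisible(x)
}
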