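## Atom pairing between two models: by identical chain / residue number /
## insertion code / atom name (challenge-style shared numbering; no
## sequence alignment). Mismatches are dropped and counted.
pair_atoms <- function(model, reference,
                       selection = c("CA", "all", "backbone", "sidechain")) {
  selection <- match.arg(selection)
  pick <- function(m) {
    a <- m$atoms[!m$atoms$is_h, , drop = FALSE]
    keep <- switch(selection,
      CA = a$atom == "CA",
      all = rep(TRUE, nrow(a)),
      backbone = a$atom %in% c("N", "CA", "C", "O"),
      sidechain = !(a$atom %in% c("N", "CA", "C", "O")))
    a[keep, , drop = FALSE]
  }
  am <- pick(model); ar <- pick(reference)
  km <- paste(am$chain, am$resno, am$ins, am$atom, sep = "|")
  kr <- paste(ar$chain, ar$resno, ar$ins, ar$atom, sep = "|")
  common <- intersect(km, kr)
  list(model_xyz = as.matrix(am[match(common, km), c("x", "y", "z")]),
       ref_xyz = as.matrix(ar[match(common, kr), c("x", "y", "z")]),
       keys = common,
       resno = am$resno[match(common, km)],
       chain = am$chain[match(common, km)],
       n_unmatched = length(km) + length(kr) - 2 * length(common))
}

## Kabsch least-squares rigid superposition (proper rotation enforced).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cq - as.numeric(R %*% cp)
  list(rotation = R, translation = t_vec)
}

#' Least-squares superposition of a model onto a reference
#'
#' Optimal rigid-body (proper rotation + translation) superposition over
#' atoms paired by chain/residue-number/atom-name identity.
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @param selection atom class used for the fit
#' @return object of class `em_superposition`: rotation (3x3),
#'   translation, paired keys, and `rmsd` over the paired selection
#' @export
superpose <- function(model, reference, selection = "CA") {
  pr <- pair_atoms(model, reference, selection)
  n <- nrow(pr$model_xyz)
  if (n < 3) stop_emvalid("need >= 3 paired atoms to superpose (got %d)", n)
  sing <- svd(sweep(pr$ref_xyz, 2, colMeans(pr$ref_xyz)))$d
  degenerate <- sing[2] < 1e-6
  k <- kabsch(pr$model_xyz, pr$ref_xyz)
  moved <- sweep(pr$model_xyz %*% t(k$rotation), 2, k$translation, "+")
  rmsd <- sqrt(mean(rowSums((moved - pr$ref_xyz)^2)))
  structure(list(rotation = k$rotation, translation = k$translation,
                 keys = pr$keys, rmsd = rmsd, n = n,
                 degenerate = degenerate,
                 n_unmatched = pr$n_unmatched),
            class = "em_superposition")
}

#' @export
print.em_superposition <- function(x, ...) {
  cat(sprintf("em_superposition: %d pairs, rmsd %.4f A%s\n", x$n, x$rmsd,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

## Largest subset of pairs simultaneously superimposable within `cutoff`,
## approximated by iterated trimmed superposition from multiple seeds
## (the full set plus every `seed_window`-residue contiguous window).
max_fit_count <- function(P, Q, cutoff, resno = NULL, seed_window = 5) {
  n <- nrow(P)
  seeds <- list(seq_len(n))
  if (!is.null(resno) && n >= seed_window) {
    ord <- order(resno)
    for (s in seq_len(n - seed_window + 1))
      seeds[[length(seeds) + 1]] <- ord[s:(s + seed_window - 1)]
  }
  best <- 0L
  for (seed in seeds) {
    sel <- seed
    for (iter in 1:25) {
      if (length(sel) < 3) break
      k <- kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      moved <- sweep(P %*% t(k$rotation), 2, k$translation, "+")
      d <- sqrt(rowSums((moved - Q)^2))
      new_sel <- which(d <= cutoff)
      if (length(new_sel) < 3) { sel <- new_sel; break }
      if (identical(new_sel, sel)) { sel <- new_sel; break }
      sel <- new_sel
    }
    best <- max(best, length(sel))
  }
  best
}

#' Global distance test scores (GDT-TS, GDC-all, GDC-SC)
#'
#' For each distance cutoff, approximates the largest fraction of paired
#' atoms simultaneously superimposable within the cutoff by iterated
#' trimmed superposition with multi-seed restarts. GDT-TS averages the
#' CA fractions over cutoffs {1, 2, 4, 8} Angstrom; GDC-all / GDC-SC
#' average all-atom / side-chain-atom fractions over cutoffs
#' {0.5, 1.0, ..., 5.0}. Also reports per-residue CA distances after the
#' all-pair superposition.
#'
#' @param model,reference [em_model()]s sharing residue numbering
#' @param gdt_cutoffs,gdc_cutoffs cutoff sets (Angstrom)
#' @return list with `gdt_ts`, `gdc_all`, `gdc_sc` (percentages),
#'   `ca_rmsd`, and `per_residue` CA distance table
#' @export
gdt_scores <- function(model, reference,
                       gdt_cutoffs = c(1, 2, 4, 8),
                       gdc_cutoffs = seq(0.5, 5, by = 0.5)) {
  ca <- pair_atoms(model, reference, "CA")
  if (nrow(ca$model_xyz) < 4) stop_emvalid("need >= 4 paired CA atoms")
  frac <- function(P, Q, cutoffs, resno) {
    if (is.null(P) || nrow(P) < 3) return(NA_real_)
    mean(vapply(cutoffs, function(cc)
      max_fit_count(P, Q, cc, resno) / nrow(P), 1))
  }
  gdt_ts <- 100 * frac(ca$model_xyz, ca$ref_xyz, gdt_cutoffs, ca$resno)
  all_p <- pair_atoms(model, reference, "all")
  gdc_all <- 100 * frac(all_p$model_xyz, all_p$ref_xyz, gdc_cutoffs, all_p$resno)
  sc <- pair_atoms(model, reference, "sidechain")
  gdc_sc <- if (nrow(sc$model_xyz) >= 3)
    100 * frac(sc$model_xyz, sc$ref_xyz, gdc_cutoffs, sc$resno) else NA_real_
  k <- kabsch(ca$model_xyz, ca$ref_xyz)
  moved <- sweep(ca$model_xyz %*% t(k$rotation), 2, k$translation, "+")
  dca <- sqrt(rowSums((moved - ca$ref_xyz)^2))
  list(gdt_ts = gdt_ts, gdc_all = gdc_all, gdc_sc = gdc_sc,
       ca_rmsd = sqrt(mean(dca^2)),
       per_residue = data.frame(chain = ca$chain, resno = ca$resno,
                                ca_dist = dca, stringsAsFactors = FALSE))
}

#' Consensus quality among a set of models
#'
#' Each model's score is the mean of its pairwise GDT-TS against every
#' other model in the set.
#'
#' @param models list of >= 2 [em_model()]s with common residue numbering
#' @return data.frame with one row per model (`model`, `davis_qa`)
#' @export
davis_qa <- function(models) {
  n <- length(models)
  if (n < 2) stop_emvalid("consensus scoring needs >= 2 models")
  g <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    g[i, j] <- g[j, i] <- gdt_scores(models[[i]], models[[j]])$gdt_ts
  }
  data.frame(model = seq_len(n),
             davis_qa = vapply(seq_len(n), function(i) mean(g[i, -i]), 1))
}
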