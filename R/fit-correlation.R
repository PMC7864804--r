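#' Global map versus model-map correlation scores
#'
#' Computes the family of global fit-to-map correlation scores from an
#' experimental map and a model-derived map on the same grid:
#' \describe{
#'   \item{ccbox / ccc}{Pearson correlation over every voxel of the grid
#'     (the two names are kept because the two lineages of tools report
#'     the same quantity under both).}
#'   \item{ccmask}{Pearson over voxels within `mask_radius` of any model
#'     atom ("only modeled regions").}
#'   \item{ccpeaks}{Pearson over the union of the top-k voxel sets of
#'     each map, with k equal to the model-mask voxel count
#'     ("high-density map and model regions").}
#'   \item{ccc_ov}{Pearson over the overlap region where each map
#'     exceeds half its own masked-mean density.}
#'   \item{lap}{Pearson of the discrete-Laplacian-filtered maps
#'     (6-neighbor stencil, interior voxels).}
#'   \item{mi / mi_ov}{mutual information (nats) of the joint density
#'     histogram with `mi_bins` equal-width bins per map, over the full
#'     grid / over the model mask.}
#' }
#'
#' Any score whose voxel selection has zero variance is returned as `NA`
#' and named in the `undefined` attribute rather than faked.
#'
#' @param map experimental [em_map()]
#' @param model_map model-derived [em_map()], congruent with `map`
#' @param model the [em_model()] (for the mask-based scores)
#' @param mask_radius model-mask radius in Angstrom
#' @param mi_bins number of equal-width histogram bins per map
#' @return object of class `em_ccset`: named list of scores
#' @export
correlation_scores <- function(map, model_map, model, mask_radius = 3,
                               mi_bins = 20) {
  check_congruent(map, model_map)
  x <- as.numeric(map$values); y <- as.numeric(model_map$values)
  mask <- mask_from_model(map, model, mask_radius)
  msk <- as.logical(mask$values)
  undefined <- character()
  pearson <- function(u, v, name) {
    if (length(u) < 2 || stats::sd(u) == 0 || stats::sd(v) == 0) {
      undefined <<- c(undefined, name); return(NA_real_)
    }
    stats::cor(u, v)
  }
  ccbox <- pearson(x, y, "ccbox")
  ccmask <- pearson(x[msk], y[msk], "ccmask")
  k <- sum(msk)
  topk <- function(v) {
    ord <- order(v, decreasing = TRUE)
    sel <- logical(length(v)); sel[ord[seq_len(min(k, length(v)))]] <- TRUE; sel
  }
  pk <- topk(x) | topk(y)
  ccpeaks <- pearson(x[pk], y[pk], "ccpeaks")
  thr_x <- 0.5 * mean(x[msk]); thr_y <- 0.5 * mean(y[msk])
  ov <- x > thr_x & y > thr_y
  ccc_ov <- if (sum(ov) >= 2) pearson(x[ov], y[ov], "ccc_ov") else {
    undefined <- c(undefined, "ccc_ov"); NA_real_
  }
  lx <- discrete_laplacian(map$values); ly <- discrete_laplacian(model_map$values)
  lap <- pearson(as.numeric(lx), as.numeric(ly), "lap")
  mi <- mutual_information(x, y, mi_bins)
  mi_ov <- mutual_information(x[msk], y[msk], mi_bins)
  structure(list(ccbox = ccbox, ccmask = ccmask, ccpeaks = ccpeaks,
                 ccc = ccbox, ccc_ov = ccc_ov, lap = lap,
                 mi = mi, mi_ov = mi_ov,
                 undefined = undefined, mask_voxels = k),
            class = "em_ccset")
}

#' @export
print.em_ccset <- function(x, ...) {
  for (nm in c("ccbox", "ccmask", "ccpeaks", "ccc_ov", "lap", "mi", "mi_ov"))
    cat(sprintf("  %-8s %s\n", nm, formatC(x[[nm]], digits = 4, format = "f")))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

## 6-neighbor discrete Laplacian on interior voxels.
discrete_laplacian <- function(v) {
  d <- dim(v)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  v[i + 1, j, k] + v[i - 1, j, k] + v[i, j + 1, k] + v[i, j - 1, k] +
    v[i, j, k + 1] + v[i, j, k - 1] - 6 * v[i, j, k]
}

## Mutual information (nats) of a joint equal-width-bin histogram.
## Bin edges span each vector's own range.
mutual_information <- function(x, y, bins = 20) {
  if (length(x) < 2) return(NA_real_)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) return(0)
  bx <- cut(x, breaks = seq(min(x), max(x), length.out = bins + 1),
            include.lowest = TRUE, labels = FALSE)
  by <- cut(y, breaks = seq(min(y), max(y), length.out = bins + 1),
            include.lowest = TRUE, labels = FALSE)
  p <- table(bx, by) / length(x)
  px <- rowSums(p); py <- colSums(p)
  pp <- as.numeric(p); pref <- as.numeric(outer(px, py))
  nz <- pp > 0
  sum(pp[nz] * log(pp[nz] / pref[nz]))
}

#' Segment-based Manders' overlap profile (SMOC)
#'
#' For each residue, computes the Manders' overlap coefficient
#' `sum(rho_map * rho_model) / sqrt(sum(rho_map^2) * sum(rho_model^2))`
#' over voxels within `mask_radius` of the atoms of a sliding window of
#' `window` residues centered on it (`window = 1` gives the
#' single-residue variant). The global score is the mean over scored
#' residues.
#'
#' @param map experimental [em_map()]
#' @param model an [em_model()]
#' @param model_map model-derived map congruent with `map`
#' @param window odd window length in residues (9 by convention)
#' @param mask_radius voxel selection radius, Angstrom
#' @return object of class `em_profile` (data.frame of per-residue
#'   scores) with attribute `global`
#' @export
smoc_profile <- function(map, model, model_map, window = 9, mask_radius = 3) {
  check_congruent(map, model_map)
  if (window < 1 || window %% 2 == 0) stop_emvalid("window must be odd and >= 1")
  ri <- residue_index(model)
  n <- length(ri)
  a <- model$atoms
  half <- (window - 1) / 2
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- max(1, i - half):min(n, i + half)
    rows <- unlist(ri[win], use.names = FALSE)
    rows <- rows[!a$is_h[rows]]
    if (!length(rows)) next
    xyz <- as.matrix(a[rows, c("x", "y", "z")])
    dist <- min_atom_distance_grid(map, xyz, mask_radius)
    sel <- dist <= mask_radius
    u <- map$values[sel]; v <- model_map$values[sel]
    den <- sqrt(sum(u^2) * sum(v^2))
    if (den > 0) scores[i] <- sum(u * v) / den
  }
  prof <- residue_profile(model, scores, metric = "smoc")
  attr(prof, "global") <- mean(scores, na.rm = TRUE)
  prof
}

## Shared per-residue profile constructor: one row per residue, explicit
## missing flag for unscored residues (never a fake 0).
residue_profile <- function(model, scores, metric) {
  a <- model$atoms
  ri <- residue_index(model)
  first <- vapply(ri, `[`, 1L, 1)
  structure(data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    resid = a$resid[first], score = scores, scored = !is.na(scores),
    stringsAsFactors = FALSE),
    metric = metric, class = c("em_profile", "data.frame"))
}
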