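#' Atom inclusion at a density threshold
#'
#' Fraction of non-hydrogen atoms whose (trilinearly interpolated) map
#' density is `>=` the threshold (ties count as inside), globally and
#' per residue.
#'
#' @param map an [em_map()]
#' @param model an [em_model()]
#' @param threshold density threshold (map units)
#' @return list with `global` fraction, and `profile` ([residue_profile])
#'   of per-residue fractions
#' @export
atom_inclusion <- function(map, model, threshold) {
  a <- model$atoms
  heavy <- which(!a$is_h)
  dens <- interpolate_density(map, as.matrix(a[heavy, c("x", "y", "z")]))
  inside <- dens >= threshold
  ri <- residue_index(model)
  per_res <- vapply(ri, function(r) {
    h <- intersect(r, heavy)
    if (!length(h)) return(NA_real_)
    mean(inside[match(h, heavy)])
  }, 1)
  list(global = mean(inside),
       profile = {
         p <- residue_profile(model, per_res, "atom_inclusion")
         attr(p, "global") <- mean(inside)
         p
       })
}

#' Envelope score
#'
#' Threshold-based score that also penalizes unmodeled density. The
#' density threshold is chosen so the enclosed volume equals
#' `molecular_weight * vol_per_dalton` (default 1.21 A^3/Da); the score
#' is the fraction of heavy atoms inside that envelope minus
#' `penalty_weight` times the fraction of envelope voxels farther than
#' `mask_radius` from any atom, clamped to `[-1, 1]`.
#'
#' @param map an [em_map()]
#' @param model an [em_model()]
#' @param molecular_weight sample molecular weight in Dalton
#' @param vol_per_dalton envelope volume per Dalton, A^3/Da
#' @param penalty_weight weight of the unmodeled-envelope penalty
#' @param mask_radius atom neighborhood radius for the penalty, Angstrom;
#'   the default 4 covers the vdW shell plus the density halo of a
#'   resolution-limited map at typical near-atomic resolutions, so a
#'   model filling its own simulated envelope scores close to 1
#' @return envelope score in `[-1, 1]`
#' @export
env_score <- function(map, model, molecular_weight, vol_per_dalton = 1.21,
                      penalty_weight = 1, mask_radius = 4) {
  if (molecular_weight <= 0) stop_emvalid("molecular_weight must be > 0")
  vox_vol <- prod(map$voxel_size)
  n_env <- round(molecular_weight * vol_per_dalton / vox_vol)
  if (n_env > length(map$values))
    stop_emvalid("envelope volume exceeds the map grid")
  if (n_env < 1) stop_emvalid("envelope volume below one voxel")
  v <- as.numeric(map$values)
  thr <- sort(v, decreasing = TRUE)[n_env]
  env <- map$values >= thr
  a <- model$atoms
  heavy <- which(!a$is_h)
  dens_in <- interpolate_density(map, as.matrix(a[heavy, c("x", "y", "z")]),
                                 fill = min(v) - 1)
  frac_in <- mean(dens_in >= thr)
  dist <- min_atom_distance_grid(map, as.matrix(a[heavy, c("x", "y", "z")]),
                                 mask_radius)
  frac_unmodeled <- sum(env & !(dist <= mask_radius)) / sum(env)
  max(-1, min(1, frac_in - penalty_weight * frac_unmodeled))
}
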