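#' Map-model Fourier shell correlation curve
#'
#' FSC per shell = `Re(sum(F1 * Conj(F2))) / sqrt(sum(|F1|^2) * sum(|F2|^2))`
#' over half-open uniform-width shells of spatial frequency, up to the
#' Nyquist frequency of the grid. An optional soft mask (e.g. from
#' [soft_mask_from_model()]) is applied to both maps before transforming.
#'
#' @param map,model_map congruent [em_map()]s with equal per-axis voxel size
#' @param soft_mask optional `em_map` of weights in `[0,1]`
#' @return object of class `em_fsc`: data.frame with shell center
#'   frequency (`freq`, 1/Angstrom), `fsc`, and Fourier term count `n`
#' @export
fsc_curve <- function(map, model_map, soft_mask = NULL) {
  check_congruent(map, model_map)
  v <- map$voxel_size
  if (max(abs(v - v[1])) > 1e-6 * v[1])
    stop_emvalid("FSC requires cubic sampling (equal voxel size per axis)")
  x <- map$values; y <- model_map$values
  if (!is.null(soft_mask)) {
    check_congruent(map, soft_mask, "map and soft mask")
    x <- x * soft_mask$values; y <- y * soft_mask$values
  }
  d <- dim(x)
  F1 <- stats::fft(x); F2 <- stats::fft(y)
  q <- freq_magnitude_grid(d, map$voxel_size)
  nyq <- 1 / (2 * v[1])
  df <- 1 / (max(d) * v[1])
  shell <- floor(q / df) + 1
  keep <- q <= nyq + 1e-12 & shell >= 1
  shell <- shell[keep]
  num <- Re(F1[keep] * Conj(F2[keep]))
  p1 <- Mod(F1[keep])^2; p2 <- Mod(F2[keep])^2
  s_num <- rowsum(num, shell); s_p1 <- rowsum(p1, shell); s_p2 <- rowsum(p2, shell)
  cnt <- rowsum(rep(1, length(shell)), shell)
  idx <- as.integer(rownames(s_num))
  den <- sqrt(s_p1 * s_p2)
  fsc <- ifelse(den > 0, s_num / den, NA_real_)
  out <- data.frame(freq = (idx - 0.5) * df, fsc = as.numeric(fsc),
                    n = as.integer(cnt))
  out <- out[order(out$freq), ]
  out <- out[out$n > 0 & !is.na(out$fsc), ]
  rownames(out) <- NULL
  structure(out, nyquist = nyq, class = c("em_fsc", "data.frame"))
}

#' Resolution at FSC = 0.5
#'
#' Reciprocal of the frequency at the first downward crossing of 0.5,
#' linearly interpolated between shell centers. If the curve never drops
#' below 0.5 the Nyquist-limit resolution is returned with attribute
#' `at_limit = TRUE` (flagged, not silently clamped).
#'
#' @param curve an `em_fsc` from [fsc_curve()]
#' @return resolution in Angstrom with attribute `at_limit`
#' @export
fsc05 <- function(curve) {
  if (!nrow(curve)) stop_emvalid("empty FSC curve")
  f <- curve$freq; s <- curve$fsc
  for (i in seq_along(s)) {
    if (s[i] < 0.5) {
      if (i == 1) return(structure(1 / f[1], at_limit = FALSE))
      f_cross <- f[i - 1] + (0.5 - s[i - 1]) * (f[i] - f[i - 1]) / (s[i] - s[i - 1])
      return(structure(1 / f_cross, at_limit = FALSE))
    }
  }
  structure(1 / attr(curve, "nyquist"), at_limit = TRUE)
}

#' Area under the FSC curve to a resolution limit
#'
#' Term-count-weighted mean of FSC over shells with center frequency
#' `<= 1/d_limit` (all shells from the origin up to the limit).
#'
#' @param curve an `em_fsc`
#' @param d_limit integration resolution limit in Angstrom
#' @return FSCavg score
#' @export
fsc_avg <- function(curve, d_limit) {
  if (1 / d_limit > attr(curve, "nyquist") + 1e-12)
    stop_emvalid("d_limit %.3g A is beyond the Nyquist limit", d_limit)
  sel <- curve$freq <= 1 / d_limit
  if (!any(sel)) stop_emvalid("no FSC shells below the resolution limit")
  sum(curve$fsc[sel] * curve$n[sel]) / sum(curve$n[sel])
}
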