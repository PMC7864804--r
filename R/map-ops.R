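#' Trilinear interpolation of map density
#'
#' @param map an [em_map()]
#' @param xyz query point(s): length-3 vector or n x 3 matrix (Angstrom)
#' @param fill value returned for points outside the grid (default 0,
#'   matching the zero background of masked maps)
#' @return numeric vector of interpolated densities
#' @export
interpolate_density <- function(map, xyz, fill = 0) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  d <- map_dims(map)
  ## fractional voxel coordinates (0-based)
  t <- sweep(sweep(xyz, 2, map$origin, "-"), 2, map$voxel_size, "/")
  out <- rep(fill, nrow(xyz))
  ## inside the grid (points exactly on the upper face included)
  ok <- t[, 1] >= 0 & t[, 2] >= 0 & t[, 3] >= 0 &
    t[, 1] <= d[1] - 1 & t[, 2] <= d[2] - 1 & t[, 3] <= d[3] - 1
  i0 <- pmin(floor(t), matrix(rep(d - 2, each = nrow(t)), ncol = 3))
  i0 <- pmax(i0, 0)
  fr <- t - i0
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fr <- fr[ok, , drop = FALSE]
  v <- map$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  val <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 1, 0) * fx * fy * (1 - fz) +
    idx(1, 0, 1) * fx * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy * fz +
    idx(1, 1, 1) * fx * fy * fz
  out[ok] <- val
  out
}

## Per-voxel minimum distance to any atom, computed only within `radius`
## of each atom (Inf elsewhere). Brute force over per-atom bounding boxes.
min_atom_distance_grid <- function(map, xyz, radius) {
  d <- map_dims(map)
  dist <- array(Inf, dim = d)
  ax <- axis_coords(map)
  for (k in seq_len(nrow(xyz))) {
    p <- xyz[k, ]
    rng <- lapply(1:3, function(i) {
      lo <- max(1, ceiling((p[i] - radius - map$origin[i]) / map$voxel_size[i]) + 1)
      hi <- min(d[i], floor((p[i] + radius - map$origin[i]) / map$voxel_size[i]) + 1)
      if (lo > hi) integer() else seq.int(lo, hi)
    })
    if (any(lengths(rng) == 0)) next
    dx <- ax[[1]][rng[[1]]] - p[1]
    dy <- ax[[2]][rng[[2]]] - p[2]
    dz <- ax[[3]][rng[[3]]] - p[3]
    dd <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    sub <- dist[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    dist[rng[[1]], rng[[2]], rng[[3]]] <- pmin(sub, dd)
  }
  dist
}

#' Mask of voxels near model atoms
#'
#' A voxel is selected iff its Cartesian center lies within `radius` of
#' any non-hydrogen atom of the model.
#'
#' @param map an [em_map()] providing the grid geometry
#' @param model an [em_model()]
#' @param radius inclusion radius in Angstrom (> 0)
#' @param sel optional atom-row selection (defaults to all heavy atoms)
#' @return an [em_mask()] with provenance `"model-radius"`
#' @export
mask_from_model <- function(map, model, radius = 3, sel = NULL) {
  if (radius <= 0) stop_emvalid("mask radius must be > 0")
  a <- model$atoms
  keep <- if (is.null(sel)) !a$is_h else sel & !a$is_h
  xyz <- as.matrix(a[keep, c("x", "y", "z")])
  if (!nrow(xyz)) stop_emvalid("empty model: no heavy atoms to mask around")
  dist <- min_atom_distance_grid(map, xyz, radius)
  em_mask(dist <= radius, map, "model-radius")
}

#' Soft (cosine-tapered) model mask
#'
#' Weight 1 within `radius` of any heavy atom, cosine falloff to 0 over
#' `taper` Angstrom beyond, 0 elsewhere. Used to soften map edges before
#' map-model FSC.
#'
#' @inheritParams mask_from_model
#' @param taper taper width in Angstrom
#' @return an `em_map` of weights in [0, 1]
#' @export
soft_mask_from_model <- function(map, model, radius = 3, taper = 3) {
  a <- model$atoms
  xyz <- as.matrix(a[!a$is_h, c("x", "y", "z")])
  dist <- min_atom_distance_grid(map, xyz, radius + taper)
  w <- array(0, dim = dim(dist))
  w[dist <= radius] <- 1
  band <- dist > radius & dist <= radius + taper
  w[band] <- 0.5 * (1 + cos(pi * (dist[band] - radius) / taper))
  em_map(w, map$voxel_size, map$origin)
}
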