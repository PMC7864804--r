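#' Density map on a regular orthogonal voxel grid
#'
#' An `em_map` holds a scalar density field sampled on an axis-aligned
#' orthogonal grid: a 3D array `values` with x the fastest-varying index,
#' per-axis voxel size (Angstrom) and the Cartesian position of voxel
#' (1,1,1)'s center (`origin`, Angstrom). The Cartesian center of voxel
#' (i,j,k) (1-based) is `origin + (i-1, j-1, k-1) * voxel_size`.
#'
#' @param values numeric 3D array (nx, ny, nz), all finite
#' @param voxel_size voxel edge lengths in Angstrom (scalar or length 3)
#' @param origin Cartesian position of the first voxel center (length 3)
#' @return object of class `em_map`
#' @export
em_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop_emvalid("values must be a 3D array")
  if (any(dim(values) < 2)) stop_emvalid("all map dimensions must be >= 2")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop_emvalid("voxel sizes must be positive")
  if (!all(is.finite(values))) stop_emvalid("map values must be finite")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "em_map")
}

#' @export
print.em_map <- function(x, ...) {
  cat(sprintf("em_map: %s voxels, voxel %s A, origin (%s) A, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

map_dims <- function(map) dim(map$values)

## Geometry congruence; mismatches are hard errors everywhere (maps are
## never silently regridded).
check_congruent <- function(a, b, what = "maps") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_size - b$voxel_size)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-4)
    stop_emvalid("incongruent %s: dims/voxel size/origin must match exactly", what)
  invisible(TRUE)
}

## Voxel-center Cartesian coordinates along each axis.
axis_coords <- function(map) {
  d <- map_dims(map)
  lapply(1:3, function(i) map$origin[i] + (seq_len(d[i]) - 1) * map$voxel_size[i])
}

#' Mask congruent with a density map
#'
#' @param values logical 3D array congruent with the parent map
#' @param map the parent `em_map` (geometry is copied)
#' @param provenance short tag describing how the mask was made
#' @return object of class `em_mask`
#' @export
em_mask <- function(values, map, provenance = "unspecified") {
  if (!identical(dim(values), dim(map$values)))
    stop_emvalid("mask dims must match parent map")
  structure(list(values = values, voxel_size = map$voxel_size,
                 origin = map$origin, provenance = provenance),
            class = "em_mask")
}

#' @export
print.em_mask <- function(x, ...) {
  cat(sprintf("em_mask (%s): %d/%d voxels true\n", x$provenance,
              sum(x$values), length(x$values)))
  invisible(x)
}
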