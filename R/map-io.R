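## MRC/CCP4 2014 map I/O (modes 0/1/2, orthogonal cells, little-endian).

MRC_HEADER_BYTES <- 1024L

#' Read an MRC/CCP4 density map
#'
#' Reads MRC2014 files in mode 0 (int8), 1 (int16) or 2 (float32). The
#' axis order is canonicalized to x-fastest regardless of the file's
#' MAPC/MAPR/MAPS permutation. The origin is taken from the ORIGIN header
#' record when any component is nonzero, otherwise from
#' NXSTART/NYSTART/NZSTART times the voxel size. Non-orthogonal cells are
#' not supported and raise an error.
#'
#' @param path file path
#' @return an [em_map()]
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop_emvalid("file not found: %s", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES) stop_emvalid("truncated MRC file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  n_crs <- ri(3)
  mode <- ri(1)
  nstart <- ri(3)
  m_xyz <- ri(3)
  cella <- rf(3)
  cellb <- rf(3)
  map_crs <- ri(3)
  invisible(rf(3))            # DMIN/DMAX/DMEAN (recomputed on write)
  invisible(ri(1))            # ISPG
  nsymbt <- ri(1)
  invisible(readBin(con, "raw", n = 25 * 4))   # extra words 26-49 incl. EXTTYP
  origin_rec <- rf(3)
  magic <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 4))        # MACHST
  invisible(rf(1))                             # RMS
  invisible(ri(1))                             # NLABL
  invisible(readBin(con, "raw", n = 800))      # labels

  if (!mode %in% c(0L, 1L, 2L))
    stop_emvalid("unsupported MRC mode %d (only 0/1/2)", mode)
  if (max(abs(cellb - 90)) > 1e-3)
    stop_emvalid("non-orthogonal cell (angles %s) unsupported",
                 paste(signif(cellb, 5), collapse = "/"))
  if (!identical(sort(map_crs), 1:3))
    stop_emvalid("invalid MAPC/MAPR/MAPS permutation")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))

  nvox <- prod(n_crs)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(vals) < nvox) stop_emvalid("truncated MRC data section: %s", path)
  arr <- array(vals, dim = n_crs)
  ## canonicalize: file dims are (columns, rows, sections); MAPC/R/S say
  ## which Cartesian axis each corresponds to
  perm <- match(1:3, map_crs)
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  m_xyz[m_xyz <= 0] <- dim(arr)[m_xyz <= 0]
  voxel <- cella / m_xyz
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop_emvalid("invalid cell/sampling in MRC header")
  origin <- if (any(abs(origin_rec) > 0)) origin_rec else nstart_xyz * voxel
  if (!identical(magic, "MAP ") && !identical(magic, "MAP\t"))
    warning("MRC file lacks 'MAP ' magic; parsed as little-endian MRC2014")
  em_map(arr, voxel, origin)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Writes an x-fastest mode-2 (float32) MRC2014 file with
#' `CELLA = dims * voxel_size`, the ORIGIN record set from the map origin
#' and DMIN/DMAX/DMEAN/RMS recomputed from the data.
#'
#' @param map an [em_map()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_density <- function(map, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_emvalid("cannot open %s for writing", path))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d <- map_dims(map)
  v <- as.numeric(map$values)
  wi(d); wi(2L)                      # NX NY NZ, MODE 2
  wi(c(0L, 0L, 0L))                  # NXSTART
  wi(d)                              # MX MY MZ
  wf(d * map$voxel_size)             # CELLA
  wf(c(90, 90, 90))                  # CELLB
  wi(1:3)                            # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))     # DMIN DMAX DMEAN
  wi(c(1L, 0L))                      # ISPG, NSYMBT
  writeBin(raw(25 * 4), con)         # extra
  wf(map$origin)                     # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))                   # RMS
  wi(0L)                             # NLABL
  writeBin(raw(800), con)            # labels
  wf(v)
  invisible(path)
}
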