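## Shared fixtures, oracles and caches for the test suite.

## Memoized synthetic reference distributions (expensive to build).
.ref_cache <- new.env(parent = emptyenv())
get_reference <- function(kind) {
  if (is.null(.ref_cache[[kind]]))
    .ref_cache[[kind]] <- reference_from_fixtures(kind, seed = 42,
                                                  n_models = 20,
                                                  n_residues = 14)
  .ref_cache[[kind]]
}

## Memoized standard helix + simulated map pair.
.fix_cache <- new.env(parent = emptyenv())
get_helix_map <- function() {
  if (is.null(.fix_cache$hm)) {
    model <- build_fixture("helix", 12)
    map <- simulate_map(model, 2.0, noise_sigma = 0.05, seed = 11)
    model_map <- simulate_map(model, 2.0, grid = map)
    .fix_cache$hm <- list(model = model, map = map, model_map = model_map)
  }
  .fix_cache$hm
}

## Single-atom model at a given position.
one_atom <- function(xyz = c(0, 0, 0), element = "C", resid = "ALA",
                     atom = "CA") {
  em_model(data.frame(chain = "A", resno = 1L, resid = resid, atom = atom,
                      element = element, x = xyz[1], y = xyz[2], z = xyz[3]))
}

## Map whose voxel values follow A*exp(-r^2/(2 sigma^2)) + B around a
## center point (the Q-score reference profile sampled at voxel centers).
gaussian_map <- function(center = c(0, 0, 0), sigma = 0.6, A = 1, B = 0,
                         half = 3, voxel = 0.2) {
  n <- 2 * half / voxel + 1
  ax <- seq(-half, half, by = voxel)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  vals <- A * exp(-r2 / (2 * sigma^2)) + B
  em_map(vals, voxel, center - half)
}

## Raw MRC writer with full header control (axis permutations, modes,
## cell angles) for exercising the reader; independent of write_density.
write_raw_mrc <- function(path, arr, voxel = 1, mapcrs = 1:3, mode = 2L,
                          cellb = c(90, 90, 90), origin = c(0, 0, 0),
                          nstart = c(0L, 0L, 0L)) {
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  ## arr is in xyz order; file stores axis mapcrs[1] fastest
  file_arr <- aperm(arr, mapcrs)
  d_file <- dim(file_arr)
  d_xyz <- dim(arr)
  wi(d_file); wi(mode)
  wi(nstart[mapcrs])
  wi(d_xyz)
  wf(d_xyz * voxel); wf(cellb)
  wi(mapcrs)
  wf(c(min(arr), max(arr), mean(arr)))
  wi(c(1L, 0L)); writeBin(raw(100), con)
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(stats::sd(as.numeric(arr))); wi(0L); writeBin(raw(800), con)
  v <- as.numeric(file_arr)
  if (mode == 2L) wf(v)
  else if (mode == 1L) writeBin(as.integer(v), con, size = 2, endian = "little")
  else writeBin(as.integer(v), con, size = 1)
  invisible(path)
}

## Brute-force Pearson from first principles (no stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Direct-DFT FSC oracle: recompute shell-wise FSC from an O(N^2)
## discrete Fourier transform, independent of stats::fft and of the
## package's shell bookkeeping.
fsc_oracle <- function(a, b, voxel) {
  d <- dim(a)
  dft <- function(v) {
    out <- array(0i, dim = d)
    for (k1 in 0:(d[1] - 1)) for (k2 in 0:(d[2] - 1)) for (k3 in 0:(d[3] - 1)) {
      ph <- outer(outer(0:(d[1] - 1) * k1 / d[1],
                        0:(d[2] - 1) * k2 / d[2], "+"),
                  0:(d[3] - 1) * k3 / d[3], "+")
      out[k1 + 1, k2 + 1, k3 + 1] <- sum(v * exp(-2i * pi * ph))
    }
    out
  }
  FA <- dft(a); FB <- dft(b)
  fr <- function(n) c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  q <- sqrt(outer(outer((fr(d[1]) / voxel)^2, (fr(d[2]) / voxel)^2, "+"),
                  (fr(d[3]) / voxel)^2, "+"))
  df <- 1 / (max(d) * voxel); nyq <- 1 / (2 * voxel)
  shell <- floor(q / df) + 1
  keep <- q <= nyq + 1e-12
  out <- list()
  for (s in sort(unique(shell[keep]))) {
    sel <- keep & shell == s
    den <- sqrt(sum(Mod(FA[sel])^2) * sum(Mod(FB[sel])^2))
    if (den > 0)
      out[[length(out) + 1]] <- data.frame(
        freq = (s - 0.5) * df, fsc = sum(Re(FA[sel] * Conj(FB[sel]))) / den)
  }
  do.call(rbind, out)
}

## Grid-search rigid superposition oracle: coarse-to-fine search over
## Euler angles (translation solved by centroid matching at each
## rotation), independent of the SVD path.
superpose_oracle <- function(P, Q) {
  euler <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  eval_rot <- function(R) sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  ## global coarse pass over all of SO(3), then refine the best candidates
  coarse <- as.matrix(expand.grid(a = seq(0, 340, 20), b = seq(0, 180, 20),
                                  c = seq(0, 340, 20)))
  rs <- vapply(seq_len(nrow(coarse)), function(g)
    eval_rot(euler(coarse[g, 1] * pi / 180, coarse[g, 2] * pi / 180,
                   coarse[g, 3] * pi / 180)), 1)
  seeds <- coarse[order(rs)[1:8], , drop = FALSE]
  best_all <- Inf
  for (s in seq_len(nrow(seeds))) {
    best <- seeds[s, ]; best_r <- Inf
    for (step in c(4, 0.8, 0.16, 0.032)) {
      grid <- as.matrix(expand.grid(
        a = best[1] + seq(-2.5 * step, 2.5 * step, by = step),
        b = best[2] + seq(-2.5 * step, 2.5 * step, by = step),
        c = best[3] + seq(-2.5 * step, 2.5 * step, by = step)))
      for (g in seq_len(nrow(grid))) {
        r <- eval_rot(euler(grid[g, 1] * pi / 180, grid[g, 2] * pi / 180,
                            grid[g, 3] * pi / 180))
        if (r < best_r) { best_r <- r; best <- grid[g, ] }
      }
    }
    best_all <- min(best_all, best_r)
  }
  best_all
}

## Closed-form spherical-cap buried area for two spheres (independent
## rederivation used against cad_score internals).
cap_area_oracle <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 * pi * min(r1, r2)^2)
  x <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x
  h2 <- r2 - (d - x)
  2 * pi * r1 * h1 + 2 * pi * r2 * h2
}
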