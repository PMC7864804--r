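## Pluggable conformational reference distributions: smoothed frequency
## grids over backbone/side-chain angle spaces with percentile-based
## outlier cutoffs. Production-quality grids derived from curated PDB
## ensembles can be loaded from text files; the package also builds
## synthetic stand-in grids from jittered ideal fixtures so the full
## outlier machinery runs without any external data.

#' Build a reference frequency distribution from angle observations
#'
#' Observations are binned on a regular (optionally periodic) grid,
#' smoothed with a separable wrapped Gaussian kernel, and normalized to
#' per-bin probabilities. Outlier/disfavored cutoffs are the 1st/5th
#' percentiles of the reference observations' own bin frequencies (the
#' MolProbity convention): a query whose bin frequency falls below the
#' outlier cutoff is rarer than 99% of the reference population.
#'
#' @param obs numeric matrix (n x d) of angle observations, degrees
#' @param dims list of per-dimension specs: `list(name=, min=, max=,
#'   nbins=, periodic=)`
#' @param smooth_bins Gaussian smoothing sigma, in bins
#' @param cutoffs percentile cutoffs in (0, 100)
#' @return object of class `em_refdist`
#' @export
build_reference <- function(obs, dims, smooth_bins = 1.5,
                            cutoffs = c(outlier = 1, disfavored = 5)) {
  obs <- as.matrix(obs)
  d <- length(dims)
  stopifnot(ncol(obs) == d, all(cutoffs > 0 & cutoffs < 100))
  nb <- vapply(dims, `[[`, 1, "nbins")
  idx <- matrix(0L, nrow(obs), d)
  for (k in seq_len(d)) idx[, k] <- bin_index(obs[, k], dims[[k]])
  counts <- array(0, dim = nb)
  lin <- as.integer(idx[, 1])
  if (d > 1) for (k in 2:d) lin <- lin + (idx[, k] - 1L) * as.integer(prod(nb[1:(k - 1)]))
  tab <- table(lin)
  counts[as.integer(names(tab))] <- as.integer(tab)
  freq <- smooth_grid(counts, smooth_bins, vapply(dims, `[[`, TRUE, "periodic"))
  freq <- freq / sum(freq)
  obs_freq <- freq[matrix(idx, ncol = d)]
  cut_vals <- stats::quantile(obs_freq, probs = cutoffs / 100, names = FALSE)
  structure(list(dims = dims, freq = freq,
                 cutoff_values = stats::setNames(cut_vals, names(cutoffs)),
                 cutoff_percentiles = cutoffs, n_obs = nrow(obs)),
            class = "em_refdist")
}

bin_index <- function(x, spec) {
  if (spec$periodic) {
    width <- (spec$max - spec$min) / spec$nbins
    i <- floor(((x - spec$min) %% (spec$max - spec$min)) / width) + 1
  } else {
    width <- (spec$max - spec$min) / spec$nbins
    i <- floor((pmin(pmax(x, spec$min), spec$max - 1e-9) - spec$min) / width) + 1
  }
  as.integer(pmin(pmax(i, 1), spec$nbins))
}

## Separable Gaussian smoothing; periodic dims wrap.
smooth_grid <- function(counts, sigma, periodic) {
  if (sigma <= 0) return(counts)
  out <- counts
  nb <- dim(counts) %||% length(counts)
  if (is.null(dim(counts))) dim(out) <- length(out)
  for (k in seq_along(nb)) {
    n <- nb[k]
    half <- max(1L, ceiling(3 * sigma))
    off <- -half:half
    w <- exp(-off^2 / (2 * sigma^2)); w <- w / sum(w)
    sm <- array(0, dim = dim(out))
    for (m in seq_along(off)) {
      sh <- shift_along(out, k, off[m], periodic[k])
      sm <- sm + w[m] * sh
    }
    out <- sm
  }
  out
}

shift_along <- function(arr, dimn, by, wrap) {
  n <- dim(arr)[dimn]
  idx <- seq_len(n) - by
  if (wrap) {
    idx <- ((idx - 1) %% n) + 1
    sel <- lapply(dim(arr), seq_len)
    sel[[dimn]] <- idx
    return(do.call(`[`, c(list(arr), sel, list(drop = FALSE))))
  }
  out <- array(0, dim = dim(arr))
  valid <- idx >= 1 & idx <= n
  if (!any(valid)) return(out)
  src <- lapply(dim(arr), seq_len); src[[dimn]] <- idx[valid]
  dstv <- lapply(dim(arr), seq_len); dstv[[dimn]] <- which(valid)
  do.call(`[<-`, c(list(out), dstv,
                   list(value = do.call(`[`, c(list(arr), src,
                                               list(drop = FALSE))))))
}

#' Look up bin frequencies for angle queries
#'
#' @param ref an `em_refdist`
#' @param x query matrix (n x d), degrees
#' @return numeric vector of bin probabilities
#' @export
reference_frequency <- function(ref, x) {
  x <- matrix(x, ncol = length(ref$dims))
  idx <- matrix(0L, nrow(x), length(ref$dims))
  for (k in seq_along(ref$dims)) idx[, k] <- bin_index(x[, k], ref$dims[[k]])
  ref$freq[matrix(idx, ncol = length(ref$dims))]
}

#' @export
print.em_refdist <- function(x, ...) {
  cat(sprintf("em_refdist: %s grid, %d observations, outlier cutoff %.3g\n",
              paste(vapply(x$dims, `[[`, 1, "nbins"), collapse = "x"),
              x$n_obs, x$cutoff_values["outlier"]))
  invisible(x)
}

#' Write / read a reference distribution as plain text
#'
#' Versioned text serialization: a JSON header line (dimension specs,
#' cutoffs) followed by one frequency per line in array order.
#'
#' @param ref an `em_refdist`
#' @param path file path
#' @return `ref` (read) or `path` invisibly (write)
#' @export
write_reference <- function(ref, path) {
  hdr <- jsonlite::toJSON(list(version = 1L, dims = ref$dims,
                               cutoff_values = as.list(ref$cutoff_values),
                               cutoff_percentiles = as.list(ref$cutoff_percentiles),
                               n_obs = ref$n_obs),
                          auto_unbox = TRUE, digits = NA)
  writeLines(c(as.character(hdr), format(as.numeric(ref$freq), digits = 17)), path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  dims <- lapply(hdr$dims, function(d)
    list(name = d$name, min = d$min, max = d$max, nbins = as.integer(d$nbins),
         periodic = isTRUE(d$periodic)))
  freq <- as.numeric(lines[-1])
  structure(list(dims = dims,
                 freq = array(freq, dim = vapply(dims, `[[`, 1, "nbins")),
                 cutoff_values = unlist(hdr$cutoff_values),
                 cutoff_percentiles = unlist(hdr$cutoff_percentiles),
                 n_obs = hdr$n_obs),
            class = "em_refdist")
}

## ---- observation collectors ------------------------------------------

## Contiguous chain stretches: runs of consecutive residues in one chain
## with CA-CA distance <= 4.5 A (chain breaks terminate stretches).
chain_stretches <- function(model, break_cut = 4.5) {
  ri <- residue_index(model)
  a <- model$atoms
  ca <- lapply(ri, function(r) atom_xyz(model, r, "CA"))
  stretches <- list(); cur <- c()
  for (i in seq_along(ri)) {
    if (length(cur)) {
      prev <- cur[length(cur)]
      linked <- a$chain[ri[[i]][1]] == a$chain[ri[[prev]][1]] &&
        !is.null(ca[[i]]) && !is.null(ca[[prev]]) &&
        vnorm(ca[[i]] - ca[[prev]]) <= break_cut
      if (!linked) { stretches[[length(stretches) + 1]] <- cur; cur <- c() }
    }
    if (!is.null(ca[[i]])) cur <- c(cur, i) else if (length(cur)) {
      stretches[[length(stretches) + 1]] <- cur; cur <- c()
    }
  }
  if (length(cur)) stretches[[length(stretches) + 1]] <- cur
  stretches
}

## phi/psi observations: list(res_index, obs matrix).
rama_observations <- function(model) {
  ri <- residue_index(model)
  idx <- c(); obs <- list()
  for (st in chain_stretches(model)) {
    if (length(st) < 3) next
    for (p in 2:(length(st) - 1)) {
      i <- st[p]
      c0 <- atom_xyz(model, ri[[st[p - 1]]], "C")
      nn <- atom_xyz(model, ri[[i]], "N"); ca <- atom_xyz(model, ri[[i]], "CA")
      cc <- atom_xyz(model, ri[[i]], "C"); n1 <- atom_xyz(model, ri[[st[p + 1]]], "N")
      if (is.null(c0) || is.null(nn) || is.null(ca) || is.null(cc) || is.null(n1)) next
      idx <- c(idx, i)
      obs[[length(obs) + 1]] <- c(dihedral(c0, nn, ca, cc), dihedral(nn, ca, cc, n1))
    }
  }
  list(index = idx, obs = if (length(obs)) do.call(rbind, obs) else
    matrix(numeric(), ncol = 2))
}

## chi1 observations for side-chain-bearing residues.
chi1_observations <- function(model) {
  ri <- residue_index(model)
  a <- model$atoms
  idx <- c(); obs <- c()
  for (i in seq_along(ri)) {
    r <- ri[[i]]
    gamma <- intersect(c("CG", "CG1", "OG", "OG1", "SG"), a$atom[r])
    if (!length(gamma)) next
    nn <- atom_xyz(model, r, "N"); ca <- atom_xyz(model, r, "CA")
    cb <- atom_xyz(model, r, "CB")
    if (is.null(nn) || is.null(ca) || is.null(cb)) next
    idx <- c(idx, i)
    obs <- c(obs, dihedral(nn, ca, cb, atom_xyz(model, r, gamma[1])) %% 360)
  }
  list(index = idx, obs = matrix(obs, ncol = 1))
}

## CaBLAM virtual-dihedral observations for residue i (needs CA of
## i-2..i+2 in one stretch): mu_in = dihedral(CA i-2,i-1,i,i+1),
## mu_out = dihedral(CA i-1,i,i+1,i+2), plus either the virtual dihedral
## of the CO directions flanking i (kind "cablam") or the CA virtual
## angle at i (kind "calpha").
cablam_observations <- function(model, kind = c("cablam", "calpha")) {
  kind <- match.arg(kind)
  ri <- residue_index(model)
  idx <- c(); obs <- list()
  for (st in chain_stretches(model)) {
    if (length(st) < 5) next
    for (p in 3:(length(st) - 2)) {
      i <- st[p]
      ca <- lapply(st[(p - 2):(p + 2)], function(j) atom_xyz(model, ri[[j]], "CA"))
      if (any(vapply(ca, is.null, TRUE))) next
      mu_in <- dihedral(ca[[1]], ca[[2]], ca[[3]], ca[[4]])
      mu_out <- dihedral(ca[[2]], ca[[3]], ca[[4]], ca[[5]])
      third <- if (kind == "cablam") {
        o0 <- atom_xyz(model, ri[[st[p - 1]]], "O")
        c0 <- atom_xyz(model, ri[[st[p - 1]]], "C")
        o1 <- atom_xyz(model, ri[[i]], "O")
        c1 <- atom_xyz(model, ri[[i]], "C")
        if (is.null(o0) || is.null(c0) || is.null(o1) || is.null(c1)) next
        dihedral(o0, c0, c1, o1)
      } else {
        bond_angle(ca[[2]], ca[[3]], ca[[4]])
      }
      idx <- c(idx, i)
      obs[[length(obs) + 1]] <- c(mu_in, mu_out, third)
    }
  }
  list(index = idx, obs = if (length(obs)) do.call(rbind, obs) else
    matrix(numeric(), ncol = 3))
}

## ---- synthetic stand-in references -----------------------------------

#' Synthetic reference distributions from jittered fixtures
#'
#' Builds a reference distribution of the requested kind from an
#' ensemble of ideal fixtures whose backbone torsions are sampled across
#' the major conformational basins (alpha: phi in [-100,-40], psi in
#' [-70,-10]; broad beta/PPII: phi in [-160,-50], psi in [90,175];
#' left-handed alpha: phi in [40,80], psi in [20,80]) and whose
#' coordinates are jittered. This emulates the *coverage* of grids
#' derived from high-quality PDB ensembles at desk scale; it is a
#' synthetic stand-in, not a curated PDB-derived grid, and basin shapes
#' are cruder than the real thing.
#'
#' @param kind `"rama"`, `"rotamer"`, `"cablam"` or `"calpha"`
#' @param seed RNG seed for basin sampling and jitter
#' @param n_models fixtures per basin
#' @param n_residues residues per fixture
#' @param jitter coordinate jitter RMS, Angstrom
#' @return an `em_refdist`
#' @export
reference_from_fixtures <- function(kind = c("rama", "rotamer", "cablam", "calpha"),
                                    seed = 1, n_models = 25, n_residues = 16,
                                    jitter = 0.1) {
  kind <- match.arg(kind)
  basins <- list(alpha = list(phi = c(-100, -40), psi = c(-70, -10)),
                 beta = list(phi = c(-160, -50), psi = c(90, 175)),
                 alpha_left = list(phi = c(40, 80), psi = c(20, 80)))
  rotamer_centers <- c(60, 180, 300)
  obs <- list()
  with_seed(seed, {
    for (b in names(basins)) {
      for (m in seq_len(n_models)) {
        ## per-residue torsion sampling across the basin box: one model
        ## contributes n_residues-2 distinct basin conformers
        phi <- stats::runif(n_residues, basins[[b]]$phi[1], basins[[b]]$phi[2])
        psi <- stats::runif(n_residues, basins[[b]]$psi[1], basins[[b]]$psi[2])
        chi <- sample(rotamer_centers, 1) + stats::runif(1, -15, 15)
        base_kind <- if (b == "alpha_left") "alpha_left" else
          if (b == "alpha") "helix" else "strand"
        fx <- build_fixture(base_kind, n_residues, chi1 = chi,
                            phi = phi, psi = psi)
        fx <- perturb_jitter(fx, jitter, seed = sample.int(2^30, 1))
        o <- switch(kind,
          rama = rama_observations(fx),
          rotamer = chi1_observations(fx),
          cablam = cablam_observations(fx, "cablam"),
          calpha = cablam_observations(fx, "calpha"))
        if (nrow(o$obs)) obs[[length(obs) + 1]] <- o$obs
      }
    }
  })
  obs <- do.call(rbind, obs)
  dims <- switch(kind,
    rama = list(list(name = "phi", min = -180, max = 180, nbins = 72, periodic = TRUE),
                list(name = "psi", min = -180, max = 180, nbins = 72, periodic = TRUE)),
    rotamer = list(list(name = "chi1", min = 0, max = 360, nbins = 36, periodic = TRUE)),
    cablam = list(list(name = "mu_in", min = -180, max = 180, nbins = 24, periodic = TRUE),
                  list(name = "mu_out", min = -180, max = 180, nbins = 24, periodic = TRUE),
                  list(name = "nu_co", min = -180, max = 180, nbins = 24, periodic = TRUE)),
    calpha = list(list(name = "mu_in", min = -180, max = 180, nbins = 24, periodic = TRUE),
                  list(name = "mu_out", min = -180, max = 180, nbins = 24, periodic = TRUE),
                  list(name = "ca_angle", min = 0, max = 180, nbins = 18, periodic = FALSE)))
  build_reference(obs, dims)
}
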