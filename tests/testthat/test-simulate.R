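## phi/psi of a model via the internal observation collector
rama_observations_of <- function(m) emvalid:::rama_observations(m)$obs

test_that("fixtures are built at their ideal backbone torsions", {
  m <- build_fixture("helix", 10)
  tors <- rama_observations_of(m)
  expect_true(all(abs(tors[, 1] - (-57)) < 0.1))
  expect_true(all(abs(tors[, 2] - (-47)) < 0.1))
  s <- build_fixture("strand", 6)
  tors_s <- rama_observations_of(s)
  expect_true(all(abs(tors_s[, 1] - (-120)) < 0.1))
  expect_true(all(abs(tors_s[, 2] - 120) < 0.1))
})

test_that("fixtures score zero geometry RMSD against the shipped library", {
  g <- geometry_rmsd(build_fixture("helix", 10))
  expect_lt(g$bond, 1e-6)
  expect_lt(g$angle, 1e-6)
  expect_lt(g$chiral, 1e-6)
  expect_lt(g$planar, 1e-6)
  expect_lt(g$dihedral, 1e-6)
})

test_that("strands are more extended than helices", {
  h <- build_fixture("helix", 10); s <- build_fixture("strand", 10)
  ca_dist <- function(m, i, j) {
    ri <- emvalid:::residue_index(m)
    sqrt(sum((emvalid:::atom_xyz(m, ri[[i]], "CA") -
                emvalid:::atom_xyz(m, ri[[j]], "CA"))^2))
  }
  expect_gt(ca_dist(s, 2, 4), ca_dist(h, 2, 4))
})

test_that("fixture input validation", {
  expect_error(build_fixture("helix", 3), "n_residues")
  expect_error(build_fixture("helix", 5, sequence = "AA"), "length")
  expect_error(build_fixture("helix", 4, sequence = "AAAW"), "A/G/L")
})

test_that("simulated single-atom density peaks at the atom, radially symmetric", {
  m <- one_atom(c(0, 0, 0))
  map <- simulate_map(m, 2, voxel_size = 0.5, padding = 6)
  pk <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  expect_equal(unname(map$origin + (pk - 1) * map$voxel_size), c(0, 0, 0))
  ## radial symmetry within interpolation error
  d1 <- interpolate_density(map, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                       c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1)))
  expect_lt(diff(range(d1)) / max(abs(d1)), 0.05)
})

test_that("resolution cutoff suppresses high-frequency power", {
  m <- build_fixture("helix", 8)
  mk <- function(res) simulate_map(m, res, voxel_size = 0.6, padding = 5)
  hi <- mk(2); lo <- simulate_map(m, 4, grid = hi)
  power_beyond <- function(map, f0) {
    F <- fft(map$values)
    q <- emvalid:::freq_magnitude_grid(dim(map$values), map$voxel_size)
    sum(Mod(F[q > f0])^2)
  }
  expect_lt(power_beyond(lo, 0.5), 0.01 * power_beyond(hi, 0.5))
})

test_that("simulated maps are deterministic under a fixed seed and linear in the model", {
  m <- build_fixture("helix", 6)
  a <- simulate_map(m, 2.5, noise_sigma = 0.1, seed = 9)
  b <- simulate_map(m, 2.5, noise_sigma = 0.1, seed = 9)
  expect_identical(a$values, b$values)
  c2 <- simulate_map(m, 2.5, noise_sigma = 0.1, seed = 10)
  expect_false(identical(a$values, c2$values))
  ## linearity over disjoint atom subsets (no noise)
  base <- simulate_map(m, 2.5)
  a1 <- m$atoms[m$atoms$resno <= 3, ]; a2 <- m$atoms[m$atoms$resno > 3, ]
  m1 <- simulate_map(em_model(a1), 2.5, grid = base)
  m2 <- simulate_map(em_model(a2), 2.5, grid = base)
  full <- simulate_map(m, 2.5, grid = base)
  expect_equal(m1$values + m2$values, full$values, tolerance = 1e-9)
})

test_that("total simulated density tracks total atomic number", {
  m <- build_fixture("strand", 6)
  map <- simulate_map(m, 2.5, padding = 6)
  z_tot <- sum(emvalid:::element_weight(m$atoms$element[!m$atoms$is_h]))
  expect_lt(abs(sum(map$values) - z_tot) / z_tot, 0.02)
})

test_that("simulation preconditions are enforced", {
  m <- build_fixture("helix", 4)
  expect_error(simulate_map(m, 2, voxel_size = 1.5), "voxel_size")
  expect_error(simulate_map(m, 2, noise_sigma = 0.1), "seed")
  small <- em_map(array(0, dim = c(4, 4, 4)), 0.5, origin = c(50, 50, 50))
  expect_error(simulate_map(m, 2, grid = small), "too small")
})

test_that("jitter has the requested RMS and is seeded", {
  m <- build_fixture("helix", 60, sequence = strrep("A", 60))
  mj <- perturb_model(m, "jitter", magnitude = 0.3, seed = 4)
  rms <- sqrt(mean(rowSums((coords(mj) - coords(m))^2)))
  expect_lt(abs(rms - 0.3) / 0.3, 0.05)
  expect_identical(coords(perturb_model(m, "jitter", magnitude = 0.3, seed = 4)),
                   coords(mj))
  expect_identical(coords(perturb_model(m, "jitter", magnitude = 0)), coords(m))
})

test_that("peptide flip keeps CA atoms fixed and moves the carbonyl O", {
  m <- build_fixture("helix", 10)
  mf <- perturb_model(m, "peptide_flip", index = 5)
  ca_sel <- m$atoms$atom == "CA"
  expect_equal(max(abs(coords(mf)[ca_sel, ] - coords(m)[ca_sel, ])), 0)
  ri <- emvalid:::residue_index(m)
  dO <- sqrt(sum((emvalid:::atom_xyz(mf, ri[[5]], "O") -
                    emvalid:::atom_xyz(m, ri[[5]], "O"))^2))
  expect_gt(dO, 1)
  expect_error(perturb_model(m, "peptide_flip", index = 10), "following")
})

test_that("misthread shifts residue identities, keeps backbone, k=0 is identity", {
  m <- build_fixture("helix", 8)
  expect_identical(perturb_model(m, "misthread", offset = 0)$atoms, m$atoms)
  mt <- perturb_model(m, "misthread", offset = 1)
  types0 <- vapply(emvalid:::residue_index(m),
                   function(r) m$atoms$resid[r[1]], "")
  types1 <- vapply(emvalid:::residue_index(mt),
                   function(r) mt$atoms$resid[r[1]], "")
  expect_equal(unname(types1[1:7]), unname(types0[2:8]))
  ## backbone coordinates unchanged
  bb0 <- m$atoms[m$atoms$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  bb1 <- mt$atoms[mt$atoms$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  expect_equal(unname(as.matrix(bb1)), unname(as.matrix(bb0)))
  expect_error(perturb_model(m, "misthread", offset = 9), "chain length")
})

test_that("rotamer swap sets chi1 to the target", {
  m <- build_fixture("helix", 12)
  for (tgt in c(60, 120, 180)) {
    ms <- perturb_model(m, "rotamer_swap", target = tgt)
    chis <- emvalid:::chi1_observations(ms)$obs
    expect_true(all(emvalid:::angdiff(chis, tgt) < 1e-6))
  }
})
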