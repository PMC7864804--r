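rigid_copy <- function(m, axis = c(1, 1, 0), angle = 30, shift = c(5, -3, 2)) {
  R <- emvalid:::rotation_about_axis(axis, angle)
  emvalid:::transform_model(m, R, shift)
}

test_that("superposition: identity, rigid invariance, and a grid-search oracle", {
  m <- build_fixture("helix", 8)
  s0 <- superpose(m, m)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  moved <- rigid_copy(m)
  expect_lt(superpose(moved, m)$rmsd, 1e-9)
  ## 4-point toy sets: SVD result matches coarse-to-fine rotation search
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(1, 1, 2))
  Q <- rbind(c(0.2, 0.1, 0), c(2.1, -0.2, 0.3), c(-0.1, 2.8, 0.4),
             c(1.3, 0.9, 1.8))
  k <- emvalid:::kabsch(P, Q)
  fitted <- sweep(P %*% t(k$rotation), 2, k$translation, "+")
  rmsd_svd <- sqrt(mean(rowSums((fitted - Q)^2)))
  expect_equal(rmsd_svd, superpose_oracle(P, Q), tolerance = 1e-3)
  expect_error(superpose(em_model(m$atoms[1:2, ]), m), ">= 3")
})

test_that("proper rotations are enforced for mirror-image inputs", {
  m <- build_fixture("helix", 8)
  mirrored <- m
  mirrored$atoms$x <- -mirrored$atoms$x
  s <- superpose(mirrored, m)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_gt(s$rmsd, 0.5)  # a mirror image cannot be superposed rigidly
})

test_that("GDT-TS: identical, rigidly moved, and one-displaced-residue cases", {
  m <- build_fixture("helix", 10, sequence = strrep("A", 10))
  expect_equal(gdt_scores(m, m)$gdt_ts, 100)
  expect_equal(gdt_scores(rigid_copy(m), m)$gdt_ts, 100)
  ## one CA displaced 10 A: every cutoff passes 9/10
  bad <- m
  ri <- emvalid:::residue_index(bad)
  sel <- ri[[5]]
  bad$atoms[sel, "x"] <- bad$atoms[sel, "x"] + 10
  g <- gdt_scores(bad, m)
  expect_equal(g$gdt_ts, 90)
  ## exhaustive subset oracle at this size: the best 9-atom superposition
  ## leaves the displaced atom > 8 A away, so 9/10 is optimal at every cutoff
  ca_m <- coords(bad, bad$atoms$atom == "CA")
  ca_r <- coords(m, m$atoms$atom == "CA")
  best8 <- 0
  for (drop in 1:10) {
    keep <- setdiff(1:10, drop)
    k <- emvalid:::kabsch(ca_m[keep, ], ca_r[keep, ])
    moved <- sweep(ca_m %*% t(k$rotation), 2, k$translation, "+")
    best8 <- max(best8, sum(sqrt(rowSums((moved - ca_r)^2)) <= 8))
  }
  expect_equal(best8, 9)
})

test_that("trimmed search does at least as well as the plain all-pair fit", {
  m <- build_fixture("helix", 12)
  bad <- perturb_model(m, "jitter", magnitude = 1.2, seed = 31)
  g <- gdt_scores(bad, m)
  s <- superpose(bad, m, "CA")
  ca_m <- coords(bad, bad$atoms$atom == "CA")
  ca_r <- coords(m, m$atoms$atom == "CA")
  moved <- sweep(ca_m %*% t(s$rotation), 2, s$translation, "+")
  plain_frac8 <- mean(sqrt(rowSums((moved - ca_r)^2)) <= 8)
  expect_gte(g$gdt_ts, 100 * plain_frac8 * (1 / 4))  # 8 A is one of 4 cutoffs
})

test_that("LDDT: identity, superposition-freeness, and a pair-enumeration oracle", {
  m <- build_fixture("helix", 8)
  expect_equal(lddt(m, m)$global, 100)
  expect_equal(lddt(rigid_copy(m), m)$global, 100, tolerance = 1e-9)
  ## toy 3-atom system, one distance perturbed
  ref <- em_model(data.frame(chain = "A", resno = 1:3, resid = "GLY",
                             atom = "CA", element = "C",
                             x = c(0, 4, 8), y = 0, z = 0))
  mod <- ref
  mod$atoms$x[3] <- 9.5   # pair (1,3): 8 -> 9.5 (+1.5); pair (2,3): 4 -> 5.5
  l <- lddt(mod, ref)
  ## enumeration: pairs (1,2) exact, (1,3) +1.5, (2,3) +1.5;
  ## thresholds 0.5,1,2,4 -> per-threshold fractions 1/3, 1/3, 1, 1
  expect_equal(l$global, 100 * mean(c(1 / 3, 1 / 3, 1, 1)), tolerance = 1e-9)
})

test_that("LDDT degrades along the jitter ladder", {
  m <- build_fixture("helix", 10)
  vals <- vapply(c(0.1, 0.4, 1.0), function(mag)
    lddt(perturb_model(m, "jitter", magnitude = mag, seed = 5), m)$global, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("CAD: identity, total contact loss, and the analytic cap-area oracle", {
  m <- build_fixture("helix", 8)
  expect_equal(cad_score(m, m), 1, tolerance = 1e-9)
  expect_equal(cad_score(rigid_copy(m), m), 1, tolerance = 1e-9)
  ## blow the model apart: every reference contact lost
  apart <- m
  ri <- emvalid:::residue_index(apart)
  for (i in seq_along(ri))
    apart$atoms[ri[[i]], c("x", "y", "z")] <-
      apart$atoms[ri[[i]], c("x", "y", "z")] + i * 50
  expect_equal(cad_score(apart, m), 0, tolerance = 1e-9)
  ## sphere-overlap area against an independent closed form
  for (cse in list(c(2, 2, 3), c(1.9, 2.2, 1.5), c(2, 1, 0.5), c(2, 1, 4))) {
    expect_equal(emvalid:::sphere_overlap_area(cse[1], cse[2], cse[3]),
                 cap_area_oracle(cse[1], cse[2], cse[3]), tolerance = 1e-9)
  }
})

test_that("hydrogen-bond precision: identity, arithmetic, undefined flag", {
  helix <- build_fixture("helix", 14)   # i -> i+4 pattern is local (sep 4)
  strand <- build_fixture("strand", 14) # extended: no nonlocal H-bonds
  hb <- hbond_precision(strand, strand)
  expect_true(hb$undefined)
  expect_true(is.na(hb$precision))
  ## synthetic two-chain contact: donors (chain A, N) over acceptors
  ## (chain B, O); cross-chain pairs count as nonlocal
  mk <- function(o_x) em_model(rbind(
    data.frame(chain = "A", resno = 1:4, resid = "GLY", atom = "N",
               element = "N", x = (0:3) * 8, y = 0, z = 0),
    data.frame(chain = "B", resno = 1:length(o_x), resid = "GLY", atom = "O",
               element = "O", x = o_x, y = 3.0, z = 0)))
  ref <- mk((0:3) * 8)                 # bonds A_i -> B_i, i = 1..4
  expect_equal(hbond_precision(ref, ref)$precision, 1)
  ## model keeps 3 of the 4 reference bonds and adds one absent from the
  ## reference (B4 moved under no donor, B5 introduced under A4)
  mod <- mk(c(0, 8, 16, 100, 24))
  hb4 <- hbond_precision(mod, ref)
  expect_equal(hb4$n_model, 4L)
  expect_equal(hb4$precision, 0.75)
})

test_that("consensus scoring: duplicates and pair symmetry", {
  m <- build_fixture("helix", 8, sequence = strrep("A", 8))
  m2 <- perturb_model(m, "jitter", magnitude = 3, seed = 2)
  dq3 <- davis_qa(list(m, m, m))
  expect_true(all(dq3$davis_qa == 100))
  dq2 <- davis_qa(list(m, m2))
  expect_equal(dq2$davis_qa[1], dq2$davis_qa[2])
  g <- gdt_scores(m, m2)$gdt_ts
  expect_equal(dq2$davis_qa[1], g)
  ## two identical pairs with cross-pair score g: each model scores (100+2g)/3
  dq4 <- davis_qa(list(m, m, m2, m2))
  expect_equal(dq4$davis_qa, rep((100 + 2 * g) / 3, 4), tolerance = 1e-9)
  expect_error(davis_qa(list(m)), ">= 2")
})
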