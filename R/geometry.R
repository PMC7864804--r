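## Internal 3D geometry primitives: angles, torsions, internal-coordinate
## atom placement (used by the fixture builder, perturbations, CaBLAM,
## EMRinger ring paths, cis-peptide detection).

## Bond angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Torsion a-b-c-d in degrees, in (-180, 180]. IUPAC sign convention.
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -rad2deg(atan2(y, x))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Place atom D given positions of A, B, C and internal coordinates:
## |CD| = bond, angle(B,C,D) = ang (deg), dihedral(A,B,C,D) = tor (deg).
## Standard natural-extension (NeRF) construction.
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang); tor <- deg2rad(tor)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Rotation matrix for angle theta (deg) about unit axis.
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis); t <- deg2rad(theta)
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

## Signed chiral volume of center with substituents p1,p2,p3 (A^3):
## (p1-c) . ((p2-c) x (p3-c)).
chiral_volume <- function(center, p1, p2, p3) {
  sum((p1 - center) * pracma_cross(p2 - center, p3 - center))
}
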