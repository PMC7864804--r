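---
title: "Validation metrics for cryo-EM models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation metrics for cryo-EM models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emvalid)
```

This vignette documents what each metric in `emvalid` computes, the
conventions and tunable parameters behind it, what the synthetic-data
module does and does not emulate, and the design decisions taken where
more than one reasonable concretization existed.

## Containers and conventions

A density map (`em_map`) is a scalar field on a regular, axis-aligned,
orthogonal grid: x-fastest storage, 1-based voxel indices, per-axis
voxel size in Å, and an origin giving the Cartesian position of the
first voxel center. MRC/CCP4 2014 files in modes 0/1/2 are read with
axis-order canonicalization (any MAPC/MAPR/MAPS permutation) and
written in mode 2; non-orthogonal cells are rejected rather than
approximated, because all the intended use cases are orthogonal and a
wrong skew transform silently corrupts every correlation score
downstream. Maps are never regridded implicitly: any operation that
combines two grids requires exact congruence (dims, voxel size, origin)
and raises an error otherwise.

An atomic model (`em_model`) is a flat atom table with residue identity
given by (chain, residue number, insertion code). Alternate conformers
are resolved at parse time by keeping the highest-occupancy location
(ties: first). `normalize_for_scoring()` applies the standard control
for models produced under heterogeneous conventions: hydrogens removed,
all B factors set to zero, and occupancies reset to one if and only if
*every* occupancy in the file is zero (a deposition artifact; mixed
occupancies are respected).

Trilinear interpolation is used for all off-grid density evaluation.
Points outside the grid return a configurable fill value (default 0,
matching the zero background of masked maps). Model masks select voxels
whose centers lie within a radius (default 3 Å) of any heavy atom.

## Fit-to-Map metrics

All correlation metrics compare the experimental map against a
**model-derived map** on the same grid. The model map is produced by
`simulate_map()` at a *user-supplied* resolution — resolution is an
explicit input for this metric class, never inferred, because the
scores depend on it materially.

* **ccbox / ccc** — Pearson over every voxel. **ccmask** — Pearson over
  the model mask. **ccpeaks** — Pearson over the union of the top-k
  voxel sets of the two maps, with k equal to the mask size (our
  concretization of "high-density map and model regions"; the exact
  rule used by other implementations is not published). **ccc_ov** —
  Pearson over the region where each map exceeds half its own
  masked-mean density. **lap** — Pearson of 6-neighbor discrete
  Laplacians (interior voxels). **mi / mi_ov** — mutual information of
  the joint histogram, 20 equal-width bins per map by default; the
  score depends on the binning, which is why the bin count is an
  exposed parameter. Any selection with zero variance yields `NA`
  flagged in `undefined` — never a fabricated number.
* **SMOC** — Manders' overlap coefficient over voxels within the mask
  radius of a sliding window of residues (window 9 by convention;
  window 1 gives the single-residue variant). Windowed profiles are
  deliberately also exposed at window 1 because multi-residue windows
  smear localized errors — the single-residue variant pinpoints a
  displaced residue while the 9-residue window spreads and shallows the
  dip; both behaviors are asserted in the test suite.
* **FSC** — shells are half-open, uniform in spatial frequency with
  width `1/(max(dim)·voxel)`, up to Nyquist. `fsc05()` reports the
  reciprocal frequency of the *first downward* crossing of 0.5 with
  linear interpolation between shell centers; a curve that never drops
  below 0.5 reports the Nyquist resolution with an explicit `at_limit`
  flag instead of a silent clamp. `fsc_avg()` is the term-count-weighted
  mean of FSC over all shells up to `1/d_limit` (integration starts at
  the origin; a low-frequency floor is not applied). The optional soft
  mask is a model mask with a cosine taper (default 3 Å width).
* **Atom inclusion** — fraction of heavy atoms whose interpolated
  density is `>=` the threshold; ties count as inside (documented
  convention). **Envelope score** — the threshold is chosen so the
  enclosed volume equals molecular weight × 1.21 Å³/Da; the score is
  the atom-inclusion fraction inside that envelope minus a penalty
  (weight 1 by default) equal to the fraction of envelope voxels
  farther than `mask_radius` from any atom, clamped to [−1, 1]. The
  penalty radius defaults to 4 Å: the density halo of a
  resolution-limited map extends beyond the vdW shell by roughly the
  resolution, and 4 Å makes a model filling its own simulated envelope
  score ≈ 1, which is the operation's defining contract.
* **Q-score** — for each heavy atom, density is sampled on concentric
  shells (radii 0–2.0 Å, step 0.1 Å, 8 points per shell, placement
  seeded for determinism), rejecting points that lie closer to another
  atom than their shell radius, and correlated against the reference
  Gaussian `A·exp(−r²/(2σ²))+B` with σ = 0.6 Å. Because Pearson
  correlation is invariant to the affine constants A and B, the score
  is fully determined by the Gaussian *shape*; σ = 0.6 Å is the
  calibration under which a well-resolved atom in a ~1.5 Å map scores
  1. Atoms with fewer than 12 usable points are flagged; locally flat
  density is reported as Q = 0 with a flag. The global score is the
  mean over scored atoms.
* **Ring-path (EMRinger-style) score** — for each residue with an
  unbranched Cγ, χ1 is swept in 5° steps, the implied Cγ position is
  placed by ideal internal coordinates, and map density is interpolated
  along the ring. The peak is rotameric iff within ±30° of 60/180/300.
  The global score is the binomial z-statistic of the rotameric count
  among peaks above a density acceptance threshold, maximized over a
  sweep of thresholds (20 quantiles), then rescaled by `10/√N` with N
  the number of scored residues. The null is p₀ = 1/2 (three 60°
  windows cover half the circle). Under this scaling a fully rotameric
  model scores `10·(1−p₀)/√(p₀(1−p₀)) = 10`, the conventional ceiling.
  These constants live in one place and are arguments, not magic
  numbers.

## Coordinates-only metrics

The restraint library ships ideals for the 20 standard amino acids:
exact connectivity, standard backbone values (N-CA 1.458 Å, CA-C
1.525 Å, C-O 1.231 Å, C-N 1.329 Å; N-CA-C 111.2°, CA-C-N 116.2°,
C-N-CA 121.7°, etc.), and class-based side-chain values (sp³ 110.5°,
sp² 120°, aromatic C-C 1.390 Å, ...). The CB improper torsion and the
ideal CA chiral volume (+2.49 ų for the L configuration, substituent
order N, C, CB) are *derived* from those angle ideals rather than
stated independently, so the library is internally consistent and the
fixture builder reproduces it exactly (geometry RMSDs of ideal fixtures
are zero to machine precision). Unknown residue types are skipped and
counted.

* **Clashscore** — overlaps `(r_i + r_j − d) ≥ 0.4 Å` per 1,000 atoms,
  heavy atoms only (scoring is defined post hydrogen-stripping).
  Exclusions follow the Probe/MolProbity convention: pairs up to three
  bonds apart (1-2, 1-3 *and* 1-4) are not clashes. With only 1-3
  exclusions, chemically ideal geometry would "clash" (e.g. the
  intra-residue O…CB 1-4 pair sits near 2.7 Å by construction), which
  contradicts the metric's purpose.
* **Ramachandran / rotamer outliers** — a residue is an outlier iff its
  (φ, ψ) (or χ1) falls in a reference-grid bin whose frequency is below
  the outlier cutoff. Cutoffs follow the MolProbity convention: the
  1st (outlier) and 5th (disfavored) percentiles of the reference
  observations' own bin frequencies. Terminal residues are unscored;
  an unscoreable chain yields `NA` with an `undefined` flag.
* **CaBLAM / Cα-geometry outliers** — for residue i with Cα i−2…i+2 in
  one contiguous stretch (stretches break where Cα-Cα > 4.5 Å), two
  virtual dihedrals μ_in = (Cα i−2, i−1, i, i+1) and
  μ_out = (Cα i−1, i, i+1, i+2) are combined with either the virtual
  dihedral of the flanking carbonyl directions — concretized as
  dihedral(O(i−1), C(i−1), C(i), O(i)) — or the Cα virtual angle at i.
  Outliers are flagged on the joint triplet frequency; the marginal
  values are logged alongside so users can inspect which component is
  anomalous. This is the machinery that catches peptide-plane flips:
  a flip leaves the Cα trace (and hence μ_in/μ_out and often a
  plausible φψ) intact while rotating the carbonyl dihedral by ~160°
  into an unpopulated region of the triplet grid.
* **Cis-peptides** — ω within 30° of 0 is cis (split cis-Pro /
  cis-nonPro), within 30° of 180 trans, otherwise twisted.

### Reference distributions

Reference grids are pluggable (`build_reference()` from any observation
set; text serialization via `write_reference()`/`read_reference()`).
The package builds its own synthetic stand-ins with
`reference_from_fixtures()`: ensembles of ideal fixtures whose backbone
torsions are sampled per residue across the three major basins
(α: φ ∈ [−100,−40], ψ ∈ [−70,−10]; broad β/PPII: φ ∈ [−160,−50],
ψ ∈ [90,175]; αL: φ ∈ [40,80], ψ ∈ [20,80]) with jittered coordinates.
These grids emulate the *coverage* of curated PDB-derived
distributions — enough to score ideal conformers as inliers and
flipped/forced conformers as outliers — but their basin shapes are
cruder than real data: they have hard box edges, no residue-type
specificity, and no rare-but-real populations (e.g. pre-proline
distributions). Passing tests against them demonstrates the outlier
machinery, not production-calibrated outlier rates on real structures;
for production use, load grids derived from a quality-filtered PDB
ensemble.

## Comparison to reference and among models

Atom pairing is by identical chain/residue-number/insertion-code/atom
name — challenge-style shared numbering, no sequence alignment;
mismatches are dropped and counted. Superposition is least-squares
(SVD) with the proper-rotation constraint. GDT-style scores approximate
the maximal simultaneously-superimposable subset per cutoff by iterated
trimmed superposition restarted from the full set and from every
5-residue window (the exact search of the original tool is unpublished;
an exhaustive-subset oracle bounds the approximation on small instances
in the tests). GDT-TS averages Cα fractions over {1, 2, 4, 8} Å;
GDC-all/GDC-SC average all-atom/side-chain fractions over
{0.5, …, 5.0} Å (the cutoff sets are arguments). LDDT uses a 15 Å
inclusion radius and {0.5, 1, 2, 4} Å thresholds over
different-residue reference pairs. CAD contact areas are approximated
analytically as summed sphere-overlap (spherical cap) areas of
vdW + 0.5 Å shells — a desk-scale simplification of Voronoi contact
areas, exact for the two-sphere geometry and verified against the
closed form. Hydrogen bonds use a heavy-atom-only criterion (donor N/O
to acceptor O ≤ 3.5 Å, sequence separation > 6, cross-chain pairs
nonlocal) because scoring is defined after hydrogen stripping; an
angular term is a config hook, not a default. A model with zero
nonlocal bonds yields `NA`-with-flag, not 0. DAVIS-QA is the mean
pairwise GDT-TS against all other models; duplicate models receive
equal scores by construction.

## Meta-analysis

Correlation matrices use pairwise-complete observations; zero-variance
metrics are flagged and excluded from clustering with a warning, never
imputed. Clustering is complete-linkage agglomeration on the distance
1 − |r|, so perfectly anti-correlated metrics merge first; the cluster
count is a *required* argument (choosing it is an inspection decision,
so merge heights are returned for that inspection), and metric order is
made lexicographic before clustering so tie-breaking is deterministic.
Composite Z-scores standardize each metric within each target over that
target's models, negate lower-is-better metrics per an explicit
orientation registry — rankings refuse metrics with undeclared
orientation, because a silent sign error is the worst failure mode
here — and combine with user weights; per-target zero-variance metrics
are dropped and logged. Percentiles use the linear-interpolation
convention (R type 7), stated because box/whisker reproduction depends
on it. Signed correlations are computed on raw metric orientations
(negation before correlation would change the signed heatmap but not
the |r| clustering).

## The synthetic-data module

`build_fixture()` constructs single-chain polypeptides from the
restraint library's own internal coordinates at ideal torsions (helix
−57/−47, strand −120/120, αL 57/47, all-trans ω), with optional
per-residue torsion overrides. The default sequence is poly-Ala with
every fourth residue Leu — enough χ-bearing residues for rotamer and
ring-path tests — with the Leu side chain at the common mt rotamer
(χ1 = 300°, χ2 = 180°), which is clash-free in both helix and strand
contexts. `simulate_map()` places point atoms weighted by atomic
number, splats them with trilinear (adjoint-interpolation) weights so
the map is exactly linear in the model and total density equals total
atomic number, applies a cosine-edge Fourier low-pass centered at
1/resolution (edge width 10% of the cutoff), and adds seeded Gaussian
white noise. This is a desk-scale stand-in for scattering-factor-based
map calculation: atomic-number point weights approximate relative
scattering, there is no solvent model, no CTF, no B-factor
heterogeneity unless requested (`b_factor_policy = "from-model"` applies
a mean-B Fourier falloff), and the noise is white rather than colored
by a reconstruction pipeline. The FSC-derived resolution of a simulated
map is checked empirically in tests (it recovers the nominal resolution
to about one shell width) rather than assumed exact. Simulated maps are
unsharpened; sharpening effects are out of scope.

`perturb_model()` implements the error taxonomy used throughout the
tests: Gaussian coordinate jitter with a requested RMS, peptide-plane
flips (C, O, next-N rotated 180° about the Cα-Cα axis — the carbonyl
points the wrong way while the trace is right), sequence misthreading
(residue identities shifted along a fixed backbone; side chains beyond
CB are dropped since they belong to the old identities), and χ1 rotamer
swaps.

### Study conditions used by the test suite

The behavioral tests run at deliberately small problem sizes chosen as
representative desk-scale analogs: the resolution series uses one
48-residue alternating Ala/Leu helix, three jittered model replicas
(0.5 Å RMS), maps at 3.1/2.3/1.8 Å with noise at half the clean map's
density SD, and compares replica-averaged scores (averaging defeats the
count granularity of the small-N ring-path statistic and tests the
trend in expectation, which is what the trend claims). The
noise-dichotomy test adds noise only outside the model mask, where the
masked scores are provably unaffected. The flip study uses 50 lightly
jittered 14-residue helices with one interior flip each. The planted
clustering study uses 63 synthetic models over 4 pseudo-targets
(16/15/15/17) with three metric triplets driven by independent latent
factors (within-block |r| ≈ 0.96, between-block |r| small), one metric
per block sign-flipped to exercise the |r| similarity.

## Numerical choices and degenerate inputs

Outside-grid interpolation returns the fill value (default 0).
Atom-inclusion ties count as inside. Flat local density gives Q = 0
with a flag; too few usable Q sample points gives a flag and exclusion
from means. FSC at-limit results are flagged, not clamped. Zero-variance
voxel selections, metrics, and per-target score columns are flagged /
dropped / logged — never imputed or silently zeroed. Clash detection
uses a small numeric tolerance (1e−9) at the 0.4 Å boundary so the
printed rule holds under floating-point arithmetic. The degenerate
(collinear) superposition case is detected and flagged. Missing
residues or atoms produce explicitly flagged unscored entries in every
per-residue profile, never a fake 0.

## Known limitations

Nucleic acids, ligands, waters and metals are not validated; hydrogens
are never placed; the mmCIF reader covers the pragmatic single-block
`_atom_site` subset, not the full specification; no symmetry expansion
or map deposition metadata; the GDT search is an approximation with an
oracle-bounded but not guaranteed optimality gap; the synthetic
reference grids are stand-ins (see above); half-map overfitting
analysis and map sharpening effects are out of scope.
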