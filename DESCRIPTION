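Package: emvalid
Title: Validation Metrics for Atomic Models Fitted into Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for scoring atomic coordinate models against
    cryogenic electron microscopy (cryo-EM) density maps and against
    reference structures. Implements the four standard validation tracks
    for near-atomic resolution structures: fit-to-map scores (map-model
    correlations, Manders' overlap profiles, Fourier shell correlation,
    atom inclusion, envelope scores, per-atom Q-scores of atom
    resolvability, and EMRinger-style side-chain ring-path analysis),
    coordinates-only stereochemistry (restraint RMSDs, clashscore,
    Ramachandran/rotamer outliers, CaBLAM virtual-dihedral backbone
    validation, cis-peptide detection), comparison to a reference model
    (GDT-TS/GDC, LDDT, CAD, nonlocal hydrogen-bond precision) and
    comparison among models (consensus DAVIS-QA), plus a meta-analysis
    layer for comparing the metrics themselves: pooled and per-target
    Pearson correlation matrices, complete-linkage clustering of metrics
    by 1-|r| similarity, percentile summaries and composite Z-score
    rankings. Includes MRC/CCP4 map and PDB/mmCIF coordinate I/O and a
    synthetic-data module (ideal secondary-structure fixtures,
    resolution-limited simulated maps, controlled model perturbations)
    so the whole metric suite can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
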