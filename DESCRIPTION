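Package: bamgeom
Title: Conformational Geometry and Functional Assay Analysis for the BAM Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative structural and biophysical analysis of the
    beta-barrel assembly machinery (BAM) complex and related multi-domain
    membrane proteins. Computes inter-domain angle profiles from anchor
    C-alpha atoms of the BamA POTRA chain, estimates a membrane frame from
    the barrel principal axis and measures vertical POTRA extension,
    performs partial (subunit-anchored) rigid-body superposition with
    per-residue displacement and hinge-residue detection, measures
    lateral-gate geometry, scans sequences and structures for candidate
    membrane-interacting segments, extracts half-times from fluorogenic
    folding-assay kinetic traces, and deconvolves native electrospray
    charge-state series into neutral masses. Includes seeded synthetic-data
    generators for every input class so all stages are testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
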