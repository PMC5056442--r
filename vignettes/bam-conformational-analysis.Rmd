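---
title: "Quantifying BAM-complex conformations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BAM-complex conformations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamgeom)
```

The β-barrel assembly machinery (BAM) of *E. coli* is a five-protein
complex (BamA–E, ~203 kDa) that folds and inserts outer-membrane proteins.
Its functional states differ in a handful of measurable geometric
quantities: the inter-domain angles of BamA's five periplasmic POTRA
domains, the vertical reach of that POTRA chain below the membrane, the
separation of the β1/β16 "lateral gate" seam of the BamA barrel, and a
rigid-body flex of BamD about a hinge in the middle of the molecule.
Complementary functional readouts are fluorogenic OmpT folding kinetics
(activity as a half-time) and native electrospray mass spectrometry
(complex stoichiometry as a deconvolved neutral mass). This vignette
documents how each quantity is defined in `bamgeom`, which knobs matter,
and where the design was genuinely open.

## Coordinates, numbering, selections

All geometry runs off a flat atom table (`bam_structure`) read from PDB or
mmCIF via bio3d. Author residue numbering is authoritative everywhere —
the anchors (F24, T93, A175, Y266, N345, R421), gate residues (430, 808)
and BamD hinge region (157) are all quoted in author numbering of the
deposited models — and no sequence alignment or renumbering is ever
applied; residues are paired across structures by author number, and
unmatched residues are dropped with a count in the report. Alternate
locations collapse to the highest-occupancy copy (ties broken by altloc
letter, so the choice is deterministic); only model 1 of multi-model files
is read; hydrogens and waters are always discarded and other heteroatoms
(lipids, detergent) only load on request. Selections are total:
`resolve_selection()` returns every requested residue either as a
coordinate or in a `missing` list, and the angle profile additionally
reports the residue identity found at each anchor, so a numbering
mismatch (precursor vs mature numbering in some deposits) is visible
rather than silently accepted.

## POTRA angle profile

Each inter-domain angle is the planar angle at the middle anchor of a
consecutive anchor triplet — e.g. P2–P3 is the angle at A175 between the
rays to T93 and Y266. Three points always define a plane, so "in-plane
angle" needs no separate projection convention; this triplet reading
reproduces the published 120° value for the wide conformation and is the
simplest interpretation consistent with the anchor list. Angles are
reported in degrees in (0, 180], printed to one decimal with full
precision retained in machine output. Anchor points closer than 0.1 Å are
rejected as degenerate.

## Membrane frame and vertical extension

The deposited models do not come with a membrane. The package stands in a
frame derived from the structure itself: the slab normal is the dominant
principal axis (SVD) of the centred barrel Cα cloud, the origin is the
barrel centroid, and the slab half-thickness defaults to 20 Å — a ~40 Å
slab, matching the measured thickness of the detergent micelle where it
contacts BamD, which in turn matches the outer membrane. The normal's
sign is fixed by requiring a user-named extracellular residue to project
positive; swapping that reference to a periplasmic residue flips the
normal and changes nothing else. Planar or collinear barrel clouds are
rejected. A practical conditioning note: the axis is only as good as the
gap between axial and transverse variance (height²/12 vs radius²/2 for a
cylinder), so barrel selections should span the full membrane height.

Vertical extension is measured from the slab's periplasmic *face*, not
from the origin plane: the reported number is how far the most distal
selected Cα hangs below `origin·normal − half_thickness`, clamped at zero
when the selection stays inside the slab. Differencing two conformations
gives the extension change; the maximum over the selection is used
because the published "up to ~20 Å" is a maximal displacement. The barrel
residue set defining "the membrane" is deliberately an input, not a
hard-coded list.

## Partial superposition, flex and hinge detection

Rigid-body superposition is the closed-form least-squares (Kabsch/SVD)
solution with the usual determinant correction, so a reflection is never
returned. A flex analysis superposes structure B onto A using only the
alignment subset (for BamD flex: the BamE Cα set, because BamE is
essentially identical between conformations and anchors the BamD–BamE
interface) and then reports per-residue Cα displacement over the reported
subunit.

Hinge detection smooths the displacement profile with a running median
(default window 5 residues — robust to single-residue noise), orients the
scan to start from the anchored, low-displacement end, and finds the
first residue whose smoothed displacement crosses the threshold (default
2 Å). For a rigid-body rotation the displacement grows linearly with
distance from the hinge axis (chord length 2·r·sin(θ/2)), so the
threshold crossing sits systematically distal to the true pivot —
severely so for small rotation angles. The detector therefore
back-extrapolates a line fitted to the ramp just past the crossing down
to the anchored baseline and reports the rounded intersection; for a
step-like profile the ramp is flat, the extrapolation is degenerate, and
the crossing residue itself is returned. This keeps the step semantics
while recovering the exact pivot of a gradual ramp.

## Lateral gate

The gate metric is the distance between residues 430 (β1) and 808 (β16),
the positions used for the disulfide-trap cysteine pair. The default is
the Cβ–Cβ distance with a 6.0 Å threshold — a deliberately permissive
disulfide-compatibility bound (Cβ–Cβ in disulfides is ~3.5–4.5 Å) — and
`closed` is inclusive at the threshold. In Cα mode the default widens to
8.0 Å. For glycine the Cβ falls back to Cα with a warning. Thresholds are
echoed into every report.

## Membrane-interaction segments

Two complementary scans. The sequence scan is a windowed-mean hydropathy
profile; the default scale is the Wimley–White water→POPC-interface
transfer free energy stored as *favorability* (−ΔG, so larger = more
interface-favorable), chosen over Kyte–Doolittle because the segments of
interest (the POTRA 3 loop core VPWWNVVG, BamD's 3₁₀ helix) are
Trp/aromatic-rich and classic hydropathy penalizes Trp. Charged side
chains use their charged-form values; His is neutral. The default window
of 3 suits the short (14–19 residue) loops involved; the default cutoff
of 0 means "favorable transfer". Segments are maximal runs of
strictly-above-cutoff window centres; coordinates are centre positions,
so they shift exactly with sequence translation. Since the published
segment assignment is visual (from density), the sequence scan is
validated on segment membership, not on a numeric score.

The structural scan (`slab_burial`) reports maximal runs of consecutive
modelled residues whose Cα lies within the membrane slab (inclusive
bounds), with mean burial depth `half_thickness − |offset|`.

## Folding kinetics

Traces are time/intensity series (the assay reads fluorescence at
430 nm after 325 nm excitation every 10 s, up to 5 h). Normalization
subtracts the mean zero-time background signal. Half-time extraction has
three numerical choices worth stating:

* **Plateau detection.** The plateau is the longest trailing window whose
  least-squares slope is *statistically compatible* with the tolerance
  (|b| ≤ tol + 2·se(b)); the pure |b| ≤ tol form rejects every window
  when noise makes a 20-point slope unestimable below tol. The default
  tolerance is 1% of the trace's maximum rise rate, with that rate taken
  as the largest sliding-window (n/20) least-squares slope rather than a
  raw forward difference, which is noise-dominated at realistic
  signal-to-noise. Minimum plateau length: 20 samples.
* **Plateau level.** The fitted baseline is evaluated at the plateau
  window's centroid — the minimum-variance point of the fit. Evaluating
  at the window start under-reads the saturation level by several percent
  (the trailing-window rule admits windows beginning where the
  exponential is ~95% saturated); centroid evaluation keeps the
  systematic half-time error within about 2% across rate constants
  10⁻⁴–10⁻² s⁻¹, at the cost of slight sensitivity to late drift.
* **Crossing.** The half-amplitude crossing is located on a lightly
  median-smoothed trace and refined by an iteratively re-centred local
  least-squares line; the raw "first sample above half" rule fires
  systematically early once noise exceeds the per-sample rise. Half-times
  are measured from the normalized zero, and are invariant under affine
  gain changes applied consistently to trace and background.

Condition summaries report mean ± s.e.m. (sd/√n) per condition, the
convention used for replicate folding assays.

## Native-MS deconvolution

A charge-state series of one species has peaks at (M + z·p)/z. Charge
assignment searches candidate charges for the lowest-m/z peak, propagates
the implied mass to every peak, and keeps the smallest candidate
minimizing the relative spread of per-peak masses — tolerant of a missing
intermediate charge state, but rejecting assignments whose charge range
is far wider than the peak count (only such spread-out assignments can
fit arbitrary spacings through integer rounding). The neutral mass is
the mean of per-peak masses and its spread the standard deviation,
matching the "observed mass ± sd" convention for intact complexes.
Average (not monoisotopic) masses are used throughout — appropriate for a
~203 kDa complex — with proton mass 1.00728 Da and water 18.0153 Da.
Predicted complex masses sum average sequence masses plus per-component
modification masses (e.g. lipid anchors); those modification masses are
user inputs, since anchor composition comes from experiment.

## Synthetic data: what it emulates, and what it does not

Every input class has a seeded generator that records its ground truth,
so the full pipeline runs with no downloads:

* `make_toy_barrel()` — points on a cylinder (two antipodal helical
  strands sharing height levels, which makes the noise-free principal
  axis exactly the cylinder axis). Defaults: 64 points, radius 12.5 Å
  (Cα radius of a 16-stranded barrel), height 40 Å.
* `make_domain_chain()` — six anchor points with prescribed
  consecutive-triplet angles, equal 30 Å arms, numbered 24…421 with the
  expected anchor identities so the real pipeline runs unchanged.
* `apply_hinge()` — rigid rotation of everything past a pivot residue;
  ground truth for hinge detection.
* `simulate_trace()` — saturating exponential with optional linear
  plateau drift and Gaussian noise, sampled every 10 s, default duration
  8/k (well into saturation).
* `simulate_charge_series()` — exact ESI ladder plus optional Gaussian
  m/z noise.
* `synthetic_bam_complex()` — a three-chain (BamA/D/E) Cα stand-in whose
  *designed* geometry takes the published values for three conformations
  (wide 120° vs acute 107° P2–P3; 2/18/20 Å extension below the slab
  face; BamD N-half flexed 6 Å about residue 157; gate Cβ–Cβ 4.5 Å
  closed vs 12 Å open). These are synthetic point models, not deposited
  coordinates: tests built on them validate that the pipeline measures
  designed geometry correctly end-to-end (including a write/reload pass
  through PDB), not that the real deposits take these values.

Noise is Gaussian everywhere — the simplest defensible model; levels are
configurable. The generators do not attempt realistic all-atom models,
detergent beads, density maps, or correlated noise, so passing recovery
tests demonstrates correctness of the measurement chain, not robustness
to every artefact of real data.

Test problem sizes: angle round-trips use 200 random chains; hinge
recovery 100 seeded cases with rotation angles 5–60°; kinetics recovery
20 seeds per rate at rates 10⁻⁴, 10⁻³, 10⁻² s⁻¹ with 5% noise; MS
round-trips use the 22–28+ charge ladder of a 203,218 Da complex with
0.5 Th noise; superposition is checked against a brute-force Euler-grid
(+ simplex refinement) oracle on ≤ 8-point sets; rigid-motion invariance
uses 100 random poses.

## Known limitations

* The membrane frame is a geometric stand-in; it is validated against a
  printed *relative* extension (a difference of ~20 Å), not against an
  independently determined bilayer position.
* Hinge back-extrapolation assumes an approximately linear displacement
  ramp near the hinge, which holds for a single rigid-body rotation but
  not necessarily for distributed flexibility.
* Half-times from the plateau-baseline procedure carry a ~1–2%
  systematic for slow rates; mechanistic multi-step fits are out of
  scope.
* Charge inference assumes one dominant species; overlapping ladders of
  sub-complexes (visible in real spectra) must be peak-picked apart
  before deconvolution.
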