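# bamgeom

Quantitative structural and functional analysis of the β-barrel assembly
machinery (BAM) — the five-protein complex (BamA–E, ~203 kDa) that folds
and inserts outer-membrane proteins in *E. coli* — and of similar
multi-domain membrane-protein systems.

BAM's functional states differ in a small set of measurable quantities,
and this package computes all of them from coordinate files, kinetic
traces and mass-spectral peak lists:

* **POTRA angle profile** — the inter-domain angles of BamA's five
  periplasmic POTRA domains, defined on six loop Cα anchors
  (F24, T93, A175, Y266, N345, R421): angle *i* is the planar angle at
  the middle anchor of triplet (pᵢ, pᵢ₊₁, pᵢ₊₂). The P2–P3 angle
  separates "wide" (~120°) from "acute" (~104–110°) conformations.
* **Membrane frame and vertical extension** — a membrane slab
  (normal = dominant principal axis of the barrel Cα cloud, half
  thickness 20 Å) and the distance the POTRA chain hangs below its
  periplasmic face; conformations differ by up to ~20 Å.
* **Partial superposition and hinge detection** — rigid least-squares
  (Kabsch) superposition on an anchor subunit (e.g. BamE), per-residue
  displacement of a reported subunit (e.g. BamD), and the hinge residue
  where a rigid-body flex pivots, found by threshold crossing of the
  median-smoothed displacement with back-extrapolation of the ramp.
* **Lateral-gate geometry** — the β1/β16 seam separation measured
  between residues 430 and 808 (Cβ–Cβ, 6 Å disulfide-compatibility
  threshold by default), classifying the barrel as laterally open or
  closed.
* **Membrane-interaction segments** — sliding-window hydropathy on the
  Wimley–White interface scale (favorability = −ΔG) and slab-burial
  scans of the structure.
* **Folding kinetics** — background normalization, plateau-baseline
  fitting and half-time extraction (t½ = earliest crossing of half the
  plateau level) for fluorogenic OmpT folding assays, with per-condition
  mean ± s.e.m. summaries.
* **Native-MS deconvolution** — charge-state inference and neutral-mass
  estimation, mᵢ = zᵢ·(m/zᵢ − p), plus average-mass prediction of
  multi-subunit complexes from sequence.

Seeded synthetic generators (toy barrels, anchor chains with prescribed
angles, hinge rotations, saturating traces, charge ladders, and full
three-chain stand-in complexes) provide ground truth for every stage, so
the entire pipeline is testable offline.

## Worked example

Compare a lateral-closed conformation with an extended, laterally open
one (here: synthetic stand-in complexes; any two loaded structures work
the same way):

```r
library(bamgeom)

em     <- synthetic_bam_complex("em", seed = 1)
closed <- synthetic_bam_complex("lateral_closed", seed = 2)

cmp <- run_compare(closed, em,
  barrel_selection = selection("A", 424:808),
  reference_extracellular_residue = closed$meta$design$extracellular_ref,
  align_spec  = selection("E", NULL),   # superpose on BamE
  report_spec = selection("D", NULL))   # report BamD displacement
cmp
#> <bam_comparison> synthetic_bam_lateral_closed (A)  vs  synthetic_bam_em (B)
#>   P1-P2: 95.0 vs 102.0 deg (delta +7.0)
#>   P2-P3: 120.0 vs 120.0 deg (delta +0.0)
#>   P3-P4: 128.0 vs 135.0 deg (delta +7.0)
#>   P4-P5: 112.0 vs 118.0 deg (delta +6.0)
#>   extension: 2.0 vs 20.0 A (delta +18.0)
#>   gate: 4.5 A (closed) vs 12.0 A (open)
#>   flex: <flex_report> 211 residues (aligned on 91, rmsd 0.00 A)
#>   displacement: mean 3.61 A, max 11.91 A at residue 30
#>   hinge at residue 157 (pre 5.95 A, post 0.00 A)
```

Reading: the P2–P3 angle stays wide (120°) in both, the POTRA chain of
the second structure reaches 18 Å further below the membrane face, its
lateral gate is open (12.0 Å > 6 Å threshold), and after superposing the
two models on BamE alone, BamD's N-terminal half is displaced (~6 Å on
average) about a hinge at residue 157 while its C-terminal half stays
put. `write_comparison(cmp, "out/")` serializes the report (JSON + TSV)
with every threshold echoed for provenance.

Kinetics and MS follow the same pattern:

```r
tr <- simulate_trace(k = 1e-3, plateau = 100, noise_sd = 5, seed = 1)
half_time(tr)
#> <half_time_result> 'sim': t1/2 = 665.4 s, plateau 98 a.u. (slope 0.0011 a.u./s)

ladder <- simulate_charge_series(203218, 22, 28)
mass_from_series(ladder, infer_charges(ladder))
#> <deconvolution_result> mass 203218 +/- 0 Da (charges 28..22, 7 peaks)
```

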