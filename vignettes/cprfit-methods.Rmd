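---
title: "Methods: induced-fit, interface and regiospecificity analysis of CPR-CYP1A2 complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: induced-fit, interface and regiospecificity analysis of CPR-CYP1A2 complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprfit)
```

## The scientific problem

Microsomal cytochrome P450s (CYPs) receive their catalytic electrons from
cytochrome P450 oxidoreductase (CPR). The FMN-binding domain (FD) of CPR
docks transiently onto the proximal face of the CYP, and single mutations in
the FD or in the hinge region that controls CPR's open/closed equilibrium can
change not only how fast CYP1A2 metabolizes caffeine but *which* position of
caffeine is demethylated — the regiospecificity across the three primary
metabolites paraxanthine (N3), theobromine (N7) and theophylline (N1).

`cprfit` packages the computational analyses needed to study this
phenomenon: a per-residue induced-fit statistic over relaxation ensembles of
FD–CYP complexes, consensus contact mapping across docked pose ensembles,
flavin/heme geometry checks, bound-minus-free RMSF differences from MD
trajectories, and the tabular reductions of the membrane-fraction caffeine
assay. Structure *generation* (docking, relaxation, MD engines) is out of
scope; the package consumes coordinates and produces statistics.

## The induced-fit differential RMSD statistic

A residue undergoes an induced fit when its side chain adopts a different
conformation in the complex than in the free domain. Relaxation programs are
stochastic, so a single complexed-vs-free comparison confounds induced fit
with relaxation noise. The statistic therefore uses a *relaxation ensemble*:

1. A few representative complex poses (3 in the canonical design) are each
   split into the unchanged complex, the isolated CYP and the isolated FD,
   coordinates copied verbatim (`split_complex()`).
2. Every split form is independently relaxed several times (3 each in the
   canonical design, giving 27 structures; `build_ensemble()` with a
   pluggable relaxer backend).
3. All structures are rigidly superposed on shared C-alpha atoms onto a
   common reference — the domain part of the first complex member.
4. For each residue, the side-chain RMSD between two structures is computed
   over heavy side-chain atoms matched by name and **normalized by division
   by the side-chain atom count** (units: Å per atom). This down-weights
   large side chains whose raw RMSD grows with atom count.
5. The *inter-model* profile averages this quantity over all
   (complex member, free member) pairs (`intermodel_rmsd()`); the
   *intradomain baseline* averages it over all unordered within-form pairs
   (`intradomain_baseline()`). The **differential profile** is their
   difference (`differential_profile()`).

Under a pure-noise null the inter-model and intradomain expectations are
equal, so the differential profile is centred at zero; genuine complex-only
rearrangements survive the subtraction. Values can legitimately be negative
(residues *more* variable within a form than across forms).

### Design choices that were genuinely open

* **Normalization.** "Divide by the side-chain atom count" admits two
  readings: RMSD ÷ count (default, `normalization = "per-atom-count"`) or
  the mean per-atom displacement (`"mean-displacement"`). Both are
  implemented and selectable so results can be compared; the default is the
  literal reading.
* **Baseline form.** Whether the subtracted intradomain term comes from the
  relaxed free domains, the relaxed complexes, or both is not dictated by
  the procedure. The default, `baseline = "both"`, averages the within-free
  and within-complex baselines: it is symmetric and unbiased whenever the
  relaxation noise level is comparable in the two forms. `"free"` and
  `"complex"` are available for sensitivity analysis.
* **Pair averaging.** All cross pairs are averaged with equal weight. In a
  complete ensemble every seed contributes the same number of members, so
  flat averaging coincides with first averaging within seed-of-origin groups
  and then across groups; no separate grouping option is needed.
* **Alignment reference.** The first complex member. Any fixed member works;
  the profile is invariant to a global rigid motion of the ensemble.

### Relaxer backends

The relaxer is an interface: `(structure, seed, form) -> structure`.
Bundled backends are `relaxer_identity()` and `relaxer_noise()` (i.i.d.
Gaussian noise on heavy side-chain atoms, backbone untouched, plus optional
targeted displacements restricted to chosen forms — the mechanism for
injecting known induced-fit signal in tests). `relaxer_from_files()` adapts
externally relaxed PDB files for real use.

## Interface contacts and consensus

`contact_pairs()` reports every cross-domain residue pair whose minimum
heavy side-chain atom distance is **≤ 3.0 Å inclusive** (the cutoff is a
parameter). Glycine cannot contact. `consensus_contacts()` counts, per
residue, the poses in which it has at least one cross-domain contact;
residues with hits in at least `ceiling(threshold * n_poses)` poses (default
threshold 0.5) form the consensus set, and residues with at least one hit
below that form a secondary tier. The consensus set is monotone
non-increasing in the threshold. Pair-level counts are exported alongside.

## Cofactor geometry

`cofactor_geometry()` measures the quantities that matter for inter-protein
electron transfer: distances from the flavin 7α/8α methyl carbons (PDB atom
names C7M, C8M) to the heme iron and to the heme-ligating cysteine Sγ
(identified as the CYS Sγ nearest the iron), and the angle between the
least-squares planes of the FMN isoalloxazine ring and the heme porphyrin
core. Planes are fitted by the smallest principal component of the centered
ring atoms; the dihedral is reported as the acute angle in [0°, 90°].
Plausible electron-transfer geometries in FD–CYP1A2 complex models fall
around 15–18 Å (methyl to iron) with steep inter-plane angles; the package
measures, it does not judge.

## RMSF differences from trajectories

`rmsf_profile()` computes, per atom, the root-mean-square fluctuation about
the atom's time-mean position; per residue, the unweighted mean over the
residue's atoms (backbone N/CA/C/O or all heavy atoms); per profile, the
mean over replicas (replica averaging after the per-replica residue
reduction). Mass weighting is deliberately absent. Trajectories should be
aligned first — `align_trajectory()` superposes every frame on a reference
frame over a chosen selection; alignment is exposed as an explicit step
rather than hidden inside the profile, because the fitting protocol is an
analysis decision.

`rmsf_difference()` is **bound − free**: positive values mean greater
mobility in the ligand-bound simulations. The sign convention is fixed and
recorded on the output because the verbal phrase "subtracted from" is
directionally ambiguous. `restrict_to_interface()` filters a difference
profile to the consensus interface residues (optionally including the
secondary tier).

For i.i.d. Gaussian positional noise with per-axis standard deviation σ the
expected atomic RMSF is √3·σ; this closed form calibrates the implementation
in the test suite.

## The membrane-fraction assay pipeline

The packaged table (`caffeine_membrane_fractions()`) characterizes 17
CPR-variant and wild-type membrane fractions co-expressing CYP1A2, plus a
CPR-null control: CYP and CPR contents (pmol/mg), the cyt *c* stability
ratio (6 h/0 h), caffeine consumed and the three metabolite amounts (µM,
mean ± SD of 3 technical replicates), and the wild-type reference mapping
used for relative profiles.

* `metabolite_fractions()`: each metabolite over the metabolite sum — the
  regiospecificity profile. The three wild-type rows average to
  86.0/6.2/7.8% (paraxanthine/theobromine/theophylline) at one decimal.
* `mass_balance()`: |consumed − metabolite sum|, tolerance 0.02 µM (printed
  two-decimal precision). All 17 assayed rows pass.
* `relative_profile()`: variant fraction ÷ matched-wild-type fraction and
  the consumption ratio. Consumed-µM ratios proxy observed-rate ratios:
  all couples share the 6 h incubation, 600 µM caffeine (≈2×K~M~) and 60 nM
  CYP1A2, so the proxy is exact up to linearity of progress curves. The
  reference mapping is enforced (`check_reference`), overridable.
* `cpr_cyp_ratio()`: `round(CYP/CPR)`, half away from zero, as "1:n". Two
  rows are *known discrepancies*: N151D (446/27.7 → 16) and G144C
  (124/14.1 → 9) disagree with their printed "1:12". They are asserted as
  disagreements in the tests — probable typos, deliberately not reconciled.
* `stability_flag()` (< 0.8 of initial cyt *c* activity → unstable; flags
  only S243P), `background_correct()` (paired no-NADPH control, negative
  results kept and flagged), `absorbance_to_rate()` (Beer–Lambert, default
  Δε = 21,000 M⁻¹cm⁻¹ for DCPIP at 600 nm), and `gradient_normalize()`
  (rates over a 0–1000 µM caffeine gradient divided by the wild-type
  zero-caffeine rate, summarized by the maximum fractional drop).

When replicate triples are available, standard deviations would propagate by
first-order rules; the packaged table carries printed means ± SD only, and
the pipeline reports SDs without asserting on them.

## What the synthetic generators emulate — and what they do not

`make_toy_complex()` builds two mini-domains of straight-chain
pseudo-residues with standard names (ALA/LEU/TYR-like atom counts, so the
side-chain machinery works unchanged), with one guaranteed facing pair at an
exact, controllable gap and all other side chains pointing away (> 5 Å).
`perturb()` adds side-chain Gaussian noise and targeted displacements.
`make_trajectories()` draws frames as topology + i.i.d. Gaussian
displacement with residue-specific sd. `make_metabolite_table()` draws
tables around the wild-type fractions (0.078, 0.062, 0.860) with
multiplicative effects and CV-scaled noise; consumption is defined as the
metabolite sum, so mass balance holds exactly by construction. All
generators are pure functions of their parameters and a seed.

These generators reproduce the *statistical* structure the analyses assume —
not physics. There are no rotamers, no correlated motions, no force field,
and trajectory noise is white. Passing tests therefore demonstrate that the
statistics recover what they are defined to recover (signal injection, rank
recovery, closed forms, oracle agreement); they do not validate external
docking, relaxation or MD engines, whose outputs the package merely
analyzes.

## Numerical choices and degenerate inputs

* Hydrogens are ignored everywhere; side chains are heavy atoms only.
* Alternate locations collapse to the highest-occupancy conformer,
  deterministic tie-break by altloc letter. Residue numbering is taken from
  the file, 1-based, never renumbered.
* Superposition rejects reflections (proper rotations only), requires ≥ 3
  non-collinear points, and errors on size mismatch. Rotation determinant
  and distance preservation hold to 1e-6.
* The contact cutoff comparison is inclusive (≤). Plane dihedrals are
  reported acute. Stoichiometric rounding is half away from zero.
* Glycine is omitted from side-chain profiles (no side-chain atoms) and a
  targeted displacement on glycine moves nothing.
* Test problem sizes: toy domains of 3–6 residues (80 for moment checks),
  ensembles of 1–3 seeds × 2–5 relaxations, trajectories of 500 frames × 4
  replicas, and 50-variant synthetic tables — sizes at which the
  distributional checks (3·SE bounds, 5–10% recovery bands) are tight while
  the whole suite runs in seconds.

## Known limitations

* Real relaxation noise is neither Gaussian nor independent across atoms;
  the baseline subtraction removes any *form-independent* noise in
  expectation, but heavy-tailed relaxers will need more relaxations per form
  for the same signal-to-noise.
* The induced-fit statistic assumes residue correspondence by (chain,
  residue number, insertion code) and identical side-chain atom name sets;
  mutated positions must be compared like-with-like or excluded.
* `relative_profile()`'s consumption ratio is a rate-ratio proxy under equal
  incubation conditions; it is not a kinetic fit, and no K~M~/V~max~
  estimation is attempted (no per-concentration consumption data).
* Statistical hypothesis testing (ANOVA and multiple-comparison correction)
  is intentionally left to standard tools; the pipeline reports effect
  sizes.
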