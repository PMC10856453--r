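---
title: "Non-targeted PFAS screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted PFAS screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasnta)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are persistent synthetic
chemicals that bioaccumulate in wildlife. Fewer than 200 authentic standards
exist for more than 10,000 known PFAS, so targeted assays cover only a
sliver of the chemical space. Non-targeted screening instead starts from an
aligned LC-HRMS feature table (m/z, retention time, per-sample peak areas)
acquired in negative mode, prioritizes the features most likely to be
fluorochemicals, and annotates them against suspect lists and fragment
libraries, grading each identification on the Schymanski 1–5 confidence
scale. `pfasnta` implements that workflow end to end for a two-tissue
(liver/muscle) wildlife biomonitoring design, together with the
differential statistics used to compare bioaccumulation between tissues.

The package ships a curated table of 60 PFAS identified in roe deer liver
and muscle (`load_table1()`): name, formula, observed [M−H]⁻ m/z, printed
mass error, diagnostic DDA fragments, RT, maximum area and confidence
level. This table is both the validation anchor of the mass arithmetic and
the source of true-compound formulas for the synthetic scenario generator.

## Mass arithmetic

All masses are monoisotopic on the IUPAC scale (¹²C = 12 exactly), with
constants fixed in `MONOISOTOPIC_MASS`. The deprotonated ion is computed as

> m/z([M−H]⁻) = M − 1.00727646 Da,

i.e. the proton mass is subtracted and the electron retained by the anion.
This convention reproduces the curated table's printed mass errors for the
standard-confirmed compounds to within the rounding of the printed 4-decimal
m/z values (about ±0.15 ppm in this mass range), which is how the convention
was selected. Formulas with no hydrogen still receive an [M−H]⁻ value (two
curated rows print one) but raise a warning.

Signed mass errors are `(observed − theoretical) / theoretical × 1e6` ppm.
Recomputing the whole curated table (`validate_table1()`) reproduces 57 of
60 printed errors within 0.5 ppm. The three discrepant rows are reported,
not forced: row 39 does not recompute under any standard adduct convention
we tried (its printed error is ~1.8 ppm away), row 1 is ~1.2 ppm away, and
row 36's printed m/z sits ~36 Da above its formula's [M−H]⁻ — it matches
the [M+Cl]⁻ adduct of the same formula to ~4 ppm, so the printed value is
almost certainly a chloride adduct. Only [M−H]⁻ is in scope, so the row
stays flagged.

## Kendrick mass defects

The Kendrick rescaling maps m/z to KM = m/z × 50 / 49.9968064, where
49.9968064 Da is the exact monoisotopic mass of one CF2 unit and 50 its
nominal mass; KMD = KM − round(KM). Homologues differing only in CF2 count
share a KMD, and fluorine-rich ions sit at slightly negative defects, which
motivates the asymmetric prioritization window [−0.25, +0.15].

Some workflow descriptions quote the CF2 referent as "50.0080", which is
neither the exact (49.9968064) nor the nominal (50) CF2 mass and reproduces
neither; we default to the chemically correct exact mass and expose both
the nominal and exact base as arguments of `kendrick()`. The KMD sign
convention (KM − round(KM), range (−0.5, 0.5]) is chosen so that
fluorine-rich ions are slightly negative, consistent with the asymmetric
window.

## The prioritization cascade

`run_cascade()` applies, in order: (1) optional exclusion-list matching
against features observed in procedural-blank runs; (2) blank-ratio
background removal; (3) the minimum-intensity cutoff; (4) the Kendrick
mass-defect window; (5) the MS² availability gate. Technical injection
replicates are averaged per biological sample first (`"max"` is available).
Every stage records its removals in a telescoping funnel report and
survivors carry provenance tags, so stage-order effects are auditable.

Decisions where the source workflow's prose was ambiguous:

* **Blank ratio.** A feature is *removed* when its maximum area over real
  samples is below 10× its maximum area over blanks ("ratio below 10"
  read as a background definition); features absent from all blanks are
  always kept, with no division. The ratio is evaluated globally over all
  non-blank samples rather than per tissue group.
* **Intensity.** Strictly greater than 1,000,000 arbitrary units, matching
  "greater than 1,000,000"; every curated compound's maximum area clears
  it (the smallest is 2.5 × 10⁶).
* **Stage order.** Blank-based removal first (it is listed first and is
  the cheapest), then intensity, KMD, MS². The funnel report makes any
  reordering visible.
* **KMD window inclusivity.** Inclusive bounds.
* **`kmd_mode`.** Several curated hydrogen-rich compounds (e.g. C22H37F9)
  fall outside [−0.25, +0.15] under this convention, so a literal window
  would have excluded identifications the curated table retains. The
  default `"or_with_suspect"` keeps out-of-window features that carry a
  suspect-list hit; `"hard"` mirrors the literal window.

## Annotation and confidence levels

Candidates are matched to suspect entries at 5 ppm on the theoretical
[M−H]⁻ m/z. Because precursor mass cannot separate isomers, *all*
in-tolerance suspects are evaluated and the one supported by the strongest
evidence is kept (standard RT match, then spectral score, then |Δppm|). The
curated sulfonate pair with a shared formula — a branched isomer eluting at
17.91 min and the linear, standard-confirmed one at 18.26 min — is the
motivating case: the RT match sends each feature to the right entry, and
same-formula features eluting before the standard are tagged
`branched-candidate` (branched perfluoroalkyl chains elute earlier).

Evidence is combined by an ordered decision list (`assign_confidence()`):

1. **CL 1** — authentic-standard RT match plus fragment or spectral support;
2. **CL 2** — library spectral score **strictly greater than 60** (the
   "higher than 60%" gate; 60.0 fails, 60.01 passes);
3. **CL 3** — suspect mass-list hit with ≥1 diagnostic fragment or
   homologous-series membership;
4. **CL 4** — unambiguous formula only;
5. **CL 5** — otherwise.

The spectral score is a 0–100 cosine over greedily paired peaks
(tolerance `max(10 ppm, 0.01 Th)`, matching the 2–3 decimals at which
diagnostic ions are printed); it stands in for online spectral-library
scores, which are not available offline, and the scoring function is
pluggable. Homologous series (`detect_series()`) are maximal chains whose
consecutive gaps are 1–3 CF2 units within 5 ppm with strictly increasing
RT, grown greedily from the lowest unassigned m/z (always extending to the
smallest admissible next member), so results are deterministic.

## Differential analysis

Abundance matrices are median-normalized per sample (each sample's median
over detected compounds is scaled to the median of per-sample medians;
zeros stay zero). Per compound, zeros are imputed at half the smallest
positive value before log2. The volcano test is a two-sided Welch t-test on
log2 areas with log2 FC = log2(mean liver / mean muscle); classification
uses raw p < 0.05 and |log2 FC| ≥ 1, mirroring the thresholds of the
source analysis (Benjamini–Hochberg is available via `p_adjust`). The test
itself is pluggable in principle; Welch was chosen because the upstream
vendor workflow does not document its test and Welch makes no
equal-variance assumption. Compounds detected in no sample of one tissue
bypass the test and are reported as exclusive to the other tissue — the
analysis that motivated this package reported 4 muscle-only and 3
liver-only compounds this way.

PCA is column-centered over samples on log2 data (zero-variance compounds
dropped with a warning). Clustering of volcano-significant compounds uses
row-standardized log2 data, Euclidean distance and Ward linkage
(`ward.D2`), with trees exportable as newick.

## The synthetic scenario generator

Raw data for the motivating study are not public, so recovery claims are
established on synthetic data with planted truth. `generate_scenario()`
emulates the study's structure with these defaults (all configurable,
chosen once as the study conditions):

* 18 animals per tissue (the study's abstract counts 18 used animals;
  20 were collected), duplicate injections (technical CV 10%), one
  procedural blank run twice, two pooled QCs;
* 60 true PFAS at the curated formulas' theoretical [M−H]⁻ m/z with
  Normal(0, 1.5 ppm) mass error and the curated RTs jittered by 0.05 min;
  per-compound geometric-mean areas log-uniform in 3×10⁶–10⁸ with 30%
  biological CV and lognormal(0, 0.2) per-sample loading factors;
* planted effects: 20 up-liver and 12 up-muscle compounds at uniform 2–8
  fold, 3 liver-only and 4 muscle-only compounds (sets drawn disjointly
  per seed), matching the counts the source analysis reported;
* 50 blank contaminants whose sample-to-blank ratios are drawn strictly
  below 10 (bounded injection noise keeps the collapsed ratio below 10
  deterministically), so the blank-ratio stage should remove exactly all
  of them;
* 2,000 hydrogen-rich background features with KMD drawn in +0.16…+0.45,
  mostly MS²-less and low-abundance — the discriminators the cascade's
  later stages exercise;
* MS² spectra for every true PFAS containing its curated diagnostic ions
  (plus Poisson noise peaks) and a clean per-suspect spectral library
  sharing those canonical intensities.

Noise levels and effect sizes are not stated by the source study; the
defaults (CV 30%, folds 2–8) were chosen so that n = 18 per group gives
high but not saturated volcano power, making recovery tests informative
rather than trivial. Planted homologous series in the ground-truth manifest
are the CF2 chains present among the *generated* true features (same chain
rule as `detect_series()`, applied to true features only): with 0.05-min RT
jitter, two curated homologues 0.01 min apart can swap elution order, so
the planted truth is defined on the data as generated, not on the curated
RTs.

What the generator does **not** emulate: profile-mode spectra and peak
shapes, matrix effects and ion suppression, isotope patterns,
chromatographic drift, missingness from alignment, and adducts other than
[M−H]⁻. Passing recovery tests therefore demonstrates the correctness of
the filtering/annotation/statistics logic under the stated noise model,
not performance on raw instrument data.

## Numerical choices and degenerate inputs

* Fragment and precursor tolerances floor at 0.01 Th to respect printed
  decimal precision.
* Exclusion-list entries merge greedily in m/z order at 5 ppm / 0.2 min,
  keeping running means.
* Suspect ties at identical |Δppm| break lexicographically by name;
  series growth breaks ties toward the smallest admissible m/z.
* Empty feature sets, empty suspect libraries, blank-free designs,
  all-zero samples and sub-2-row clustering inputs raise explicit errors
  or warnings rather than propagating NAs.
* All exchange formats are tab-separated text (plus MGF for spectra);
  areas are written as integers and m/z at six decimals, so write/read
  round trips are exact.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the test suite run the default scenario
(2,110 features × 78 injections), 100-instance randomized equivalence
checks against a brute-force reapplication of the filter rules, a
1,000-compound null calibration of the Welch test, and a 20-seed volcano
recovery experiment; these sizes keep the whole suite under a minute while
leaving the statistical checks well-powered.

## Known limitations

* Only singly charged [M−H]⁻ ions; no isotopic fine structure or RDBE
  plausibility scoring.
* The spectral score is a local cosine stand-in; absolute values are not
  comparable to online library scores (the >60 gate applies to the local
  score).
* The 60-compound table's own funnel (17,742 → 373 features on the
  original raw data) is not reproducible without the unpublished raw
  files; the package reproduces the *rules*, validated on planted truth.
* Quantification is out of scope: areas are arbitrary units and all
  statements are qualitative or relative.
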