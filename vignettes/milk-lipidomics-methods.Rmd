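---
title: "Methods: precursor-stepped MS/MS lipidomics of milk, and its simulation"
author: "milkLipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: precursor-stepped MS/MS lipidomics of milk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkLipidomics)
```

## The measurement model

A precursor-stepped, data-independent acquisition fragments every
precursor window of 1 amu across m/z 400–1000 and records one TOF MS/MS
spectrum per step and polarity (fragments m/z 150–1000). There is no
survey scan: everything the pipeline knows comes from fragment spectra.
A species with precursor m/z *p* is co-isolated by the step
`floor(p + 0.5)`, i.e. the isolation window is modeled as
`[step − 0.5, step + 0.5)`; the true window width of such acquisitions
is instrument-dependent and unit width is the natural default for 1-amu
stepping.

All mass arithmetic is assembled from a plain-text monoisotopic element
table (C, H, N, O, P) plus the electron mass. Ion m/z subtracts one
electron mass per positive charge and adds one per negative charge —
without this correction the phosphocholine fragment computes to
184.0739 rather than the observed 184.0733, so the electron term is not
optional at TOF accuracy. Lipid formulas follow the standard
construction: backbone (glycerol or a glycerophospho-headgroup) plus
acyl chains minus one water per ester/amide bond; sphingomyelin is a
dihydroxy long-chain base plus amide FA plus phosphocholine minus two
waters. The lipid class fixes the backbone, so sum-composition
annotations suffice to fix a formula for every supported class.

Adducts per class and polarity are the standard shotgun choices
consistent with ammonium-formate infusion: TAG as [M+NH4]+, PC/SM as
[M+H]+ for headgroup detection, PC as [M+HCOO]− for FA-level fragments,
PE/PS/PI as [M−H]−.

## Identification

Three routes, mirroring the fragment chemistry that carries structural
information:

* **TAG, positive mode.** For each candidate sum composition whose
  ammoniated precursor falls in an acquired step, neutral-loss fragments
  (loss of FA free acid + NH3) are predicted for every *chemically
  consistent* acyl — one that a pool acyl pair can complete to the sum
  composition. At least 2 distinct matched losses are required: a single
  neutral loss is indistinguishable from a random peak, and the cost of
  the rule is only that mono-acyl TAGs (e.g. tripalmitin) are not
  identifiable, which is why the packaged fixtures carry mixed-acyl
  species instead. The default acyl pool spans 4–20 carbons and 0–5
  double bonds.
* **Glycerophospholipids, negative mode.** A molecular candidate
  FA1-FA2 requires every distinct FA carboxylate anion to match in its
  precursor's step; the pairing automatically satisfies the precursor
  sum composition. PS also requires the serine-loss fragment. The
  default pool spans 12–22 carbons (short-chain glycerophospholipids do
  not occur in milk).
* **PC/SM, positive mode, sum level.** The 184.0733 headgroup fragment
  plus the residual (unfragmented) precursor at its exact m/z. The
  residual-precursor confirmation is what resolves PC/SM candidates that
  share one isolation window — with no survey scan, it is the only
  carrier of exact precursor mass in the data. PC species seen in both
  modes merge to the molecular record.

Fragment matching is nearest-peak within an absolute tolerance
(default ±0.01 m/z, TOF-like; ties resolve to the lower m/z peak). Two
arbitration rules are applied and logged: predictions closer than the
tolerance may share a peak, and an identification whose matched
fragment set is a strict subset of a co-identified species' set in the
same spectrum is dropped. The latter matters because the formate adduct
of a PC species is *elementally identical* to the deprotonated PS
species three carbons up and one double bond down; a single-anion PC
candidate riding on a PS spectrum is then a guaranteed false positive.
Type-II interference (shared peak intensities supporting several
precursors) is deliberately not corrected; it is a documented
limitation of the acquisition itself.

Spiked internal standards are targeted lookups of known composition:
they bypass the minimum-evidence thresholds (the TAG standard
17:1-17:1-17:1 has a single distinct neutral loss) and the headgroup
standards accept on the headgroup fragment alone, so that one jittered
high-m/z residual precursor cannot void a class standard.

## Quantification and the TAG indices

`pmol(species) = spike_pmol(std) × Σ evidence(species) / Σ evidence(std)`,
computed within lipid class and identification route. Evidence sums use
only structure-specific fragments (neutral losses for TAG, FA anions
for glycerophospholipids, the headgroup intensity for PC/SM sum
species) — never the serine-loss or residual-precursor confirmations,
whose share of the ion current differs between species with different
fragment counts and would bias the ratio. Standards are excluded from
every composition denominator. No response-factor or isotope correction
is applied; the simulator's default response factor is 1 per class so
round trips are exact, and per-class factors are configurable for
robustness experiments.

Isomeric TAG stoichiometry is deliberately not deconvolved — fragment
yields depend on chain length, unsaturation and glycerol position, so
per-isomer amounts from shared fragments are not trustworthy in a
matrix as complex as milk. The FA index is the stated alternative: per
sum composition, the share of each FA among its neutral-loss
intensities. The pmol-weighted index gives the overall TAG FA profile,
and its aggregation over double-bond counts 0–5 the unsaturation index.
FAs beyond 5 double bonds raise an error by default (configurable cap);
none occur in milk TAGs.

## GC-FAME profiling

GC inputs are integrated peak tables (retention time, area); peak
detection is out of scope. Identification assigns each peak to the
unique library FAME within ±window minutes (default 0.1 min; nearest
wins, ties toward lower RT, libraries with entries closer than twice
the window are rejected). Amounts come from per-FAME ordinary
least-squares calibration lines of amount on area — a full line rather
than a one-point response factor, with extrapolation beyond the fitted
range flagged. Percentages are mole-based by default; a weight basis
(free-acid mass weighting) is available since published FA percentages
do not always state their basis. Group comparison is one-way ANOVA with
Fisher's LSD on the pooled mean squared error, flagged at α = 0.01.
The positional suffixes of FAME names ("n-9c") are carried verbatim but
are opaque: GC resolves positional/cis-trans isomerism, MS/MS does not,
so the cross-workflow key space is carbons:double-bonds.

## What the simulator emulates — and what it does not

`makeFixture()` builds deterministic ground-truth lipidomes:

* `human1`/`human2`: TAG-dominated (97.8 mol% TAG) with long-chain
  unsaturated species; acyl positions are ~46% mono- and ~10%
  di-unsaturated, and ~1.4% short-chain (≤ 10 C). `human2` applies a
  seeded ±10% perturbation to the TAG amounts of `human1`, mimicking
  inter-individual variation.
* `cow`: TAG-dominated with a short-chain arm (butyryl/caproyl/caprylyl
  on TAG 36:0/38:0/38:1-like species, ~12% of acyl positions) and a
  more saturated profile (~64% saturated positions).
* `lacprodan`: phospholipid-enriched formula concentrate with class
  fractions 25/35/18/8/9/5 mol% (TAG/PE/PC/SM/PS/PI) and each
  glycerophospholipid class dominated by its hallmark species
  (PC 16:0-18:1, PE 18:1-18:1, PI 18:0-18:1, PS 18:0-18:1), with minor
  arachidonoyl/docosapentaenoyl species below 5 mol%.

The per-species amounts within those constraints are design choices
made once; totals sit near 2000 pmol so that sample species and the
~100 pmol standards occupy a similar dynamic range.

`simulateMsmsAll()` places each species' predicted fragments into the
spectrum of its precursor's step with total intensity proportional to
pmol × response factor, split evenly across the acyl *positions* and
pooled per distinct fragment — so neutral-loss and anion shares reflect
moiety stoichiometry (a 16:0-18:1-18:1 species yields 1/3 vs 2/3
shares, not 1/2 vs 1/2). This choice is what makes the package's
strongest internal check possible: at zero noise the GC-derived FA
percentages and the MS-derived TAG FA profile agree to 1e-9 when
restricted to the ≥ 10 C key space. Confirmation fragments (serine
loss, residual precursor) carry a fixed half share and are excluded
from evidence sums, so quantification stays exactly linear in pmol.
Co-isolated species superimpose additively; centroids closer than
1e-4 m/z merge.

Noise is three-part and fully seeded: Gaussian m/z jitter (ppm scale,
per peak), multiplicative log-normal intensity noise (given as a CV,
with the log-mean shifted so the expectation is unbiased), and
Poisson-count uniform-m/z baseline peaks with exponential intensities.
Identical seeds reproduce experiments byte-for-byte through
`writeExperiment()`'s canonical formatting (fixed key order, m/z to 4
decimals, intensity to 1).

Deliberately *not* modeled: isotopologue envelopes and isotope
correction, collision-energy- and position-dependent fragment yields
(only an even position split), profile-mode peak shapes,
chromatographic peak shapes on the GC side, and double-bond or
sn-position isomerism. Consequently, passing tests demonstrate the
correctness of the identification/quantification logic under the
stated acquisition geometry — not robustness to fragmentation-yield
biases or isotopic interference in real instrument data. The optional
per-class response factors and the m/z-jitter/recall experiments are
the supported ways to probe sensitivity to such effects.

## Numerical choices and degenerate inputs

* Matching tolerance ±0.01 m/z absolute; equidistant peak ties resolve
  to lower m/z; matched intensities below the configurable floor are
  dropped.
* Steps round half-up (`floor(x + 0.5)`), consistent with the
  half-open isolation window.
* TAG sum-composition candidates are enumerated from achievable acyl
  triples via a pair-achievability table, so neutral-loss evidence is
  only collected for moieties that can complete the composition.
* Zero-evidence TAG species are excluded from the FA index with a
  message; empty quantification tables, missing standards and zero
  standard intensities are errors (the pipeline optionally degrades a
  missing class standard to a warning and drops the class).
* Calibration fits require ≥ 2 distinct areas and a positive slope;
  ANOVA requires ≥ 2 groups with ≥ 2 replicates each.
* The parser accepts en-dash or hyphen separators and emits hyphens;
  SM requires an explicit hydroxyl count (`;2`) on the long-chain base,
  which is the only backbone modeled.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
packaged fixtures (10–37 species per sample plus 6 standards, ~60–80
occupied spectra per experiment) and use 20 seeded noisy simulations
(5% intensity CV, 5 ppm jitter) per stochastic check; the candidate
space under the default pools holds ~700 TAG sum compositions and
~9000 molecular glycerophospholipids. These sizes exercise every code
path while keeping a complete run in minutes on one core.

## Known limitations

* Headgroup-based PC/SM quantification shares one fragment species per
  step; exactly co-isolating PC and SM species would share intensity
  (none of the fixtures do, and the residual-precursor check prevents
  misassignment, but real samples can).
* The evidence-subset arbitration is a parsimony heuristic; a real
  minor species whose fragments are genuinely a subset of a co-isolated
  major species' fragments would be suppressed.
* Amounts are reported per extract (pmol); dilution metadata is carried
  but not applied to concentrations per mL of milk.
* SM quantification assumes the dihydroxy backbone; other sphingoid
  bases would need new formula rules.
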