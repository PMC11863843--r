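---
title: "Detecting functional groups in IR spectra with a split two-head network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional groups in IR spectra with a split two-head network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An infrared absorbance spectrum is, for an organic chemist, a fingerprint
of the functional groups a molecule carries: a nitrile announces itself
near 2200–2300 cm⁻¹, a carbonyl near 1700–1800 cm⁻¹, an O–H as a broad
band above 3200 cm⁻¹. Reading these correlations by hand is reliable but
slow, and does not scale to repository-sized collections of spectra.
`irfgnet` automates the task as a multi-label classification problem:
given a spectrum on a fixed wavenumber grid, predict for each of 17
functional groups (alkane, methyl, alkene, alkyne, alcohols, amines,
nitriles, aromatics, alkyl halides, esters, ketones, aldehydes,
carboxylic acids, ether, acyl halides, amides, nitro) whether the
molecule contains it.

## Ground-truth labels from structures

Training labels come from the molecule's SMILES string by SMARTS
substructure matching against the pinned catalog in `fg_catalog()`. Three
semantic choices deserve explanation:

* **The corrected ether pattern.** The naive ether query
  `[OD2]([#6])[#6]` matches the C(=O)–O–C oxygen of every ester, so all
  esters would also be labeled ethers. The catalog instead uses
  `[OD2]([#6;!$(C=O)])([#6;!$(C=O)])`, which requires both flanking
  carbons to be non-carbonyl. Methyl acetate is then an ester and not an
  ether, while a methoxy-substituted ester genuinely carrying both motifs
  keeps both bits.
* **Halogens on any carbon count as "alkyl halides".** The worked
  4-fluoroanisole example is labeled {methyl, aromatics, alkyl halides,
  ether}: its only halogen sits on an aromatic carbon, so the pinned
  pattern `[#6][F,Cl,Br,I]` deliberately matches aryl (and acyl) halogens
  too. `label_functional_groups("CC(=O)Cl")` therefore sets both
  `acyl halides` and `alkyl halides`.
* **"Alkane" means an sp3 carbon bonded only to carbon or hydrogen**
  (`[CX4;!$([CX4][!#6;!#1])]`). A methoxy CH₃ is methyl but not alkane;
  a toluene CH₃ is both. Without the neighbor restriction, almost every
  organic molecule would be an "alkane" and the label would carry no
  information.

Aromaticity perception follows Open Babel's default model; the 37-molecule
fixture panel in `fixture_molecules()` pins the resulting behavior (it was
additionally audited against an independent cheminformatics toolkit during
development, with full agreement). Matching is presence/absence only —
match counts are never used, because the labels are binary.

## Preprocessing

Spectra arrive as JCAMP-DX files in heterogeneous conventions. The
pipeline in `preprocess_record()` runs in a fixed order:

1. **Parse** (`read_jcampdx()`): AFFN `(X++(Y..Y))` and `XYPOINTS`
   payloads are supported; SQZ/DIF/DUP compression is rejected with an
   explicit error rather than mis-parsed. Descending axes (the common
   storage order) are silently reordered ascending, and micrometer axes
   are converted by ν = 10⁴/λ.
2. **Convert to absorbance** (`to_absorbance()`): transmittance becomes
   A = −log₁₀(max(T, 10⁻⁶)); a maximum above 1.5 marks percent
   transmittance, divided by 100 first. When the file declares no unit,
   values hovering near 1 (mean > 0.7, max ≤ 1.1) are treated as
   fractional transmittance and values with mean < 0.3 as absorbance;
   anything else raises an error rather than guessing. Headers in wild
   data are unreliable, which is why the max-value heuristic overrides a
   percent scale even when "transmittance" is declared.
3. **Interpolate** onto the fixed grid, 600–4000 cm⁻¹ at 1 cm⁻¹
   (3401 points). Grid points outside the measured range are set to 0,
   the post-normalization neutral value — extrapolation would fabricate
   signal. The 1 cm⁻¹ step is finer than the 8 cm⁻¹ resolution of typical
   reference libraries, so no information is lost, and it is a config
   knob (`fg_grid()`).
4. **Clip** negative absorbances to 0 (baseline artifacts), then
   **min–max normalize** per spectrum to [0, 1]. Normalization is per
   spectrum, not global, because acquisition scales differ between
   sources; a constant spectrum maps to all zeros. Whether to normalize
   before or after interpolation is not dictated by the data; the order
   above is fixed so results are reproducible.

Repository data can hold several spectra per molecule; `dedup_latest()`
keeps the newest per canonical SMILES (later uploads usually supersede
earlier, noisier measurements), breaking timestamp ties toward the
lexicographically larger id so the choice never depends on input order.
Manual visual screening of noisy spectra is irreproducible, so the
package offers `screen_high_baseline()` — reject when the median
normalized intensity exceeds 0.5 — as an optional, automated, documented
stand-in, disabled by default.

## The split network

The fingerprint region (≤ 1800 cm⁻¹) is dense with overlapping,
molecule-specific bands; the functional-group region (> 1800 cm⁻¹)
carries cleaner, characteristic stretches. A single dense network would
learn latent features entangled across both. The split architecture
enforces an inductive bias by encoding the regions separately:

$$ y = f_{\mathrm{joint}}(h_1, h_2), \qquad
   h_1 = f_{\mathrm{FP}}(x_{\mathrm{FP}}), \qquad
   h_2 = f_{\mathrm{FG}}(x_{\mathrm{FG}}) $$

Each head is dense(input → input size) + batch norm + ReLU + dropout 0.2,
then dense(→ 256) + batch norm + ReLU + dropout 0.3. The concatenated
512-vector passes through one dense layer of size 512 (no batch norm, no
dropout) and a 17-unit logistic output. Points exactly at 1800 cm⁻¹ go to
the fingerprint side (the fingerprint region is conventionally "below
1800"), giving 1201 + 2200 = 3401 inputs on the default grid. Hidden
activations are rectifiers and the output is logistic — the standard
pairing for a multi-label binary cross-entropy objective. "Layer 1 size:
input size" is implemented literally: the first head layer has as many
units as its region has grid points.

Head isolation is a testable consequence of the factorization: perturbing
any functional-group-region input leaves $h_1$ bit-identical, and vice
versa (`splitnet_head_features()`).

Weights are initialized with a uniform fan-based (Glorot) scheme under an
explicit seed, so initialization is bit-reproducible. Batch normalization
uses ε = 10⁻⁵ and running-statistic momentum 0.1; dropout is inverted
(activations rescaled by 1/(1−p) at train time) so inference needs no
correction.

## Training and evaluation protocol

`splitnet_train()` minimizes mean binary cross-entropy over the 17
outputs with Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) and a linear
learning-rate decay: epoch $e$ (1-based) of $E$ trains at
$\eta_0 (1 - (e-1)/E)$. Defaults are 50 epochs, base rate 10⁻³, batch
size 32 — the rate and batch size are deliberately exposed knobs. The
loss is computed in its numerically stable logit form, so it cannot
overflow; a non-finite loss (only possible from non-finite inputs)
aborts training with the offending epoch named.

`cross_validate()` implements plain (unstratified) seeded 5-fold
cross-validation and reports per-group F1 as mean ± sd over folds.
`holdout_protocol()` first isolates an untouched 10% test split, runs
5-fold CV on the remaining 90% (72/18/10 of the full data per fold, the
70–20–10 design), and evaluates all five fold models on the test split.

Metric conventions:

* **Molecular F1** per group: $2TP/(2TP + FP + FN)$ over molecules. A
  group with TP = FP = FN = 0 is *undefined*, reported `NA`, and excluded
  from macro averages — silently imputing 0 would drag the average down
  on datasets where a rare group (acyl halides, in practice) never
  occurs.
* **Perfect match**: all 17 bits correct, tabulated by the number of
  groups truly present.
* **FPR/FNR** per sample over its 17 bits (FPR undefined without true
  negatives, FNR without true positives), averaged over defined samples
  per group-count bucket.

All three implementations are tested against literal brute-force
confusion counting on randomized instances (agreement within 10⁻¹²).

One batch-norm property is worth knowing: if every row of a minibatch is
identical, the batch statistics erase all feature contrast and learning
proceeds only through the post-normalization parameters. The repeated-
sample overfit test therefore uses a hotter schedule (rate 0.1, batch 25,
150 epochs) than the study configuration; real minibatches are unaffected.

## Spectral attribution

`attribute_spectrum()` explains a single prediction by Shapley values
over contiguous spectral segments (default 50 cm⁻¹, matching the visual
granularity at which chemists read correlation charts; exact per-point
Shapley over 3401 players is intractable). Values are estimated by
permutation sampling: segments are revealed in random order starting from
the all-zero spectrum, and each segment is credited with the probability
change it causes on arrival. The all-zero baseline is the
post-normalization "no absorbance" state — the one input the model is
guaranteed to interpret as "nothing there". Per-permutation marginals
telescope, so the segment values sum to f(x) − f(0) exactly up to
floating-point error; the residual is recorded on the map. Estimates
converge to exact Shapley values (verified against subset enumeration on
small segmentations), and a model whose output does not react to the
spectrum at all yields an all-zero map flagged `degenerate` rather than
an error.

## The synthetic generator

The synthetic module exists so the entire pipeline — parsing, training,
evaluation, attribution — is exercisable without access to commercial
reference libraries. `generate_spectrum()` sums one Gaussian peak per
band of each present group (center drawn uniformly inside the band's
range, amplitude jittered ±20%), adds a slow sinusoidal baseline drift
(amplitude 0.05) and white noise (sd 0.02), and min–max normalizes.
Group counts per sample are uniform on 1–5, inside the 0–9 range real
compilations show and centered near their typical 3–4. The band catalog
(`band_catalog()`) uses the published correlation ranges for the four
4-fluoroanisole groups; all other entries are standard correlation-table
ranges, some narrowed when the catalog was designed so that each group's
band *combination* stays identifiable (e.g. nitrile C≡N at 2210–2260 vs.
alkyne C≡C at 2100–2200; the methyl umbrella bend at 1370–1385 vs. the
generic CH₂ scissor at 1455–1475). They are generator settings, not
literature claims.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: Lorentzian/Voigt line shapes, overtone
and combination bands, Fermi resonances, intensity coupling between
co-occurring groups, instrument-specific artifacts (atmospheric CO₂ and
water lines, detector nonlinearity), and the label correlations of real
chemistry (synthetic labels are drawn independently; real aromatics
co-occur with almost everything). Synthetic-recovery scores are therefore
an internal consistency check of the learning machinery, not a forecast
of accuracy on measured spectra.

## Problem sizes and reproducibility

The packaged tests run the full study configuration — 2,000 training and
500 held-out synthetic spectra on the 3401-point grid, 50 epochs — for
the recovery check, and coarser grids (steps of 100–400 cm⁻¹) wherever
only the mechanics of a component are under test, since the mechanics are
resolution-independent. Every stochastic component (generator, weight
initialization, shuffling, dropout, fold assignment, attribution
permutations) is governed by explicit seeds, and identical seeds
reproduce results bit-for-bit on one platform. Model checkpoints embed a
hash of the SMARTS catalog and refuse to load against a different one, so
a trained model can never silently be paired with re-defined labels.

## Known limitations

* The JCAMP reader covers the AFFN dialects; compressed SQZ/DIF/DUP
  files must be converted upstream.
* The SMARTS catalog is pinned for reproducibility; it encodes the
  semantic choices above and is not a universal chemical ontology.
  Extending beyond the 17 groups is out of scope.
* Training is CPU-bound dense linear algebra; a full-scale run takes
  minutes, not seconds, and scales with the square of the head input
  sizes.
* Attribution is sampling-based; with the default 200 permutations,
  segment values carry Monte-Carlo error of a few percent of the
  probability scale.
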