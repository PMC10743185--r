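---
title: "Variable-selection workflows for NIR calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-selection workflows for NIR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsnir)
```

## The problem

Near-infrared diffuse-reflectance spectra of intact biological samples
contain thousands of strongly collinear absorbance variables, most of
which carry no information about a given low-concentration analyte.
Quantifying such an analyte (here the motivating case is a phenolic
glycoside present at 0.05–0.20 mg/g in fresh plant tissue) from FT-NIR
spectra therefore combines:

1. spectral preprocessing (mean centering, autoscaling, SNV, MSC,
   Savitzky–Golay smoothing/derivatives),
2. Monte Carlo prediction-error screening for outlying samples,
3. a deterministic Kennard–Stone split into calibration and prediction
   sets (ratio 3:1),
4. variable selection — ordered predictors selection (autoOPS, feedOPS,
   iOPS) optionally refined by the successive projections algorithm
   (SPA), and
5. calibration by NIPALS PLS1 or, for small selected subsets, MLR,
   evaluated with R², RMSEC/RMSECV/RMSEP, RPD, RER, SEP/SEC and
   per-sample relative errors.

`opsnir` implements each stage as an exported function and the whole
chain as `runWorkflow()`. Spectra live in `SpectraSet`, an S4 class
extending `SummarizedExperiment` (wavelengths as rows, samples as
columns), with the chemometric samples-by-wavelengths orientation exposed
through `spectra()`.

## Models and algorithms

**NIPALS PLS1.** `fitPLS()` centers X and y internally and extracts
components by w = Xᵀy/‖Xᵀy‖, t = Xw, p = Xᵀt/(tᵀt), q = tᵀy/(tᵀt),
deflating X ← X − tpᵀ and y ← y − tq. The regression vector is
b = W(PᵀW)⁻¹q; predictions are ŷ = ȳ + (x − x̄)ᵀb. With as many
components as the rank of centered X this reproduces ordinary least
squares, which the test suite uses as an independent oracle. Extraction
stops early, with a warning, when no X–y covariance remains.

**Cross-validation.** `crossValidatePLS()` defaults to 10 deterministic
venetian-blind folds; RMSECV and Rcv² are reported per latent-variable
count and the chosen complexity is the smallest count within 2% of the
minimum RMSECV (a parsimony band). The original study fixed 10 latent
variables for its full-spectrum tables without stating a rule; the
workflow accepts a fixed `lv` to reproduce that setting.

**Kernel (Gram) evaluation path.** Wrapper selection evaluates thousands
of PLS models on nested column subsets. Since NIPALS PLS1 depends on the
data only through XXᵀ and Xᵀy, the package evaluates subset models from
an incrementally updated Gram matrix, O(n²h) per fit independent of the
variable count. This path is algebraically identical to the NIPALS path
(asserted to 1e-8 in the tests) and is used inside `opsRun()` and
`monteCarloOutliers()`.

**Informative vectors.** `informativeVector()` implements REG, COR, COV,
VIP, WGHT, URXY, SQR and NAS. Two of these are named in the source
literature without formulas, so their definitions are package choices,
isolated behind the vector kind so they can be swapped:

* SQR is the per-variable explained fraction
  1 − ‖x_j − x̂_j‖²/‖x_j‖² of the h-component reconstruction X̂ = TPᵀ;
* NAS is |b_j|·‖Xb‖/‖b‖², the column norm of the rank-1 net-analyte
  approximation X b bᵀ/‖b‖².

**Ordered predictors selection.** `opsRun()` sorts variables by
|score| descending and scores prefix subsets of sizes window,
window+increment, …, p by cross-validated PLS; the full set is always
included as the final candidate so selection can never report a subset
worse (in RMSECV) than the full spectrum. `autoOPS()` searches all eight
vector kinds plus pairwise products of min–max-normalized vectors (36
candidate orderings), `feedOPS()` iterates autoOPS on its own selection
until the RMSECV improvement falls below a relative tolerance (rounds
that would worsen the incumbent are rejected), and `iOPS()` applies
autoOPS per contiguous interval before a final pass over the pooled
selection. Defaults: vector/model complexity from the full-spectrum CV
choice, window = 10·h, increment = p/50, and 5 venetian folds for the
selection-stage CV (ranking candidate subsets needs stability more than
precision; the modelling CV keeps 10 folds). Ties always resolve toward
fewer variables, then lexicographic vector-kind name.

**Successive projections algorithm.** `spaChain()` is the classical
collinearity-minimizing forward chain: each unselected column is
projected onto the orthogonal complement of the selected ones and the
largest residual norm wins. `spaSelect()` fits MLR models on every chain
prefix between `minVars` and `maxVars` (default min(30, n/5)) for every
start column (all columns, when at most 2000 remain) and picks the
global minimum of the validation RMSE. Following the original
prediction-error-driven formulation, the validation set defaults to the
Kennard–Stone prediction set; this lets the prediction set influence
selection, so a cross-validated alternative (`validation = "cv"`) is
provided for leakage-averse use.

**Outlier screening.** `monteCarloOutliers()` repeatedly splits the
samples 3:1 at random, fits PLS on the training part and records signed
test errors; per-sample MEAN and SD of those errors form the diagnostic
map. The published analysis removed three samples by visual inspection
of that map; no numeric threshold is recoverable from it, so
`flagOutliers()` applies a reproducible robust rule instead: flag when
|MEAN| or SD exceeds its median + k·MAD (default k = 3, with an absolute
floor of √ε so exactly-fitting models never flag). Under approximately
normal per-sample errors this rule intentionally tolerates a small
false-positive rate (≈1% of samples) rather than miss true outliers; the
planted-outlier simulations therefore assert that planted samples are
flagged and top-ranked, not that they are the only flags. The default
iteration count targets ≈500 test-set appearances per sample
(iterations = 500/(1 − trainFraction)).

## Workflow order and leakage

`runWorkflow()` fixes the stage order: outlier scan on all samples →
preprocessing → Kennard–Stone split → selection chain → model →
evaluation, mirroring the study design. Two points needed a decision:

* The split must use the preprocessed spectra, but preprocessing
  statistics must not be fitted on prediction samples. The split
  distances therefore use a provisional fit on all retained samples,
  after which the modelling statistics are re-fitted on calibration rows
  only and replayed onto the prediction rows.
* The outlier scan runs before preprocessing on the raw absorbances
  (PLS centers internally, so the scan is invariant to mean centering —
  the pretreatment the downstream analysis uses anyway).

The one documented exception to the no-leakage rule is SPA's default
prediction-set-driven subset choice, inherited from the original method.

## The synthetic scenario

No spectra are deposited for the motivating study, so `nirScenario()` /
`simulateNIR()` generate FT-NIR-like data with known ground truth:
Beer–Lambert mixing of Gaussian-band constituent spectra on a 1000–2500
nm grid, per-sample polynomial baseline drift (degree ≤ 2),
multiplicative scatter gain, and additive Gaussian noise. The default
scenario has 260 samples and 1000 grid points and was designed to
reproduce the practical regime reported for the real data, where the
full-spectrum model is noticeably degraded by uninformative variables
(RPD ≈ 2 for the full spectrum against ≈ 4–6 after selection):

* an analyte, uniform 0.05–0.20 mg/g, with bands at 1420, 1959 and
  2140 nm (first-overtone and combination O–H regions typical of
  phenolics);
* a dominant water-like interferent (1460, 1920 nm) overlapping the
  analyte bands;
* two broad matrix constituents;
* eight minor background constituents with independent concentrations,
  spread over the rest of the axis — real tissue contains many minor
  absorbers, and their structured variance is what makes uninformative
  regions actively harmful to a latent-variable model rather than
  merely useless;
* noise whose standard deviation (0.002 AU in the interior) ramps up
  7-fold toward the grid edges, emulating the sensitivity falloff of an
  InGaAs detector at the ends of its range.

The ground-truth variable set is every grid index within two band widths
of an analyte band center — a property of the scenario geometry,
independent of the seed.

What the generator does **not** emulate: nonlinear detector response,
wavelength-dependent path length, temperature-driven band shifts, and
correlated (rather than independent) constituent concentrations.
Passing recovery tests on this generator therefore show that the
selection machinery finds planted linear signal under realistic
interference and noise — not that it would perform identically on any
real instrument's data.

## Numerical choices

* Sample (n−1) standard deviations everywhere.
* Savitzky–Golay boundaries use shrink-window symmetric fits (polynomial
  order capped by the shrunk width) so the output keeps the input width
  and selection indices stay valid; the first/last point of a derivative
  copies its neighbour (a one-point window has no slope). Derivatives
  are scaled by the wavelength step and require a uniform axis.
* Kennard–Stone ties break toward the lowest index; with the distance
  matrix cached the scan is O(n²).
* PLS early-stops at ‖Xᵀy‖ ≤ 1e-12 (relative); SPA chains stop at
  residual norms below 1e-10.
* MSC's reference is the calibration-set mean spectrum.
* Text round trips: spectra are written with 17 significant digits (bit
  round trip), wavelengths with 6; reports with 6.

## Problem sizes used in the tests

Unit tests run on small matrices (tens of samples, tens to hundreds of
variables). The acceptance simulations run the default scenario at 200
samples × 400 wavelengths over seeds 1–20 with 400 outlier-scan
iterations, and fix 10 latent variables for the full-vs-selected
comparison, matching the published tables' setting; these sizes keep the
whole suite a few minutes long while leaving every rate estimate stable
across seeds. Planted outliers shift a sample's reference value by
+0.05 mg/g (about ten times the attainable RMSEP). Recovery is asserted
as: the autoOPS stage covers ≥80% of ground-truth variables on average;
the final ≤30-variable SPA–MLR subset overlaps the planted analyte bands
in ≥90% of seeds; the median chain prediction R² is ≥0.95; and the
selected-variable PLS model beats the full spectrum on RMSEP in at least
18 of 20 seeds.

## Known limitations

* PLS1 only (single response); no PLS2 or kernel variants.
* OPS combination vectors stop at pairwise products; triples are not
  searched.
* The SQR and NAS informative vectors are package-defined readings of
  names used without formulas in the source literature.
* SPA's paper-faithful mode consumes the prediction set during
  selection; its reported prediction statistics are accordingly
  optimistic relative to a held-out third set.
* The outlier rule's k is a convention (3), not a calibrated error rate.
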