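# opsnir

Chemometric calibration of analyte concentrations from near-infrared
(NIR) diffuse-reflectance spectra, built around two variable-selection
families: **ordered predictors selection** (autoOPS / feedOPS / iOPS) and
the **successive projections algorithm** (SPA).

## Who this is for

Quantifying a minor constituent — the motivating case is a phenolic
glycoside at 0.05–0.20 mg/g in fresh plant tissue — from FT-NIR spectra
(1000–2500 nm, thousands of collinear absorbance variables) requires
more than a regression fit: spectra must be preprocessed, outlying
samples screened, the sample set split reproducibly, and above all the
few informative wavelengths separated from thousands of useless ones.
`opsnir` packages that whole workflow for R, with spectra held in a
`SpectraSet` (an S4 class extending `SummarizedExperiment`).

## The core methods

**NIPALS PLS1** — per component *a*:

    w_a = X'y / ||X'y||,  t_a = X w_a,  p_a = X't_a/(t_a't_a),
    q_a = t_a'y/(t_a't_a),  X <- X - t_a p_a',  y <- y - t_a q_a

with regression vector `b = W (P'W)^-1 q` and predictions
`yhat = ybar + (x - xbar)'b`. With full rank this is OLS, which the test
suite uses as an independent oracle.

**Ordered predictors selection** — rank variables by an *informative
vector* (REG, COR, COV, VIP, WGHT, URXY, SQR, NAS, or pairwise products
of min–max-normalized vectors), then evaluate growing prefixes
(`window`, `window + increment`, …) by cross-validated PLS and keep the
prefix with the lowest RMSECV. `autoOPS()` searches all vectors,
`feedOPS()` iterates on its own selection, `iOPS()` works per spectral
interval before a final pooled pass.

**Successive projections algorithm** — a forward chain that repeatedly
appends the column with the largest norm orthogonal to the span of the
selected ones (minimal collinearity), then picks the chain prefix whose
MLR model minimizes the validation RMSE.

**Evaluation** — R², RMSEC/RMSECV/RMSEP, RPD = SD(y_pred)/RMSEP,
RER = range(y_pred)/RMSEP, SEP/SEC = RMSEP/RMSEC, per-sample relative
errors (%).

Supporting stages: mean centering, autoscaling, SNV, MSC,
Savitzky–Golay smoothing/derivatives (`applyPreprocess()`),
Kennard–Stone max-min splitting (`kennardStone()`), Monte Carlo
prediction-error outlier screening (`monteCarloOutliers()` +
`flagOutliers()`), and a synthetic FT-NIR generator with known ground
truth (`nirScenario()` / `simulateNIR()`).

## Worked example

Simulate the default scenario at reduced size, run the full workflow
(outlier scan → mean centering → Kennard–Stone 3:1 split → autoOPS →
SPA → MLR) and print the evaluation report:

```r
library(opsnir)

cfg <- workflowConfig(
    scenario  = nirScenario(nSamples = 200, nPoints = 400),
    steps     = list("mean_center"),
    selection = c("autoops", "spa"),
    model     = "mlr",
    ops       = list(hVec = 10, hModel = 10),
    seed      = 1)
res <- runWorkflow(cfg)
print(res)
```

```
Workflow result
 - input: 200 samples x 400 variables 
 - outlier scan: 5 flagged, 195 samples retained 
 - split: 146 calibration / 49 prediction 
 - autoops: 400 -> 180 variables 
 - spa: 180 -> 22 variables 
 - MLR: 22 variables 
 - evaluation: Rp2 0.9261 RMSEP 0.009881 
Calibration model evaluation
  n (cal/pred): 146 / 49   variables: 22
  Rc2 0.9461  RMSEC 0.0096
  Rp2 0.9261  RMSEP 0.0099  RPD 3.72  RER 13.22  SEP/SEC 1.03
  |RE%| median 4.47  max 28.47
```

Reading the report: the 22-wavelength MLR model explains 93% of the
prediction-set variance; RPD ≈ 3.7 is well above the ≈2 threshold below
which an NIR calibration is considered unusable, and SEP/SEC ≈ 1.0
indicates the model generalizes without optimism. The selected
wavelengths (`res$selectedWavelengths`) combine points on the planted
analyte bands (1925, 2135 nm, on the 1959 and 2140 nm bands) with
points on interfering constituents and noisy edge regions that the MLR
uses to cancel their contributions — the typical anatomy of an SPA
subset.

A thin command-line interface wraps the same functions:

```sh
exec/opsnir simulate --samples 200 --points 400 --seed 1 --out spectra.csv
exec/opsnir run --in spectra.csv --selection autoops,spa --model mlr \
    --outdir results/
```

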