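# ftirbone

Bone-quality imaging features and treatment-duration models for
trabecular bone FTIR microspectroscopy.

Long-term oral bisphosphonate therapy for postmenopausal osteoporosis
raises a clinical question: do bone mineral and matrix properties keep
changing with treatment duration, and are those changes — rather than
bone mineral density — what tracks low-energy fractures? Answering it
requires joining three very different data sources per patient:
hyperspectral FTIR maps of iliac-crest biopsies, quantitative
histomorphometry, and clinical covariates. `ftirbone` implements that
analysis chain end to end for researchers working with bone FTIR
imaging, together with a synthetic cohort generator that plants a known
statistical structure so every stage is testable without patient data.

The pipeline:

1. **Spectral map analysis** — per 6×6 µm pixel on a scan grid aligned
   to the trabecular axis, four standard ratios:
   * mineral-to-matrix ratio `MMR = A(phosphate ν1ν3, 900–1200 cm⁻¹) / A(amide I, 1585–1720 cm⁻¹)`
   * carbonate-to-phosphate ratio `CPR = A(carbonate ν2, 840–890 cm⁻¹) / A(phosphate)`
   * crystallinity `= h(1030) / h(1020)` (sub-band peak heights)
   * collagen cross-link ratio `XLR = h(1660) / h(1690)`

   with trapezoidal band areas over an endpoint-anchored linear
   baseline.
2. **Feature table** — each parameter is categorized low/medium/high by
   half-split thresholds (lower-half mean − 1 SD / upper-half mean +
   1 SD over pooled pixels), category statistics are area-normalized,
   and each sample yields exactly 44 infrared features
   (4 × (mean, SD) + 4 × 3 × (fraction, normalized mean, normalized
   SD)), joined with 12 histomorphometric parameters and covariates.
3. **Duration model** — treatment duration is dichotomized at candidate
   cutpoints c ∈ {5,…,9} years (first period iff duration ≤ c); each
   candidate is scored by repeated class-balanced down-sampling,
   mRMR feature reduction and a regularized gradient-boosted linear
   classifier under stratified cross-validation; the argmax-AUC
   candidate is the selected change-point, and feature sets are
   compared at it.
4. **Fracture model** — the same machinery with the low-energy fracture
   flag as outcome and duration (categorical or continuous) among the
   candidate predictors; signed standardized coefficients with a
   |coefficient| > 0.2 retention rule report what drives each model.

## Worked example

Simulate the default 67-patient cohort, extract features and sweep the
duration cutpoint (`analysis/01_simulate.R` … `05_null_calibration.R`
run these stages as a scripted workflow writing to `results/`):

```r
library(ftirbone)

sim <- simulate_cohort(generator_config())   # 67 patients, seed 1
sweep <- sweep_cutpoints(sim$cohort, n_repeats = 20, seed = 1)
round(sweep$grid[, 1:3], 3)
```

```
  cutpoint   auc accuracy
1        5 0.806    0.716
2        6 0.876    0.805
3        7 0.960    0.881
4        8 1.000    0.995
5        9 0.969    0.968
```

Each row is one candidate dichotomization of treatment duration; `auc`
is the mean held-out area under the ROC curve over 20 balanced
down-sampling repeats of 5-fold cross-validation. The generator plants
a change in bone-quality parameters at 8 years and the sweep selects
cutpoint 8 (`sweep$selected`). The fracture model then reports which
parameters drive fracture:

```r
imp <- fracture_importances(sim$cohort, n_repeats = 20, seed = 1)
head(imp, 5)
```

```
                 feature coefficient retained
1                   ac_f  -0.5300279     TRUE
2               n_oc_bpm  -0.4094129     TRUE
3               duration   0.4044457     TRUE
4                    bmi  -0.2525297     TRUE
5 crystallinity_low_frac  -0.1737558    FALSE
```

Coefficients are standardized boosted-linear weights averaged over
balanced draws; positive values are associated with fracture, and a
feature is retained when |coefficient| > 0.2. The planted mechanism is
driven by duration and the mineral parameters with hip BMD uninvolved —
here hip BMD is indeed not retained, but at the 67-patient study size
the top of the ranking is noisy (suppressed remodeling indices, which
proxy duration, edge it out at this seed). Rerun with
`generator_config(n_patients = 200)` and continuous duration ranks
first in every recovery seed; `analysis/04_fracture_model.R` shows that
run.

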