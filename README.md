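# mpMRIquant

Quantification pipeline for multiparametric MRI of tumor therapy response
in preclinical liver-tumor studies.

Vascular-disrupting agents shut down established tumor vessels within
hours but spare a viable peripheral rim from which tumors regrow;
antiangiogenic agents block new vessel formation and can transiently
"normalize" tumor vasculature. Tracking whether a combination of the two
works — and through which mechanism — requires quantitative imaging
biomarkers rather than tumor size alone. This package implements the
full analysis chain by which such studies quantify therapy response on a
clinical scanner, end to end and testable without any animal data:

* **Diffusion (DWI):** per-voxel apparent diffusion coefficient from the
  mono-exponential decay *S(b) = S₀ e^(−b·ADC)* over ten b-values
  (0–1000 s/mm²), whole-tumor ADC normalized to liver (rADC). High ADC
  marks necrosis; low ADC marks cellular tumor.
* **Permeability (DCE-MRI):** standard two-parameter Tofts model
  *C_t(t) = K^trans ∫ C_p(τ) e^(−K^trans(t−τ)/v_e) dτ* fitted to
  relative-enhancement curves, with the arterial input function from the
  abdominal aorta (measured or biexponential population fit). Yields the
  transfer constant K^trans (min⁻¹) and extracellular fraction v_e.
* **Perfusion (DSC-MRI):** tracer-dilution theory on ΔR₂*(t) curves —
  relative blood volume from the tissue/arterial integral ratio and
  relative blood flow from truncated-SVD deconvolution of
  *C_t = Δt·A·(F·R)*; MTT = rBV/rBF by the central volume theorem.
* **Morphometry:** tumor volume and percent change, relative viable rim
  (100 × maximal rim thickness / maximal tumor diameter) and relative
  necrosis volume from label masks.
* **Statistics:** per-timepoint Kruskal–Wallis comparisons of percent
  changes across four treatment arms with Bonferroni-corrected pairwise
  rank-sum post-hocs, and stepwise (partial-F) linear regression to find
  independent predictors of tumor volume change.
* **Digital phantom + cohort simulator:** ellipsoidal rim/core/liver/
  aorta geometry with ground-truth parameter maps, Rician noise, and a
  4-group × 5-timepoint longitudinal cohort generator — every estimator
  in the package is validated against this known truth.

The data model is Bioconductor-style S4: `ImageSeries4D` (4D signal +
acquisition metadata), `RoiMaskSet` (integer labels + legend),
`ParamMap`, `ConcentrationCurve`, `AifModel`/`GammaVariateAif`,
`PhantomTruth`, with validity methods and accessors throughout. NIfTI-1
volumes are read/written via RNifti with JSON/YAML sidecars; record
tables are plain CSV.

## Worked example

Simulate a phantom, quantify all three modalities, then analyze a
simulated cohort:

```r
library(mpMRIquant)

masks <- makeGeometry(shape = c(48, 48, 14), spacing = c(1, 1, 2.2),
                      tumorRadii = c(8, 8, 8), rimThickness = 2)
truth <- makePhantomTruth(masks, noiseSigma = 10, seed = 7)
meta  <- acquisitionMeta(inPlaneSpacing = c(1, 1))

map  <- adcMap(simulateDWI(masks, truth, meta), masks)
radc <- relativeADC(regionMean(map, masks, "tumor"),
                    regionMean(map, masks, "liver"))

dce <- simulateDCE(masks, truth, meta)
aif <- extractAIF(regionCurve(dce, masks, "aorta"), mode = "biexp_fit")
fit <- fitTofts(regionCurve(dce, masks, "viable_rim"), aif)

dsc <- simulateDSC(masks, truth, meta)
dec <- deconvolveTSVD(regionCurve(dsc, masks, "viable_rim"),
                      regionCurve(dsc, masks, "aorta"), threshold = 0.2)

morphometryRecord(masks, meta)
```

This prints:

```
rADC = 1.437
Ktrans = 0.250 /min, ve = 0.350 (converged: TRUE)
rBV = 5.98 a.u., rBF = 1.09 a.u., MTT = 5.5 s
  tumor_volume max_tumor_diameter rim_percent necrosis_percent
1       2153.8                 17    13.15334         41.36874
```

Reading the numbers: whole-tumor ADC sits above liver (rADC 1.44)
because 41% of this phantom tumor is high-ADC necrosis. The viable-rim
Tofts fit recovers the generating truth (K^trans 0.25 min⁻¹, v_e 0.35)
exactly at this noise level. The rim's true blood volume is
F × MTT = 1.5 × 4 = 6 a.u.: the integral-ratio rBV (5.98) is on target,
while tSVD flow (1.09 vs 1.5) shows the well-known truncation
underestimate, so MTT is correspondingly high — the package documents
rather than hides this regularization bias. The rim index (13.2%)
digitizes 100 × 2 mm / 16 mm = 12.5% to within one voxel.

Cohort-level inference on a simulated 44-animal study:

```r
rec <- simulateCohort(seed = 1)       # 10/11/11/12 animals x 5 timepoints
an  <- runStudyAnalysis(rec)
an$comparisons[["rbv@4h"]]
```

```
rBV change at 4 h: H = 32.3 (df 3), p = 4.5e-07
  group_a group_b    raw_p adjusted_p
3 control   ZdTha 7.61e-05   0.000457
5      Zd   ZdTha 6.22e-01   1.000000
6     Tha   ZdTha 4.87e-05   0.000292
```

The simulated vascular shutdown at 4 h is detected: the combination arm
differs sharply from control and from the antiangiogenic-only arm, but
not from the vascular-disrupting-only arm, which shares the same acute
rBV collapse. And the predictor-selection layer, on a cohort where the
12-day volume change depends only on the ADC change (population
correlation −0.65, four decoy candidates, n = 12):

```r
d  <- simulatePredictorStudy(n = 12, r = -0.65, nDecoys = 4, seed = 4)
sw <- stepwiseRegression(d$response, d$candidates)
```

```
selected: d_radc
r = -0.656, entry p = 0.021
```

A full run — cohort simulation, image materialization and fitting for a
subject subset, records, statistics, provenance manifest — is one call:

```r
runPipeline(studyConfig(seed = 1), "runs/exp1")
```

or from a shell via the thin CLI at `inst/cli/mpmri.R`
(`mpmri.R run --config study.yaml --out runs/exp1`, with standalone
`simulate` / `fit-adc` / `fit-dce` / `fit-dsc` / `morphometry` /
`analyze` subcommands).

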