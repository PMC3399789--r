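---
title: "Quantifying tumor therapy response with multiparametric MRI: models and methods"
author: "mpMRIquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor therapy response with multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpMRIquant)
```

## Scope and data model

mpMRIquant implements the quantitative imaging pipeline used to evaluate
combined vascular-disrupting plus antiangiogenic therapy in preclinical
liver-tumor studies: ADC mapping from multi-b diffusion-weighted imaging
(DWI), Tofts-model pharmacokinetics from dynamic contrast-enhanced MRI
(DCE), deconvolution-based perfusion indexes from dynamic susceptibility
contrast MRI (DSC), morphometric response endpoints from label masks, and
the per-timepoint nonparametric statistics plus stepwise predictor
selection applied to the resulting per-animal summary table.

All images are 4D arrays with spatial axes (x, y, z) first and the series
axis (b-value or dynamic frame) last; this convention is asserted at every
boundary. Regions of interest are integer label volumes on the image grid
with a legend mapping labels to semantic roles (viable rim, necrotic core,
liver, aorta); the tumor is always the union of rim and core. Masks are
never resampled implicitly — a grid mismatch is an error.

The default acquisition metadata reproduce the protocol the package
emulates: ten b-values from 0 to 1000 s/mm&sup2;, 80 DCE frames of 3.7 s
and 80 DSC frames of 2 s with the contrast bolus arriving after the 20th
frame, a DSC echo time of 46 ms, and 2 mm slices with a 0.2 mm gap.
Volumetry uses thickness + gap (2.2 mm) as the per-slice extent,
attributing gap tissue to the nearer slice; the acquisition itself does
not state a convention, so this one is fixed and documented here.

## Diffusion: mono-exponential ADC

Per voxel the DWI signal is modelled as $S(b) = S_0 e^{-b\,\mathrm{ADC}}$
over all ten b-values. Two fitters are provided:

* **log-linear** — weighted least squares of $\ln S$ on $b$ with weights
  $S^2$; non-positive samples are excluded (the log is undefined there);
* **nonlinear** (default) — vectorized Levenberg–Marquardt on the signal
  scale, initialized from the log-linear solution, keeping all samples.

The default matters because magnitude MRI noise is Rician: at the noise
floor reached by high-b images the log-domain fit acquires a systematic
bias, while the signal-scale fit does not. The tests assert this
directly — the log-domain bias grows with the noise scale while the
nonlinear median error stays below 5% down to SNR 10. Negative fitted
ADCs are clipped to zero and flagged; failed voxels are `NA`, never
silently zero.

Whole-tumor ADC is the mean over finite voxels of the tumor region across
all slices, normalized to same-examination liver ADC to give the relative
ADC (rADC). Normalizing to same-timepoint liver (rather than baseline
liver) reflects that liver ROIs are drawn at each scan. Response
endpoints use the shared transform
$100\,(x_{\mathrm{post}} - x_{\mathrm{pre}})/x_{\mathrm{pre}}$.

## DCE: standard Tofts model on relative concentration

Signal is converted to relative enhancement
$C_{rel}(t) = (S(t) - \bar S_{base})/\bar S_{base}$ — the linearized
low-dose regime; no T1 mapping or hematocrit scaling is applied, so
K^trans^ is comparable within-study only. The arterial input is taken
from the aorta ROI, either as the measured curve or as a fitted
biexponential population-decay model
$C_p(\tau) = a_1 e^{-m_1\tau} + a_2 e^{-m_2\tau}$ with arrival fixed at
the end of the baseline frames (a single injection shared by all tissue,
so arrival is metadata, not a per-voxel estimate).

The biexponential is fitted by *variable projection*: for any rate pair
$(m_1, m_2)$ the amplitudes solve a linear least-squares problem, so the
search runs over the two rates only, started from a coarse log-spaced
grid. This is deliberate: over a 5-minute window the two exponentials are
nearly collinear and a naive four-parameter descent stalls far from the
optimum even on noiseless data, while the profiled search recovers all
four parameters to numerical precision.

Tissue kinetics follow the standard two-parameter Tofts model
$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,
  e^{-K^{trans}(t-\tau)/v_e}\,d\tau,$$
without a plasma-volume term, because only K^trans^ and v~e~ are
reported endpoints. The convolution is evaluated by **product
integration**: the AIF is treated as piecewise linear between frame
samples and each segment is integrated against the exponential kernel in
closed form, accumulated by an $O(n)$ recursion. This reduces to the
trapezoid rule as $k_{ep}\Delta t \to 0$ but stays exact for fast
kinetics; plain trapezoid on the 3.7 s grid errs by several percent at
$k_{ep} = 10\,\mathrm{min}^{-1}$, which would dominate the fit tolerances
below. Frame-grid and 10-fold-refined evaluations agree to machine
precision, which the tests verify.

Fitting minimizes the residual sum of squares with L-BFGS-B under
K^trans^ ∈ [0, 5] min⁻¹ and v~e~ ∈ (10⁻³, 1], initialized at (0.1, 0.3);
these bounds cover the simulator's truth ranges with stable convergence
and are configurable. ROI-mean fitting is the default for record-level
outputs, matching the whole-tumor measurement workflow. Non-convergence
is reported via a flag, never an exception; a flat tissue curve yields
K^trans^ = 0.

A practical caveat the pipeline makes visible: fitting the ROI-mean curve
of a *heterogeneous* tumor (enhancing rim plus near-silent necrotic core)
returns effective parameters close to the enhancing fraction times the
rim values, not the voxel-mean of the truth maps. The end-to-end
recovery test therefore uses a homogeneous-tumor phantom for tight
tolerances, and the pipeline documentation treats whole-tumor K^trans^
and v~e~ as effective, within-study indexes.

## DSC: tracer-dilution deconvolution

DSC signal is converted by
$\Delta R_2^*(t) = -\ln(S(t)/\bar S_{base})/TE$ (TE in seconds), taken
proportional to concentration. Relative blood volume is the integral
ratio $\mathrm{rBV} = \int C_t / \int C_a$ over the full acquisition (no
gamma-variate recirculation correction — the study design reports
relative, arbitrary-unit indexes, and the within-subject percent-change
endpoints cancel scale). Relative blood flow comes from truncated-SVD
deconvolution of the discretized convolution
$C_t = \Delta t\, A\, (F R)$, with $A$ the lower-triangular Toeplitz
matrix of AIF samples: singular values below 0.2 of the maximum are
zeroed (the standard choice for this conditioning; configurable), the
flow-scaled residue maximum gives rBF, and MTT = rBV/rBF via the central
volume theorem. The standard (non-circulant) formulation assumes
delay-free curves, which the simulator generates; a block-circulant
delay-insensitive variant is a noted extension point, not implemented.

Known tSVD behaviour is asserted rather than hidden: at threshold 0.2,
dt = 2 s and MTT = 6 s the flow is underestimated by roughly 10%
(tolerance 15% in the tests), MTT is recovered within 20% at curve SNR
≥ 30, and deconvolution followed by re-convolution reproduces the tissue
curve with a truncation-level residual.

## Morphometry

Tumor volume is voxel count × in-plane area × slice pitch. Relative
necrosis volume is the core/tumor count ratio. The relative viable rim is
100 × (maximal rim thickness)/(maximal tumor diameter), with two
conventions fixed after deliberate choices:

* **Diameters** are edge-to-edge: the maximal pairwise in-plane distance
  between voxel centers plus one in-plane voxel extent, matching
  caliper-style radiological measurement (a single voxel reads its own
  extent). Center-to-center is available as an option.
* **Rim thickness** is the maximal in-plane radial width of the rim
  (outer tumor boundary to necrosis boundary), measured **on the
  reference slice(s) of maximal tumor diameter**. The restriction is
  essential: an oblique cut through a spherical shell exaggerates its
  apparent in-plane width without bound (a 2 mm shell of a 16 mm sphere
  reads over 30% on off-center slices), while the reference slice
  recovers the true 12.5% within one voxel, as the geometry tests
  verify. A rim-region Feret diameter would degenerately equal the tumor
  diameter and is rejected. In the no-necrosis limit the index is 100 by
  convention; an empty rim gives 0.

Necrosis masks are inputs: contouring the unenhanced area on
post-contrast imaging is expert work upstream of this package, and the
phantom generator produces the masks directly.

## The digital phantom and cohort generator

The simulator exists so that every stage is testable against known
truth without any animal data. It emulates:

* an ellipsoidal tumor (viable rim + necrotic core, the core being the
  inner ellipsoid offset by the rim thickness), a normal-liver block and
  an aortic cylinder for AIF extraction, digitized on voxel centers with
  a 10-voxel floor per region mirroring the delineation practice;
* per-region truth maps with generic soft-tissue/tumor literature values
  (defaults: viable tumor ADC 0.9×10⁻³ mm²/s, K^trans^ 0.25 min⁻¹,
  v~e~ 0.35, F 1.5 a.u., MTT 4 s; necrosis high-ADC, near-zero transfer
  and flow; liver intermediate) — simulator defaults, not claims about
  any specific animals. The blood-volume map is constructed as
  flow × MTT, so the truth itself satisfies the central volume theorem
  and its validity method enforces that;
* **Rician noise** on all magnitude images (Gaussian on two quadrature
  channels, magnitude afterwards), because the ADC fitter's bias
  behaviour under the Rician floor is a tested property; the noise scale
  is calibrated (sample sd within 5% of σ in the high-SNR limit);
* a biexponential instant-rise AIF for DCE (classical population
  plasma-decay parameters a₁ = 3.99, a₂ = 4.78, m₁ = 0.144 min⁻¹,
  m₂ = 0.0111 min⁻¹, arrival after frame 20) and a **gamma-variate
  first-pass bolus for DSC** (peak 6 a.u., 5 s to peak, shape 3). The
  DSC input is deliberately not the instant-rise biexponential: sampled
  at 2 s frames, the jump discontinuity leaves a first-order quadrature
  error that breaks the 1% central-volume recovery the package
  guarantees, whereas the smoothly rising gamma-variate — the standard
  first-pass model in susceptibility-contrast imaging — meets it. For
  the same reason the boxcar-residue convolution handles the residue
  edge exactly via cumulative-integral differences.

The longitudinal cohort generator draws, per subject and timepoint,
each summary quantity as baseline × group factor × lognormal noise, with
the lognormal mean-calibrated so group means converge to
baseline × factor (verified to <2% at 10⁴ subjects). The default group
sizes are the study's 10/11/11/12 randomization; the default
between-subject CV is 0.15. The effect trajectories encode only the
signed, qualitative dynamics of the emulated study — vascular shutdown
(rBV, K^trans^ collapse) at 4 h with rapid rebound for the
vascular-disrupting agent alone, sustained suppression plus the largest
growth delay, thinner rim and larger necrosis for the combination, a
brief early effect and late v~e~ rise for the antiangiogenic alone —
with magnitudes as configurable package defaults, because the source
study's per-group means live in supplementary material not reproduced
here. Noise is drawn independently per record, which makes
percent-change endpoints properly noisy and lets the null configuration
(all factors 1) serve as a calibration standard: the omnibus test's
rejection rate at α = 0.05 lands near nominal (3–5% over 200
replicates).

What the generator does **not** emulate — realistic liver anatomy,
respiratory motion, partial-volume AIFs, bolus delay/dispersion, scanner
drift — bounds what passing tests show: they validate the estimators
against their own forward models under Rician noise, not robustness to
acquisition artifacts of real animal data.

## Statistics

Per post-treatment timepoint, each endpoint's percent change from the
pre scan is compared across the four groups with the Kruskal–Wallis rank
test (mid-ranks, tie correction; the all-tied degenerate case returns
H = 0, p = 1), followed by all six pairwise two-sided Wilcoxon rank-sum
tests (normal approximation with tie correction) with Bonferroni
adjustment min(1, 6p). The omnibus path is exhaustively checked against
a hand-computed rank-sum H on all small three-group integer datasets.

Stepwise multiple linear regression identifies independent predictors of
the 12-day volume change within the combination arm, with the percent
changes of rADC, K^trans^, v~e~, rBV and rBF as candidates: forward
entry of the smallest partial-F p-value below 0.05, backward removal
above 0.10 after each entry, ordinary least squares throughout, every
entry/removal logged. The 0.05/0.10 thresholds are the conventional
stepwise defaults of the statistical software the emulated analysis
used; they are configurable. For a single-predictor final model the
signed `model_r` equals the sample correlation between response and
predictor — the reported r of such an analysis is numerically identical
under either reading, and the result object carries both r and R².

One calibration property deserves honesty: with $k$ independent null
candidates, forward selection at entry p < 0.05 leaves the selection
empty with probability about $(0.95)^k$ — roughly 77% for five
candidates — not more. No uncorrected stepwise procedure reaches a 90%
empty-selection rate at this threshold; the simulation results in the
tests reflect the true rate rather than an aspirational one.

The repeated-measures general linear model of longitudinal designs is
intentionally out of scope; the per-timepoint nonparametric path covers
every fixed-timepoint claim, and no multiplicity control is applied
across endpoints (only within-timepoint pairwise comparisons are
corrected), matching the emulated analysis.

## Pipeline, reproducibility and problem sizes

`runPipeline()` drives simulate → fit → morphometry → records →
statistics from a single validated configuration (unknown keys are
rejected before any compute). A master seed deterministically derives
per-subject, per-stage sub-seeds through a string-tagged modular hash,
so identical configurations reproduce every numeric output
bit-identically — the tests compare md5 checksums of reruns. Full image
series are materialized and fitted for a configurable subject subset
(default 1) while the remaining records come from the truth generator;
this keeps the 44-subject, 5-timepoint emulation at desk scale. Each run
directory carries the config copy, seed, package version and per-file
checksums in a provenance manifest.

Default problem sizes were chosen as the package's own desk-scale
working points: a 48×48×14 voxel phantom grid (1×1×2.2 mm) for imaging
subjects, 10⁴ voxels for ADC noise calibration, 500 replicates for
fit-error and selection-rate estimates, and 200 replicate cohorts for
test-level calibration; all complete in well under a minute each on a
single core.

## Known limitations

* K^trans^ and v~e~ are on the relative-enhancement scale —
  within-study indexes, not absolute pharmacokinetic constants.
* rBV/rBF are arbitrary-unit and leakage-uncorrected; no
  pre-load/Boxerman correction, no absolute quantification.
* No bolus-delay correction in the deconvolution (delay-free simulator).
* ROI-mean fitting of heterogeneous tumors yields effective parameters
  (see the DCE section).
* The simulator's anatomy and noise are idealized; see the generator
  section for what passing tests do and do not establish.
* Tumor/necrosis segmentation itself is upstream: the package consumes
  expert (or generator) masks, by design.
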