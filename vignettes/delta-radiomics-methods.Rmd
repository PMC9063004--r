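---
title: "Delta-radiomics texture analysis of longitudinal MR setup images: methods and design"
author: "DeltaRadiomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeltaRadiomics)
```

## The analysis in one paragraph

Patients treated with MR-guided stereotactic ablative radiotherapy (SBRT)
receive a volumetric setup image before every fraction. The gross tumor
volume (GTV) is contoured on each image, and each image's tumor texture is
summarized by 39 second-order features from four 3D texture matrices. To
compare patients treated with different fraction sizes, fraction images are
placed on a common delivered-dose axis using the biologically effective
dose, $BED = n\,d\,(1 + d/(\alpha/\beta))$ with $\alpha/\beta = 10$ Gy.
Two delta-feature sets are formed per patient — the change from the
pre-treatment image to the image acquired after 20–30 Gy BED (BED20) and
after 40 Gy BED (BED40). Within each bin, a 500-tree random forest ranks
the 39 delta features by mean decrease in Gini, the top two are kept, and
their joint predictive value for binary response (responder RS vs
non-responder NR) is estimated by a bootstrapped two-covariate logistic
regression: 1,000 iterations, each fitting on a random two-thirds subset
and scoring **all** patients, summarized by the mean AUC and the empirical
2.5/97.5 percentiles.

## Dose bookkeeping

The setup image of fraction $k+1$ is acquired *before* that fraction is
delivered, so it reflects a cumulative delivered BED of $k \times BED/fx$.
The BED20 image is the first whose preceding cumulative BED reaches 20 Gy;
the delivered dose must stay within the closed window $[20, 30]$ Gy (a
first crossing beyond 30 Gy is flagged out-of-window). The BED40 image is
the first whose preceding cumulative BED reaches 40 Gy. Dose is assumed
equal across fractions within a schedule, matching the single BED/fraction
each schedule reports. When a fraction count must be recovered from a
total BED and a (possibly rounded) per-fraction BED, the count is
`round(total/perFraction)` and the stored per-fraction value is recomputed
as `total/n`, so that the consistency invariant
$|BED/fx \times n - BED_{total}| \le 0.1$ Gy always holds even when the
printed per-fraction value was rounded (e.g. 54.8 Gy at a printed
11.0 Gy/fx: $n = 5$, stored 10.96 Gy/fx, same bin pair). A bin that no
fraction reaches is `NA`: the patient is excluded from that bin's table,
never zero-filled.

## Preprocessing

Two steps turn a masked GTV into the integer grid the texture matrices
consume. All statistics are computed over in-mask voxels only; the mask
geometry is never altered.

* **Dynamic-range limiting.** In-mask intensities are clipped to
  $[\mu - 3\sigma,\ \mu + 3\sigma]$. $\sigma$ is the *sample* ($n-1$)
  standard deviation — the conventional estimator for ROIs of a few
  hundred voxels; the choice is documented because the test oracle must
  match it. Out-of-range voxels are clipped, not excluded: exclusion would
  change the ROI geometry seen by the texture matrices. A constant ROI is
  a warned no-op.
* **Histogram-equalization quantization.** A voxel with intensity $x$ maps
  to $\lceil G\,\hat F(x)\rceil$ clamped to $[1, G]$, $G = 64$ by default,
  where $\hat F$ is the in-mask empirical CDF with ties sharing their
  common value (`rank(..., ties.method = "max")/n`). The map is monotone,
  deterministic under ties, and distributes voxels as evenly over levels
  as ties permit (at most a factor 2 occupancy ratio when distinct values
  outnumber levels).

## Texture matrices and features

All four matrices use the 26-neighborhood of the cubic grid, represented
by its 13 unique displacement vectors (one per $\pm$ pair). Aggregation is
*merged*: per-direction counts are summed into a single matrix per class
before features are computed, rather than averaging features over
directions. Voxels are treated on the index grid: the native
$1.5 \times 1.5 \times 3.0$ mm anisotropy is not resampled and no
distance weighting is applied, because the extraction chain this package
mirrors works on the native grid with displacement one.

* **GLCM** — symmetric co-occurrence probabilities at displacement 1,
  accumulated over the 13 directions and both orientations. Joint forms
  are used for variance and entropy. Eight features.
* **GLRLM** — maximal constant-level runs along every scan line of each
  direction; out-of-mask voxels break runs. Under merged aggregation the
  run lengths conserve $\sum R(g,l)\,l = 13\,N_v$, and run percentage is
  $N_r/(13\,N_v)$. Thirteen features.
* **GLSZM** — 26-connected constant-level zones (face, edge or corner
  contact); zone sizes partition the ROI, $\sum Z(g,s)\,s = N_v$.
  Thirteen features.
* **NGTDM** — per level, the summed absolute difference between a voxel's
  level and the mean level of its in-mask 26-neighbors. Voxels with no
  in-mask neighbor are excluded so mask edges cannot fabricate
  differences. Five features.

### Volume-decoupled ("modified") features

Five features carry known trends with ROI volume. The package exposes a
`modified` toggle (default on) with these volume-decoupled forms:

| feature | unmodified scaling | modified form |
|---|---|---|
| GLRLM gray-level non-uniformity | $\propto N_r$ | divided by $N_r$ |
| GLRLM run-length non-uniformity | $\propto N_r$ | divided by $N_r$ |
| NGTDM coarseness | $\propto 1/N_v$ | multiplied by $N_v$ |
| NGTDM busyness | $\propto N_v$ | divided by $N_v$ |
| GLCM energy | bounded | identical (flagged only) |

The direction of each correction follows the feature's actual scaling:
busyness grows with voxel count (its numerator $\sum_i p_i s_i$ sums over
voxels), so decoupling *divides* by $N_v$; coarseness is its reciprocal
case. GLCM energy is already normalized by the squared probability mass
and is kept in its standard form under either setting of the toggle; it is
flagged so users can trace which columns the toggle governs. The exact
closed forms of previously published volume corrections are not
reproduced; these standard normalizations are this package's own choice,
and the unmodified twins are always one toggle away.

### Degenerate inputs

Features whose denominators vanish (correlation of a single-level ROI,
NGTDM coarseness/busyness of a uniform ROI) return `NaN` — a quiet
degenerate sentinel, never an error. Delta construction propagates the
sentinel to a missing value, and downstream model stages refuse missing
covariates explicitly (listwise per bin, no imputation). NGTDM strength
returns 0 when $\sum s_i = 0$, its conventional limit.

## Delta features

The model-facing convention is the raw difference
$\Delta f = f_{pre} - f_{post}$, where *pre* is the fraction-1 image and
*post* the bin's assigned image; an increase under treatment is a negative
delta. Percent change, $100\,(f_{pre} - f_{post})/f_{pre}$, is computed
alongside for summary displays only, and is undefined (missing, warned)
when the pre-treatment value is 0. Ratio-style deltas are out of scope.

## Feature selection

`rankByGini()` grows a 500-tree classification forest (Gini split
criterion, bootstrap per tree, `mtry = floor(sqrt(39)) = 6`, node size 1,
unlimited depth — the conventional defaults for the method) and ranks
features by mean decrease in Gini, descending, with ties broken by feature
name for determinism. Rows are put in canonical patient-ID order before
training so the ranking depends on the data, not storage order. No class
weighting is applied despite the 11/19 imbalance. The seed is a required
recorded input.

## Internal validation

Each iteration draws `round(2/3 n)` patients *without replacement*
("two-thirds, 20 of 30 at a time" reads as a subset size; a
with-replacement variant is config-selectable), fits an intercept +
two-covariate maximum-likelihood logistic regression with covariates
standardized by training-subset statistics, scores **all** patients —
the procedure's stated definition, accepted optimism included — and
computes the Mann–Whitney AUC (ties count 1/2). Single-class training
draws are redrawn and counted. Fits that separate (diverging ML
coefficients) are refit with a small ridge penalty ($\lambda = 10^{-3}$,
intercept unpenalized) via iteratively reweighted least squares and
counted. The 1,000 AUCs are summarized by their mean and empirical
type-7 2.5/97.5 percentiles (the default linear-interpolation definition,
fixed for bit-reproducibility).

### What "chance" looks like under this procedure

Because every iteration scores its own training patients, the AUC
distribution of an uninformative feature pair centers slightly above 0.5
(the package's null simulations put the mean near 0.55–0.60 for
$n = 30$ with an 11/19 split). Consequently the per-dataset 95% percentile
interval tracks that dataset's optimistic center and does *not* behave
like a confidence interval for 0.5: across null replications it covers
0.5 only about two thirds of the time. A second, larger optimism enters
when the two covariates are themselves *selected* as the most
label-separating of 39 noise features: best-of-39 selection at $n = 30$
followed by all-patient scoring can push the mean AUC of pure-noise
tables far above the fixed-feature null band (the test suite measures
0.65–0.99 across generator seeds). Real feature panels are strongly
inter-correlated, which shrinks the effective number of independent
candidates and with it this selection optimism; the generator's
near-independent noise features are a worst case in this respect. Both
optimism effects are properties of the validation definition itself, and
the package reports them rather than correcting for them.

## The synthetic cohort generator

`generateCohort()` emulates the structure the analysis assumes, not MR
physics:

* 30 patients, 11 RS / 19 NR, schedules drawn from the reference
  fractionation mix (3–5 fractions, BED/fraction 11–26.4 Gy; the default
  30-patient cohort uses the reference schedule–label pairing verbatim);
* ellipsoidal GTV-scale masks of 500–3,000 voxels on a $32^3$ grid
  (random aspect ratios 0.75–1.25);
* each patient's tumor is a fixed white-noise field smoothed to a baseline
  Gaussian autocorrelation length of 1.2 voxels and standardized; every
  fraction re-images the same field with fresh i.i.d. acquisition noise
  (SD 0.15 of the structured field's unit SD);
* for responders, the image assigned to the BED20 bin is smoothed to an
  autocorrelation length of 2.0 voxels instead — a change of co-occurrence
  structure at nearly constant intensity histogram, which is exactly the
  signal class second-order features measure and first-order statistics
  miss. By the BED40 image the texture is back at baseline, so BED40
  deltas are noise by construction.

The drift and noise magnitudes were fixed once as a clearly detectable
effect at GTV scale. What the generator does **not** emulate: bSSFP
contrast, banding, coil profiles, inter-scan intensity drift, daily
recontouring variability (the fraction-1 mask is reused), or correlated
acquisition noise. Passing tests therefore demonstrate that the pipeline
recovers a genuine second-order texture drift and stays calibrated on
null cohorts — not that any particular clinical effect size is
detectable at 0.35 T.

## Numerical and testing choices

* Matrix builders are vectorized (index-block shifts for co-occurrence
  and neighborhoods, anchor-sorted run-length encoding per direction,
  graph connected components for zones) and verified against independent
  brute-force voxel-loop oracles on 200 random ROIs up to $4^3$ voxels
  and 4 gray levels, to $10^{-10}$.
* Conservation identities (GLCM mass 1, GLSZM zone partition, NGTDM
  counts) are asserted on every extraction.
* All 39 features are invariant under 90° grid rotations, which the
  merged 13-direction aggregation and 26-connectivity guarantee.
* Test problem sizes: property suites run cohorts of 6–30 patients on
  $20^3$–$32^3$ grids with 100–1,000 bootstrap iterations; the full-scale
  checks (null calibration band, BED20 signal recovery, byte-level
  determinism) use the default 30-patient configuration.

## Known limitations

* The BED40 "absence of signal" check inherits the selection-optimism
  floor described above: with per-bin selection over near-independent
  noise features, mean internal-validation AUCs of 0.7–0.9 on drift-free
  tables are expected behavior of the procedure, not a pipeline defect.
* Masks are propagated from fraction 1 by the generator; daily
  recontouring exists in clinical data and is supported by the reader
  (`fx<k>_mask.nii.gz` per fraction) but not simulated.
* No resampling: image/mask grid mismatches are a hard error.
* First-order, shape, and filtered features are out of scope, as are 2D
  aggregation modes.
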