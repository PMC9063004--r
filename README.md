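# DeltaRadiomics

Delta-radiomics texture analysis of longitudinal MR-guided radiotherapy
setup images, for radiation-oncology and medical-imaging researchers who
want to quantify *treatment-induced* texture change and test whether it
predicts response.

MR-guided SBRT produces a volumetric setup image before every fraction.
This package turns those images into a response-prediction analysis:

1. **Dose binning.** Schedules with different fraction sizes are placed on
   a common axis with the biologically effective dose,
   *BED = n·d·(1 + d/(α/β))*, α/β = 10 Gy. The setup image of fraction
   *k+1* reflects *k·BED/fx* of delivered dose; each patient's images are
   assigned to a **BED20** bin (first image after 20–30 Gy delivered) and
   a **BED40** bin (first image after 40 Gy).
2. **Texture extraction.** The tumor ROI of each image is dynamic-range
   limited to μ ± 3σ, quantized to 64 gray levels by histogram
   equalization, and summarized by **39 second-order 3D features** from
   four matrices over the 26-neighborhood — GLCM (8), GLRLM (13),
   GLSZM (13), NGTDM (5) — with merged-direction aggregation, displacement
   one, and volume-decoupled variants of five features.
3. **Delta features.** Per patient and bin, Δf = f(pre-treatment) −
   f(bin image).
4. **Selection.** A 500-tree random forest ranks the 39 deltas by mean
   decrease in Gini; the top 2 are kept.
5. **Internal validation.** A bootstrapped logistic regression (1,000
   iterations; each fits on a random two-thirds subset and scores *all*
   patients) yields a mean AUC with empirical 2.5/97.5 percentiles.

A synthetic cohort generator produces longitudinal phantoms with a
responder-only texture drift at the BED20 image, so the whole chain is
testable without patient data. Everything is seed-deterministic.

## Worked example

```r
library(DeltaRadiomics)

computeBED(nFractions = 5, dosePerFraction = 10)
#> [1] 100

sch <- table3Schedule()          # packaged 30-patient reference schedule
sch
#> TreatmentSchedule with 30 patients
#>   alpha/beta: 10 Gy
#>   total BED [Gy]: median 100  range 54.8 - 132
#>   response: 11 RS / 19 NR

head(cbind(BED20 = binImageIndex(assignDoseBins(sch), "BED20"),
           BED40 = binImageIndex(assignDoseBins(sch), "BED40")), 4)
#>   BED20 BED40
#> 1     3     4
#> 2     3     5
#> 3     3     4
#> 4     2     3

cohort <- generateCohort(cohortSpec(), seed = 1)   # 30 synthetic patients
res <- runPipeline(cohort, config = pipelineConfig(), seed = 1)
res$BED20$report
#> ValidationReport (BED20): 1000 iterations
#>   features: glszm.large_zone_emphasis.48P8 + glcm.contrast.ACUI
#>   mean AUC 1.000 [1.000-1.000]
res$BED40$report
#> ValidationReport (BED40): 1000 iterations
#>   features: glrlm.gray_level_variance.8CE5 + glrlm.high_gray_level_run_emphasis.G3QZ
#>   mean AUC 0.990 [0.957-1.000]
```

Reading the numbers: patient 1 (BED/fx 14.4 over 5 fractions) pairs the
pre-treatment image with fraction 3 for BED20 and fraction 4 for BED40;
patient 4 (20 Gy/fx over 3 fractions) with fractions 2 and 3. On the
synthetic cohort the injected BED20 drift is recovered perfectly
(mean AUC 1.0). The BED40 deltas contain *no* drift by construction, yet
the report shows 0.99 — this is the optimism of selecting the 2 most
label-separating of 39 noise features at n = 30 and then scoring the
training patients, a property of the validation procedure itself that the
package reports rather than hides; see the methods vignette
(`vignettes/delta-radiomics-methods.Rmd`) for the analysis and for the
null calibration with fixed features (mean AUC ≈ 0.55–0.60).

A thin command-line wrapper covers the same flow
(`inst/cli/deltarad.R simulate|run`), and `writeCohort()` /
`runPipeline(<dir>, outputDir = ...)` exchange the on-disk layout
(`fx<k>_image.nii.gz`, `fx<k>_mask.nii.gz`, `schedule.csv`, `labels.csv`)
with CSV/JSON artifacts plus a manifest that makes every reported number
regenerable.

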