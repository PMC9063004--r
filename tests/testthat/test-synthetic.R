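small_spec <- function(...) {
  cohortSpec(gridDim = 20, roiVoxelRange = c(300, 600), ...)
}

test_that("zero effect and zero noise give identical fraction volumes", {
  sp <- small_spec(noiseSD = 0, effectBin = "none")
  pat <- generatePatient(sp, "RS", 4, driftFraction = 3, seed = 5)
  expect_length(pat$volumes, 4)
  for (fx in 2:4) expect_identical(pat$volumes[[1]], pat$volumes[[fx]])
  # hence all delta features are exactly zero
  f1 <- extractTextureFeatures(maskedROI(pat$volumes[[1]], pat$mask), nLevels = 16)
  f3 <- extractTextureFeatures(maskedROI(pat$volumes[[3]], pat$mask), nLevels = 16)
  expect_equal(deltaFeature(f1, f3), rep(0, 39), ignore_attr = TRUE)
})

test_that("generation is deterministic under a fixed seed", {
  sp <- small_spec()
  p1 <- generatePatient(sp, "RS", 5, driftFraction = 3, seed = 99)
  p2 <- generatePatient(sp, "RS", 5, driftFraction = 3, seed = 99)
  expect_identical(p1, p2)
  b1 <- generateCohort(cohortSpec(nPatients = 4, nRS = 2, gridDim = 16,
                                  roiVoxelRange = c(150, 300)), seed = 7)
  b2 <- generateCohort(cohortSpec(nPatients = 4, nRS = 2, gridDim = 16,
                                  roiVoxelRange = c(150, 300)), seed = 7)
  expect_identical(b1$patients, b2$patients)
  expect_identical(b1$labels, b2$labels)
})

test_that("the default cohort mirrors the reference cohort structure", {
  sp <- cohortSpec()
  expect_equal(sp@nPatients, 30L)
  expect_equal(sp@nRS, 11L)
  b <- generateCohort(small_spec(), seed = 3)
  labels <- b$labels
  expect_length(labels, 30)
  expect_equal(sum(labels == "RS"), 11)
  expect_equal(sum(labels == "NR"), 19)
  # schedule mix reproduces the reference bin-pair pattern
  ref <- assignDoseBins(table3Schedule())
  got <- b$assignment
  expect_equal(sort(table(binImageIndex(got, "BED20"))),
               sort(table(binImageIndex(ref, "BED20"))), ignore_attr = TRUE)
  expect_equal(sort(table(binImageIndex(got, "BED40"))),
               sort(table(binImageIndex(ref, "BED40"))), ignore_attr = TRUE)
  # ROI sizes in the GTV-scale band
  nv <- vapply(b$patients, `[[`, numeric(1), "nVoxels")
  expect_true(all(nv >= 250 & nv <= 700))
})

test_that("responder drift moves co-occurrence deltas more than non-responders", {
  sp <- small_spec()
  keys <- c("glcm.correlation.NI2N", "glcm.contrast.ACUI", "glcm.homogeneity.IB1Z")
  deltas <- function(label, seeds) t(vapply(seeds, function(s) {
    pat <- generatePatient(sp, label, 5, driftFraction = 3, seed = s)
    f1 <- extractTextureFeatures(maskedROI(pat$volumes[[1]], pat$mask), nLevels = 32)
    f3 <- extractTextureFeatures(maskedROI(pat$volumes[[3]], pat$mask), nLevels = 32)
    deltaFeature(f1, f3)[keys]
  }, numeric(3)))
  drs <- deltas("RS", 1:10)
  dnr <- deltas("NR", 11:20)
  for (k in seq_along(keys))
    expect_gt(mean(abs(drs[, k])), mean(abs(dnr[, k])))
})

test_that("undersized ROIs and inconsistent class counts are rejected", {
  expect_error(cohortSpec(roiVoxelRange = c(4, 6)), "8 voxels")
  expect_error(cohortSpec(nPatients = 5, nRS = 7), "exceeds")
  expect_error(generateCohort(small_spec()), "seed")
})

test_that("written cohorts follow the on-disk layout and round-trip", {
  dir <- withr::local_tempdir()
  b <- generateCohort(cohortSpec(nPatients = 3, nRS = 1, gridDim = 16,
                                 roiVoxelRange = c(150, 300)), seed = 11,
                      dir = dir)
  expect_true(file.exists(file.path(dir, "schedule.csv")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  ids <- patientIDs(b$schedule)
  nf <- nFractions(b$schedule)
  for (p in ids) {
    for (fx in seq_len(nf[[p]])) {
      expect_true(file.exists(file.path(dir, p, sprintf("fx%d_image.nii.gz", fx))))
      expect_true(file.exists(file.path(dir, p, sprintf("fx%d_mask.nii.gz", fx))))
    }
  }
  sch <- readSchedule(file.path(dir, "schedule.csv"))
  expect_equal(totalBED(sch), totalBED(b$schedule))
  img <- RNifti::readNifti(file.path(dir, ids[1], "fx1_image.nii.gz"))
  expect_equal(array(as.numeric(img), dim = dim(img)),
               b$patients[[ids[1]]]$volumes[[1]], tolerance = 1e-6)
})

test_that("selection recovers the injected autocorrelation drift at BED20", {
  # The drift lengthens the spatial autocorrelation of responder BED20
  # images, which is carried by local co-occurrence structure: GLCM
  # features and the NGTDM neighborhood-difference features respond most
  # directly. Selection should place one of them in the top 2.
  hits <- 0
  for (s in 11:16) {
    sp <- cohortSpec(gridDim = 24, roiVoxelRange = c(300, 800))
    b <- generateCohort(sp, seed = s)
    ft <- extractCohortFeatures(b, b$assignment, pipelineConfig())
    tbl <- buildDeltaTable(ft, b$assignment, b$labels, "BED20")
    top <- topFeatures(rankByGini(tbl, nTrees = 500, seed = s))
    if (any(grepl("^(glcm|ngtdm)\\.", top))) hits <- hits + 1
  }
  expect_gte(hits, 5)
})
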