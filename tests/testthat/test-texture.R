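test_that("the direction set is the canonical half of the 26-neighborhood", {
  d <- directionSet3D()
  expect_equal(nrow(d), 13)
  expect_true(all(d %in% -1:1))
  expect_true(all(rowSums(abs(d)) > 0))
  # no two offsets are negations of each other
  keys <- apply(d, 1, paste, collapse = ",")
  negs <- apply(-d, 1, paste, collapse = ",")
  expect_length(intersect(keys, negs), 0)
  # together with negations they cover all 26 neighbors
  expect_length(unique(c(keys, negs)), 26)
})

test_that("GLCM matches hand-worked small cases", {
  # uniform 2x2x1 ROI: all mass at (1,1)
  q <- quantizedROI(array(1L, c(2, 2, 1)), nLevels = 2)
  P <- buildGLCM(q)@P
  expect_equal(P[1, 1], 1)
  # 1x1x2 ROI levels (1,2): only one direction pairs them
  q2 <- quantizedROI(array(c(1L, 2L), c(1, 1, 2)))
  P2 <- buildGLCM(q2)@P
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2))
  f <- glcmFeatures(buildGLCM(q2))
  expect_equal(unname(f["glcm.contrast.ACUI"]), 1)
  expect_equal(unname(f["glcm.sum_average.ZGXS"]), 3)
  # uniform ROI at level k: contrast 0, homogeneity 1, sum average 2k
  qk <- quantizedROI(array(3L, c(2, 2, 2)), nLevels = 4)
  fk <- glcmFeatures(buildGLCM(qk))
  expect_equal(unname(fk["glcm.contrast.ACUI"]), 0)
  expect_equal(unname(fk["glcm.dissimilarity.8S9J"]), 0)
  expect_equal(unname(fk["glcm.homogeneity.IB1Z"]), 1)
  expect_equal(unname(fk["glcm.sum_average.ZGXS"]), 6)
  expect_true(is.nan(fk["glcm.correlation.NI2N"]))  # single level: undefined
  expect_equal(unname(fk["glcm.entropy.TU9B"]), 0)  # one nonzero cell
  # no in-mask pair: error
  lone <- array(NA_integer_, c(3, 3, 3)); lone[1, 1, 1] <- 1L; lone[3, 3, 1] <- 2L
  expect_error(buildGLCM(quantizedROI(lone, 2)), "pair")
})

test_that("GLRLM matches hand-worked runs and conserves voxels", {
  # 1x1x3 levels (1,1,2), single direction (0,0,1)
  q <- quantizedROI(array(c(1L, 1L, 2L), c(1, 1, 3)))
  R <- buildGLRLM(q, directions = matrix(c(0L, 0L, 1L), 1))@R
  expect_equal(R, matrix(c(0, 1, 1, 0), 2))
  f <- glrlmFeatures(buildGLRLM(q, directions = matrix(c(0L, 0L, 1L), 1)))
  expect_equal(unname(f["glrlm.run_percentage.9ZK5"]), 2 / 3)
  # checkerboard: no two 26-neighbors share a level is impossible in 3D with
  # 2 levels, so use a line with alternating levels along every direction
  qa <- quantizedROI(array(c(1L, 2L, 1L, 2L), c(1, 1, 4)))
  Ra <- buildGLRLM(qa)
  fa <- glrlmFeatures(Ra)
  expect_equal(unname(fa["glrlm.short_run_emphasis.220V"]), 1)
  expect_equal(unname(fa["glrlm.long_run_emphasis.W4KF"]), 1)
  expect_equal(unname(fa["glrlm.run_percentage.9ZK5"]), 1)
  # merged conservation across 13 directions
  set.seed(7)
  q3 <- random_small_roi()
  g3 <- buildGLRLM(q3)
  lens <- seq_len(ncol(g3@R))
  expect_equal(sum(sweep(g3@R, 2, lens, "*")), g3@nVoxels * 13)
})

test_that("GLSZM matches hand-worked zones including corner connectivity", {
  q <- quantizedROI(array(1L, c(2, 2, 2)), nLevels = 2)
  z <- buildGLSZM(q)
  expect_equal(z@Z[1, 8], 1)
  expect_equal(sum(z@Z), 1)
  f <- glszmFeatures(z)
  expect_equal(unname(f["glszm.large_zone_emphasis.48P8"]), 64)
  expect_equal(unname(f["glszm.small_zone_emphasis.5QRC"]), 1 / 64)
  expect_equal(unname(f["glszm.zone_percentage.P30P"]), 1 / 8)
  expect_equal(unname(f["glszm.low_gray_level_zone_emphasis.XMSY"]), 1)
  # two voxels touching only at a cube corner form one zone
  la <- array(NA_integer_, c(2, 2, 2)); la[1, 1, 1] <- 1L; la[2, 2, 2] <- 1L
  z2 <- buildGLSZM(quantizedROI(la, 2))
  expect_equal(z2@Z[1, 2], 1)
  expect_equal(sum(z2@Z), 1)
  # all zones size 1: zone percentage 1
  lb2 <- array(c(1L, NA, 2L), c(3, 1, 1))
  z3 <- buildGLSZM(quantizedROI(lb2, 2))
  expect_equal(unname(glszmFeatures(z3)["glszm.zone_percentage.P30P"]), 1)
})

test_that("NGTDM matches hand-worked cases and the degenerate policy", {
  # 1x1x2 levels (1,2): each voxel has one neighbor, |1-2| = 1
  q <- quantizedROI(array(c(1L, 2L), c(1, 1, 2)))
  m <- buildNGTDM(q)
  expect_equal(m@s, c(1, 1))
  expect_equal(m@n, c(1, 1))
  f <- ngtdmFeatures(m, modified = FALSE)
  # hand evaluation: p = (1/2, 1/2), s = (1, 1), Ngp = 2
  expect_equal(unname(f["ngtdm.contrast.65HE"]),
               (0.5 * 0.5 * 1) / (2 * 1) * (2 / 2) * 2)
  expect_equal(unname(f["ngtdm.coarseness.QCDE"]), 1)
  # uniform ROI: zero contrast/complexity, sentinel coarseness/busyness
  qu <- quantizedROI(array(2L, c(2, 2, 2)), nLevels = 3)
  fu <- ngtdmFeatures(buildNGTDM(qu))
  expect_equal(unname(fu["ngtdm.contrast.65HE"]), 0)
  expect_equal(unname(fu["ngtdm.complexity.HDEZ"]), 0)
  expect_true(is.nan(fu["ngtdm.coarseness.QCDE"]))
  expect_true(is.nan(fu["ngtdm.busyness.NQ30"]))
})

test_that("all four matrices equal brute-force enumeration on random ROIs", {
  set.seed(101)
  for (rep in 1:40) {
    q <- random_small_roi()
    L <- q@levels; G <- q@nLevels
    nv <- sum(!is.na(L))
    expect_equal(buildGLCM(q)@P, oracle_glcm(L, G), tolerance = 1e-12)
    R <- buildGLRLM(q)@R
    RO <- oracle_glrlm(L, G)
    expect_equal(R, RO, tolerance = 1e-12, ignore_attr = TRUE)
    Z <- buildGLSZM(q)@Z
    ZO <- oracle_glszm(L, G)
    expect_equal(Z, ZO, tolerance = 1e-12, ignore_attr = TRUE)
    m <- buildNGTDM(q)
    mo <- oracle_ngtdm(L, G)
    expect_equal(m@s, mo$s, tolerance = 1e-10)
    expect_equal(m@n, mo$n)
  }
})

test_that("per-direction runs conserve voxels before merging", {
  set.seed(33)
  dirs <- directionSet3D()
  for (rep in 1:5) {
    q <- random_small_roi()
    nv <- sum(!is.na(q@levels))
    for (d in seq_len(nrow(dirs))) {
      Rd <- buildGLRLM(q, directions = dirs[d, , drop = FALSE])@R
      expect_equal(sum(sweep(Rd, 2, seq_len(ncol(Rd)), "*")), nv)
    }
  }
})

test_that("the extracted vector has the 39 registry features and is stable", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 39)
  expect_equal(as.integer(table(reg$class)[c("glcm", "glrlm", "glszm", "ngtdm")]),
               c(8, 13, 13, 5))
  expect_false(anyDuplicated(reg$key) > 0)
  expect_equal(sum(reg$modified), 5)
  roi <- random_field_roi(10, seed = 2)
  fv1 <- extractTextureFeatures(roi, nLevels = 16)
  fv2 <- extractTextureFeatures(roi, nLevels = 16)
  expect_identical(fv1, fv2)            # determinism
  expect_equal(names(fv1), reg$key)
  expect_true(all(is.finite(fv1)))
})

test_that("features are invariant to 90-degree grid rotations", {
  roi <- random_field_roi(10, seed = 4)
  fv <- extractTextureFeatures(roi, nLevels = 16)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  for (ax in 1:3) {
    img <- roi@image; msk <- roi@mask
    if (ax == 2) { img <- aperm(img, c(2, 3, 1)); msk <- aperm(msk, c(2, 3, 1)) }
    if (ax == 3) { img <- aperm(img, c(3, 1, 2)); msk <- aperm(msk, c(3, 1, 2)) }
    fr <- extractTextureFeatures(maskedROI(rot(img), rot(msk)), nLevels = 16)
    expect_equal(unname(fr), unname(fv), tolerance = 1e-12)
  }
})

test_that("unmodified twins relate to the modified features as documented", {
  roi <- random_field_roi(10, seed = 6)
  q <- quantizeHistEq(limitDynamicRange(roi), 16)
  nv <- sum(!is.na(q@levels))
  r <- buildGLRLM(q)
  fm <- glrlmFeatures(r, modified = TRUE)
  fu <- glrlmFeatures(r, modified = FALSE)
  Nr <- sum(r@R)
  expect_equal(fm[["glrlm.gray_level_nonuniformity.R5YN"]],
               fu[["glrlm.gray_level_nonuniformity.R5YN"]] / Nr)
  expect_equal(fm[["glrlm.run_length_nonuniformity.W92Y"]],
               fu[["glrlm.run_length_nonuniformity.W92Y"]] / Nr)
  m <- buildNGTDM(q)
  nm <- ngtdmFeatures(m, modified = TRUE)
  nu <- ngtdmFeatures(m, modified = FALSE)
  expect_equal(nm[["ngtdm.coarseness.QCDE"]], nu[["ngtdm.coarseness.QCDE"]] * nv)
  expect_equal(nm[["ngtdm.busyness.NQ30"]], nu[["ngtdm.busyness.NQ30"]] / nv)
})
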