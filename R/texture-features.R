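# The 39 texture features. Formulas follow the standard IBSI definitions
# on the merged matrices; the five features flagged `modified` use
# volume-decoupled variants (see the methods vignette): GLRLM gray-level /
# run-length non-uniformity are normalized by the run count, NGTDM
# coarseness is multiplied and busyness divided by the voxel count. GLCM
# energy is flagged but identical to the IBSI form at the default settings.
# Degenerate denominators yield NaN ("degenerate sentinel"), never an error.

.registryTable <- local({
  df <- rbind(
    data.frame(class = "glcm", feature = c(
      "contrast", "dissimilarity", "homogeneity", "correlation", "energy",
      "variance", "entropy", "sum_average"),
      code = c("ACUI", "8S9J", "IB1Z", "NI2N", "8ZQL", "UR99", "TU9B", "ZGXS"),
      modified = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    data.frame(class = "glrlm", feature = c(
      "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
      "run_length_nonuniformity", "run_percentage",
      "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
      "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
      "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis",
      "gray_level_variance", "run_length_variance"),
      code = c("220V", "W4KF", "R5YN", "W92Y", "9ZK5", "V3SW", "G3QZ",
               "HTZT", "GD3A", "IVPO", "3KUM", "8CE5", "8CE5"),
      modified = c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 9))),
    data.frame(class = "glszm", feature = c(
      "small_zone_emphasis", "large_zone_emphasis", "gray_level_nonuniformity",
      "zone_size_nonuniformity", "zone_percentage",
      "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
      "small_zone_low_gray_level_emphasis", "small_zone_high_gray_level_emphasis",
      "large_zone_low_gray_level_emphasis", "large_zone_high_gray_level_emphasis",
      "gray_level_variance", "zone_size_variance"),
      code = c("5QRC", "48P8", "JNSA", "4JP3", "P30P", "XMSY", "5GN9",
               "5RAI", "HW1V", "YH51", "J17V", "BYLV", "BYLV"),
      modified = rep(FALSE, 13)),
    data.frame(class = "ngtdm", feature = c(
      "coarseness", "contrast", "busyness", "complexity", "strength"),
      code = c("QCDE", "65HE", "NQ30", "HDEZ", "1X9X"),
      modified = c(TRUE, FALSE, TRUE, FALSE, FALSE)))
  df$key <- paste(df$class, df$feature, df$code, sep = ".")
  df
})

#' The 39-feature registry
#'
#' One row per texture feature: matrix class, feature name, IBSI code as
#' printed in the feature table this package implements, whether the
#' feature uses a volume-decoupled ("modified") form, and the column key
#' \code{class.feature.code} used in all feature vectors and delta tables.
#'
#' @return A data.frame with 39 rows and columns \code{class},
#'   \code{feature}, \code{code}, \code{modified}, \code{key}.
#' @export
featureRegistry <- function() .registryTable

# marginal level distribution of a symmetric GLCM
.glcmMarginal <- function(P) rowSums(P)

#' Co-occurrence features
#'
#' Contrast, dissimilarity, homogeneity (inverse difference), correlation,
#' energy, (joint) variance, (joint) entropy, and sum average of a
#' symmetric normalized GLCM. Correlation is NaN for a single-level ROI.
#'
#' @param glcm A [GLCMatrix-class].
#' @return Named numeric vector of 8 features (registry keys).
#' @export
glcmFeatures <- function(glcm) {
  stopifnot(methods::is(glcm, "GLCMatrix"))
  P <- glcm@P
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pg <- .glcmMarginal(P)
  mu <- sum(seq_len(G) * pg)
  sig2 <- sum((seq_len(G) - mu)^2 * pg)
  pos <- P > 0
  out <- c(
    contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + abs(i - j))),
    correlation = if (sig2 > 0) (sum(P * i * j) - mu^2) / sig2 else NaN,
    energy = sum(P^2),
    variance = sum(P * (i - mu)^2),
    entropy = -sum(P[pos] * log2(P[pos])),
    sum_average = sum(P * (i + j)))
  names(out) <- .registryTable$key[.registryTable$class == "glcm"]
  out
}

#' Run-length features
#'
#' The 13 run-length statistics of a merged GLRLM. With the modified
#' (volume-decoupled) forms, gray-level and run-length non-uniformity are
#' additionally divided by the total run count. Run percentage is
#' \code{n_runs / (N_v * n_directions)} under merged aggregation.
#'
#' @param glrlm A [GLRLMatrix-class].
#' @param modified Use the volume-decoupled non-uniformities (default TRUE).
#' @return Named numeric vector of 13 features (registry keys).
#' @export
glrlmFeatures <- function(glrlm, modified = TRUE) {
  stopifnot(methods::is(glrlm, "GLRLMatrix"))
  R <- glrlm@R
  Nr <- sum(R)
  g <- seq_len(nrow(R)); l <- seq_len(ncol(R))
  rg <- rowSums(R)   # per gray level
  rl <- colSums(R)   # per run length
  p <- R / Nr
  mug <- sum(g * rg) / Nr
  mul <- sum(l * rl) / Nr
  gln <- sum(rg^2) / Nr
  rln <- sum(rl^2) / Nr
  out <- c(
    short_run_emphasis = sum(t(t(R) / l^2)) / Nr,
    long_run_emphasis = sum(t(t(R) * l^2)) / Nr,
    gray_level_nonuniformity = if (modified) gln / Nr else gln,
    run_length_nonuniformity = if (modified) rln / Nr else rln,
    run_percentage = Nr / (glrlm@nVoxels * glrlm@nDirections),
    low_gray_level_run_emphasis = sum(rg / g^2) / Nr,
    high_gray_level_run_emphasis = sum(rg * g^2) / Nr,
    short_run_low_gray_level_emphasis = sum(R / outer(g^2, l^2)) / Nr,
    short_run_high_gray_level_emphasis = sum(R * outer(g^2, 1 / l^2)) / Nr,
    long_run_low_gray_level_emphasis = sum(R * outer(1 / g^2, l^2)) / Nr,
    long_run_high_gray_level_emphasis = sum(R * outer(g^2, l^2)) / Nr,
    gray_level_variance = sum(p * (matrix(g, length(g), length(l)) - mug)^2),
    run_length_variance = sum(p * (matrix(l, length(g), length(l), byrow = TRUE) - mul)^2))
  names(out) <- .registryTable$key[.registryTable$class == "glrlm"]
  out
}

#' Size-zone features
#'
#' The 13 size-zone statistics of a GLSZM, including large zone low
#' gray-level emphasis. Zone percentage is \code{n_zones / N_v}.
#'
#' @param glszm A [GLSZMatrix-class].
#' @return Named numeric vector of 13 features (registry keys).
#' @export
glszmFeatures <- function(glszm) {
  stopifnot(methods::is(glszm, "GLSZMatrix"))
  Z <- glszm@Z
  Nz <- sum(Z)
  g <- seq_len(nrow(Z)); s <- seq_len(ncol(Z))
  zg <- rowSums(Z); zs <- colSums(Z)
  p <- Z / Nz
  mug <- sum(g * zg) / Nz
  mus <- sum(s * zs) / Nz
  out <- c(
    small_zone_emphasis = sum(t(t(Z) / s^2)) / Nz,
    large_zone_emphasis = sum(t(t(Z) * s^2)) / Nz,
    gray_level_nonuniformity = sum(zg^2) / Nz,
    zone_size_nonuniformity = sum(zs^2) / Nz,
    zone_percentage = Nz / glszm@nVoxels,
    low_gray_level_zone_emphasis = sum(zg / g^2) / Nz,
    high_gray_level_zone_emphasis = sum(zg * g^2) / Nz,
    small_zone_low_gray_level_emphasis = sum(Z / outer(g^2, s^2)) / Nz,
    small_zone_high_gray_level_emphasis = sum(Z * outer(g^2, 1 / s^2)) / Nz,
    large_zone_low_gray_level_emphasis = sum(Z * outer(1 / g^2, s^2)) / Nz,
    large_zone_high_gray_level_emphasis = sum(Z * outer(g^2, s^2)) / Nz,
    gray_level_variance = sum(p * (matrix(g, length(g), length(s)) - mug)^2),
    zone_size_variance = sum(p * (matrix(s, length(g), length(s), byrow = TRUE) - mus)^2))
  names(out) <- .registryTable$key[.registryTable$class == "glszm"]
  out
}

#' Neighborhood gray-tone difference features
#'
#' Coarseness, contrast, busyness, complexity and strength. With the
#' modified (volume-decoupled) forms, coarseness is multiplied and busyness
#' divided by the ROI voxel count. A uniform ROI has zero contrast and
#' complexity but undefined coarseness and busyness, which return NaN.
#'
#' @param ngtdm A [NGTDMatrix-class].
#' @param modified Use the volume-decoupled coarseness/busyness (default TRUE).
#' @return Named numeric vector of 5 features (registry keys).
#' @export
ngtdmFeatures <- function(ngtdm, modified = TRUE) {
  stopifnot(methods::is(ngtdm, "NGTDMatrix"))
  s <- ngtdm@s; n <- ngtdm@n
  N <- sum(n)
  Nv <- as.numeric(ngtdm@nVoxels)
  p <- n / N
  act <- which(p > 0)
  Ngp <- length(act)
  i <- seq_along(p)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else NaN
  if (Ngp > 1) {
    ii <- matrix(i[act], Ngp, Ngp); jj <- t(ii)
    pi_ <- matrix(p[act], Ngp, Ngp); pj <- t(pi_)
    si <- matrix(s[act], Ngp, Ngp); sj <- t(si)
    contrast <- sum(pi_ * pj * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(ii * pi_ - jj * pj))
    busy <- if (busy_den > 0) ps / busy_den else NaN
    complexity <- sum(abs(ii - jj) * (pi_ * si + pj * sj) / (pi_ + pj)) / N
    str_num <- sum((pi_ + pj) * (ii - jj)^2)
    strength <- if (sum(s) > 0) str_num / sum(s) else 0
  } else {
    contrast <- 0; busy <- NaN; complexity <- 0; strength <- 0
  }
  out <- c(
    coarseness = if (modified) coarse * Nv else coarse,
    contrast = contrast,
    busyness = if (modified) busy / Nv else busy,
    complexity = complexity,
    strength = strength)
  names(out) <- .registryTable$key[.registryTable$class == "ngtdm"]
  out
}

#' Extract the full 39-feature texture vector from a masked ROI
#'
#' The complete per-image pipeline: dynamic-range limiting to
#' \eqn{\mu \pm k\sigma}, histogram-equalization quantization to G gray
#' levels, construction of the four texture matrices over the
#' 26-neighborhood, and evaluation of all 39 features in registry order.
#' Internal conservation identities (GLCM probabilities sum to 1, GLSZM
#' zone sizes and NGTDM counts sum to the voxel count) are asserted on
#' every extraction.
#'
#' @param roi A [MaskedROI-class] (or an already-quantized
#'   [QuantizedROI-class], in which case preprocessing is skipped).
#' @param nLevels Gray levels G for quantization, default 64.
#' @param kSigma Dynamic-range limit in standard deviations, default 3.
#' @param modified Use the volume-decoupled feature variants (default TRUE).
#' @param displacement GLCM voxel displacement, default 1.
#' @return Named numeric vector of length 39 (registry keys, registry
#'   order). Degenerate features are NaN.
#' @examples
#' set.seed(1)
#' img <- array(rnorm(8^3), c(8, 8, 8))
#' msk <- array(TRUE, c(8, 8, 8))
#' fv <- extractTextureFeatures(maskedROI(img, msk), nLevels = 8)
#' length(fv)  # 39
#' @export
extractTextureFeatures <- function(roi, nLevels = 64, kSigma = 3,
                                   modified = TRUE, displacement = 1L) {
  if (methods::is(roi, "MaskedROI")) {
    q <- quantizeHistEq(limitDynamicRange(roi, kSigma = kSigma),
                        nLevels = nLevels)
  } else if (methods::is(roi, "QuantizedROI")) {
    q <- roi
  } else stop("roi must be a MaskedROI or QuantizedROI")
  nv <- sum(!is.na(q@levels))
  glcm <- buildGLCM(q, displacement = displacement)
  glrlm <- buildGLRLM(q)
  glszm <- buildGLSZM(q)
  ngtdm <- buildNGTDM(q)
  stopifnot(abs(sum(glcm@P) - 1) < 1e-8,
            abs(sum(sweep(glszm@Z, 2, seq_len(ncol(glszm@Z)), "*")) - nv) < 1e-6)
  out <- c(glcmFeatures(glcm),
           glrlmFeatures(glrlm, modified = modified),
           glszmFeatures(glszm),
           ngtdmFeatures(ngtdm, modified = modified))
  stopifnot(identical(names(out), .registryTable$key))
  out
}
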