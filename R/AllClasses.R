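#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TreatmentSchedule: per-patient fractionation and BED bookkeeping
#'
#' Holds one row per patient with the fraction count, total biologically
#' effective dose (BED), BED per fraction and (optionally) the physical dose
#' per fraction, plus the binary response label. BED is computed with the
#' linear-quadratic formula \eqn{n d (1 + d/(\alpha/\beta))} using
#' \eqn{\alpha/\beta = 10} Gy by default.
#'
#' @slot patientData A \link[S4Vectors]{DataFrame} with columns
#'   \code{patient_id}, \code{n_fractions}, \code{dose_per_fraction_gy}
#'   (may be \code{NA}), \code{total_bed_gy}, \code{bed_per_fraction_gy},
#'   \code{response} (\code{"RS"} or \code{"NR"}, may be \code{NA}).
#' @slot alphaBeta Numeric scalar, the \eqn{\alpha/\beta} ratio in Gy.
#'
#' @seealso [treatmentSchedule()], [assignDoseBins()], [table3Schedule()]
#' @export
setClass("TreatmentSchedule",
  representation(patientData = "DataFrame", alphaBeta = "numeric"))

setValidity("TreatmentSchedule", function(object) {
  pd <- object@patientData
  need <- c("patient_id", "n_fractions", "dose_per_fraction_gy",
            "total_bed_gy", "bed_per_fraction_gy", "response")
  if (!all(need %in% colnames(pd)))
    return(paste("missing columns:", paste(setdiff(need, colnames(pd)), collapse = ", ")))
  if (anyDuplicated(pd$patient_id)) return("duplicated patient_id")
  if (any(pd$n_fractions < 1)) return("n_fractions must be >= 1")
  d <- pd$dose_per_fraction_gy
  if (any(!is.na(d) & d <= 0)) return("dose_per_fraction_gy must be positive")
  # bed_per_fraction * n_fractions must reproduce total_bed to 0.1 Gy
  gap <- abs(pd$bed_per_fraction_gy * pd$n_fractions - pd$total_bed_gy)
  if (any(gap > 0.1 + 1e-9))
    return("bed_per_fraction_gy * n_fractions differs from total_bed_gy by more than 0.1 Gy")
  resp <- pd$response
  if (any(!is.na(resp) & !resp %in% c("RS", "NR")))
    return("response must be 'RS', 'NR' or NA")
  if (length(object@alphaBeta) != 1L || object@alphaBeta <= 0)
    return("alphaBeta must be a positive scalar")
  TRUE
})

#' DoseBinAssignment: fraction image indices for the BED20 and BED40 bins
#'
#' For each patient, the 1-based fraction index of the setup image paired
#' with the fraction-1 (pre-treatment) image for the BED20 bin (cumulative
#' delivered BED in [20, 30] Gy) and the BED40 bin (cumulative delivered
#' BED >= 40 Gy). Dose delivered after fraction k is credited to the setup
#' image of fraction k + 1, since setup images are acquired before delivery.
#' An unreachable bin is stored as \code{NA} (the patient is excluded from
#' that bin, never zero-filled).
#'
#' @slot assignments A \link[S4Vectors]{DataFrame} with columns
#'   \code{patient_id}, \code{bed20_image_index}, \code{bed40_image_index},
#'   \code{bed20_out_of_window} (logical: first crossing of 20 Gy overshot
#'   30 Gy).
#' @export
setClass("DoseBinAssignment", representation(assignments = "DataFrame"))

setValidity("DoseBinAssignment", function(object) {
  a <- object@assignments
  need <- c("patient_id", "bed20_image_index", "bed40_image_index",
            "bed20_out_of_window")
  if (!all(need %in% colnames(a)))
    return(paste("missing columns:", paste(setdiff(need, colnames(a)), collapse = ", ")))
  i20 <- a$bed20_image_index; i40 <- a$bed40_image_index
  bad <- !is.na(i20) & i20 < 2
  if (any(bad)) return("bed20_image_index must be >= 2 (fraction-1 image is the baseline)")
  both <- !is.na(i20) & !is.na(i40)
  if (any(both & i40 <= i20))
    return("bed40_image_index must exceed bed20_image_index")
  TRUE
})

#' MaskedROI: a real-valued image restricted to a binary mask
#'
#' The raw contract between image I/O and preprocessing: a 3D intensity
#' array, a congruent logical mask (the GTV), and the voxel size in mm.
#' All ROI statistics (mean, SD, empirical CDF) are computed over in-mask
#' voxels only.
#'
#' @slot image Numeric 3D array of voxel intensities.
#' @slot mask Logical 3D array, same dimensions as \code{image}.
#' @slot voxelSize Numeric length-3, voxel edge lengths in mm.
#' @seealso [maskedROI()], [limitDynamicRange()], [quantizeHistEq()]
#' @export
setClass("MaskedROI",
  representation(image = "array", mask = "array", voxelSize = "numeric"))

setValidity("MaskedROI", function(object) {
  if (length(dim(object@image)) != 3L) return("image must be a 3D array")
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask dimensions differ")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask is empty")
  if (any(!is.finite(object@image[object@mask])))
    return("in-mask intensities must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers (mm)")
  TRUE
})

#' QuantizedROI: integer gray levels 1..G over the mask
#'
#' Produced by [quantizeHistEq()]. Out-of-mask voxels carry \code{NA} and
#' are excluded from every texture statistic.
#'
#' @slot levels Integer 3D array; in-mask voxels hold levels in 1..G,
#'   out-of-mask voxels hold \code{NA}.
#' @slot nLevels Integer, the number of gray levels G (default 64).
#' @slot voxelSize Numeric length-3 voxel size in mm.
#' @export
setClass("QuantizedROI",
  representation(levels = "array", nLevels = "integer", voxelSize = "numeric"))

setValidity("QuantizedROI", function(object) {
  if (length(dim(object@levels)) != 3L) return("levels must be a 3D array")
  v <- object@levels[!is.na(object@levels)]
  if (length(v) == 0L) return("no in-mask voxels")
  if (any(v < 1L | v > object@nLevels))
    return("in-mask levels must lie in [1, nLevels]")
  if (object@nLevels < 2L) return("nLevels must be >= 2")
  TRUE
})

# ---- texture matrix containers -------------------------------------------

#' GLCMatrix: merged-direction gray-level co-occurrence matrix
#'
#' Symmetric G x G probability table accumulated over the 13 unique
#' 26-neighborhood directions and both orientations (IBSI merged-3D
#' aggregation, code IAZD), at a voxel displacement of one.
#'
#' @slot P Numeric G x G matrix; entries sum to 1.
#' @slot displacement Integer voxel displacement (1).
#' @export
setClass("GLCMatrix", representation(P = "matrix", displacement = "integer"))

setValidity("GLCMatrix", function(object) {
  P <- object@P
  if (nrow(P) != ncol(P)) return("P must be square")
  if (any(P < 0)) return("P entries must be >= 0")
  if (abs(sum(P) - 1) > 1e-8) return("P entries must sum to 1")
  if (max(abs(P - t(P))) > 1e-12) return("P must be symmetric")
  TRUE
})

#' GLRLMatrix: merged-direction gray-level run-length matrix
#'
#' Counts of maximal same-level runs by (gray level, run length), summed
#' over the 13 unique scan directions (IBSI merged aggregation, IAZD).
#' Under merged aggregation the voxel-conservation identity is
#' \eqn{\sum_{g,l} R(g,l) \, l = N_v \times n_{dir}}.
#'
#' @slot R Numeric G x Lmax count matrix.
#' @slot nVoxels Integer, in-mask voxel count.
#' @slot nDirections Integer, number of merged directions (13).
#' @export
setClass("GLRLMatrix",
  representation(R = "matrix", nVoxels = "integer", nDirections = "integer"))

setValidity("GLRLMatrix", function(object) {
  if (any(object@R < 0)) return("run counts must be >= 0")
  lens <- seq_len(ncol(object@R))
  tot <- sum(sweep(object@R, 2, lens, "*"))
  if (abs(tot - object@nVoxels * object@nDirections) > 1e-6)
    return("run lengths do not conserve voxels across merged directions")
  TRUE
})

#' GLSZMatrix: gray-level size-zone matrix (26-connectivity)
#'
#' Counts of 26-connected constant-level zones by (gray level, zone size).
#' Zone sizes partition the ROI: \eqn{\sum_{g,s} Z(g,s)\, s = N_v}.
#'
#' @slot Z Numeric G x Smax count matrix.
#' @slot nVoxels Integer, in-mask voxel count.
#' @export
setClass("GLSZMatrix", representation(Z = "matrix", nVoxels = "integer"))

setValidity("GLSZMatrix", function(object) {
  if (any(object@Z < 0)) return("zone counts must be >= 0")
  sizes <- seq_len(ncol(object@Z))
  if (abs(sum(sweep(object@Z, 2, sizes, "*")) - object@nVoxels) > 1e-6)
    return("zone sizes must sum to the voxel count")
  TRUE
})

#' NGTDMatrix: neighborhood gray-tone difference matrix
#'
#' For each gray level i: \code{n[i]} voxels at that level having at least
#' one in-mask 26-neighbor, and \code{s[i]} the summed absolute difference
#' between the level and the mean level of the in-mask neighbors.
#'
#' @slot s Numeric length-G vector of summed absolute differences.
#' @slot n Numeric length-G vector of voxel counts per level.
#' @slot nVoxels Integer, in-mask voxel count of the ROI (isolated voxels
#'   with no in-mask neighbor are excluded from \code{n} but counted here).
#' @export
setClass("NGTDMatrix",
  representation(s = "numeric", n = "numeric", nVoxels = "integer"))

setValidity("NGTDMatrix", function(object) {
  if (length(object@s) != length(object@n)) return("s and n lengths differ")
  if (any(object@s < 0)) return("s entries must be >= 0")
  if (any(object@n == 0 & object@s != 0)) return("levels with n = 0 must have s = 0")
  if (sum(object@n) > object@nVoxels + 1e-9)
    return("counted voxels exceed the ROI voxel count")
  TRUE
})

# ---- analysis containers -------------------------------------------------

#' DeltaFeatureTable: per-patient delta features for one dose bin
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"delta"} (39 features x patients; delta = pre - post), feature
#' metadata in \code{rowData} (class, feature name, IBSI code, modified
#' flag) and the binary response label plus paired fraction index in
#' \code{colData}. \code{metadata()} records the bin tag (\code{"BED20"} or
#' \code{"BED40"}) and the delta convention. An optional assay
#' \code{"percent_change"} holds \eqn{100 (pre - post)/pre}.
#'
#' @seealso [buildDeltaTable()], [rankByGini()], [bootstrapValidate()]
#' @export
setClass("DeltaFeatureTable", contains = "SummarizedExperiment")

setValidity("DeltaFeatureTable", function(object) {
  if (!"delta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'delta' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"response" %in% colnames(cd)) return("colData must contain 'response'")
  if (any(!cd$response %in% c("RS", "NR")))
    return("response must be 'RS' or 'NR'")
  bt <- S4Vectors::metadata(object)$bin_tag
  if (is.null(bt) || !bt %in% c("BED20", "BED40"))
    return("metadata bin_tag must be 'BED20' or 'BED40'")
  TRUE
})

#' ImportanceRanking: random-forest Gini importance ranking
#'
#' Mean decrease in Gini per delta feature from a classification forest
#' trained on response labels, sorted in decreasing importance (ties broken
#' by feature name), plus the selected top-k feature names.
#'
#' @slot ranking A \link[S4Vectors]{DataFrame} with columns \code{feature},
#'   \code{mean_decrease_gini}, \code{rank}.
#' @slot topFeatures Character, the selected top-k feature names.
#' @slot nTrees Integer, number of trees grown.
#' @slot seed Integer seed used for the forest.
#' @slot binTag Character, \code{"BED20"} or \code{"BED40"}.
#' @export
setClass("ImportanceRanking",
  representation(ranking = "DataFrame", topFeatures = "character",
                 nTrees = "integer", seed = "integer", binTag = "character"))

setValidity("ImportanceRanking", function(object) {
  r <- object@ranking
  if (!all(c("feature", "mean_decrease_gini", "rank") %in% colnames(r)))
    return("ranking must have feature, mean_decrease_gini, rank")
  if (any(r$mean_decrease_gini < -1e-9)) return("importances must be >= 0")
  if (!identical(sort(r$rank), seq_len(nrow(r)))) return("rank must be a permutation")
  if (!all(object@topFeatures %in% r$feature))
    return("topFeatures must be ranked features")
  TRUE
})

#' ValidationReport: bootstrapped logistic-regression internal validation
#'
#' Per-iteration AUCs from refitting a two-feature logistic regression on
#' random training subsets and scoring all patients, with the mean and the
#' empirical 2.5/97.5 percentiles.
#'
#' @slot binTag Character, \code{"BED20"} or \code{"BED40"}.
#' @slot features Character, the two covariate names.
#' @slot aucs Numeric vector of per-iteration AUCs.
#' @slot meanAUC Numeric scalar.
#' @slot ci Numeric length-2, the 2.5 and 97.5 percentiles.
#' @slot nIter Integer iteration count.
#' @slot trainFraction Numeric, fraction of patients in each training set.
#' @slot seed Integer seed.
#' @slot nRedraws Integer, single-class training draws that were redrawn.
#' @slot nRidge Integer, separable fits refit with a ridge penalty.
#' @export
setClass("ValidationReport",
  representation(binTag = "character", features = "character",
                 aucs = "numeric", meanAUC = "numeric", ci = "numeric",
                 nIter = "integer", trainFraction = "numeric",
                 seed = "integer", nRedraws = "integer", nRidge = "integer"))

setValidity("ValidationReport", function(object) {
  if (any(object@aucs < -1e-12 | object@aucs > 1 + 1e-12))
    return("AUCs must lie in [0, 1]")
  if (length(object@ci) != 2L) return("ci must have length 2")
  if (object@ci[1] > object@ci[2] + 1e-12)
    return("2.5 percentile must not exceed 97.5 percentile")
  TRUE
})

# ---- show methods --------------------------------------------------------

setMethod("show", "TreatmentSchedule", function(object) {
  pd <- object@patientData
  cat("TreatmentSchedule with", nrow(pd), "patients\n")
  cat("  alpha/beta:", object@alphaBeta, "Gy\n")
  cat("  total BED [Gy]: median", stats::median(pd$total_bed_gy),
      " range", min(pd$total_bed_gy), "-", max(pd$total_bed_gy), "\n")
  if (!all(is.na(pd$response)))
    cat("  response:", sum(pd$response == "RS", na.rm = TRUE), "RS /",
        sum(pd$response == "NR", na.rm = TRUE), "NR\n")
})

setMethod("show", "DoseBinAssignment", function(object) {
  a <- object@assignments
  cat("DoseBinAssignment for", nrow(a), "patients\n")
  cat("  BED20 reachable:", sum(!is.na(a$bed20_image_index)),
      " BED40 reachable:", sum(!is.na(a$bed40_image_index)), "\n")
})

setMethod("show", "MaskedROI", function(object) {
  cat("MaskedROI", paste(dim(object@image), collapse = " x "),
      "grid,", sum(object@mask), "in-mask voxels,",
      paste(object@voxelSize, collapse = " x "), "mm\n")
})

setMethod("show", "QuantizedROI", function(object) {
  cat("QuantizedROI", paste(dim(object@levels), collapse = " x "),
      "grid,", sum(!is.na(object@levels)), "in-mask voxels,",
      object@nLevels, "gray levels\n")
})

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking (", object@binTag, "): ", object@nTrees,
      " trees, seed ", object@seed, "\n", sep = "")
  cat("  top features:", paste(object@topFeatures, collapse = ", "), "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport (", object@binTag, "): ",
      length(object@aucs), " iterations\n", sep = "")
  cat("  features:", paste(object@features, collapse = " + "), "\n")
  cat(sprintf("  mean AUC %.3f [%.3f-%.3f]\n",
              object@meanAUC, object@ci[1], object@ci[2]))
})
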