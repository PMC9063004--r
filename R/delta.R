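#' Delta feature value
#'
#' The delta convention is pre-treatment minus post-dose
#' (\code{pre - post}), so a feature that increases under treatment has a
#' negative delta. Degenerate (NaN) inputs propagate to missing.
#'
#' @param fPre Feature value on the pre-treatment (fraction 1) image.
#' @param fPost Feature value on the dose-bin image.
#' @return \code{fPre - fPost}; \code{NA} if either input is missing.
#' @examples
#' deltaFeature(10, 12)  # -2: an increase gives a negative delta
#' @export
deltaFeature <- function(fPre, fPost) {
  out <- fPre - fPost
  out[!is.finite(fPre) | !is.finite(fPost)] <- NA_real_
  out
}

#' Percent change relative to the pre-treatment value
#'
#' \eqn{100 (pre - post)/pre}: increases are negative percent changes,
#' decreases positive. Used for summary plots, not for the models.
#'
#' @param fPre Pre-treatment feature value (nonzero).
#' @param fPost Post-dose feature value.
#' @return Percent change; \code{NA} (with a warning) where \code{fPre} is 0.
#' @examples
#' percentChange(10, 12)  # -20
#' percentChange(10, 5)   # +50
#' @export
percentChange <- function(fPre, fPost) {
  out <- 100 * (fPre - fPost) / fPre
  bad <- !is.finite(fPre) | !is.finite(fPost) | fPre == 0
  if (any(bad & fPre == 0, na.rm = TRUE))
    warning("percent change undefined where the pre-treatment value is 0")
  out[bad] <- NA_real_
  out
}

#' Build the per-patient delta feature table for one dose bin
#'
#' Pairs each patient's fraction-1 feature vector with the vector of the
#' fraction assigned to the requested bin and emits the 39 deltas
#' (\code{pre - post}) plus a percent-change assay. Patients whose bin is
#' unreachable, or whose assigned fraction has no extracted features, are
#' dropped with a warning — never zero-filled.
#'
#' @param featureTable Tidy data.frame of extracted features: columns
#'   \code{patient_id}, \code{fraction}, then the 39 registry keys (one row
#'   per patient-fraction image).
#' @param assignment A [DoseBinAssignment-class].
#' @param labels Named character vector of \code{"RS"}/\code{"NR"} response
#'   labels, names = patient IDs.
#' @param binTag \code{"BED20"} or \code{"BED40"}.
#' @return A [DeltaFeatureTable-class] (39 features x patients).
#' @export
buildDeltaTable <- function(featureTable, assignment, labels, binTag) {
  binTag <- match.arg(binTag, c("BED20", "BED40"))
  stopifnot(methods::is(assignment, "DoseBinAssignment"))
  keys <- featureRegistry()$key
  if (!all(keys %in% colnames(featureTable)))
    stop("featureTable lacks registry feature columns")
  idx <- binImageIndex(assignment, binTag)
  pats <- patientIDs(assignment)
  delta <- pct <- matrix(NA_real_, nrow = length(keys), ncol = 0,
                         dimnames = list(keys, NULL))
  kept <- character(0)
  frac_used <- integer(0)
  for (p in pats) {
    k <- idx[[p]]
    if (is.na(k)) {
      warning(sprintf("patient %s: %s bin unreachable, dropped", p, binTag))
      next
    }
    pre <- featureTable[featureTable$patient_id == p & featureTable$fraction == 1L, keys]
    post <- featureTable[featureTable$patient_id == p & featureTable$fraction == k, keys]
    if (nrow(pre) != 1L || nrow(post) != 1L) {
      warning(sprintf("patient %s: missing image features for %s, dropped", p, binTag))
      next
    }
    pre <- as.numeric(pre); post <- as.numeric(post)
    delta <- cbind(delta, deltaFeature(pre, post))
    pct <- cbind(pct, suppressWarnings(percentChange(pre, post)))
    kept <- c(kept, p)
    frac_used <- c(frac_used, k)
  }
  if (length(kept) == 0L) stop("no patient reaches the ", binTag, " bin")
  colnames(delta) <- colnames(pct) <- kept
  if (!all(kept %in% names(labels))) stop("missing response labels")
  reg <- featureRegistry()
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(delta = delta, percent_change = pct),
    rowData = S4Vectors::DataFrame(class = reg$class, feature = reg$feature,
                                   code = reg$code, modified = reg$modified,
                                   row.names = reg$key),
    colData = S4Vectors::DataFrame(response = unname(labels[kept]),
                                   paired_fraction = frac_used,
                                   row.names = kept))
  dt <- methods::as(se, "DeltaFeatureTable")
  S4Vectors::metadata(dt) <- list(bin_tag = binTag,
                                  convention = "pre_minus_post")
  methods::validObject(dt)
  dt
}

#' Write a delta table to CSV
#'
#' One row per patient: \code{patient_id}, \code{response}, then the 39
#' delta columns.
#'
#' @param table A [DeltaFeatureTable-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeDeltaTable <- function(table, path) {
  m <- t(SummarizedExperiment::assay(table, "delta"))
  df <- data.frame(patient_id = rownames(m),
                   response = SummarizedExperiment::colData(table)$response,
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
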