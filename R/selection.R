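#' Rank delta features by random-forest Gini importance
#'
#' Trains a classification random forest (500 trees by default, Gini split
#' criterion, bootstrap resampling per tree with out-of-bag evaluation) on
#' the delta features against the binary response and returns the mean
#' decrease in Gini per feature in decreasing order. Ties are broken by
#' feature name. Rows are put in canonical patient-ID order before
#' training, so the ranking depends on the data, not on storage order.
#' Features containing missing values are excluded from the forest
#' (listwise per-feature; a warning reports them).
#'
#' @param table A [DeltaFeatureTable-class] with both classes present.
#' @param nTrees Number of trees, default 500.
#' @param seed Integer seed (required; recorded in the result).
#' @param mtry Features tried per split; default
#'   \code{floor(sqrt(n_features))}.
#' @return An [ImportanceRanking-class] with the top-2 features selected.
#' @export
rankByGini <- function(table, nTrees = 500, seed, mtry = NULL) {
  stopifnot(methods::is(table, "DeltaFeatureTable"))
  if (missing(seed)) stop("seed is required for a reproducible ranking")
  X <- t(SummarizedExperiment::assay(table, "delta"))
  y <- SummarizedExperiment::colData(table)$response
  # canonical row order: ranking must not depend on storage order
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]
  y <- factor(y[ord], levels = c("NR", "RS"))
  if (nlevels(droplevels(y)) < 2L) stop("both response classes are required")
  if (nrow(X) < 4L) stop("need at least 2 patients per class")
  ok <- colSums(!is.finite(X)) == 0L
  if (!all(ok)) {
    warning("features with missing values excluded from the forest: ",
            paste(colnames(X)[!ok], collapse = ", "))
    X <- X[, ok, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need at least 2 complete features")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = as.data.frame(X), y = y, ntree = nTrees, mtry = mtry,
    nodesize = 1, importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord2 <- order(-imp, names(imp))   # descending importance, name tie-break
  rk <- S4Vectors::DataFrame(feature = names(imp)[ord2],
                             mean_decrease_gini = unname(imp[ord2]),
                             rank = seq_along(imp))
  obj <- methods::new("ImportanceRanking", ranking = rk,
                      topFeatures = rk$feature[seq_len(min(2L, nrow(rk)))],
                      nTrees = as.integer(nTrees), seed = as.integer(seed),
                      binTag = as.character(S4Vectors::metadata(table)$bin_tag))
  obj
}

#' Select the k top-ranked features
#'
#' @param ranking An [ImportanceRanking-class].
#' @param k Number of features to select, default 2.
#' @return Character vector of k feature names in rank order.
#' @export
selectTopK <- function(ranking, k = 2) {
  stopifnot(methods::is(ranking, "ImportanceRanking"))
  r <- ranking@ranking
  if (k > nrow(r)) stop("k exceeds the number of ranked features")
  sel <- r$feature[seq_len(k)]
  if (k < nrow(r) && r$mean_decrease_gini[k] == r$mean_decrease_gini[k + 1])
    message("tie at the rank-", k, " boundary broken by feature name")
  sel
}

#' Write an importance ranking to CSV
#'
#' Columns \code{feature}, \code{mean_decrease_gini}, \code{rank}.
#'
#' @param ranking An [ImportanceRanking-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.csv(giniRanking(ranking), path, row.names = FALSE)
  invisible(path)
}
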