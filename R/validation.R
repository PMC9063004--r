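#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The fraction of (positive, negative) patient pairs whose scores are
#' correctly ordered, with ties counted 1/2:
#' \deqn{AUC = \frac{1}{n_+ n_-} \sum_{i \in +} \sum_{j \in -}
#'   \left[ \mathbf{1}(s_i > s_j) + \tfrac12 \mathbf{1}(s_i = s_j) \right]}
#'
#' @param scores Numeric predicted scores or probabilities.
#' @param labels Binary labels: logical, 0/1, or \code{"RS"}/\code{"NR"}
#'   (\code{"RS"} is the positive class).
#' @return AUC in [0, 1].
#' @examples
#' computeAUC(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
computeAUC <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "RS"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  # rank-sum form: sum of positive-class ranks, midranks handle ties as 1/2
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares (intercept unpenalized). The penalty keeps the Hessian invertible
# under complete separation and with arbitrarily unbalanced classes.
.ridgeLogistic <- function(x, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  X1 <- cbind(1, x)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X1, y - mu) - pen %*% beta
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Logistic fit with ridge fallback on (quasi-)separation. Returns linear
# scores for `newx`. Covariates are standardized with the training mean/sd.
.fitScore <- function(x, y, newx, standardize = TRUE, ridgeLambda = 1e-3) {
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    newx <- sweep(sweep(newx, 2, mu), 2, sdv, "/")
  }
  df <- data.frame(y = y, x)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!sep && fit$converged) {
    eta <- as.numeric(cbind(1, newx) %*% stats::coef(fit))
    return(list(score = eta, ridge = FALSE))
  }
  # separation: maximum-likelihood coefficients diverge; stabilize with a
  # small ridge penalty
  beta <- .ridgeLogistic(x, as.numeric(y), lambda = ridgeLambda)
  eta <- as.numeric(cbind(1, newx) %*% beta)
  list(score = eta, ridge = TRUE)
}

#' Bootstrapped logistic-regression internal validation
#'
#' Per iteration: a training subset of \code{round(trainFraction * n)}
#' patients (two-thirds, 20 of 30, by default) is drawn without
#' replacement, an intercept + two-covariate logistic regression is fit by
#' maximum likelihood on the training subset (covariates standardized with
#' training statistics), all patients — including the training subset, by
#' construction of the procedure — are scored, and the AUC is computed.
#' The report summarizes the \code{nIter} AUCs by their mean and empirical
#' (type-7) 2.5/97.5 percentiles. Training draws containing a single class
#' are redrawn (counted); separable fits fall back to a ridge-stabilized
#' refit (counted).
#'
#' @param table A [DeltaFeatureTable-class].
#' @param features Character vector of 2 feature keys (rows of the table).
#' @param nIter Number of bootstrap iterations, default 1000.
#' @param trainFraction Fraction of patients per training subset, default 2/3.
#' @param seed Integer seed (required).
#' @param replace Draw training subsets with replacement instead of the
#'   default subsampling without replacement.
#' @return A [ValidationReport-class].
#' @export
bootstrapValidate <- function(table, features, nIter = 1000,
                              trainFraction = 2 / 3, seed, replace = FALSE) {
  stopifnot(methods::is(table, "DeltaFeatureTable"))
  if (missing(seed)) stop("seed is required for a reproducible report")
  if (length(features) != 2L) stop("exactly 2 features are required")
  A <- SummarizedExperiment::assay(table, "delta")
  if (!all(features %in% rownames(A))) stop("unknown feature name")
  X <- t(A[features, , drop = FALSE])
  y <- SummarizedExperiment::colData(table)$response == "RS"
  if (anyNA(X) || any(!is.finite(X)))
    stop("the selected features must be non-missing for all patients")
  n <- nrow(X)
  ntrain <- round(trainFraction * n)
  if (!any(y) || all(y)) stop("both classes must be present")
  set.seed(as.integer(seed))
  aucs <- numeric(nIter)
  nredraw <- 0L; nridge <- 0L
  for (it in seq_len(nIter)) {
    repeat {
      tr <- sample.int(n, ntrain, replace = replace)
      if (length(unique(y[tr])) == 2L) break
      nredraw <- nredraw + 1L
    }
    fs <- .fitScore(X[tr, , drop = FALSE], y[tr], X)
    if (fs$ridge) nridge <- nridge + 1L
    aucs[it] <- computeAUC(fs$score, y)
  }
  ci <- unname(stats::quantile(aucs, c(0.025, 0.975), type = 7))
  methods::new("ValidationReport",
               binTag = as.character(S4Vectors::metadata(table)$bin_tag),
               features = features, aucs = aucs, meanAUC = mean(aucs),
               ci = ci, nIter = as.integer(nIter),
               trainFraction = trainFraction, seed = as.integer(seed),
               nRedraws = nredraw, nRidge = nridge)
}

#' Serialize a validation report
#'
#' Writes a JSON summary and (optionally) a CSV of per-iteration AUCs.
#'
#' @param report A [ValidationReport-class].
#' @param jsonPath Output JSON path.
#' @param aucCSVPath Optional CSV path for the per-iteration AUCs.
#' @return \code{jsonPath}, invisibly.
#' @export
writeValidationReport <- function(report, jsonPath, aucCSVPath = NULL) {
  x <- list(bin = report@binTag, features = report@features,
            mean_auc = report@meanAUC,
            percentile_2.5 = report@ci[1], percentile_97.5 = report@ci[2],
            n_iter = report@nIter, train_fraction = report@trainFraction,
            seed = report@seed, n_redraws = report@nRedraws,
            n_ridge_refits = report@nRidge)
  jsonlite::write_json(x, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(aucCSVPath))
    utils::write.csv(data.frame(iteration = seq_along(report@aucs),
                                auc = report@aucs),
                     aucCSVPath, row.names = FALSE)
  invisible(jsonPath)
}
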