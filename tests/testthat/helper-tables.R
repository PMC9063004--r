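# construct a DeltaFeatureTable with arbitrary delta values, for model tests
toy_delta_table <- function(n = 30, nRS = 11, seed = 1, inject = NULL,
                            effect = 1, noise = 1, bin = "BED20") {
  set.seed(seed)
  reg <- DeltaRadiomics::featureRegistry()
  labels <- sample(c(rep("RS", nRS), rep("NR", n - nRS)))
  ids <- sprintf("p%02d", seq_len(n))
  X <- matrix(rnorm(39 * n, sd = noise), nrow = 39,
              dimnames = list(reg$key, ids))
  if (!is.null(inject))
    X[inject, ] <- effect * (labels == "RS") + rnorm(n, sd = noise)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(delta = X),
    rowData = S4Vectors::DataFrame(class = reg$class, feature = reg$feature,
                                   code = reg$code, modified = reg$modified,
                                   row.names = reg$key),
    colData = S4Vectors::DataFrame(response = labels, row.names = ids))
  dt <- methods::as(se, "DeltaFeatureTable")
  S4Vectors::metadata(dt) <- list(bin_tag = bin, convention = "pre_minus_post")
  dt
}
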