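#' Default pipeline configuration
#'
#' All defaults equal the study's printed settings: 64 gray levels, a
#' +/- 3 sigma dynamic-range limit, GLCM displacement 1, modified
#' (volume-decoupled) feature variants, a 500-tree forest, top-2 feature
#' selection, 1000 bootstrap iterations over two-thirds training subsets.
#' The configuration round-trips losslessly through YAML
#' ([readPipelineConfig()] / [writePipelineConfig()]).
#'
#' @param ... Named overrides of any default.
#' @return A named list of settings.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(nLevels = 64L, kSigma = 3, displacement = 1L, modified = TRUE,
              nTrees = 500L, topK = 2L, nIter = 1000L, trainFraction = 2 / 3,
              replace = FALSE, propagateMask = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config settings: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @rdname pipelineConfig
#' @param config A configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

# read one fraction image + mask for a patient directory
.readFractionROI <- function(pdir, fx, propagateMask = FALSE) {
  imgf <- file.path(pdir, sprintf("fx%d_image.nii.gz", fx))
  mskf <- file.path(pdir, sprintf("fx%d_mask.nii.gz", fx))
  if (!file.exists(mskf) && propagateMask)
    mskf <- file.path(pdir, "fx1_mask.nii.gz")
  if (!file.exists(imgf) || !file.exists(mskf)) return(NULL)
  img <- RNifti::readNifti(imgf)
  msk <- RNifti::readNifti(mskf)
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("image/mask grid mismatch for ", imgf, " (resampling is out of scope)")
  vs <- RNifti::pixdim(img)[1:3]
  maskedROI(array(as.numeric(img), dim = dim(img)[1:3]),
            array(msk > 0, dim = dim(msk)[1:3]), voxelSize = vs)
}

#' Extract texture features for a cohort
#'
#' Extracts the 39-feature vector for every (patient, fraction) image the
#' dose-bin analysis needs: fraction 1 plus the assigned BED20 and BED40
#' fractions. A patient whose image fails a stage is excluded from the
#' affected rows with a warning, never crashed on.
#'
#' @param cohort Either a cohort directory (layout of [writeCohort()]) or
#'   an in-memory bundle from [generateCohort()].
#' @param assignment A [DoseBinAssignment-class].
#' @param config Configuration from [pipelineConfig()].
#' @return Tidy data.frame: \code{patient_id}, \code{fraction}, \code{n_voxels},
#'   then the 39 registry keys; one row per extracted image.
#' @export
extractCohortFeatures <- function(cohort, assignment,
                                  config = pipelineConfig()) {
  stopifnot(methods::is(assignment, "DoseBinAssignment"))
  onDisk <- is.character(cohort)
  i20 <- binImageIndex(assignment, "BED20")
  i40 <- binImageIndex(assignment, "BED40")
  rows <- list()
  for (p in patientIDs(assignment)) {
    fxs <- sort(unique(stats::na.omit(c(1L, i20[[p]], i40[[p]]))))
    for (fx in fxs) {
      roi <- tryCatch({
        if (onDisk) .readFractionROI(file.path(cohort, p), fx,
                                     config$propagateMask)
        else {
          pat <- cohort$patients[[p]]
          if (is.null(pat) || fx > length(pat$volumes)) NULL
          else maskedROI(pat$volumes[[fx]], pat$mask)
        }
      }, error = function(e) {
        warning(sprintf("patient %s fx%d: %s", p, fx, conditionMessage(e)))
        NULL
      })
      if (is.null(roi)) next
      fv <- tryCatch(
        extractTextureFeatures(roi, nLevels = config$nLevels,
                               kSigma = config$kSigma,
                               modified = config$modified,
                               displacement = config$displacement),
        error = function(e) {
          warning(sprintf("patient %s fx%d failed extraction: %s",
                          p, fx, conditionMessage(e)))
          NULL
        })
      if (is.null(fv)) next
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = p, fraction = fx,
                   n_voxels = sum(roi@mask), t(fv), check.names = FALSE)
    }
  }
  if (!length(rows)) stop("no image could be extracted")
  do.call(rbind, rows)
}

#' Run the end-to-end delta-radiomics pipeline
#'
#' schedule -> preprocess -> texture -> delta -> Gini selection ->
#' bootstrap validation, for the BED20 and BED40 bins, writing per-stage
#' artifacts (feature CSV, delta CSVs, importance CSVs, validation JSONs)
#' and a run manifest to \code{outputDir}. Stage seeds are derived from
#' the run seed (forest: seed + 101/102, bootstrap: seed + 201/202 for
#' BED20/BED40), so one seed reproduces every number in the manifest.
#'
#' @param cohort Cohort directory or in-memory bundle from
#'   [generateCohort()].
#' @param outputDir Output directory for artifacts (created); \code{NULL}
#'   skips writing.
#' @param config Configuration from [pipelineConfig()].
#' @param seed Integer run seed (required).
#' @return List with \code{features} (tidy data.frame), and per bin the
#'   [DeltaFeatureTable-class], [ImportanceRanking-class] and
#'   [ValidationReport-class], plus the \code{manifest} list.
#' @export
runPipeline <- function(cohort, outputDir = NULL, config = pipelineConfig(),
                        seed) {
  if (missing(seed)) stop("seed is required")
  seed <- as.integer(seed)
  onDisk <- is.character(cohort)
  schedule <- if (onDisk) readSchedule(file.path(cohort, "schedule.csv"))
              else cohort$schedule
  labels <- responseLabels(schedule)
  if (onDisk) {
    lf <- file.path(cohort, "labels.csv")
    if (file.exists(lf)) {
      ldf <- utils::read.csv(lf, stringsAsFactors = FALSE)
      labels <- stats::setNames(ldf$response, ldf$patient_id)
    }
  }
  assignment <- assignDoseBins(schedule)
  features <- extractCohortFeatures(cohort, assignment, config)
  out <- list(features = features, assignment = assignment,
              schedule = schedule)
  binSeeds <- list(BED20 = c(rf = seed + 101L, boot = seed + 201L),
                   BED40 = c(rf = seed + 102L, boot = seed + 202L))
  for (bin in c("BED20", "BED40")) {
    tbl <- buildDeltaTable(features, assignment, labels, bin)
    rkg <- rankByGini(tbl, nTrees = config$nTrees,
                      seed = binSeeds[[bin]][["rf"]])
    top <- selectTopK(rkg, k = config$topK)
    rpt <- bootstrapValidate(tbl, top[1:2], nIter = config$nIter,
                             trainFraction = config$trainFraction,
                             seed = binSeeds[[bin]][["boot"]],
                             replace = config$replace)
    out[[bin]] <- list(table = tbl, ranking = rkg, report = rpt)
  }
  manifest <- list(
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("DeltaRadiomics")),
    n_patients = length(patientIDs(schedule)),
    n_images_extracted = nrow(features),
    bins = lapply(c(BED20 = "BED20", BED40 = "BED40"), function(b) list(
      n_patients = ncol(out[[b]]$table),
      seeds = as.list(binSeeds[[b]]),
      top_features = topFeatures(out[[b]]$ranking),
      mean_auc = meanAUC(out[[b]]$report),
      auc_percentiles = as.list(aucInterval(out[[b]]$report)))))
  out$manifest <- manifest
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(outputDir, "features.csv"),
                     row.names = FALSE)
    for (bin in c("BED20", "BED40")) {
      writeDeltaTable(out[[bin]]$table,
                      file.path(outputDir, paste0("delta_", tolower(bin), ".csv")))
      writeRanking(out[[bin]]$ranking,
                   file.path(outputDir, paste0("importance_", tolower(bin), ".csv")))
      writeValidationReport(out[[bin]]$report,
                            file.path(outputDir, paste0("validation_", tolower(bin), ".json")),
                            file.path(outputDir, paste0("aucs_", tolower(bin), ".csv")))
    }
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
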