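# Synthetic longitudinal cohorts with the statistical structure the
# analysis assumes: GTV-sized ellipsoidal ROIs over correlated Gaussian
# random fields, fractionation schedules drawn from the reference cohort
# mix, and a class-dependent texture drift injected at the BED20 image of
# responders. The drift changes the spatial autocorrelation length, not
# the mean intensity, so it is invisible to first-order statistics and is
# carried by the co-occurrence structure the texture features measure.

#' CohortSpec: parameters of a synthetic cohort
#'
#' @slot nPatients Integer number of patients (default 30).
#' @slot nRS Integer number of responders (default 11; the rest are NR).
#' @slot gridDim Integer edge length of the cubic voxel grid (default 32).
#' @slot roiVoxelRange Integer length-2, target in-mask voxel count range
#'   (default 500-3000, GTV scale).
#' @slot noiseSD Numeric, i.i.d. acquisition-noise SD as a fraction of the
#'   structured field's unit SD (default 0.15).
#' @slot sigmaBaseline Numeric, Gaussian autocorrelation length (voxels) of
#'   the baseline texture (default 1.2).
#' @slot sigmaDrift Numeric, autocorrelation length at the drifted image
#'   (default 2.0). Equal to \code{sigmaBaseline} for a null cohort.
#' @slot effectBin Character, bin at which responders drift
#'   (\code{"BED20"}; \code{"none"} disables the drift).
#' @slot voxelSize Numeric length-3, mm (default 1.5 x 1.5 x 3.0).
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", nRS = "integer", gridDim = "integer",
                 roiVoxelRange = "integer", noiseSD = "numeric",
                 sigmaBaseline = "numeric", sigmaDrift = "numeric",
                 effectBin = "character", voxelSize = "numeric"))

setValidity("CohortSpec", function(object) {
  if (object@nRS > object@nPatients) return("nRS exceeds nPatients")
  if (object@nPatients < 1L) return("nPatients must be >= 1")
  if (any(object@roiVoxelRange < 8L)) return("ROI must have at least 8 voxels")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@sigmaBaseline <= 0 || object@sigmaDrift <= 0)
    return("autocorrelation lengths must be positive")
  if (!object@effectBin %in% c("BED20", "none"))
    return("effectBin must be 'BED20' or 'none'")
  TRUE
})

#' Construct a CohortSpec
#'
#' Defaults emulate the reference cohort: 30 patients (11 RS / 19 NR),
#' 3-5 fraction schedules with BED/fraction between 11 and 26.4 Gy,
#' GTV-sized ROIs of 500-3000 voxels on a 32^3 grid, and a responder-only
#' change of texture autocorrelation length at the BED20 image.
#'
#' @param nPatients,nRS,gridDim,roiVoxelRange,noiseSD,sigmaBaseline,sigmaDrift,effectBin,voxelSize
#'   See [CohortSpec-class].
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 30, nRS = 11, gridDim = 32,
                       roiVoxelRange = c(500, 3000), noiseSD = 0.15,
                       sigmaBaseline = 1.2, sigmaDrift = 2.0,
                       effectBin = "BED20",
                       voxelSize = c(1.5, 1.5, 3.0)) {
  methods::new("CohortSpec", nPatients = as.integer(nPatients),
               nRS = as.integer(nRS), gridDim = as.integer(gridDim),
               roiVoxelRange = as.integer(roiVoxelRange),
               noiseSD = noiseSD, sigmaBaseline = sigmaBaseline,
               sigmaDrift = sigmaDrift, effectBin = effectBin,
               voxelSize = as.numeric(voxelSize))
}

# separable Gaussian smoothing on a 3D array (reflecting boundaries)
.smooth3D <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, min(ceiling(3 * sigma), min(dim(x)) - 1L))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  conv1 <- function(v) {
    n <- length(v)
    # reflect-pad so the field keeps unit scale near edges
    vp <- c(v[r:1], v, v[n:(n - r + 1)])
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  # smooth along the current first axis, then rotate axes cyclically;
  # three rounds smooth each axis once and restore the orientation
  for (i in 1:3) {
    dd <- dim(x)
    x <- apply(x, c(2, 3), conv1)
    dim(x) <- dd
    x <- aperm(x, c(2, 3, 1))
  }
  stopifnot(identical(dim(x), d))
  x
}

# ellipsoidal mask with approximately `target` in-mask voxels
.ellipsoidMask <- function(gridDim, target, aspect = c(1, 1, 1)) {
  # semi-axes from target volume 4/3 pi a b c with the given aspect ratios
  c0 <- (3 * target / (4 * pi * prod(aspect)))^(1 / 3)
  ax <- c0 * aspect
  ctr <- (gridDim + 1) / 2
  g <- seq_len(gridDim)
  d1 <- ((g - ctr) / ax[1])^2
  d2 <- ((g - ctr) / ax[2])^2
  d3 <- ((g - ctr) / ax[3])^2
  outer(outer(d1, d2, "+"), d3, "+") <= 1
}

#' Generate one synthetic patient
#'
#' The patient's tumor texture is a fixed white-noise field smoothed to the
#' baseline autocorrelation length; every fraction's setup image re-images
#' the same field with fresh i.i.d. acquisition noise. For responders with
#' an active effect bin, the image assigned to that bin is smoothed to the
#' drifted autocorrelation length instead, altering the co-occurrence
#' structure while leaving the intensity histogram essentially unchanged.
#' With zero noise and no drift all fraction volumes are identical.
#'
#' @param spec A [CohortSpec-class].
#' @param classLabel \code{"RS"} or \code{"NR"}.
#' @param nFractions Number of fractions for this patient.
#' @param driftFraction Fraction index whose image carries the drift
#'   (\code{NA} for none).
#' @param seed Integer seed.
#' @return List with \code{volumes} (list of 3D arrays, one per fraction),
#'   \code{mask} (logical 3D array), \code{nVoxels}.
#' @export
generatePatient <- function(spec, classLabel, nFractions, driftFraction = NA,
                            seed) {
  stopifnot(methods::is(spec, "CohortSpec"))
  if (min(spec@roiVoxelRange) < 8L) stop("ROI smaller than 8 voxels")
  set.seed(as.integer(seed))
  d <- spec@gridDim
  target <- stats::runif(1, spec@roiVoxelRange[1], spec@roiVoxelRange[2])
  aspect <- stats::runif(3, 0.75, 1.25)
  mask <- .ellipsoidMask(d, target, aspect)
  W <- array(stats::rnorm(d^3), dim = c(d, d, d))
  base <- .smooth3D(W, spec@sigmaBaseline)
  base <- base / stats::sd(base)
  drifted <- NULL
  volumes <- vector("list", nFractions)
  for (fx in seq_len(nFractions)) {
    drift_here <- classLabel == "RS" && !is.na(driftFraction) &&
      fx == driftFraction && spec@effectBin != "none"
    if (drift_here) {
      if (is.null(drifted)) {
        drifted <- .smooth3D(W, spec@sigmaDrift)
        drifted <- drifted / stats::sd(drifted)
      }
      field <- drifted
    } else field <- base
    noise <- if (spec@noiseSD > 0)
      array(stats::rnorm(d^3, sd = spec@noiseSD), dim = c(d, d, d))
    else 0
    volumes[[fx]] <- 500 + 100 * (field + noise)
  }
  list(volumes = volumes, mask = mask, nVoxels = sum(mask))
}

# schedule mix of the reference cohort: (total BED, BED/fx) pairs
.referenceMix <- function() {
  sch <- table3Schedule()
  pd <- data.frame(total = totalBED(sch), n = nFractions(sch),
                   response = responseLabels(sch))
  pd
}

#' Generate a synthetic cohort
#'
#' Draws schedules from the reference fractionation mix (verbatim pairing
#' for the default 30-patient cohort, resampled otherwise), generates each
#' patient's longitudinal volumes, and optionally writes the on-disk layout
#' the pipeline consumes: one directory per patient with
#' \code{fx<k>_image.nii.gz} / \code{fx<k>_mask.nii.gz}, plus cohort-level
#' \code{schedule.csv} and \code{labels.csv}.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer seed; all patient substreams derive from it.
#' @param dir Optional output directory; created if missing.
#' @return (Invisibly when writing) a list with \code{schedule}
#'   (a [TreatmentSchedule-class]), \code{labels}, \code{assignment}
#'   (a [DoseBinAssignment-class]), \code{patients} (named list of
#'   [generatePatient()] results), \code{dir}.
#' @export
generateCohort <- function(spec = cohortSpec(), seed, dir = NULL) {
  stopifnot(methods::is(spec, "CohortSpec"))
  if (missing(seed)) stop("seed is required")
  seed <- as.integer(seed)
  ref <- .referenceMix()
  n <- spec@nPatients
  ids <- sprintf("sim%02d", seq_len(n))
  set.seed(seed)
  if (n == nrow(ref)) {
    tot <- ref$total; nf <- ref$n
    labels <- ref$response  # printed pairing: 11 RS / 19 NR
    if (spec@nRS != sum(labels == "RS"))
      labels <- sample(c(rep("RS", spec@nRS), rep("NR", n - spec@nRS)))
  } else {
    pick <- sample.int(nrow(ref), n, replace = TRUE)
    tot <- ref$total[pick]; nf <- ref$n[pick]
    labels <- sample(c(rep("RS", spec@nRS), rep("NR", n - spec@nRS)))
  }
  schedule <- treatmentSchedule(ids, nFractions = nf, totalBED = tot,
                                response = labels)
  assignment <- assignDoseBins(schedule)
  drift_idx <- binImageIndex(assignment, "BED20")
  patients <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    patSeed <- (seed + 7919L * i) %% 2147483647L
    patients[[i]] <- generatePatient(spec, labels[i], nf[i],
                                     driftFraction = drift_idx[[ids[i]]],
                                     seed = patSeed)
  }
  bundle <- list(schedule = schedule,
                 labels = stats::setNames(labels, ids),
                 assignment = assignment, patients = patients, dir = dir)
  if (!is.null(dir)) {
    writeCohort(bundle, dir, voxelSize = spec@voxelSize)
    return(invisible(bundle))
  }
  bundle
}

#' Write a cohort bundle to the on-disk pipeline layout
#'
#' @param bundle A cohort bundle from [generateCohort()].
#' @param dir Output directory.
#' @param voxelSize Numeric length-3 voxel size in mm.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(bundle, dir, voxelSize = c(1.5, 1.5, 3.0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- patientIDs(bundle$schedule)
  nf <- nFractions(bundle$schedule)
  for (p in ids) {
    pdir <- file.path(dir, p)
    dir.create(pdir, showWarnings = FALSE)
    pat <- bundle$patients[[p]]
    for (fx in seq_len(nf[[p]])) {
      RNifti::writeNifti(RNifti::asNifti(pat$volumes[[fx]], pixdim = voxelSize),
                         file.path(pdir, sprintf("fx%d_image.nii.gz", fx)))
      RNifti::writeNifti(RNifti::asNifti(pat$mask * 1L, pixdim = voxelSize),
                         file.path(pdir, sprintf("fx%d_mask.nii.gz", fx)))
    }
  }
  pd <- bundle$schedule@patientData
  utils::write.csv(as.data.frame(pd[, c("patient_id", "n_fractions",
                                        "total_bed_gy", "response")]),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = ids,
                              response = unname(bundle$labels[ids])),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
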