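# Accessor generics for the package's S4 containers. Slot access from user
# code should go through these, never through @.

#' @rdname TreatmentSchedule-class
#' @param object A package object.
#' @export
setGeneric("patientIDs", function(object) standardGeneric("patientIDs"))

#' @rdname TreatmentSchedule-class
#' @export
setGeneric("nFractions", function(object) standardGeneric("nFractions"))

#' @rdname TreatmentSchedule-class
#' @export
setGeneric("totalBED", function(object) standardGeneric("totalBED"))

#' @rdname TreatmentSchedule-class
#' @export
setGeneric("bedPerFractionOf", function(object) standardGeneric("bedPerFractionOf"))

#' @rdname TreatmentSchedule-class
#' @export
setGeneric("responseLabels", function(object) standardGeneric("responseLabels"))

#' @rdname DoseBinAssignment-class
#' @param object A package object.
#' @param bin \code{"BED20"} or \code{"BED40"}.
#' @export
setGeneric("binImageIndex", function(object, bin) standardGeneric("binImageIndex"))

#' @rdname ImportanceRanking-class
#' @param object A package object.
#' @export
setGeneric("giniRanking", function(object) standardGeneric("giniRanking"))

#' @rdname ImportanceRanking-class
#' @export
setGeneric("topFeatures", function(object) standardGeneric("topFeatures"))

#' @rdname ValidationReport-class
#' @param object A package object.
#' @export
setGeneric("meanAUC", function(object) standardGeneric("meanAUC"))

#' @rdname ValidationReport-class
#' @export
setGeneric("aucInterval", function(object) standardGeneric("aucInterval"))

#' @rdname ValidationReport-class
#' @export
setGeneric("iterationAUCs", function(object) standardGeneric("iterationAUCs"))

setMethod("patientIDs", "TreatmentSchedule", function(object)
  as.character(object@patientData$patient_id))
setMethod("nFractions", "TreatmentSchedule", function(object)
  stats::setNames(object@patientData$n_fractions, object@patientData$patient_id))
setMethod("totalBED", "TreatmentSchedule", function(object)
  stats::setNames(object@patientData$total_bed_gy, object@patientData$patient_id))
setMethod("bedPerFractionOf", "TreatmentSchedule", function(object)
  stats::setNames(object@patientData$bed_per_fraction_gy, object@patientData$patient_id))
setMethod("responseLabels", "TreatmentSchedule", function(object)
  stats::setNames(object@patientData$response, object@patientData$patient_id))
setMethod("patientIDs", "DoseBinAssignment", function(object)
  as.character(object@assignments$patient_id))
setMethod("binImageIndex", "DoseBinAssignment", function(object, bin) {
  bin <- match.arg(bin, c("BED20", "BED40"))
  col <- if (bin == "BED20") "bed20_image_index" else "bed40_image_index"
  stats::setNames(object@assignments[[col]], object@assignments$patient_id)
})
setMethod("giniRanking", "ImportanceRanking", function(object)
  as.data.frame(object@ranking))
setMethod("topFeatures", "ImportanceRanking", function(object) object@topFeatures)
setMethod("meanAUC", "ValidationReport", function(object) object@meanAUC)
setMethod("aucInterval", "ValidationReport", function(object)
  stats::setNames(object@ci, c("2.5%", "97.5%")))
setMethod("iterationAUCs", "ValidationReport", function(object) object@aucs)
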