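#' Biologically effective dose of a fractionated schedule
#'
#' Linear-quadratic BED for \code{n} fractions of physical dose \code{d} Gy:
#' \deqn{BED = n\,d\,(1 + d/(\alpha/\beta))}
#' with \eqn{\alpha/\beta = 10} Gy by default (the conventional value for
#' tumor response). Five fractions of 10 Gy give 100 Gy BED; five fractions
#' of 12 Gy give 132 Gy.
#'
#' @param nFractions Number of fractions (>= 1). Vectorized.
#' @param dosePerFraction Physical dose per fraction in Gy (> 0).
#' @param alphaBeta Alpha/beta ratio in Gy (> 0), default 10.
#' @return Total BED in Gy.
#' @examples
#' computeBED(5, 10)   # 100
#' computeBED(5, 12)   # 132
#' @export
computeBED <- function(nFractions, dosePerFraction, alphaBeta = 10) {
  if (any(nFractions < 1)) stop("nFractions must be >= 1")
  if (any(dosePerFraction <= 0)) stop("dosePerFraction must be > 0")
  if (any(alphaBeta <= 0)) stop("alphaBeta must be > 0")
  nFractions * dosePerFraction * (1 + dosePerFraction / alphaBeta)
}

#' BED delivered per fraction
#'
#' Divides the total BED equally between fractions; used to place each
#' patient's setup images on a common delivered-dose axis.
#'
#' @param totalBED Total BED in Gy.
#' @param nFractions Number of fractions (>= 1).
#' @return BED per fraction in Gy.
#' @examples
#' bedPerFraction(72, 5)   # 14.4
#' @export
bedPerFraction <- function(totalBED, nFractions) {
  if (any(nFractions < 1)) stop("nFractions must be >= 1")
  totalBED / nFractions
}

#' Physical dose per fraction from BED per fraction
#'
#' Inverts \eqn{d (1 + d/(\alpha/\beta))} for the positive root.
#'
#' @param bedPerFx BED per fraction in Gy.
#' @param alphaBeta Alpha/beta ratio in Gy, default 10.
#' @return Physical dose per fraction in Gy.
#' @export
physicalDosePerFraction <- function(bedPerFx, alphaBeta = 10) {
  if (any(bedPerFx <= 0)) stop("bedPerFx must be > 0")
  (-alphaBeta + sqrt(alphaBeta^2 + 4 * alphaBeta * bedPerFx)) / 2
}

#' Construct a TreatmentSchedule
#'
#' Fills in whichever of \code{totalBED} / \code{dosePerFraction} /
#' \code{nFractions} can be derived from the others. When
#' \code{nFractions} is missing it is recovered as
#' \code{round(totalBED / bedPerFx)}; the rounded value must reproduce the
#' total BED to 0.1 Gy per fraction.
#'
#' @param patientID Character vector of unique patient labels.
#' @param nFractions Integer fraction counts (optional if both
#'   \code{totalBED} and \code{bedPerFx} are given).
#' @param dosePerFraction Physical dose per fraction in Gy (optional).
#' @param totalBED Total BED in Gy (optional if \code{dosePerFraction} and
#'   \code{nFractions} are given).
#' @param bedPerFx BED per fraction in Gy (optional, derived otherwise).
#' @param response Character vector of \code{"RS"}/\code{"NR"} labels or NA.
#' @param alphaBeta Alpha/beta ratio in Gy, default 10.
#' @return A [TreatmentSchedule-class] object.
#' @export
treatmentSchedule <- function(patientID, nFractions = NULL,
                              dosePerFraction = NULL, totalBED = NULL,
                              bedPerFx = NULL, response = NULL,
                              alphaBeta = 10) {
  n <- length(patientID)
  rep_or_na <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(rep(x, length.out = n))
  dose <- rep_or_na(dosePerFraction)
  tb <- rep_or_na(totalBED)
  bpf <- rep_or_na(bedPerFx)
  nf <- if (is.null(nFractions)) rep(NA_integer_, n) else as.integer(rep(nFractions, length.out = n))
  miss_nf <- is.na(nf)
  if (any(miss_nf)) {
    if (any(miss_nf & (is.na(tb) | is.na(bpf))))
      stop("nFractions missing and not derivable from totalBED / bedPerFx")
    nf[miss_nf] <- as.integer(round(tb[miss_nf] / bpf[miss_nf]))
  }
  need_tb <- is.na(tb)
  idx <- which(need_tb & !is.na(dose))
  if (length(idx)) tb[idx] <- computeBED(nf[idx], dose[idx], alphaBeta)
  idx <- which(need_tb & is.na(dose) & !is.na(bpf))
  if (length(idx)) tb[idx] <- bpf[idx] * nf[idx]
  if (any(is.na(tb))) stop("totalBED missing and not derivable")
  # a supplied bedPerFx (possibly a rounded printed value) only serves to
  # recover n; the stored value is recomputed so bpf * n == total exactly
  bpf <- tb / nf
  resp <- if (is.null(response)) rep(NA_character_, n) else as.character(rep(response, length.out = n))
  pd <- S4Vectors::DataFrame(
    patient_id = as.character(patientID),
    n_fractions = nf,
    dose_per_fraction_gy = dose,
    total_bed_gy = tb,
    bed_per_fraction_gy = bpf,
    response = resp)
  methods::new("TreatmentSchedule", patientData = pd, alphaBeta = alphaBeta)
}

#' Read a schedule table from CSV
#'
#' Expected columns: \code{patient_id}, \code{response} (RS/NR), and any
#' derivable combination of \code{n_fractions}, \code{dose_per_fraction_gy},
#' \code{total_bed_gy}, \code{bed_per_fraction_gy}.
#'
#' @param path Path to the CSV file.
#' @param alphaBeta Alpha/beta ratio in Gy, default 10.
#' @return A [TreatmentSchedule-class] object.
#' @export
readSchedule <- function(path, alphaBeta = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("schedule CSV needs a patient_id column")
  pick <- function(col) if (col %in% names(df)) df[[col]] else NULL
  treatmentSchedule(patientID = df$patient_id,
                    nFractions = pick("n_fractions"),
                    dosePerFraction = pick("dose_per_fraction_gy"),
                    totalBED = pick("total_bed_gy"),
                    bedPerFx = pick("bed_per_fraction_gy"),
                    response = pick("response"),
                    alphaBeta = alphaBeta)
}

#' The packaged 30-patient reference schedule
#'
#' Loads the packaged fixture describing the 30-patient pancreatic SBRT
#' cohort (total BED 54.8-132 Gy over 3-5 fractions, 11 responders and 19
#' non-responders) that the dose-bin logic is checked against.
#'
#' @return A [TreatmentSchedule-class] with 30 patients.
#' @export
table3Schedule <- function() {
  readSchedule(system.file("extdata", "reference_cohort_schedule.csv",
                           package = "DeltaRadiomics", mustWork = TRUE))
}

#' Assign setup images to the BED20 and BED40 dose bins
#'
#' The setup image of fraction \eqn{k+1} is acquired after \eqn{k} fractions
#' have been delivered, i.e. after a cumulative BED of
#' \eqn{k \times BED/fx}. The BED20 image is the first whose preceding
#' cumulative BED reaches 20 Gy (the delivered dose must also stay within
#' the 20-30 Gy window; an overshoot past 30 Gy at the first crossing is
#' flagged \code{bed20_out_of_window}). The BED40 image is the first whose
#' preceding cumulative BED reaches 40 Gy. A bin no fraction reaches is
#' \code{NA} — the patient is excluded from that bin downstream, not
#' crashed on.
#'
#' @param schedule A [TreatmentSchedule-class].
#' @return A [DoseBinAssignment-class].
#' @examples
#' sch <- treatmentSchedule("p1", nFractions = 5, totalBED = 72)
#' binImageIndex(assignDoseBins(sch), "BED20")  # fraction 3
#' @export
assignDoseBins <- function(schedule) {
  stopifnot(methods::is(schedule, "TreatmentSchedule"))
  pd <- schedule@patientData
  one <- function(bpf, nf) {
    cum <- bpf * seq_len(nf)           # cumulative BED after fraction k
    k20 <- which(cum >= 20 - 1e-9)[1]  # first crossing of 20 Gy
    k40 <- which(cum >= 40 - 1e-9)[1]
    # image k+1 is usable only if the patient has that many fractions
    i20 <- if (!is.na(k20) && k20 + 1 <= nf) k20 + 1L else NA_integer_
    i40 <- if (!is.na(k40) && k40 + 1 <= nf) k40 + 1L else NA_integer_
    oow <- !is.na(k20) && cum[k20] > 30 + 1e-9
    list(i20 = i20, i40 = i40, oow = oow)
  }
  res <- mapply(one, pd$bed_per_fraction_gy, pd$n_fractions, SIMPLIFY = FALSE)
  a <- S4Vectors::DataFrame(
    patient_id = pd$patient_id,
    bed20_image_index = vapply(res, `[[`, integer(1), "i20"),
    bed40_image_index = vapply(res, `[[`, integer(1), "i40"),
    bed20_out_of_window = vapply(res, `[[`, logical(1), "oow"))
  methods::new("DoseBinAssignment", assignments = a)
}
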