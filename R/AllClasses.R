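#' @import methods
NULL

.LEADS <- c("I", "II", "III", "avR", "avL", "avF",
            "V1", "V2", "V3", "V4", "V5", "V6")

.SEXES <- c("male", "female", "unknown")

#' Single-lead ECG record
#'
#' Holds one lead's amplitude sequence in ADC counts together with the
#' sampling rate and the patient metadata needed for lead-, sex- and
#' age-specific ST thresholds. All sample indices exposed by the package are
#' 0-based; times are \code{index / fs} seconds.
#'
#' @slot samples numeric vector of amplitudes in ADC counts.
#' @slot fs sampling rate in Hz.
#' @slot lead lead name, one of I, II, III, avR, avL, avF, V1-V6.
#' @slot sex "male", "female" or "unknown".
#' @slot age age in years, \code{NA_real_} when unknown.
#' @slot recordId free-text identifier.
#' @export
setClass("EcgRecord",
  representation(samples = "numeric", fs = "numeric", lead = "character",
                 sex = "character", age = "numeric", recordId = "character"),
  prototype(fs = 500, lead = "II", sex = "unknown", age = NA_real_,
            recordId = "record"))

setValidity("EcgRecord", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be nonempty")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@lead) != 1L || !(object@lead %in% .LEADS))
    msg <- c(msg, sprintf("lead must be one of: %s",
                          paste(.LEADS, collapse = ", ")))
  if (length(object@sex) != 1L || !(object@sex %in% .SEXES))
    msg <- c(msg, "sex must be 'male', 'female' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct an EcgRecord
#'
#' @param samples numeric amplitude sequence in ADC counts.
#' @param fs sampling rate in Hz (default 500).
#' @param lead lead name.
#' @param sex "male", "female" or "unknown".
#' @param age age in years or NA.
#' @param recordId identifier string.
#' @return An \linkS4class{EcgRecord}.
#' @examples
#' rec <- EcgRecord(sin(seq(0, 10, length.out = 500)) * 100, lead = "V2")
#' length(ecgSamples(rec))
#' @export
EcgRecord <- function(samples, fs = 500, lead = "II", sex = "unknown",
                      age = NA_real_, recordId = "record") {
  new("EcgRecord", samples = as.numeric(samples), fs = as.numeric(fs),
      lead = as.character(lead), sex = as.character(sex),
      age = as.numeric(age), recordId = as.character(recordId))
}

#' Per-record beat annotation set
#'
#' One row per detected heartbeat with the stopping-time landmarks: the QRS
#' slope stopping time, the R peak, the minimum after R, the S point
#' (downhill U-turn), the J point, the T peak and the T-end U-turn, plus the
#' search ranges actually used. All indices are 0-based.
#'
#' @slot beats data.frame of per-beat landmark indices/amplitudes.
#' @slot avgInterval mean R-peak-to-S-point interval in samples.
#' @slot rangeT T-peak search range in samples.
#' @slot rangeUturn clamped downhill U-turn range (25-100) in samples.
#' @slot n record length in samples.
#' @slot fs sampling rate in Hz.
#' @export
setClass("EcgAnnotation",
  representation(beats = "data.frame", avgInterval = "numeric",
                 rangeT = "numeric", rangeUturn = "numeric",
                 n = "numeric", fs = "numeric"))

setValidity("EcgAnnotation", function(object) {
  need <- c("omega_qrs", "r_peak_idx", "r_peak_amp", "omega_min_amp",
            "min_amp", "omega_s", "omega_j", "j_amp", "omega_tmax",
            "tmax_amp", "omega_t_end", "truncated")
  if (!all(need %in% names(object@beats)))
    return(sprintf("beats must have columns: %s", paste(need, collapse = ", ")))
  TRUE
})

#' Diagnostic report for one or more leads of a record
#'
#' @slot recordId record identifier.
#' @slot leads named list of per-lead results (annotation rows, baseline,
#'   ST evaluation, direction evidence).
#' @slot stemiRatio fraction of flagged beats in the most affected lead.
#' @slot miVerdict logical STEMI verdict (any processed lead).
#' @slot inversionVerdict "non-inversed" or "inversed".
#' @slot rvFlag right-ventricle-infarction flag; NA when II/III/avF are not
#'   all available.
#' @slot parameters list of the parameters used.
#' @export
setClass("EcgReport",
  representation(recordId = "character", leads = "list",
                 stemiRatio = "numeric", miVerdict = "logical",
                 inversionVerdict = "character", rvFlag = "logical",
                 parameters = "list"))

setValidity("EcgReport", function(object) {
  if (length(object@stemiRatio) == 1L && is.finite(object@stemiRatio) &&
      (object@stemiRatio < 0 || object@stemiRatio > 1))
    return("stemiRatio must lie in [0, 1]")
  TRUE
})

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord '%s': %d samples @ %g Hz, lead %s (%s%s)\n",
              object@recordId, length(object@samples), object@fs,
              object@lead, object@sex,
              if (is.na(object@age)) "" else sprintf(", %g y", object@age)))
})

setMethod("show", "EcgAnnotation", function(object) {
  cat(sprintf("EcgAnnotation: %d beats, avg R-S interval %.1f samples\n",
              nrow(object@beats), object@avgInterval))
  if (nrow(object@beats))
    print(utils::head(object@beats[, c("r_peak_idx", "omega_s", "omega_j",
                                       "omega_tmax")], 5))
})

setMethod("show", "EcgReport", function(object) {
  cat(sprintf("EcgReport '%s': %d lead(s)\n", object@recordId,
              length(object@leads)))
  cat(sprintf("  STEMI ratio %.3f -> MI %s; waveform %s; RV flag %s\n",
              object@stemiRatio, object@miVerdict, object@inversionVerdict,
              if (is.na(object@rvFlag)) "indeterminate" else object@rvFlag))
})
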