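sigmoid <- function(x) 1 / (1 + exp(-x))

#' Baseline representative point
#'
#' Two chained backward downhill U-turns before the QRS. State 1 searches
#' backward from the QRS slope stopping time with the clamped T-stage range
#' (reward = R peak amplitude, next-state coefficient -1, so the action
#' value stays the stopping amplitude); state 2 searches backward from that
#' point with the average R-to-S interval as range. Both stopping times are
#' displaced backward by half their range, since the score contrasts two
#' search ranges; the state-2 result is the baseline representative point on
#' the PR segment.
#'
#' @param d numeric samples.
#' @param omegaQrs 0-based QRS slope stopping time of the beat.
#' @param avgInterval mean R-to-S interval (samples).
#' @param rangeUturn clamped U-turn range in [25, 100].
#' @param rPeakAmp R peak amplitude (reward bookkeeping).
#' @return list with \code{omegaPreR}, \code{omegaBaseline},
#'   \code{amplitude}, \code{baselineInterval} (0-based c(lo, hi)),
#'   \code{truncated}.
#' @export
baselineRepresentativePoint <- function(d, omegaQrs, avgInterval, rangeUturn,
                                        rPeakAmp = NA_real_) {
  n <- length(d)
  r1 <- as.integer(rangeUturn)
  st1 <- downhillUturn(d, omegaQrs, r1, "backward")
  omegaPreR <- clip0(st1$omega - as.integer(round(r1 / 2)), n)
  r2 <- max(1L, as.integer(round(avgInterval)))
  st2 <- downhillUturn(d, omegaPreR, r2, "backward")
  omegaBaseline <- clip0(st2$omega - as.integer(round(r2 / 2)), n)
  list(omegaPreR = omegaPreR, omegaBaseline = omegaBaseline,
       amplitude = dAt(d, omegaBaseline),
       baselineInterval = c(clip0(omegaBaseline - r2, n), omegaBaseline),
       range = r2, truncated = st1$truncated || st2$truncated)
}

#' Weight adjustment of the baseline amplitude
#'
#' Sweeps 21 weights w in \{0.1, 0.2, ..., 2.1\} over the last amplitude of
#' the baseline interval. As printed the weighted baseline
#' \code{w * d(tau_last) / (0.1 * d(tau_last) + 1 * d(tau_last))} cancels to
#' \code{w / 1.1} for any nonzero amplitude; it is fed through a sigmoid and
#' a squared-difference loss against the representative amplitude. The
#' weight with the smallest absolute finite-difference loss gradient across
#' the sweep is selected (ties toward the smaller weight). The adjusted
#' amplitude is the representative amplitude plus the recentred sigmoid
#' output -- a sub-count correction.
#'
#' @param d numeric samples.
#' @param baselinePoint result of \code{\link{baselineRepresentativePoint}}.
#' @return list with \code{weight}, \code{adjustedAmplitude},
#'   \code{flagged} (TRUE when the zero-amplitude guard fired).
#' @export
adjustWeight <- function(d, baselinePoint) {
  tauLast <- baselinePoint$baselineInterval[1L]
  dLast <- dAt(d, tauLast)
  amp <- baselinePoint$amplitude
  if (dLast == 0)
    return(list(weight = 1.0, adjustedAmplitude = amp, flagged = TRUE))
  w <- seq(0.1, 2.1, by = 0.1)
  baselineW <- w * dLast / (0.1 * dLast + 1 * dLast)   # = w / 1.1
  cand <- sigmoid(baselineW)
  loss <- (amp - cand)^2
  grad <- diff(loss) / diff(w)                         # forward differences
  kStar <- which.min(abs(grad))                        # first min = smaller w
  wStar <- w[kStar]
  adj <- amp + (sigmoid(wStar / 1.1) - 0.5)
  list(weight = wStar, adjustedAmplitude = adj, flagged = FALSE)
}

#' Lead-, sex- and age-specific ST elevation threshold
#'
#' V2/V3 in males under 40: 0.25 mV; V2/V3 in males 40 and over: 0.20 mV;
#' V2/V3 in females: 0.15 mV; every other lead: 0.10 mV. Unknown sex or age
#' on V2/V3 falls back to the largest (most conservative) applicable
#' threshold and is flagged. Counts follow the linear calibration
#' \code{countsPer0p10mV} per 0.10 mV.
#'
#' @param lead lead name.
#' @param sex "male", "female" or "unknown".
#' @param age years or NA.
#' @param countsPer0p10mV calibration constant (default 17 counts = 0.10 mV).
#' @return list with \code{mV}, \code{counts}, \code{flagged}.
#' @examples
#' stThreshold("V2", "male", 35)  # 0.25 mV
#' stThreshold("II", "unknown", NA)$counts  # 17
#' @export
stThreshold <- function(lead, sex = "unknown", age = NA,
                        countsPer0p10mV = 17) {
  if (!(lead %in% .LEADS))
    stop(sprintf("stThreshold: invalid lead '%s'", lead))
  if (countsPer0p10mV <= 0) stop("stThreshold: calibration must be positive")
  flagged <- FALSE
  if (lead %in% c("V2", "V3")) {
    if (identical(sex, "male")) {
      if (is.na(age)) { mv <- 0.25; flagged <- TRUE }
      else mv <- if (age < 40) 0.25 else 0.20
    } else if (identical(sex, "female")) {
      mv <- 0.15
    } else { mv <- 0.25; flagged <- TRUE }
  } else mv <- 0.10
  list(mV = mv, counts = round(mv / 0.10 * countsPer0p10mV),
       flagged = flagged)
}

#' Per-beat ST elevation evaluation
#'
#' Elevation is the amplitude difference between the J point and the
#' weight-adjusted baseline representative point; a beat is flagged when it
#' strictly exceeds the threshold. Beats with a missing landmark are
#' excluded from numerator and denominator.
#'
#' @param jAmps numeric J-point amplitudes (counts), NA for missing.
#' @param baselineAmps adjusted baseline amplitudes (counts).
#' @param thresholdCounts threshold in counts.
#' @param countsPer0p10mV calibration for the reported mV values.
#' @return data.frame with \code{elevation_counts}, \code{elevation_mV},
#'   \code{stemi}, \code{evaluable}.
#' @export
evaluateStBeats <- function(jAmps, baselineAmps, thresholdCounts,
                            countsPer0p10mV = 17) {
  elev <- jAmps - baselineAmps
  evaluable <- is.finite(elev)
  data.frame(elevation_counts = elev,
             elevation_mV = elev / countsPer0p10mV * 0.10,
             stemi = evaluable & elev > thresholdCounts,
             evaluable = evaluable)
}

#' STEMI ratio and MI verdict
#'
#' The STEMI ratio is the flagged fraction of evaluable beats; the record is
#' called MI when it strictly exceeds 39.9999 percent. A single
#' representative beat therefore yields a ratio of exactly 0 or 1.
#'
#' @param flags logical per-beat STEMI flags (NA = not evaluable).
#' @param ratioThreshold MI decision threshold (default 0.399999).
#' @return list with \code{stemiRatio}, \code{miVerdict} (NA when no beat is
#'   evaluable), \code{nEvaluable}.
#' @export
miDecision <- function(flags, ratioThreshold = 0.399999) {
  ok <- !is.na(flags)
  if (!any(ok))
    return(list(stemiRatio = NA_real_, miVerdict = NA, nEvaluable = 0L))
  ratio <- sum(flags[ok]) / sum(ok)
  list(stemiRatio = ratio, miVerdict = ratio > ratioThreshold,
       nEvaluable = sum(ok))
}

#' Right-ventricle infarction flag
#'
#' TRUE iff leads II, III and avF are all MI-positive; a positive flag
#' contraindicates nitroglycerin. When any of the three verdicts is missing
#' the flag is indeterminate (NA), never silently FALSE.
#'
#' @param perLeadVerdicts named logical vector of per-lead MI verdicts.
#' @return TRUE, FALSE or NA.
#' @examples
#' rvInfarctionFlag(c(II = TRUE, III = TRUE, avF = TRUE))
#' @export
rvInfarctionFlag <- function(perLeadVerdicts) {
  need <- c("II", "III", "avF")
  if (!all(need %in% names(perLeadVerdicts))) return(NA)
  v <- perLeadVerdicts[need]
  if (any(is.na(v))) return(NA)
  all(v)
}
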