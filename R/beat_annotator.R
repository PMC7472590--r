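# neighboring-sample slope sequence: slope(i) = (d(i+interval) - d(i))/interval
# returned vector is indexed by 0-based i = 0 .. n-1-interval
slopeSeq <- function(d, interval = 2L) {
  n <- length(d)
  if (n <= interval) return(numeric(0))
  (d[(interval + 1L):n] - d[1:(n - interval)]) / interval
}

#' Detect QRS complex peaks
#'
#' The record is partitioned into consecutive 300-sample subsets (one subset
#' holds at most one QRS complex at 500 Hz). Within each subset the stopping
#' time is the argmax of the neighboring-sample slope (interval 2), taken
#' only over positions where the slope increases; the candidate is then
#' refined to the amplitude maximum over the 600 samples around it (the
#' action value with reward = slope-point amplitude, gamma = 1, P = 1 equals
#' the amplitude itself, so its argmax is the amplitude argmax). The whole
#' stage runs twice, feeding first-pass peaks as second-pass anchors, and
#' peaks closer than 300 samples are merged keeping the larger amplitude.
#'
#' @param d numeric samples (preprocessed, nonnegative).
#' @param subset subset length in samples (default 300).
#' @param interval slope interval in samples (default 2).
#' @return data.frame with 0-based \code{omega_qrs} (slope stopping time),
#'   \code{r_peak_idx}, \code{r_peak_amp}, \code{alpha} (first-hit softmax
#'   temperature for the refinement pair).
#' @export
detectQrsPeaks <- function(d, subset = 300L, interval = 2L) {
  n <- length(d)
  if (n == 0L) stop("detectQrsPeaks: empty input")
  sl <- slopeSeq(d, interval)
  if (length(sl) == 0L || all(sl <= 0))
    return(data.frame(omega_qrs = integer(0), r_peak_idx = integer(0),
                      r_peak_amp = numeric(0), alpha = numeric(0)))

  onePass <- function(anchors, halfWin) {
    # anchors: list of (lo, hi) 0-based inclusive windows to search slopes in
    out <- list()
    for (w in anchors) {
      lo <- max(0L, w[1L])
      hi <- min(n - 1L - interval, w[2L])
      if (hi < lo) next
      s <- sl[(lo + 1L):(hi + 1L)]
      if (all(s <= 0)) next
      wQrs <- lo + which.max(s) - 1L
      rl <- max(0L, wQrs - halfWin)
      rh <- min(n - 1L, wQrs + halfWin)
      seg <- d[(rl + 1L):(rh + 1L)]
      rIdx <- rl + which.max(seg) - 1L
      out[[length(out) + 1L]] <-
        c(omega_qrs = wQrs, r_peak_idx = rIdx, r_peak_amp = dAt(d, rIdx))
    }
    if (!length(out))
      return(data.frame(omega_qrs = integer(0), r_peak_idx = integer(0),
                        r_peak_amp = numeric(0)))
    as.data.frame(do.call(rbind, out))
  }

  dedup <- function(pk, minSep = subset) {
    if (nrow(pk) <= 1L) return(pk)
    pk <- pk[order(pk$r_peak_idx), , drop = FALSE]
    keep <- list(pk[1L, ])
    for (k in 2:nrow(pk)) {
      last <- keep[[length(keep)]]
      if (pk$r_peak_idx[k] - last$r_peak_idx < minSep) {
        if (pk$r_peak_amp[k] > last$r_peak_amp)
          keep[[length(keep)]] <- pk[k, ]
      } else keep[[length(keep) + 1L]] <- pk[k, ]
    }
    do.call(rbind, keep)
  }

  # pass 1: non-overlapping subsets (single-window fallback for short records)
  starts <- seq(0L, max(0L, n - 1L), by = subset)
  blocks <- lapply(starts, function(s) c(s, min(n - 1L, s + subset - 1L)))
  p1 <- dedup(onePass(blocks, halfWin = 300L))
  if (!nrow(p1)) return(cbind(p1, alpha = numeric(0)))

  # pass 2: re-search around the pass-1 peaks
  wins <- lapply(p1$r_peak_idx, function(p) c(p - 300L, p + 300L))
  p2 <- dedup(onePass(wins, halfWin = 300L))
  if (!nrow(p2)) p2 <- p1

  # temperature bookkeeping for the (slope-point amplitude, peak amplitude) pair
  p2$alpha <- mapply(function(w, a) searchAlpha(dAt(d, w), a),
                     p2$omega_qrs, p2$r_peak_amp)
  p2$omega_qrs <- as.integer(p2$omega_qrs)
  p2$r_peak_idx <- as.integer(p2$r_peak_idx)
  rownames(p2) <- NULL
  p2
}

#' Minimum amplitude around the R wave
#'
#' Stopping time of the argmin over the 50 samples before and after the R
#' peak (clipped at record borders); ties break toward the smallest index.
#'
#' @param d numeric samples.
#' @param rPeakIdx 0-based R peak index.
#' @param halfWindow search half-width in samples (default 50).
#' @return list with \code{omega} (0-based), \code{value} (= d(omega)) and
#'   \code{vNext} (difference to the R peak amplitude).
#' @export
minAmpAfterR <- function(d, rPeakIdx, halfWindow = 50L) {
  n <- length(d)
  rPeakIdx <- as.integer(rPeakIdx)
  lo <- clip0(rPeakIdx - halfWindow, n)
  hi <- clip0(rPeakIdx + halfWindow, n)
  seg <- d[(lo + 1L):(hi + 1L)]
  omega <- lo + which.min(seg) - 1L
  list(omega = omega, value = dAt(d, omega),
       vNext = dAt(d, omega) - dAt(d, rPeakIdx))
}

#' Locate the S point
#'
#' Three chained algorithmic states. State 1 runs the forward downhill
#' U-turn from the QRS slope stopping time with range 24 (two 25-term
#' windows covering 50 samples); its updated value is the stopping amplitude
#' plus 24. The temporarily lower point is whichever of the minimum-after-R
#' state and state 1 carries the lower updated value. State 2 searches 150
#' samples on each side of it for the amplitude closest to its reward (the
#' temporarily lower amplitude). State 3 evaluates the two candidate action
#' values -- stopping amplitude plus the slope from the QRS peak, or from the
#' QRS downhill point, to the temporarily lower point -- and the larger slope
#' fixes which anchor pairs with the S point; the returned S point is the
#' state-2 stopping time.
#'
#' @param d numeric samples.
#' @param omegaQrs 0-based QRS slope stopping time.
#' @param rPeakIdx,rPeakAmp R peak index and amplitude.
#' @param minAfterR result of \code{\link{minAmpAfterR}}.
#' @return list with \code{omega} (S point, 0-based), \code{value},
#'   \code{omegaHillUturn}, \code{pairing} ("qrs_peak" or "qrs_downhill"),
#'   \code{truncated}.
#' @export
locateSPoint <- function(d, omegaQrs, rPeakIdx, rPeakAmp, minAfterR) {
  n <- length(d)
  omegaQrs <- as.integer(omegaQrs)
  rPeakIdx <- as.integer(rPeakIdx)
  st1 <- downhillUturn(d, omegaQrs, 24L, "forward")
  v1 <- st1$value + 24          # Q' = Rs + (d(omega) - Rs + 24)
  vMin <- minAfterR$value       # Q with gamma, P held at 1 stays the amplitude
  if (vMin <= v1) {
    tl <- minAfterR$omega
  } else {
    tl <- st1$omega
  }
  tlAmp <- dAt(d, tl)
  lo <- clip0(tl - 150L, n)
  hi <- clip0(tl + 150L, n)
  seg <- d[(lo + 1L):(hi + 1L)]
  omega3 <- lo + which.min(abs(seg - tlAmp)) - 1L
  # state 3: larger slope fixes the QRS-peak / S-point pairing
  cand <- c(qrs_peak = NA_real_, qrs_downhill = NA_real_)
  if (rPeakIdx != tl)
    cand["qrs_peak"] <- (rPeakAmp - tlAmp) / (rPeakIdx - tl)
  if (st1$omega != tl)
    cand["qrs_downhill"] <- (st1$value - tlAmp) / (st1$omega - tl)
  pairing <- if (all(is.na(cand))) NA_character_
             else names(cand)[which.max(cand)]
  list(omega = omega3, value = dAt(d, omega3), omegaHillUturn = st1$omega,
       pairing = pairing, truncated = st1$truncated)
}

#' Locate the J point
#'
#' Forward downhill U-turn from the S point with range 1.5 times the average
#' R-peak-to-S-point interval; the stopping time is displaced by half the
#' range because the score contrasts two search ranges. The resulting index
#' sits at the ST-deviation measurement range after the conventional QRS
#' end, which is where elevation is read clinically.
#'
#' @param d numeric samples.
#' @param omegaS 0-based S point.
#' @param avgInterval mean R-to-S interval over the record's beats (samples).
#' @param rewardMinAmp the minimum-after-R amplitude (reward bookkeeping).
#' @return list with \code{omega} (J point), \code{value}, \code{range},
#'   \code{truncated}.
#' @export
locateJPoint <- function(d, omegaS, avgInterval, rewardMinAmp = NA_real_) {
  range <- as.integer(round(1.5 * avgInterval))
  if (is.na(range) || range < 1L) stop("locateJPoint: search range < 1")
  st <- downhillUturn(d, as.integer(omegaS), range, "forward")
  omega <- clip0(st$omega + as.integer(round(range / 2)), length(d))
  list(omega = omega, value = dAt(d, omega), range = range,
       truncated = st$truncated)
}

#' Locate the T wave peak and its trailing U-turn
#'
#' The T peak is the amplitude argmax over \code{tau in [0, rangeT]} after
#' the J point, where \code{rangeT} is the record mean of
#' \code{300 + omega_qrs - omega_s} minus 50. The second state repeats the
#' forward downhill U-turn from the J point with range 1.5 times the average
#' R-to-S interval clamped into [25, 100], displaced by half the range.
#'
#' @param d numeric samples.
#' @param omegaJ 0-based J point.
#' @param rangeT T-peak search range (samples).
#' @param rangeUturn clamped U-turn range in [25, 100].
#' @return list with \code{omegaTmax}, \code{tmaxAmp}, \code{omegaTEnd},
#'   \code{truncated}.
#' @export
locateTWave <- function(d, omegaJ, rangeT, rangeUturn) {
  n <- length(d)
  omegaJ <- as.integer(omegaJ)
  rangeT <- as.integer(max(0, round(rangeT)))
  hi <- omegaJ + rangeT
  truncated <- hi > n - 1L
  hi <- clip0(hi, n)
  seg <- d[(omegaJ + 1L):(hi + 1L)]
  omegaTmax <- omegaJ + which.max(seg) - 1L
  st <- downhillUturn(d, omegaJ, as.integer(rangeUturn), "forward")
  omegaTEnd <- clip0(st$omega + as.integer(round(rangeUturn / 2)), n)
  list(omegaTmax = omegaTmax, tmaxAmp = dAt(d, omegaTmax),
       omegaTEnd = omegaTEnd, truncated = truncated || st$truncated)
}

# clamp the 1.5x average-interval U-turn range into [25, 100]
clampUturnRange <- function(avgInterval) {
  as.integer(min(100L, max(25L, round(1.5 * avgInterval))))
}

#' Annotate every beat of a record
#'
#' Runs the full stopping-time cascade: QRS peaks, minimum after R, S point,
#' J point, T peak and T-end U-turn, with the search ranges derived from the
#' record's own average R-to-S interval.
#'
#' @param x numeric samples (preprocessed) or an \linkS4class{EcgRecord};
#'   records are passed through \code{\link{preprocessRecord}} first.
#' @param fs sampling rate, for bookkeeping only.
#' @return An \linkS4class{EcgAnnotation}.
#' @export
annotateBeats <- function(x, fs = 500) {
  if (is(x, "EcgRecord")) {
    fs <- samplingRate(x)
    d <- preprocessRecord(x)$samples
  } else d <- as.numeric(x)
  n <- length(d)
  peaks <- detectQrsPeaks(d)
  empty <- data.frame(omega_qrs = integer(0), r_peak_idx = integer(0),
                      r_peak_amp = numeric(0), omega_min_amp = integer(0),
                      min_amp = numeric(0), omega_s = integer(0),
                      omega_j = integer(0), j_amp = numeric(0),
                      omega_tmax = integer(0), tmax_amp = numeric(0),
                      omega_t_end = integer(0), truncated = logical(0))
  if (!nrow(peaks))
    return(new("EcgAnnotation", beats = empty, avgInterval = NA_real_,
               rangeT = NA_real_, rangeUturn = NA_real_, n = n, fs = fs))

  nb <- nrow(peaks)
  mins <- lapply(seq_len(nb), function(k)
    minAmpAfterR(d, peaks$r_peak_idx[k]))
  sPts <- lapply(seq_len(nb), function(k)
    locateSPoint(d, peaks$omega_qrs[k], peaks$r_peak_idx[k],
                 peaks$r_peak_amp[k], mins[[k]]))
  omegaS <- vapply(sPts, `[[`, 0, "omega")
  avgInterval <- mean(abs(omegaS - peaks$r_peak_idx))
  if (!is.finite(avgInterval) || avgInterval < 1) avgInterval <- 1
  rangeU <- clampUturnRange(avgInterval)
  rangeT <- mean(300 + peaks$omega_qrs - omegaS) - 50

  jPts <- lapply(seq_len(nb), function(k)
    locateJPoint(d, omegaS[k], avgInterval,
                 rewardMinAmp = mins[[k]]$value))
  tPts <- lapply(seq_len(nb), function(k)
    locateTWave(d, jPts[[k]]$omega, rangeT, rangeU))

  beats <- data.frame(
    omega_qrs = peaks$omega_qrs,
    r_peak_idx = peaks$r_peak_idx,
    r_peak_amp = peaks$r_peak_amp,
    omega_min_amp = vapply(mins, `[[`, 0, "omega"),
    min_amp = vapply(mins, `[[`, 0, "value"),
    omega_s = omegaS,
    omega_j = vapply(jPts, `[[`, 0, "omega"),
    j_amp = vapply(jPts, `[[`, 0, "value"),
    omega_tmax = vapply(tPts, `[[`, 0, "omegaTmax"),
    tmax_amp = vapply(tPts, `[[`, 0, "tmaxAmp"),
    omega_t_end = vapply(tPts, `[[`, 0, "omegaTEnd"),
    truncated = vapply(sPts, `[[`, TRUE, "truncated") |
                vapply(jPts, `[[`, TRUE, "truncated") |
                vapply(tPts, `[[`, TRUE, "truncated"))
  new("EcgAnnotation", beats = beats, avgInterval = avgInterval,
      rangeT = rangeT, rangeUturn = as.numeric(rangeU), n = n, fs = fs)
}
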