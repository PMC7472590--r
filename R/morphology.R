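#' Least-first-power T wave direction
#'
#' Per beat, the J-to-T-peak segment is summarized by its standard deviation
#' about the J amplitude \code{p = d(omega_j)}, signed so that a segment
#' lying above the J amplitude (an upright T) yields a negative beta: the
#' side point \code{r* = p - beta} then sits closer to the first T-peak
#' amplitude than \code{q* = p + beta}, the least-first-power approximation
#' picks the r side, and the direction is upward. Positive beta marks a
#' downward (inverted) T.
#'
#' @param d numeric samples.
#' @param omegaJs 0-based per-beat J points.
#' @param omegaTmaxs 0-based per-beat T peaks.
#' @param window length of the J-to-T segment in samples; defaults to the
#'   largest J-to-T-peak distance. Passing the T-stage search range makes
#'   the segment cover the whole T region, so a trough below the J
#'   amplitude weighs in even though the T-peak search itself is an argmax.
#' @return list with \code{direction} ("upward"/"downward"), \code{beta},
#'   \code{sumQ}, \code{sumR} (the two absolute-deviation sums),
#'   \code{lowConfidence} (flat-segment tie).
#' @export
lfpTDirection <- function(d, omegaJs, omegaTmaxs, window = NULL) {
  stopifnot(length(omegaJs) == length(omegaTmaxs))
  if (!length(omegaJs)) stop("lfpTDirection: no beats")
  if (is.null(window)) window <- max(omegaTmaxs - omegaJs)
  window <- max(1L, as.integer(round(window)))
  n <- length(d)
  betas <- numeric(length(omegaJs))
  ps <- numeric(length(omegaJs))
  for (k in seq_along(omegaJs)) {
    lo <- omegaJs[k]
    hi <- clip0(omegaJs[k] + window, n)
    if (hi == lo) stop("lfpTDirection: zero-length J-to-T segment")
    seg <- d[(lo + 1L):(hi + 1L)]
    p <- dAt(d, omegaJs[k])
    dev <- stats::sd(seg)
    if (!is.finite(dev)) dev <- 0
    betas[k] <- -sign(mean(seg - p)) * dev
    ps[k] <- p
  }
  beta <- mean(betas)
  ymFirst <- dAt(d, omegaTmaxs[1L])
  sumQ <- sum(abs(ymFirst - (ps + beta)))
  sumR <- sum(abs(ymFirst - (ps - beta)))
  if (beta < 0) dir <- "upward"
  else if (beta > 0) dir <- "downward"
  else dir <- "upward"
  list(direction = dir, beta = beta, sumQ = sumQ, sumR = sumR,
       lowConfidence = beta == 0)
}

#' Approximate-entropy next-state value
#'
#' Counts the slope magnitudes strictly below the threshold and returns the
#' logarithm of the count divided by half the search range; an empty count
#' returns 0 (log-of-zero guard).
#'
#' @param slopes numeric slope values (magnitudes are compared).
#' @param threshold tolerance.
#' @param halfRange half of the search range (>= 1).
#' @return The next-state value, non-decreasing in \code{threshold}.
#' @examples
#' approximateEntropyNextState(c(0.5, 1, 2, 3), 2.5, 2)  # log(3)/2
#' @export
approximateEntropyNextState <- function(slopes, threshold, halfRange) {
  if (halfRange < 1) stop("approximateEntropyNextState: halfRange must be >= 1")
  cnt <- sum(abs(slopes) < threshold)
  if (cnt == 0) 0 else log(cnt) / halfRange
}

#' Reward of the waveform-direction stage
#'
#' \code{reward = (slopeMax + mean(-slopes)) / 2}: the descending slopes
#' after the R peak enter with their signs (so their negated mean is a
#' positive magnitude) and \code{slopeMax} is the largest slope magnitude in
#' play -- by default of the supplied set, or of both slope sets when the
#' caller passes the shared maximum.
#'
#' @param slopes nonempty numeric slope values, raw signs.
#' @param slopeMax slope magnitude maximum (default \code{max(abs(slopes))}).
#' @return The reward value.
#' @examples
#' directionReward(c(-2, -4), slopeMax = 6)  # 4.5
#' @export
directionReward <- function(slopes, slopeMax = max(abs(slopes))) {
  if (!length(slopes)) stop("directionReward: empty slope set")
  (slopeMax + mean(-1 * slopes)) / 2
}

#' Grid search of the next-state coefficient gamma
#'
#' Scans gamma over \{0, 0.5, ..., 2.5\} and returns the value minimizing
#' the product of the pairwise softmax outputs of the two action values;
#' minimizing the product steers away from a gamma at which one abruptly
#' large action value (a large QRS slope or a noise component) dominates.
#' Ties break toward the smallest gamma.
#'
#' @param qPairs 6 x 2 matrix of action-value pairs, one row per gamma.
#' @return list with \code{gamma} and \code{index} (row).
#' @export
searchGamma <- function(qPairs) {
  qPairs <- as.matrix(qPairs)
  grid <- seq(0, 2.5, by = 0.5)
  if (nrow(qPairs) != length(grid) || ncol(qPairs) != 2L)
    stop("searchGamma: expected a 6 x 2 matrix of action values")
  prods <- apply(qPairs, 1L, function(q) prod(softmaxPair(q[1L], q[2L])))
  k <- which.min(prods)                     # first minimum = smallest gamma
  list(gamma = grid[k], index = k)
}

# per-beat slope windows after the R peak and after the minimum-after-R
directionSlopeSets <- function(d, rIdx, minIdx, windowLen, interval = 2L) {
  n <- length(d)
  grab <- function(from) {
    lo <- clip0(from, n)
    hi <- clip0(from + windowLen - 1L + interval, n)
    s <- slopeSeq(d[(lo + 1L):(hi + 1L)], interval)
    if (!length(s)) 0 else s
  }
  list(afterR = grab(rIdx), afterMin = grab(minIdx))
}

#' Record-level waveform-direction state value
#'
#' Per beat: rewards from the two slope sets (after the R peak and after
#' the minimum after R, each over twice the mean R-to-minimum interval),
#' approximate-entropy next states with the shared absolute-maximum slope as
#' threshold, gamma from \code{\link{searchGamma}} (P = 1), the softmax
#' policy between the two optimized action values with alpha from the
#' 0.5-100.5 first-hit search, and the absolute updated state value. The
#' incorporated third state counts, across beats, the appearances of a
#' longer interval before and after the T wave (two increment-by-one
#' rewards), uses gamma = 10 with the approximate-entropy values as next
#' states, floors the softmax policy at 0.0001 and fixes alpha = 1; the
#' final per-beat value adds the resulting updated value to the first-state
#' value (gamma = 1, P = 1). The record value is the sum over beats.
#'
#' @param d numeric samples (preprocessed).
#' @param ann \linkS4class{EcgAnnotation} of the same samples.
#' @return list with \code{value} and per-beat diagnostics.
#' @export
waveformDirectionValue <- function(d, ann) {
  beats <- beatTable(ann)
  nb <- nrow(beats)
  if (nb < 1L) stop("waveformDirectionValue: no annotated beats")
  avgRmin <- mean(abs(beats$omega_min_amp - beats$r_peak_idx))
  if (!is.finite(avgRmin) || avgRmin < 1) avgRmin <- 1
  windowLen <- as.integer(round(2 * avgRmin))
  halfRange <- max(1, round(avgRmin))
  gammaGrid <- seq(0, 2.5, by = 0.5)

  priorInt <- beats$omega_tmax - beats$omega_j
  postInt <- beats$omega_t_end - beats$omega_tmax
  rp <- cumsum(c(0, diff(priorInt) > 0))
  rq <- cumsum(c(0, diff(postInt) > 0))

  perBeat <- numeric(nb)
  gammas <- numeric(nb)
  alphas <- numeric(nb)
  for (k in seq_len(nb)) {
    sets <- directionSlopeSets(d, beats$r_peak_idx[k],
                               beats$omega_min_amp[k], windowLen)
    slopeMax <- max(abs(c(sets$afterR, sets$afterMin)))
    rewA <- directionReward(sets$afterR, slopeMax)
    rewB <- directionReward(sets$afterMin, slopeMax)
    apenA <- approximateEntropyNextState(sets$afterR, slopeMax, halfRange)
    apenB <- approximateEntropyNextState(sets$afterMin, slopeMax, halfRange)
    qPairs <- cbind(rewA + gammaGrid * apenA, rewB + gammaGrid * apenB)
    g <- searchGamma(qPairs)
    qA <- rewA + g$gamma * apenA
    qB <- rewB + g$gamma * apenB
    qLo <- min(qA, qB); qHi <- max(qA, qB)
    alpha <- searchAlpha(qLo, qHi)
    v1 <- if (alpha == 0) updateStateValue(1, qHi, 0)
          else updateStateValue(softmaxPolicy(qLo, qHi, alpha), qHi, alpha)
    v1 <- abs(v1)
    # incorporated third state: interval-increment rewards, gamma = 10
    q3p <- rp[k] + 10 * apenA
    q3q <- rq[k] + 10 * apenB
    pi3 <- max(softmaxPair(q3p, q3q)[which.max(c(q3p, q3q))], 1e-4)
    v3 <- updateStateValue(pi3, max(q3p, q3q), 1)
    perBeat[k] <- v1 + v3            # second state: reward + next state
    gammas[k] <- g$gamma
    alphas[k] <- alpha
  }
  list(value = sum(perBeat), perBeat = perBeat, gamma = gammas,
       alpha = alphas)
}

#' Decide overall waveform inversion
#'
#' Computes the waveform-direction state value on the record and on its
#' amplitude-inverted copy (reflected about the amplitude axis, then shifted
#' nonnegative and re-annotated from scratch); the branch with the higher
#' value wins. A tie defaults to non-inversed and is flagged.
#'
#' @param d numeric preprocessed samples.
#' @param ann \linkS4class{EcgAnnotation} of \code{d} (recomputed when NULL).
#' @return list with \code{verdict}, \code{valueNoninv}, \code{valueInv},
#'   \code{ratio} (Eq.-style percentage contrast of the two values),
#'   \code{tie}.
#' @export
decideInversion <- function(d, ann = NULL) {
  if (is.null(ann)) ann <- annotateBeats(d)
  vNon <- tryCatch(waveformDirectionValue(d, ann)$value,
                   error = function(e) -Inf)
  dInv <- shiftNonnegative(-d)$samples
  annInv <- annotateBeats(dInv)
  vInv <- tryCatch(waveformDirectionValue(dInv, annInv)$value,
                   error = function(e) -Inf)
  tie <- isTRUE(all.equal(vNon, vInv))
  verdict <- if (tie || vNon >= vInv) "non-inversed" else "inversed"
  denom <- max(vNon, vInv)
  ratio <- if (is.finite(denom) && denom > 0)
    abs(vNon - vInv) / denom * 100 else 0
  list(verdict = verdict, valueNoninv = vNon, valueInv = vInv,
       ratio = ratio, tie = tie)
}

#' Arbitrate the two direction stages
#'
#' When the least-first-power and approximate-entropy verdicts agree, that
#' verdict stands. On conflict each stage's percentage contrast
#' \code{|sv_non - sv_inv| / max(sv) * 100} decides: the stage with the
#' larger (more numerically deterministic) ratio wins. Finally, a STEMI
#' ratio above 20.0 percent overrides to non-inversed, since elevation
#' itself builds an upright impulsive wave from the S point to the T peak.
#'
#' @param lfp result of \code{\link{lfpTDirection}}.
#' @param inversion result of \code{\link{decideInversion}}.
#' @param stemiRatio record STEMI beat ratio in [0, 1].
#' @param overrideRatio override threshold (default 0.20).
#' @return list with \code{finalDirection}, \code{lfpVerdict},
#'   \code{apenVerdict}, \code{lfpRatio}, \code{apenRatio},
#'   \code{overrideApplied}.
#' @export
resolveDirection <- function(lfp, inversion, stemiRatio,
                             overrideRatio = 0.20) {
  lfpVerdict <- if (lfp$direction == "upward") "non-inversed" else "inversed"
  apenVerdict <- inversion$verdict
  denom <- max(lfp$sumQ, lfp$sumR)
  lfpRatio <- if (is.finite(denom) && denom > 0)
    abs(lfp$sumQ - lfp$sumR) / denom * 100 else 0
  apenRatio <- inversion$ratio
  final <- if (lfpVerdict == apenVerdict) lfpVerdict
           else if (lfpRatio >= apenRatio) lfpVerdict else apenVerdict
  overrideApplied <- FALSE
  if (is.finite(stemiRatio) && stemiRatio > overrideRatio &&
      final != "non-inversed") {
    final <- "non-inversed"
    overrideApplied <- TRUE
  }
  list(finalDirection = final, lfpVerdict = lfpVerdict,
       apenVerdict = apenVerdict, lfpRatio = lfpRatio,
       apenRatio = apenRatio, overrideApplied = overrideApplied)
}
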