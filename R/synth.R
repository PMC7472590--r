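# Hann bump with compact support: amp * 0.5*(1 + cos(pi*(t - center)/hw))
# on |t - center| <= hw, exactly 0 outside. Compact support keeps the
# ground-truth J amplitude free of tail contamination from other waves.
hannBump <- function(t, center, hw, amp) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= hw
  out[inside] <- amp * 0.5 * (1 + cos(pi * (t[inside] - center) / hw))
  out
}

# smooth 0->1->0 ST plateau: cosine ramp up over [up0,up1], flat 1 to down0,
# cosine ramp down to 0 at down1
stPlateau <- function(t, up0, up1, down0, down1) {
  out <- numeric(length(t))
  ramp <- t >= up0 & t < up1
  out[ramp] <- 0.5 * (1 - cos(pi * (t[ramp] - up0) / (up1 - up0)))
  out[t >= up1 & t <= down0] <- 1
  fall <- t > down0 & t <= down1
  out[fall] <- 0.5 * (1 + cos(pi * (t[fall] - down0) / (down1 - down0)))
  out
}

#' Synthetic ECG configuration
#'
#' Defaults describe a clean adult lead-II strip: 10 beats at 60 bpm sampled
#' at 500 Hz, R amplitude 170 counts (1.0 mV at 17 counts per 0.10 mV) on a
#' 100-count baseline, P 20 counts, S depth 25 counts, T 51 counts (0.3 mV).
#' Beat geometry (offsets from the R peak, in samples): P center -110, QRS
#' onset -25, S trough +20, QRS end +33, ground-truth J (the ST measurement
#' anchor, 0.04 s after QRS end) +53, ST plateau to +110, T peak +150.
#'
#' @param seed integer seed; the generator is deterministic given it.
#' @param nBeats number of beats (>= 1).
#' @param fs sampling rate in Hz.
#' @param heartRate beats per minute.
#' @param ampP,ampR,ampS,ampT wave amplitudes in counts (S is a depth).
#' @param base isoelectric baseline level in counts.
#' @param stOffset injected J-baseline elevation in counts.
#' @param inverted reflect the beat train about the baseline.
#' @param wanderAmp,wanderFreq baseline wander sinusoid (counts, Hz).
#' @param noiseSd white muscle-noise standard deviation in counts.
#' @param lead lead label.
#' @return list of class "SynthConfig".
#' @export
synthConfig <- function(seed = 1L, nBeats = 10L, fs = 500, heartRate = 60,
                        ampP = 20, ampR = 170, ampS = 25, ampT = 51,
                        base = 100, stOffset = 0, inverted = FALSE,
                        wanderAmp = 0, wanderFreq = 0.3, noiseSd = 0,
                        lead = "II") {
  if (fs <= 0) stop("synthConfig: fs must be positive")
  if (nBeats < 1) stop("synthConfig: nBeats must be >= 1")
  if (noiseSd < 0) stop("synthConfig: noiseSd must be >= 0")
  structure(list(seed = as.integer(seed), nBeats = as.integer(nBeats),
                 fs = fs, heartRate = heartRate, ampP = ampP, ampR = ampR,
                 ampS = ampS, ampT = ampT, base = base, stOffset = stOffset,
                 inverted = isTRUE(inverted), wanderAmp = wanderAmp,
                 wanderFreq = wanderFreq, noiseSd = noiseSd, lead = lead),
            class = "SynthConfig")
}

#' Generate a synthetic ECG record with ground truth
#'
#' Beats are built from compact-support raised-cosine kernels at the P, QRS
#' and T loci over an explicitly flat PR baseline; \code{stOffset} raises the
#' S-to-T segment through a smooth plateau that is exactly \code{stOffset}
#' at the ground-truth J index; inversion reflects the pre-noise beat train
#' about the baseline; wander and white noise are added last. Ground truth
#' records the pre-noise landmark indices and flags.
#'
#' @param config a \code{\link{synthConfig}} list.
#' @return list with \code{record} (\linkS4class{EcgRecord}) and
#'   \code{truth} (data.frame of per-beat 0-based truth indices plus the
#'   attributes \code{baseline}, \code{inverted}, \code{stOffset},
#'   \code{period}).
#' @examples
#' g <- generateRecord(synthConfig(seed = 7, stOffset = 30))
#' head(g$truth)
#' @export
generateRecord <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  cfg <- config
  period <- as.integer(round(60 / cfg$heartRate * cfg$fs))
  n <- cfg$nBeats * period
  t <- seq_len(n) - 1L                       # 0-based time axis
  rIdx <- as.integer(floor(period / 2) + (seq_len(cfg$nBeats) - 1L) * period)

  x <- rep(cfg$base, n)
  for (r in rIdx) {
    x <- x + hannBump(t, r - 110, 30, cfg$ampP) +
         hannBump(t, r, 25, cfg$ampR) +
         hannBump(t, r + 20, 12, -cfg$ampS) +
         hannBump(t, r + 150, 60, cfg$ampT) +
         cfg$stOffset * stPlateau(t, r + 25, r + 33, r + 110, r + 140)
  }
  # ground-truth landmarks are the extrema of the noiseless upright
  # waveform (kernel superposition shifts them off the kernel centers);
  # the truth J is the ST measurement anchor 0.04 s after the QRS end
  argExt <- function(r, lo, hi, fun) {
    lo <- max(0L, r + lo); hi <- min(n - 1L, r + hi)
    lo + fun(x[(lo + 1L):(hi + 1L)]) - 1L
  }
  sTruth <- vapply(rIdx, argExt, 0L, lo = 0L, hi = 50L, fun = which.min)
  tTruth <- vapply(rIdx, argExt, 0L, lo = 90L, hi = 210L, fun = which.max)

  if (cfg$inverted) x <- 2 * cfg$base - x

  truth <- data.frame(
    r_peak = rIdx,
    s_point = sTruth,
    qrs_end = rIdx + 33L,
    j_point = rIdx + 33L + as.integer(round(0.04 * cfg$fs)),
    t_peak = tTruth,
    stemi = rep(NA, cfg$nBeats))
  attr(truth, "baseline") <- cfg$base
  attr(truth, "inverted") <- cfg$inverted
  attr(truth, "stOffset") <- cfg$stOffset
  attr(truth, "period") <- period

  # noise last, under a locally scoped RNG stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  if (cfg$wanderAmp > 0)
    x <- x + cfg$wanderAmp * sin(2 * pi * cfg$wanderFreq * t / cfg$fs + phase)
  if (cfg$noiseSd > 0)
    x <- x + stats::rnorm(n, 0, cfg$noiseSd)

  rec <- EcgRecord(x, fs = cfg$fs, lead = cfg$lead,
                   recordId = sprintf("synth-%d", cfg$seed))
  list(record = rec, truth = truth)
}

#' Generate a labelled synthetic STEMI cohort
#'
#' Positives carry an injected elevation of at least
#' \code{thresholdCounts + margin} counts at the J point; negatives at most
#' \code{thresholdCounts - margin}. Heart rate varies per record (55-75 bpm)
#' and mild wander (5 counts, 0.3 Hz) and muscle noise (2 counts sd) emulate
#' a monitored but non-ideal strip. Per-record seeds derive from \code{seed}
#' so the cohort is reproducible as a whole.
#'
#' @param nPos,nNeg record counts per class.
#' @param seed cohort seed.
#' @param thresholdCounts ST threshold in counts the labels refer to.
#' @param margin guard band in counts (0 allowed, boundary cases then
#'   intentionally ambiguous).
#' @param inverted generate inverted records instead (labels keep meaning).
#' @param noiseSd,wanderAmp noise levels passed to every record.
#' @return list of \code{generateRecord} outputs; each element also has
#'   \code{$label} (TRUE for positive).
#' @export
generateCohort <- function(nPos, nNeg, seed = 1L, thresholdCounts = 17,
                           margin = 10, inverted = FALSE, noiseSd = 2,
                           wanderAmp = 5) {
  stopifnot(nPos >= 0, nNeg >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  total <- nPos + nNeg
  labels <- rep(c(TRUE, FALSE), c(nPos, nNeg))
  hrs <- sample(55:75, total, replace = TRUE)
  offPos <- thresholdCounts + margin + stats::runif(total, 0, 10)
  offNeg <- pmax(0, thresholdCounts - margin - stats::runif(total, 0, 7))
  seeds <- as.integer((as.numeric(seed) * 7919 + 13 * seq_len(total)) %%
                        2147483647)
  out <- vector("list", total)
  for (k in seq_len(total)) {
    cfg <- synthConfig(seed = seeds[k], heartRate = hrs[k],
                       stOffset = if (labels[k]) offPos[k] else offNeg[k],
                       inverted = inverted, noiseSd = noiseSd,
                       wanderAmp = wanderAmp)
    g <- generateRecord(cfg)
    g$truth$stemi <- labels[k]
    g$label <- labels[k]
    out[[k]] <- g
  }
  out
}
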