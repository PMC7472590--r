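#' Large-oscillation noise compensation
#'
#' Iteratively shrinks a multiplier on the record's mean absolute amplitude
#' until fewer than \code{limit} samples lie strictly below
#' \code{multiplier * mean(|samples|)}; samples at or above the final bound
#' are clipped to it (sign-preserving), so the sample grid and every
#' downstream index are preserved. The multiplier starts at 3.0 and decreases
#' by 0.1 per iteration with a floor of 0.1; shrinking the bound is the only
#' direction that reduces the below-bound count toward the criterion.
#'
#' On signals without gross artifacts the below-bound count only falls under
#' \code{limit} once the bound drops into the physiologic amplitude range, so
#' committing the clip would flatten the QRS. \code{maxClipFrac} guards the
#' pipeline against that failure mode: when the would-be-clipped fraction
#' exceeds it, the samples are returned unchanged (the multiplier and count
#' are still reported). The default 1 always commits, i.e. the literal rule.
#'
#' @param x numeric samples or an \linkS4class{EcgRecord}.
#' @param limit below-bound count criterion (default 3000).
#' @param startMultiplier,step,floorMultiplier multiplier schedule.
#' @param maxClipFrac commit the clip only if at most this fraction of
#'   samples is affected.
#' @return list with \code{samples}, \code{multiplier}, \code{bound},
#'   \code{nClipped}, \code{committed}.
#' @examples
#' x <- c(rep(1, 100), 500)        # flat baseline with one spike
#' compensateNoise(x, limit = 50)$nClipped
#' @export
compensateNoise <- function(x, limit = 3000, startMultiplier = 3,
                            step = 0.1, floorMultiplier = 0.1,
                            maxClipFrac = 1) {
  v <- if (is(x, "EcgRecord")) ecgSamples(x) else as.numeric(x)
  if (length(v) == 0L) stop("compensateNoise: empty input")
  if (limit <= 0) stop("compensateNoise: limit must be positive")
  meanAbs <- mean(abs(v))
  if (meanAbs == 0)
    return(list(samples = v, multiplier = startMultiplier, bound = 0,
                nClipped = 0L, committed = FALSE))
  m <- startMultiplier
  count <- sum(abs(v) < m * meanAbs)
  while (count >= limit && m > floorMultiplier + 1e-9) {
    m <- m - step
    count <- sum(abs(v) < m * meanAbs)
  }
  bound <- m * meanAbs
  over <- abs(v) >= bound
  nClipped <- sum(over)
  committed <- nClipped <= maxClipFrac * length(v)
  out <- v
  if (committed && nClipped > 0L)
    out[over] <- sign(v[over]) * bound
  list(samples = out, multiplier = m, bound = bound,
       nClipped = if (committed) nClipped else 0L, committed = committed)
}

#' Nonnegative amplitude shift
#'
#' Adds |min| to every sample when the minimum is negative, so that all
#' downstream amplitude bookkeeping works on nonnegative counts. Idempotent.
#'
#' @param samples numeric vector.
#' @return list with \code{samples} (min >= 0) and \code{offset} (the added
#'   constant, 0 when nothing was added).
#' @examples
#' shiftNonnegative(c(-5, 0, 5))   # samples 0 5 10, offset 5
#' @export
shiftNonnegative <- function(samples) {
  if (length(samples) == 0L) stop("shiftNonnegative: empty input")
  m <- min(samples)
  if (m < 0)
    list(samples = samples - m, offset = -m)
  else
    list(samples = samples, offset = 0)
}

#' Full data-input stage
#'
#' Noise compensation followed by the nonnegative shift, as applied by
#' \code{\link{runPipeline}}. Length is always preserved.
#'
#' @param record an \linkS4class{EcgRecord} or numeric vector.
#' @param limit below-bound count criterion.
#' @param maxClipFrac see \code{\link{compensateNoise}}; the pipeline default
#'   0.05 commits clipping only for sparse large-amplitude artifacts.
#' @param ... passed to \code{\link{compensateNoise}}.
#' @return list with \code{samples}, \code{multiplier}, \code{offset},
#'   \code{nClipped}, \code{committed}.
#' @export
preprocessRecord <- function(record, limit = 3000, maxClipFrac = 0.05, ...) {
  comp <- compensateNoise(record, limit = limit, maxClipFrac = maxClipFrac,
                          ...)
  sh <- shiftNonnegative(comp$samples)
  list(samples = sh$samples, multiplier = comp$multiplier,
       offset = sh$offset, nClipped = comp$nClipped,
       committed = comp$committed)
}
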