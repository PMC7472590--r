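# 0-based index helpers ------------------------------------------------------

# amplitude at 0-based index (scalar or vector), no clipping
dAt <- function(d, idx0) d[idx0 + 1L]

# clip 0-based indices into the record
clip0 <- function(idx0, n) pmin(pmax(idx0, 0L), n - 1L)

#' Downhill U-turn stopping time
#'
#' The windowed score behind every landmark after the R peak: a sample is
#' contrasted against a trailing window of the same length,
#' \deqn{score(i) = \sum_{j=0}^{range} [ d(a+i) - d(a+i+range+j) ]}
#' for \code{i in 0..range} (forward; the backward form negates every
#' offset). The stopping time is \code{omega = anchor +/- argmax_i score(i)},
#' ties broken toward the smallest \code{i}. The score is maximized where a
#' descending trajectory is about to turn upward, which is why callers that
#' target the turn itself displace omega by half the range.
#'
#' Out-of-record indices are clipped to the record borders and the result is
#' flagged \code{truncated}.
#'
#' @param d numeric amplitude sequence.
#' @param anchor 0-based anchor index.
#' @param range window length parameter (>= 1); the search spans
#'   \code{2 * range + 1} samples past the anchor.
#' @param direction "forward" or "backward".
#' @return list with \code{omega} (0-based stopping index), \code{value}
#'   (= d(omega)), \code{score} (max score) and \code{truncated}.
#' @examples
#' downhillUturn(c(5, 4, 1, 0, 2, 6), anchor = 0, range = 1)$omega  # 1
#' @export
downhillUturn <- function(d, anchor, range,
                          direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  n <- length(d)
  if (n == 0L) stop("downhillUturn: empty input")
  if (range < 1L) stop("downhillUturn: range must be >= 1")
  anchor <- as.integer(anchor)
  range <- as.integer(range)
  if (anchor < 0L || anchor > n - 1L)
    stop("downhillUturn: anchor outside the record")
  sgn <- if (direction == "forward") 1L else -1L
  jj <- 0:range
  scores <- numeric(range + 1L)
  truncated <- FALSE
  for (i in 0:range) {
    here <- anchor + sgn * i
    there <- anchor + sgn * (i + range + jj)
    if (here < 0L || here > n - 1L || any(there < 0L | there > n - 1L))
      truncated <- TRUE
    here <- clip0(here, n)
    there <- clip0(there, n)
    scores[i + 1L] <- sum(dAt(d, here) - dAt(d, there))
  }
  iStar <- which.max(scores) - 1L        # which.max takes the first maximum
  omega <- clip0(anchor + sgn * iStar, n)
  list(omega = omega, value = dAt(d, omega), score = scores[iStar + 1L],
       truncated = truncated)
}
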