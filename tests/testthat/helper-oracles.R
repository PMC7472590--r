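# Independent brute-force oracles for the stopping-time decisions.
# Deliberately written as plain double loops over the printed index ranges,
# sharing no code with the package internals. All indices 0-based.

oracleUturn <- function(d, anchor, range, direction = "forward") {
  n <- length(d)
  sgn <- if (direction == "forward") 1L else -1L
  cl <- function(i) min(max(i, 0L), n - 1L)
  best <- -Inf; bestI <- NA_integer_
  for (i in 0:range) {
    s <- 0
    for (j in 0:range) {
      s <- s + d[cl(anchor + sgn * i) + 1L] -
        d[cl(anchor + sgn * (i + range + j)) + 1L]
    }
    if (s > best) { best <- s; bestI <- i }
  }
  cl(anchor + sgn * bestI)
}

oracleSlopeArgmax <- function(d, interval = 2L) {
  best <- -Inf; bestI <- NA_integer_
  for (i in 0:(length(d) - 1L - interval)) {
    s <- (d[i + interval + 1L] - d[i + 1L]) / interval
    if (s > best) { best <- s; bestI <- i }
  }
  bestI
}

oracleArgminWindow <- function(d, center, half) {
  n <- length(d)
  lo <- min(max(center - half, 0L), n - 1L)
  hi <- min(max(center + half, 0L), n - 1L)
  best <- Inf; bestI <- NA_integer_
  for (t in lo:hi) {
    if (d[t + 1L] < best) { best <- d[t + 1L]; bestI <- t }
  }
  bestI
}

oracleArgmaxFrom <- function(d, from, range) {
  n <- length(d)
  hi <- min(from + range, n - 1L)
  best <- -Inf; bestI <- NA_integer_
  for (t in from:hi) {
    if (d[t + 1L] > best) { best <- d[t + 1L]; bestI <- t }
  }
  bestI
}

# brute-force scan of the full alpha grid, independent of searchAlpha
oracleAlpha <- function(Q, Qopt) {
  for (a in 0.5 + 0:100) {
    p <- exp(Qopt / a) / (exp(Q / a) + exp(Qopt / a))
    if (is.nan(p)) {  # naive overflow: recompute shifted
      m <- max(Q, Qopt) / a
      p <- exp(Qopt / a - m) / (exp(Q / a - m) + exp(Qopt / a - m))
    }
    v <- p * (Qopt - a * log(p))
    if (v > Q) return(a)
  }
  0
}

# clean synthetic record plus annotation of its preprocessed samples
annotatedClean <- function(seed = 1, ...) {
  g <- generateRecord(synthConfig(seed = seed, ...))
  d <- preprocessRecord(g$record)$samples
  list(g = g, d = d, ann = annotateBeats(d), truth = g$truth)
}
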