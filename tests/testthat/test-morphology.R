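test_that("least-first-power direction follows the sign of beta", {
  # upright: segment above the J amplitude, beta < 0, r side closer
  a <- annotatedClean(seed = 12)
  b <- beatTable(a$ann)
  up <- lfpTDirection(a$d, b$omega_j, b$omega_tmax, window = a$ann@rangeT)
  expect_identical(up$direction, "upward")
  expect_lt(up$beta, 0)
  expect_gt(up$sumQ, up$sumR)   # |ym - (p + beta)| > |ym - (p - beta)|
  # inverted synthetic T: peak below J -> downward
  ai <- annotatedClean(seed = 12, inverted = TRUE)
  bi <- beatTable(ai$ann)
  dn <- lfpTDirection(ai$d, bi$omega_j, bi$omega_tmax, window = ai$ann@rangeT)
  expect_identical(dn$direction, "downward")
  expect_gt(dn$beta, 0)
  # flat segment: tie defaults upward, flagged low-confidence
  flat <- lfpTDirection(rep(5, 300), 10L, 60L, window = 50)
  expect_identical(flat$direction, "upward")
  expect_true(flat$lowConfidence)
  expect_error(lfpTDirection(rep(1, 10), integer(0), integer(0)), "no beats")
})

test_that("approximate-entropy next state is log(count)/halfRange with guard", {
  expect_equal(approximateEntropyNextState(c(0.5, 1, 2, 3), 2.5, 2),
               log(3) / 2, tolerance = 1e-12)
  expect_identical(approximateEntropyNextState(c(5, 6), 2, 4), 0)
  expect_equal(approximateEntropyNextState(rnorm(50), Inf, 5), log(50) / 5)
  expect_error(approximateEntropyNextState(1, 1, 0), "halfRange")
  # non-decreasing in the threshold
  set.seed(3)
  s <- rnorm(40)
  vals <- vapply(seq(0, 3, by = 0.25),
                 function(th) approximateEntropyNextState(s, th, 7), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("direction reward combines the maximum and negated mean slope", {
  expect_identical(directionReward(c(-2, -4), slopeMax = 6), 4.5)
  expect_identical(directionReward(c(0, 0, 0)), 0)
  s <- -3.7
  expect_identical(directionReward(s), abs(s))
  expect_error(directionReward(numeric(0)), "empty")
})

test_that("gamma search minimizes the softmax product over its 6-point grid", {
  equal <- matrix(5, nrow = 6, ncol = 2)
  expect_identical(searchGamma(equal)$gamma, 0)    # constant 0.25: tie -> 0
  q <- cbind(rep(1, 6), c(1, 1.2, 0.8, 1.1, 30, 1))
  expect_identical(searchGamma(q)$gamma, 2)        # extreme asymmetry row 5
  # grid-scan oracle on random pairs
  set.seed(23)
  for (k in 1:50) {
    qq <- matrix(rnorm(12, sd = 5), ncol = 2)
    prods <- apply(qq, 1, function(r) {
      e <- exp(r - max(r)); p <- e / sum(e); prod(p)
    })
    expect_identical(searchGamma(qq)$index, which.min(prods))
  }
  expect_error(searchGamma(matrix(0, 3, 2)), "6 x 2")
})

test_that("record-level direction value separates upright from inverted", {
  for (s in c(5, 18)) {
    a <- annotatedClean(seed = s)
    vNon <- waveformDirectionValue(a$d, a$ann)$value
    dInv <- shiftNonnegative(-a$d)$samples
    vInv <- waveformDirectionValue(dInv, annotateBeats(dInv))$value
    expect_gt(vNon, vInv)
  }
  # single beat: the interval-increment rewards stay vacuous but the value
  # is still finite and positive
  a1 <- annotatedClean(seed = 5, nBeats = 1)
  v1 <- waveformDirectionValue(a1$d, a1$ann)
  expect_identical(length(v1$perBeat), 1L)
  expect_true(is.finite(v1$value))
})

test_that("inversion decisions flip under amplitude inversion", {
  for (s in c(3, 9, 27)) {
    a <- annotatedClean(seed = s, noiseSd = 2, wanderAmp = 5)
    fwd <- decideInversion(a$d, a$ann)
    bwd <- decideInversion(shiftNonnegative(-a$d)$samples)
    expect_identical(fwd$verdict, "non-inversed")
    if (!fwd$tie && !bwd$tie)
      expect_false(identical(fwd$verdict, bwd$verdict))
    # the two branch values swap (slope bookkeeping is offset-invariant)
    expect_equal(fwd$valueNoninv, bwd$valueInv, tolerance = 1e-8)
    expect_equal(fwd$valueInv, bwd$valueNoninv, tolerance = 1e-8)
  }
})

test_that("stage arbitration follows ratios and the STEMI override", {
  mkLfp <- function(dir, sq, sr)
    list(direction = dir, beta = if (dir == "upward") -1 else 1,
         sumQ = sq, sumR = sr)
  mkInv <- function(verdict, vn, vi)
    list(verdict = verdict, valueNoninv = vn, valueInv = vi,
         ratio = abs(vn - vi) / max(vn, vi) * 100, tie = FALSE)
  # Eq-style ratio arithmetic: (80, 60) -> 25.0
  inv <- mkInv("non-inversed", 80, 60)
  expect_equal(inv$ratio, 25)
  # agreement passes through
  r <- resolveDirection(mkLfp("upward", 10, 90), inv, stemiRatio = 0)
  expect_identical(r$finalDirection, "non-inversed")
  # conflict: stage with the larger ratio wins
  r2 <- resolveDirection(mkLfp("downward", 30, 70),      # ratio 40/70 -> 57
                         mkInv("non-inversed", 55, 50),  # ratio ~9
                         stemiRatio = 0)
  expect_identical(r2$finalDirection, "inversed")
  r3 <- resolveDirection(mkLfp("downward", 63, 70),      # ratio 10
                         mkInv("non-inversed", 80, 48),  # ratio 40
                         stemiRatio = 0)
  expect_identical(r3$finalDirection, "non-inversed")
  # STEMI override: elevation ratio above 20 percent forces non-inversed
  r4 <- resolveDirection(mkLfp("downward", 10, 90),
                         mkInv("inversed", 10, 90), stemiRatio = 0.3)
  expect_identical(r4$finalDirection, "non-inversed")
  expect_true(r4$overrideApplied)
  r5 <- resolveDirection(mkLfp("downward", 10, 90),
                         mkInv("inversed", 10, 90), stemiRatio = 0.2)
  expect_identical(r5$finalDirection, "inversed")  # 0.2 does not exceed 20.0%
  # pure function: identical evidence, identical verdict
  expect_identical(r4, resolveDirection(mkLfp("downward", 10, 90),
                                        mkInv("inversed", 10, 90),
                                        stemiRatio = 0.3))
})
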