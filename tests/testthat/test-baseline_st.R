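test_that("baseline representative point recovers the flat PR level", {
  a <- annotatedClean(seed = 8)
  b <- beatTable(a$ann)
  for (k in seq_len(nrow(b))) {
    bp <- baselineRepresentativePoint(a$d, b$omega_qrs[k], a$ann@avgInterval,
                                      a$ann@rangeUturn)
    expect_lt(abs(bp$amplitude - attr(a$truth, "baseline")), 3)
    expect_lt(bp$omegaBaseline, b$r_peak_idx[k])
  }
})

test_that("baseline stages equal the brute-force backward scans", {
  set.seed(19)
  for (k in 1:50) {
    d <- rnorm(200)
    anchor <- sample(60:199, 1)
    st1 <- oracleUturn(d, anchor, 25L, "backward") - 12L   # half-range back
    st1 <- max(st1, 0L)
    bp <- baselineRepresentativePoint(d, anchor, avgInterval = 8,
                                      rangeUturn = 25L)
    expect_identical(bp$omegaPreR, st1)
    expect_identical(bp$omegaBaseline,
                     max(oracleUturn(d, st1, 8L, "backward") - 4L, 0L))
    expect_identical(bp$amplitude, d[bp$omegaBaseline + 1L])
  }
})

test_that("truncated pre-R searches are flagged", {
  d <- rnorm(400)
  bp <- baselineRepresentativePoint(d, 10, avgInterval = 20, rangeUturn = 30L)
  expect_true(bp$truncated)
})

test_that("weight adjustment sweeps 21 weights and guards zero amplitude", {
  a <- annotatedClean(seed = 8)
  b <- beatTable(a$ann)
  bp <- baselineRepresentativePoint(a$d, b$omega_qrs[2], a$ann@avgInterval,
                                    a$ann@rangeUturn)
  aw <- adjustWeight(a$d, bp)
  expect_true(aw$weight %in% seq(0.1, 2.1, by = 0.1))
  expect_false(aw$flagged)
  # the printed weighted-baseline form cancels its amplitude: the correction
  # is the recentred sigmoid of w/1.1, below half a count in magnitude
  expect_lt(abs(aw$adjustedAmplitude - bp$amplitude), 0.5)
  zero <- list(baselineInterval = c(0L, 5L), amplitude = 0)
  d0 <- rep(0, 10)
  aw0 <- adjustWeight(d0, zero)
  expect_identical(aw0$weight, 1.0)
  expect_true(aw0$flagged)
})

test_that("ST thresholds reproduce the lead/sex/age table", {
  expect_identical(stThreshold("V2", "male", 35)$mV, 0.25)
  expect_identical(stThreshold("V3", "male", 64)$mV, 0.20)
  expect_identical(stThreshold("V2", "female", 60)$mV, 0.15)
  expect_identical(stThreshold("V3", "female", 25)$mV, 0.15)
  expect_identical(stThreshold("II", "male", 50)$mV, 0.10)
  expect_identical(stThreshold("II", "unknown", NA)$counts, 17)
  # total over all leads and strata; unknown metadata on V2/V3 is the
  # conservative maximum and flagged
  for (ld in c("I", "II", "III", "avR", "avL", "avF", paste0("V", 1:6)))
    for (sx in c("male", "female", "unknown"))
      for (ag in c(18, 40, 80, NA)) {
        r <- stThreshold(ld, sx, ag)
        expect_true(r$mV %in% c(0.25, 0.20, 0.15, 0.10))
      }
  expect_true(stThreshold("V2", "unknown", 30)$flagged)
  expect_identical(stThreshold("V2", "unknown", 30)$mV, 0.25)
  expect_identical(stThreshold("V3", "male", NA)$mV, 0.25)
  expect_error(stThreshold("X9"), "invalid lead")
})

test_that("per-beat ST evaluation uses a strict threshold", {
  r <- evaluateStBeats(c(128, 117, 90, NA), rep(100, 4), 17)
  expect_identical(r$stemi, c(TRUE, FALSE, FALSE, FALSE))  # 28 > 17; 17 = 17
  expect_identical(r$evaluable, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$elevation_mV[1], 28 / 17 * 0.10)
})

test_that("MI verdict applies the strict 39.9999 percent rule", {
  expect_true(miDecision(rep(c(TRUE, FALSE), 5))$miVerdict)          # 0.5
  expect_false(miDecision(rep(FALSE, 10))$miVerdict)
  expect_true(miDecision(c(rep(TRUE, 4), rep(FALSE, 6)))$miVerdict)  # 0.4
  expect_false(miDecision(c(rep(TRUE, 3), rep(FALSE, 7)))$miVerdict)
  one <- miDecision(TRUE)
  expect_identical(one$stemiRatio, 1)
  expect_true(one$miVerdict)
  expect_identical(miDecision(FALSE)$stemiRatio, 0)
  expect_true(is.na(miDecision(c(NA, NA))$miVerdict))
  # beats with missing landmarks leave numerator and denominator
  expect_identical(miDecision(c(TRUE, NA, FALSE, NA))$stemiRatio, 0.5)
})

test_that("MI verdict is monotone in per-beat elevation", {
  base <- rep(100, 10)
  j <- c(rep(130, 4), rep(105, 6))
  v0 <- miDecision(evaluateStBeats(j, base, 17)$stemi)$miVerdict
  for (k in 1:10) {
    j2 <- j; j2[k] <- j2[k] + 50
    v1 <- miDecision(evaluateStBeats(j2, base, 17)$stemi)$miVerdict
    expect_true(v1 >= v0)  # raising a J amplitude never flips MI off
  }
})

test_that("RV flag is the II/III/avF conjunction with NA propagation", {
  expect_true(rvInfarctionFlag(c(II = TRUE, III = TRUE, avF = TRUE)))
  expect_false(rvInfarctionFlag(c(II = TRUE, III = TRUE, avF = FALSE)))
  expect_true(is.na(rvInfarctionFlag(c(II = TRUE, III = TRUE))))
  expect_true(is.na(rvInfarctionFlag(c(II = TRUE, III = NA, avF = TRUE))))
  # equals the logical AND oracle over the full truth table
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) for (cc in c(TRUE, FALSE))
    expect_identical(rvInfarctionFlag(c(II = a, III = b, avF = cc, V1 = TRUE)),
                     a && b && cc)
})
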