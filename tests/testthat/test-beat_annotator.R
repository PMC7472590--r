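test_that("QRS detection resolves the toy bump and degenerate records", {
  p <- detectQrsPeaks(c(0, 1, 2, 8, 2, 1, 0))
  expect_identical(nrow(p), 1L)
  expect_identical(p$omega_qrs, 1L)      # slope (8-1)/2 = 3.5 at i = 1
  expect_identical(p$r_peak_idx, 3L)
  expect_identical(p$r_peak_amp, 8)
  expect_identical(nrow(detectQrsPeaks(rep(5, 2000))), 0L)  # no rising slope
  expect_error(detectQrsPeaks(numeric(0)), "empty")
})

test_that("QRS peaks of a clean synthetic train are recovered exactly", {
  a <- annotatedClean(seed = 21)
  b <- beatTable(a$ann)
  expect_identical(nrow(b), nrow(a$truth))
  expect_true(all(abs(b$r_peak_idx - a$truth$r_peak) <= 2))
})

test_that("minimum after R matches the brute-force argmin and tie rule", {
  d <- rep(1, 201); d[90 + 1] <- 0; d[110 + 1] <- 0  # 0-based 90 and 110
  m <- minAmpAfterR(d, 100)
  expect_identical(m$omega, 90L)          # two equal minima: earlier wins
  set.seed(77)
  for (k in 1:100) {
    d <- rnorm(300)
    r <- sample(0:299, 1)
    expect_identical(minAmpAfterR(d, r)$omega, oracleArgminWindow(d, r, 50L))
  }
})

test_that("S point lands on the clean-beat trough", {
  a <- annotatedClean(seed = 4)
  b <- beatTable(a$ann)
  expect_true(all(abs(b$omega_s - a$truth$s_point) <= 3))
  # a symmetric V after the anchor: state 1 stops inside the descent
  v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9,
         rep(10, 60))
  st <- downhillUturn(v, 0, 5)
  expect_identical(st$omega, oracleUturn(v, 0L, 5L))
})

test_that("J point equals the brute-force score argmax plus half range", {
  set.seed(31)
  for (k in 1:50) {
    d <- rnorm(80)
    s <- sample(0:40, 1)
    # avgInterval chosen so the range rounds to 2 -> displacement 1
    r <- locateJPoint(d, s, avgInterval = 4 / 3)
    expect_identical(r$range, 2L)
    expect_identical(r$omega,
                     min(oracleUturn(d, s, 2L) + 1L, length(d) - 1L))
    expect_identical(r$value, d[r$omega + 1L])   # amplitude is d(omega_J)
  }
  expect_error(locateJPoint(rnorm(50), 10, avgInterval = 0.1), "range")
})

test_that("T search range is clamped into [25, 100]", {
  expect_identical(stecg:::clampUturnRange(100), 100L)  # 1.5*100 -> 100
  expect_identical(stecg:::clampUturnRange(10), 25L)    # 15 -> 25
  expect_identical(stecg:::clampUturnRange(40), 60L)    # inside the band
})

test_that("T peak and T-end stopping times match their oracles", {
  a <- annotatedClean(seed = 9)
  b <- beatTable(a$ann)
  expect_true(all(abs(b$omega_tmax - a$truth$t_peak) <= 2))
  set.seed(13)
  for (k in 1:50) {
    d <- rnorm(400)
    j <- sample(0:150, 1)
    r <- locateTWave(d, j, rangeT = 120, rangeUturn = 25L)
    expect_identical(r$omegaTmax, oracleArgmaxFrom(d, j, 120L))
    expect_identical(r$omegaTEnd,
                     min(oracleUturn(d, j, 25L) + 12L, length(d) - 1L))
  }
})

test_that("landmark ordering holds on synthetic records", {
  for (s in c(2, 14, 35)) {
    a <- annotatedClean(seed = s, noiseSd = 2, wanderAmp = 5)
    b <- beatTable(a$ann)
    expect_true(all(b$r_peak_idx < b$omega_s))
    expect_true(all(b$omega_s <= b$omega_j))
    expect_true(all(b$omega_j < b$omega_tmax))
    expect_true(all(b$omega_qrs >= 0 & b$omega_t_end <= a$ann@n - 1))
  }
})

test_that("annotation is translation-equivariant and offset-invariant", {
  g <- generateRecord(synthConfig(seed = 6))
  d <- ecgSamples(g$record)
  b0 <- beatTable(annotateBeats(d))
  k <- 17L
  dShift <- c(rep(d[1], k), d[seq_len(length(d) - k)])
  bS <- beatTable(annotateBeats(dShift))
  idx <- c("omega_qrs", "r_peak_idx", "omega_min_amp", "omega_s",
           "omega_j", "omega_tmax", "omega_t_end")
  expect_identical(nrow(bS), nrow(b0))
  for (cn in idx) expect_identical(bS[[cn]], b0[[cn]] + k)
  bOff <- beatTable(annotateBeats(d + 250))
  for (cn in idx) expect_identical(bOff[[cn]], b0[[cn]])
})
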