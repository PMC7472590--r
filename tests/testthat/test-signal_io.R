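test_that("CSV round trip restores the selected lead exactly", {
  tmp <- tempfile(fileext = ".csv")
  set.seed(101)
  cols <- setNames(lapply(1:12, function(k) round(rnorm(500, 100, 30))),
                   c("I", "II", "III", "avR", "avL", "avF", paste0("V", 1:6)))
  writeEcgCsv(cols, tmp)
  rec <- readEcgCsv(tmp, lead = "V2")
  expect_identical(ecgSamples(rec), as.numeric(cols$V2))
  expect_identical(leadName(rec), "V2")
  expect_identical(samplingRate(rec), 500)
  unlink(tmp)
})

test_that("single-column files and headerless files read as one lead", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("42", "43", "41"), tmp)           # no header at all
  rec <- readEcgCsv(tmp, lead = "II")
  expect_identical(ecgSamples(rec), c(42, 43, 41))
  writeLines(c("sig", "1", "2"), tmp)            # header auto-detected
  expect_identical(ecgSamples(readEcgCsv(tmp, lead = "II")), c(1, 2))
  unlink(tmp)
})

test_that("missing leads and bad cells produce informative errors", {
  tmp <- tempfile(fileext = ".csv")
  writeEcgCsv(list(I = c(1, 2), II = c(3, 4)), tmp)
  expect_error(readEcgCsv(tmp, lead = "V2"), "available columns: I, II")
  writeLines(c("I,II", "1,2", "1,x"), tmp)
  expect_error(readEcgCsv(tmp, lead = "II"), "row 2")
  expect_error(readEcgCsv(tempfile(), lead = "II"), "no such file")
  unlink(tmp)
})

test_that("WFDB format-16 records round-trip and bounds are checked", {
  stem <- file.path(tempdir(), "wfdbtest")
  set.seed(9)
  sig <- list(II = as.integer(round(rnorm(400, 0, 200))),
              V1 = as.integer(round(rnorm(400, 0, 150))))
  writeWfdbRecord(sig, stem, fs = 360)
  r0 <- readWfdbRecord(stem, channel = 0)
  expect_identical(ecgSamples(r0), as.numeric(sig$II))
  expect_identical(samplingRate(r0), 360)
  expect_identical(leadName(r0), "II")
  r1 <- readWfdbRecord(stem, channel = 1)
  expect_identical(ecgSamples(r1), as.numeric(sig$V1))
  expect_error(readWfdbRecord(stem, channel = 5), "out of range")
  expect_error(readWfdbRecord(file.path(tempdir(), "nope")), "missing header")
  unlink(paste0(stem, c(".hea", ".dat")))
})

test_that("JSON reports are reread-equal and schema-valid", {
  g <- generateRecord(synthConfig(seed = 15, stOffset = 30))
  rep <- runPipeline(g$record)
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  x <- readReport(f)
  expect_identical(x$record_id, recordId(rep))
  expect_equal(x$stemi_ratio, rep@stemiRatio)
  expect_identical(x$mi_verdict, rep@miVerdict)
  expect_identical(x$inversion_verdict, rep@inversionVerdict)
  # all annotated beats serialized
  expect_identical(nrow(x$leads$II$beats), nrow(rep@leads$II$beats))
  expect_silent(validateReport(x))
  # mi_verdict true comes with a consistent ratio
  expect_true(x$mi_verdict)
  expect_gt(x$stemi_ratio, 0.399999)
  bad <- x; bad$stemi_ratio <- 1.5
  expect_error(validateReport(bad), "stemi_ratio")
  bad2 <- x; bad2$mi_verdict <- NULL
  expect_error(validateReport(bad2), "missing fields")
  unlink(f)
})

test_that("record and annotation objects validate and print", {
  expect_error(EcgRecord(numeric(0)), "nonempty")
  expect_error(EcgRecord(1:10, lead = "W9"), "lead")
  expect_error(EcgRecord(1:10, fs = -1), "fs")
  rec <- EcgRecord(1:400, lead = "V3", sex = "female", age = 61)
  expect_output(show(rec), "V3")
  a <- annotatedClean(seed = 1)
  expect_output(show(a$ann), "beats")
})
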