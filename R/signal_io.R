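#' Read one lead from a CSV ECG file
#'
#' Dialect: comma-separated, optional single header row, one column per
#' lead, one sample per row, amplitudes in ADC counts. Only the requested
#' lead is loaded; a single-column file is taken as the requested lead
#' whatever its header. Sample indices are 0-based from here on.
#'
#' @param path CSV file path.
#' @param lead lead name to extract.
#' @param sex,age patient metadata (default unknown).
#' @param fs sampling rate in Hz (default 500).
#' @param recordId identifier; defaults to the file name.
#' @return An \linkS4class{EcgRecord}.
#' @export
readEcgCsv <- function(path, lead = "II", sex = "unknown", age = NA,
                       fs = 500, recordId = NULL) {
  if (!file.exists(path)) stop(sprintf("readEcgCsv: no such file: %s", path))
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- utils::read.csv(path, header = hasHeader,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 1L) {
    col <- 1L
  } else {
    if (!hasHeader)
      stop("readEcgCsv: multi-column CSV without a header row; ",
           "cannot locate lead '", lead, "'")
    hit <- which(tolower(names(tab)) == tolower(lead))
    if (!length(hit))
      stop(sprintf("readEcgCsv: lead '%s' not found; available columns: %s",
                   lead, paste(names(tab), collapse = ", ")))
    col <- hit[1L]
  }
  v <- tab[[col]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
    stop(sprintf("readEcgCsv: non-numeric value in column %d at data row %d",
                 col, bad))
  }
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("readEcgCsv: missing value in column %d at data row %d",
                 col, bad))
  }
  EcgRecord(v, fs = fs, lead = lead, sex = sex, age = age,
            recordId = if (is.null(recordId)) basename(path) else recordId)
}

#' Write one or more leads to a CSV ECG file
#'
#' Inverse of \code{\link{readEcgCsv}}: one column per lead with a header
#' row, one sample per row.
#'
#' @param x named list of numeric vectors (names = leads), a numeric
#'   vector, or an \linkS4class{EcgRecord}.
#' @param path output file.
#' @param lead column name when \code{x} is a bare vector.
#' @export
writeEcgCsv <- function(x, path, lead = "II") {
  if (is(x, "EcgRecord")) {
    cols <- stats::setNames(list(ecgSamples(x)), leadName(x))
  } else if (is.numeric(x)) {
    cols <- stats::setNames(list(x), lead)
  } else cols <- x
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a channel of a WFDB record
#'
#' Minimal reader for PhysioNet-style WFDB records: the header
#' (\code{<stem>.hea}) provides the channel count, sampling rate and sample
#' count; the signal file is decoded for formats 16 (16-bit little-endian)
#' and 212 (packed 12-bit pairs). The selected channel is returned as raw
#' digital ADC counts with \code{fs} taken from the header.
#'
#' @param stem record path without extension.
#' @param channel 0-based channel index.
#' @param sex,age metadata for downstream thresholds.
#' @return An \linkS4class{EcgRecord} (lead label from the header's signal
#'   description when it matches a standard lead, else "II").
#' @export
readWfdbRecord <- function(stem, channel = 0L, sex = "unknown", age = NA) {
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop("readWfdbRecord: missing header: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(top[3L]) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (channel < 0L || channel >= nsig)
    stop(sprintf("readWfdbRecord: channel %d out of range (record has %d)",
                 channel, nsig))
  sigLines <- lines[2:(1L + nsig)]
  fields <- strsplit(trimws(sigLines), "\\s+")
  datFile <- file.path(dirname(stem), fields[[1L]][1L])
  if (!file.exists(datFile))
    stop("readWfdbRecord: missing signal file: ", datFile)
  fmt <- sub("x.*$", "", fields[[channel + 1L]][2L])
  raw <- readBin(datFile, "raw", n = file.info(datFile)$size)
  if (fmt == "16") {
    all <- readBin(raw, "integer", n = length(raw) / 2L, size = 2L,
                   endian = "little", signed = TRUE)
    mat <- matrix(all[seq_len((length(all) %/% nsig) * nsig)], nrow = nsig)
    v <- mat[channel + 1L, ]
  } else if (fmt == "212") {
    if (nsig != 2L) stop("readWfdbRecord: format 212 supported for 2 channels")
    b <- as.integer(raw)
    nTrip <- length(b) %/% 3L
    i <- 3L * (seq_len(nTrip) - 1L)
    lo0 <- b[i + 1L]; mid <- b[i + 2L]; lo1 <- b[i + 3L]
    s0 <- bitwAnd(mid, 15L) * 256L + lo0
    s1 <- bitwAnd(bitwShiftR(mid, 4L), 15L) * 256L + lo1
    s0 <- ifelse(s0 > 2047L, s0 - 4096L, s0)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    v <- if (channel == 0L) s0 else s1
  } else stop("readWfdbRecord: unsupported format ", fmt)
  if (!is.na(nsamp) && length(v) >= nsamp) v <- v[seq_len(nsamp)]
  desc <- fields[[channel + 1L]]
  lead <- desc[length(desc)]
  if (!(lead %in% .LEADS)) lead <- "II"
  EcgRecord(v, fs = fs, lead = lead, sex = sex, age = age,
            recordId = basename(stem))
}

#' Write a WFDB record (format 16)
#'
#' Companion writer used for round-trip fixtures and interchange: one
#' header plus an interleaved 16-bit little-endian signal file.
#'
#' @param signals named list of integer vectors of equal length.
#' @param stem output path without extension.
#' @param fs sampling rate.
#' @export
writeWfdbRecord <- function(signals, stem, fs = 500) {
  nsig <- length(signals)
  n <- unique(lengths(signals))
  if (length(n) != 1L) stop("writeWfdbRecord: signals must have equal length")
  name <- basename(stem)
  hea <- c(sprintf("%s %d %g %d", name, nsig, fs, n),
           vapply(names(signals), function(nm)
             sprintf("%s.dat 16 200 16 0 0 0 0 %s", name, nm), ""))
  writeLines(hea, paste0(stem, ".hea"))
  mat <- do.call(rbind, lapply(signals, as.integer))
  writeBin(as.integer(mat), paste0(stem, ".dat"), size = 2L,
           endian = "little")
  invisible(stem)
}

# ---- JSON report -----------------------------------------------------------

reportToList <- function(report) {
  list(record_id = report@recordId,
       stemi_ratio = report@stemiRatio,
       mi_verdict = report@miVerdict,
       inversion_verdict = report@inversionVerdict,
       rv_flag = report@rvFlag,
       parameters = report@parameters,
       leads = report@leads)
}

#' Write a diagnosis report as JSON
#'
#' Stable key order, reread-equal via \code{\link{readReport}}; the shape is
#' described by the schema shipped at
#' \code{system.file("schema", "report-schema.json", package = "stecg")}.
#'
#' @param report an \linkS4class{EcgReport} or an equivalent list.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  x <- if (is(report, "EcgReport")) reportToList(report) else report
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Validate a report against the shipped schema
#'
#' Checks the required top-level fields, their types and the range
#' invariants (stemi_ratio in [0, 1], verdict vocabulary).
#'
#' @param x a report list (as read back) or \linkS4class{EcgReport}.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validateReport <- function(x) {
  if (is(x, "EcgReport")) x <- reportToList(x)
  need <- c("record_id", "stemi_ratio", "mi_verdict", "inversion_verdict",
            "rv_flag", "parameters", "leads")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("validateReport: missing fields: ", paste(miss, collapse = ", "))
  if (!is.character(x$record_id))
    stop("validateReport: record_id must be a string")
  if (!is.null(x$stemi_ratio) && !is.na(x$stemi_ratio) &&
      (x$stemi_ratio < 0 || x$stemi_ratio > 1))
    stop("validateReport: stemi_ratio must lie in [0, 1]")
  if (!is.na(x$inversion_verdict) &&
      !x$inversion_verdict %in% c("non-inversed", "inversed"))
    stop("validateReport: inversion_verdict vocabulary violation")
  invisible(TRUE)
}
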