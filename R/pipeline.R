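defaultConfig <- function() {
  list(countsPer0p10mV = 17,
       miRatioThreshold = 0.399999,
       inversionOverrideRatio = 0.20,
       noiseLimit = 3000,
       noiseMaxClipFrac = 0.05,
       runInversion = TRUE)
}

mergeConfig <- function(config) {
  cfg <- defaultConfig()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

# run every evaluation stage on one preprocessed lead
processLead <- function(record, cfg, verbose = FALSE) {
  pre <- preprocessRecord(record, limit = cfg$noiseLimit,
                          maxClipFrac = cfg$noiseMaxClipFrac)
  d <- pre$samples
  ann <- annotateBeats(d, fs = samplingRate(record))
  beats <- beatTable(ann)
  thr <- stThreshold(leadName(record), record@sex, record@age,
                     cfg$countsPer0p10mV)
  if (!nrow(beats)) {
    return(list(lead = leadName(record), nBeats = 0L, beats = beats,
                stemiRatio = NA_real_, miVerdict = NA,
                threshold = thr, direction = NULL,
                finalDirection = NA_character_, preprocess = pre[-1L]))
  }
  nb <- nrow(beats)
  base <- lapply(seq_len(nb), function(k)
    baselineRepresentativePoint(d, beats$omega_qrs[k], ann@avgInterval,
                                ann@rangeUturn, beats$r_peak_amp[k]))
  adj <- lapply(base, function(b) adjustWeight(d, b))
  baseAmp <- vapply(adj, `[[`, 0, "adjustedAmplitude")
  st <- evaluateStBeats(beats$j_amp, baseAmp, thr$counts,
                        cfg$countsPer0p10mV)
  flags <- ifelse(st$evaluable, st$stemi, NA)
  mi <- miDecision(flags, cfg$miRatioThreshold)

  lfp <- tryCatch(lfpTDirection(d, beats$omega_j, beats$omega_tmax,
                                window = ann@rangeT),
                  error = function(e) NULL)
  direction <- NULL
  finalDir <- NA_character_
  if (isTRUE(cfg$runInversion) && !is.null(lfp)) {
    inv <- decideInversion(d, ann)
    direction <- resolveDirection(lfp, inv, mi$stemiRatio,
                                  cfg$inversionOverrideRatio)
    finalDir <- direction$finalDirection
    direction$inversion <- inv[c("valueNoninv", "valueInv", "ratio", "tie")]
  } else if (!is.null(lfp)) {
    finalDir <- if (lfp$direction == "upward") "non-inversed" else "inversed"
  }
  if (verbose)
    message(sprintf("lead %s: %d beats, STEMI ratio %.3f, direction %s",
                    leadName(record), nb, mi$stemiRatio, finalDir))

  beats$baseline_amp <- vapply(base, `[[`, 0, "amplitude")
  beats$baseline_adj <- baseAmp
  beats$omega_baseline <- vapply(base, `[[`, 0L, "omegaBaseline")
  beats$elevation_counts <- st$elevation_counts
  beats$elevation_mV <- st$elevation_mV
  beats$stemi <- st$stemi

  list(lead = leadName(record), nBeats = nb, beats = beats,
       stemiRatio = mi$stemiRatio, miVerdict = mi$miVerdict,
       threshold = thr, lfp = if (is.null(lfp)) NULL else
         lfp[c("direction", "beta", "sumQ", "sumR")],
       direction = direction, finalDirection = finalDir,
       preprocess = pre[-1L])
}

#' Run the full evaluation pipeline
#'
#' Executes the five evaluation stages per lead -- data input
#' (noise compensation + nonnegative shift), stopping-time beat annotation,
#' baseline approximation, ST-segment deviation, and waveform direction --
#' then aggregates verdicts and, when leads II, III and avF were all
#' processed, the right-ventricle-infarction flag. Fully deterministic for
#' fixed inputs; per-lead failures are isolated into the report.
#'
#' @param input an \linkS4class{EcgRecord}, a list of them (one per lead),
#'   or a path to a CSV file in the package dialect.
#' @param leads leads to process when reading from a file (default: all
#'   columns present).
#' @param sex,age,fs metadata used when reading from a file.
#' @param config named list overriding \code{stecg:::defaultConfig()}:
#'   countsPer0p10mV, miRatioThreshold, inversionOverrideRatio, noiseLimit,
#'   noiseMaxClipFrac, runInversion.
#' @param verbose emit per-lead progress messages.
#' @return An \linkS4class{EcgReport}. The top-level STEMI ratio is the
#'   maximum over processed leads and the MI verdict is true when any lead
#'   is MI-positive; the top-level inversion verdict is the majority over
#'   leads (ties to non-inversed).
#' @export
runPipeline <- function(input, leads = NULL, sex = "unknown", age = NA,
                        fs = 500, config = list(), verbose = FALSE) {
  cfg <- mergeConfig(config)
  if (is(input, "EcgRecord")) {
    records <- list(input)
  } else if (is.list(input) && all(vapply(input, is, TRUE, "EcgRecord"))) {
    records <- input
  } else if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input))
      stop("runPipeline: no such file: ", input)
    if (is.null(leads)) {
      first <- strsplit(readLines(input, n = 1L), ",")[[1L]]
      leads <- intersect(gsub("\"", "", trimws(first)), .LEADS)
      if (!length(leads)) leads <- "II"
    }
    records <- lapply(leads, function(ld)
      readEcgCsv(input, lead = ld, sex = sex, age = age, fs = fs))
  } else stop("runPipeline: input must be an EcgRecord, a list of them, ",
              "or a CSV path")

  results <- list()
  for (rec in records) {
    res <- tryCatch(processLead(rec, cfg, verbose),
                    error = function(e)
                      list(lead = leadName(rec), error = conditionMessage(e),
                           nBeats = 0L, stemiRatio = NA_real_,
                           miVerdict = NA, finalDirection = NA_character_))
    results[[leadName(rec)]] <- res
  }

  ratios <- vapply(results, function(r) r$stemiRatio, 0)
  verdicts <- vapply(results, function(r)
    if (is.null(r$miVerdict)) NA else r$miVerdict, NA)
  dirs <- vapply(results, function(r) r$finalDirection, "")
  topRatio <- if (all(is.na(ratios))) NA_real_ else max(ratios, na.rm = TRUE)
  topMi <- if (all(is.na(verdicts))) NA else any(verdicts, na.rm = TRUE)
  nInv <- sum(dirs == "inversed", na.rm = TRUE)
  nNon <- sum(dirs == "non-inversed", na.rm = TRUE)
  topDir <- if (nInv + nNon == 0L) NA_character_
            else if (nInv > nNon) "inversed" else "non-inversed"
  rv <- rvInfarctionFlag(verdicts)

  new("EcgReport",
      recordId = recordId(records[[1L]]),
      leads = results,
      stemiRatio = topRatio,
      miVerdict = topMi,
      inversionVerdict = topDir,
      rvFlag = rv,
      parameters = cfg)
}

#' Batch-run the pipeline over several inputs
#'
#' @param inputs list of pipeline inputs (records, record lists or paths).
#' @param config see \code{\link{runPipeline}}.
#' @param truth optional logical vector of MI truth labels; when given a
#'   confusion summary (sensitivity/specificity/accuracy) is attached.
#' @param ... passed to \code{\link{runPipeline}}.
#' @return data.frame with one row per input (record_id, stemi_ratio,
#'   mi_verdict, inversion_verdict, rv_flag, failed); the confusion summary,
#'   when computed, is in \code{attr(, "summary")}.
#' @export
runBatch <- function(inputs, config = list(), truth = NULL, ...) {
  if (!length(inputs)) stop("runBatch: empty input list")
  rows <- lapply(seq_along(inputs), function(k) {
    rep <- tryCatch(runPipeline(inputs[[k]], config = config, ...),
                    error = function(e) NULL)
    if (is.null(rep))
      return(data.frame(record_id = sprintf("input-%d", k),
                        stemi_ratio = NA_real_, mi_verdict = NA,
                        inversion_verdict = NA_character_, rv_flag = NA,
                        failed = TRUE))
    data.frame(record_id = rep@recordId, stemi_ratio = rep@stemiRatio,
               mi_verdict = rep@miVerdict,
               inversion_verdict = rep@inversionVerdict,
               rv_flag = rep@rvFlag, failed = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    ok <- !out$failed & !is.na(out$mi_verdict)
    tp <- sum(out$mi_verdict[ok] & truth[ok])
    tn <- sum(!out$mi_verdict[ok] & !truth[ok])
    fp <- sum(out$mi_verdict[ok] & !truth[ok])
    fn <- sum(!out$mi_verdict[ok] & truth[ok])
    attr(out, "summary") <- list(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = if (sum(ok) > 0) (tp + tn) / sum(ok) else NA_real_,
      n = sum(ok))
  }
  out
}

#' Build an EcgReport list-of-leads into a JSON-ready report
#'
#' Convenience wrapper: run the pipeline and write the JSON report.
#'
#' @param input,path see \code{\link{runPipeline}} / \code{\link{writeReport}}.
#' @param ... passed to \code{\link{runPipeline}}.
#' @return The \linkS4class{EcgReport}, invisibly.
#' @export
diagnoseToJson <- function(input, path, ...) {
  rep <- runPipeline(input, ...)
  writeReport(rep, path)
  invisible(rep)
}
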