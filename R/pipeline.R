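#' Three-decimal display form of a p-value
#'
#' Mirrors the reporting style common in the behavioral literature:
#' `"<.0001"` below 1e-4, otherwise three decimals without a leading zero.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
formatP <- function(p) {
  ifelse(p < 1e-4, "<.0001", sub("^0\\.", ".", sprintf("%.3f", p)))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

.writeReportCSV <- function(df, path, header_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full sensitivity-comparison pipeline
#'
#' Executes, in order: read (or accept) the study, complete-case filtering,
#' pooled z-standardization, the QC equivalence gate (raw vs z one-way
#' ANOVAs must agree; failure aborts unless `strictQC = FALSE`), the
#' omnibus two-way (time x measure) within-subject ANOVA, per-measure
#' one-way ANOVAs, trend contrasts and LSD pairwise comparisons, the
#' sensitivity summary and the ranking. Reports are written to
#' `outputDir`: `qc.csv`, `omnibus.csv`, `sensitivity.csv`, `ranking.json`
#' and `run_log.txt`. Every report names the package version and a hash of
#' the configuration; the analysis path itself contains no randomness, so
#' identical inputs give byte-identical reports.
#'
#' @param input a CSV path (long format, see [readStudyCSV()]) or a
#'   [SensitivityStudy-class].
#' @param outputDir directory for the report bundle (created if needed);
#'   `NULL` skips writing and just returns the results.
#' @param alpha significance level used throughout (default 0.05).
#' @param sdDenominator passed to [standardizeMeasures()].
#' @param errorTerm passed to the follow-up tests.
#' @param deltaPairs,directions passed to [summarizeSensitivity()].
#' @param strictQC abort on QC failure (default TRUE); otherwise downgrade
#'   to a warning.
#' @param qcTolerance tolerance of the QC equivalence gate.
#' @param seed seed to echo in the reports when the input was simulated
#'   (metadata only; the analysis is deterministic).
#' @return (invisibly) list: `study` (filtered), `z`, `qc`, `omnibus`,
#'   `oneway`, `trends`, `pairwise`, `summary`, `ranking`, `config`.
#' @examples
#' res <- runPipeline(simulateStressStudy(seed = 1), outputDir = NULL)
#' res$ranking
#' @export
runPipeline <- function(input, outputDir = NULL, alpha = 0.05,
                        sdDenominator = c("n-1", "n"),
                        errorTerm = c("separate", "pooled"),
                        deltaPairs = list(c(1L, 2L), c(1L, 3L)),
                        directions = NULL, strictQC = TRUE,
                        qcTolerance = 1e-9, seed = NULL) {
  sdDenominator <- match.arg(sdDenominator)
  errorTerm <- match.arg(errorTerm)
  stopifnot(alpha > 0, alpha < 1)

  study <- .stage("read", {
    if (methods::is(input, "SensitivityStudy")) input
    else readStudyCSV(input)
  })
  study <- .stage("complete_cases", filterCompleteCases(study))
  z <- .stage("standardize",
              standardizeMeasures(study, sdDenominator = sdDenominator))
  qc <- .stage("qc", qcEquivalence(study, z, alpha = alpha,
                                   tolerance = qcTolerance))
  if (!all(qc$passed)) {
    bad <- paste(qc$measure[!qc$passed], collapse = ", ")
    msg <- paste0("QC equivalence check failed for measure(s): ", bad)
    if (strictQC) stop("[qc] ", msg, call. = FALSE) else warning(msg)
  }
  omnibus <- .stage("two_way_anova", rmAnovaTwoWay(z, alpha = alpha))
  fu <- .stage("follow_up",
               analyzeSensitivity(z, alpha = alpha, errorTerm = errorTerm,
                                  deltaPairs = deltaPairs,
                                  directions = directions))
  ranking <- .stage("ranking", rankMeasures(fu$summary))

  config <- list(alpha = alpha, sd_denominator = sdDenominator,
                 error_term = errorTerm,
                 delta_z_pairs = lapply(deltaPairs, as.integer),
                 strict_qc = strictQC, qc_tolerance = qcTolerance,
                 seed = seed)
  res <- list(study = study, z = z, qc = qc, omnibus = omnibus,
              oneway = fu$oneway, trends = fu$trends,
              pairwise = fu$pairwise, summary = fu$summary,
              ranking = ranking, config = config)
  if (!is.null(outputDir))
    .stage("report", .writeReports(res, outputDir))
  invisible(res)
}

.writeReports <- function(res, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  version <- as.character(utils::packageVersion("zsens"))
  hash <- rlang::hash(res$config)
  stamp <- c(sprintf("# zsens %s", version),
             sprintf("# config_hash %s", hash),
             sprintf("# seed %s",
                     if (is.null(res$config$seed)) "NA" else res$config$seed))

  qc <- res$qc
  .writeReportCSV(qc, file.path(outputDir, "qc.csv"), stamp)

  omnibus <- res$omnibus
  omnibus$p_uncorrected_display <- formatP(omnibus$p_uncorrected)
  omnibus$p_gg_display <- formatP(omnibus$p_gg)
  .writeReportCSV(omnibus, file.path(outputDir, "omnibus.csv"), stamp)

  summ <- res$summary
  summ$oneway_p_display <- formatP(summ$oneway_p)
  .writeReportCSV(summ, file.path(outputDir, "sensitivity.csv"), stamp)

  jsonlite::write_json(
    list(package = "zsens", version = version, config_hash = hash,
         seed = res$config$seed, config = res$config,
         ranking = res$ranking),
    file.path(outputDir, "ranking.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    stamp,
    sprintf("subjects=%d sessions=%d measures=%d",
            length(subjectIDs(res$study)), nSessions(res$study),
            length(measureNames(res$study))),
    sprintf("qc_passed=%s", all(res$qc$passed)),
    sprintf("config=%s",
            jsonlite::toJSON(res$config, auto_unbox = TRUE, null = "null"))
  )
  writeLines(log_lines, file.path(outputDir, "run_log.txt"))
  invisible(outputDir)
}
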