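#' SensitivityStudy: a multi-metric repeated-measures study
#'
#' `SensitivityStudy` extends [SummarizedExperiment::SummarizedExperiment].
#' Rows are dependent measures (outcome metrics); columns are
#' subject-by-session observation cells, with `colData` columns `subject`
#' (character) and `session` (integer, consecutive from 1). The first assay
#' holds the observed values in each measure's native units — or z-scores,
#' after [standardizeMeasures()]. A missing observation is an `NA` cell;
#' [filterCompleteCases()] enforces the complete-case balanced design the
#' downstream within-subject ANOVAs require.
#'
#' Measures keep the order in which they were supplied (or first appeared in
#' a long file); subjects are ordered by identifier; columns are grouped by
#' subject and ordered by session within subject.
#'
#' After [standardizeMeasures()] the per-measure grand means and SDs are
#' carried in `rowData` and retrievable with [standardization()].
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @seealso [SensitivityStudy()] to construct one from long-format data,
#'   [readStudyCSV()] for file input, [simulateStudy()] to generate one.
#' @export
setClass("SensitivityStudy", contains = "SummarizedExperiment")

.validSensitivityStudy <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject", "session") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'subject' and 'session' columns")
  else {
    sess <- cd$session
    if (!is.integer(sess))
      msg <- c(msg, "'session' must be an integer vector")
    else {
      tt <- sort(unique(sess))
      if (length(tt) < 2L || !identical(tt, seq_len(max(tt))))
        msg <- c(msg, "sessions must be consecutive integers 1..T with T >= 2")
      if (anyDuplicated(paste(cd$subject, sess, sep = "\r")))
        msg <- c(msg, "duplicate (subject, session) observation cells")
      # every subject must carry a column for every session (value may be NA)
      if (length(msg) == 0L) {
        ns <- table(cd$subject)
        if (length(unique(ns)) > 1L || ns[1L] != length(tt))
          msg <- c(msg, "every subject must have one column per session")
      }
    }
  }
  if (length(SummarizedExperiment::assays(object)) < 1L)
    msg <- c(msg, "at least one assay is required")
  else {
    a <- SummarizedExperiment::assay(object, 1L)
    if (!is.numeric(a))
      msg <- c(msg, "assay values must be numeric")
    else if (any(is.infinite(a) | is.nan(a)))
      msg <- c(msg, "assay values must be finite or NA")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "measures (rownames) must be unique and non-NULL")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SensitivityStudy", .validSensitivityStudy)

#' @describeIn SensitivityStudy-class compact display of design and state
#' @param object a `SensitivityStudy`
#' @export
setMethod("show", "SensitivityStudy", function(object) {
  cat(sprintf(
    "SensitivityStudy: %d measure(s), %d subject(s) x %d session(s)%s\n",
    nrow(object), length(subjectIDs(object)), nSessions(object),
    if (isStandardized(object)) " [z-standardized]" else ""
  ))
  cat(sprintf("  balanced (complete cases): %s\n", isBalanced(object)))
  m <- measureNames(object)
  cat(sprintf("  measures: %s%s\n", paste(utils::head(m, 4L), collapse = ", "),
              if (length(m) > 4L) sprintf(", ... (%d more)", length(m) - 4L) else ""))
  invisible(NULL)
})
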