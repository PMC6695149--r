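#' Construct a SensitivityStudy from long-format observations
#'
#' One row per (subject, session, measure, value) observation. Sessions must
#' be orderable labels; if they are not already the consecutive integers
#' `1..T` they are re-indexed to `1..T` in increasing label order, with a
#' warning. At most one observation per (subject, session, measure) key is
#' allowed. Missing cells are permitted at construction time and surface as
#' `NA` in the assay; use [filterCompleteCases()] before analysis.
#'
#' @param long data.frame with columns `subject`, `session`, `measure`,
#'   `value`.
#' @param measureLevels optional character vector fixing the measure order;
#'   defaults to order of first appearance.
#' @return a [SensitivityStudy-class] object with assay `"values"`.
#' @examples
#' long <- data.frame(
#'   subject = rep(c("a", "b"), each = 4),
#'   session = rep(1:2, times = 4),
#'   measure = rep(rep(c("m1", "m2"), each = 2), 2),
#'   value   = rnorm(8)
#' )
#' SensitivityStudy(long)
#' @export
SensitivityStudy <- function(long, measureLevels = NULL) {
  required <- c("subject", "session", "measure", "value")
  missing_col <- setdiff(required, colnames(long))
  if (length(missing_col))
    stop("missing required column(s): ", paste(missing_col, collapse = ", "))
  long <- as.data.frame(long)[, required]
  long$subject <- as.character(long$subject)
  long$measure <- as.character(long$measure)

  sess_num <- suppressWarnings(as.numeric(long$session))
  bad <- which(is.na(sess_num))
  if (length(bad))
    stop("non-numeric session value in row ", bad[1L])
  if (any(sess_num != round(sess_num)))
    stop("session labels must be integers")
  sess <- as.integer(sess_num)

  if (!is.numeric(long$value))
    stop("'value' column must be numeric")
  bad <- which(!is.finite(long$value))
  if (length(bad))
    stop("non-finite value in row ", bad[1L])

  key <- paste(long$subject, sess, long$measure, sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate observation for (%s, %d, %s)",
                 d$subject, sess[duplicated(key)][1L], d$measure))
  }

  labels <- sort(unique(sess))
  if (length(labels) < 2L)
    stop("a study needs at least 2 sessions")
  if (!identical(labels, seq_along(labels))) {
    warning("session labels ", paste(labels, collapse = ","),
            " re-indexed to 1..", length(labels), " in label order")
    sess <- match(sess, labels)
  }
  T_ <- length(labels)

  measures <- if (is.null(measureLevels)) unique(long$measure) else measureLevels
  if (!all(long$measure %in% measures))
    stop("measureLevels does not cover all measures present")
  subjects <- sort(unique(long$subject))

  cd <- S4Vectors::DataFrame(
    subject = rep(subjects, each = T_),
    session = rep(seq_len(T_), times = length(subjects))
  )
  rownames(cd) <- paste(cd$subject, cd$session, sep = ".")

  a <- matrix(NA_real_, nrow = length(measures), ncol = nrow(cd),
              dimnames = list(measures, rownames(cd)))
  col_idx <- (match(long$subject, subjects) - 1L) * T_ + sess
  a[cbind(match(long$measure, measures), col_idx)] <- long$value

  methods::new("SensitivityStudy",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(values = a), colData = cd))
}

# fast internal constructor for generator output: assay already laid out as
# measures x (subject-major, session-within) columns
.newStudy <- function(a, subjects, T_) {
  cd <- S4Vectors::DataFrame(
    subject = rep(subjects, each = T_),
    session = rep(seq_len(T_), times = length(subjects))
  )
  rownames(cd) <- paste(cd$subject, cd$session, sep = ".")
  colnames(a) <- rownames(cd)
  methods::new("SensitivityStudy",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(values = a), colData = cd))
}

#' Read a long-format study CSV
#'
#' Expects a UTF-8 CSV with header `subject,session,measure,value`, one
#' observation per row. Values and sessions must be numeric; duplicate
#' (subject, session, measure) keys are rejected.
#'
#' @param path path to the CSV file.
#' @param measureLevels optional explicit measure ordering.
#' @return a [SensitivityStudy-class].
#' @seealso [writeStudyCSV()]
#' @export
readStudyCSV <- function(path, measureLevels = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("subject", "session", "measure", "value")
  missing_col <- setdiff(required, colnames(raw))
  if (length(missing_col))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_col, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in row %d of %s",
                 raw$value[bad[1L]], bad[1L], path))
  sess <- suppressWarnings(as.numeric(raw$session))
  bad <- which(is.na(sess))
  if (length(bad))
    stop(sprintf("non-numeric session '%s' in row %d of %s",
                 raw$session[bad[1L]], bad[1L], path))
  SensitivityStudy(
    data.frame(subject = raw$subject, session = sess,
               measure = raw$measure, value = val,
               stringsAsFactors = FALSE),
    measureLevels = measureLevels
  )
}

#' Write a study back to long-format CSV
#'
#' Emits only observed (non-`NA`) cells, ordered by subject, session and
#' measure, so `readStudyCSV(writeStudyCSV(x, f))` reproduces the same
#' observations. Output is deterministic: identical objects give
#' byte-identical files.
#'
#' @param x a [SensitivityStudy-class].
#' @param path output path.
#' @param assay assay to write (index or name); defaults to the first.
#' @return `path`, invisibly.
#' @export
writeStudyCSV <- function(x, path, assay = 1L) {
  long <- asLongDataFrame(x, assay = assay)
  long <- long[order(long$subject, long$session, match(long$measure, measureNames(x))), ]
  long$value <- sprintf("%.17g", long$value)  # lossless double round-trip
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname zsens-generics
#' @export
setMethod("measureNames", "SensitivityStudy", function(x) rownames(x))

#' @rdname zsens-generics
#' @export
setMethod("subjectIDs", "SensitivityStudy", function(x)
  unique(SummarizedExperiment::colData(x)$subject))

#' @rdname zsens-generics
#' @export
setMethod("nSessions", "SensitivityStudy", function(x)
  max(SummarizedExperiment::colData(x)$session))

#' @rdname zsens-generics
#' @export
setMethod("isBalanced", "SensitivityStudy", function(x)
  !anyNA(SummarizedExperiment::assay(x, 1L)))

#' @rdname zsens-generics
#' @export
setMethod("isStandardized", "SensitivityStudy", function(x)
  isTRUE(S4Vectors::metadata(x)$standardized))

#' Complete-case filtering
#'
#' Retains only subjects with an observed value for every (session, measure)
#' combination, mirroring the complete-case rule used for within-subject
#' designs; no imputation is attempted. The number of dropped subjects is
#' reported via `message()`.
#'
#' @param x a [SensitivityStudy-class].
#' @return a balanced `SensitivityStudy`. Errors if no subject is complete.
#' @rdname zsens-generics
#' @export
setMethod("filterCompleteCases", "SensitivityStudy", function(x) {
  cd <- SummarizedExperiment::colData(x)
  a <- SummarizedExperiment::assay(x, 1L)
  incomplete <- unique(cd$subject[colSums(is.na(a)) > 0L])
  if (length(incomplete) == 0L) return(x)
  keep <- !(cd$subject %in% incomplete)
  if (!any(keep))
    stop("empty design: no subject has complete data for every ",
         "(session, measure) combination")
  message(sprintf("filterCompleteCases: dropped %d of %d subjects with incomplete data",
                  length(incomplete), length(unique(cd$subject))))
  x[, keep]
})

#' Wide subjects-by-sessions matrix for one measure
#'
#' @param x a balanced [SensitivityStudy-class].
#' @param measure measure identifier (rowname).
#' @param assay assay index or name; defaults to the first (z-scores on a
#'   standardized study, native values otherwise).
#' @return numeric matrix, rows ordered by subject identifier, columns by
#'   session index.
#' @rdname zsens-generics
#' @export
setMethod("measureMatrix", "SensitivityStudy", function(x, measure, assay = 1L) {
  if (!measure %in% rownames(x))
    stop("unknown measure: ", measure)
  cd <- SummarizedExperiment::colData(x)
  v <- SummarizedExperiment::assay(x, assay)[measure, ]
  subjects <- subjectIDs(x)
  T_ <- nSessions(x)
  m <- matrix(NA_real_, nrow = length(subjects), ncol = T_,
              dimnames = list(subjects, seq_len(T_)))
  m[cbind(match(cd$subject, subjects), cd$session)] <- v
  m
})

#' @rdname zsens-generics
#' @export
setMethod("studyCube", "SensitivityStudy", function(x, assay = 1L) {
  cd <- SummarizedExperiment::colData(x)
  subjects <- subjectIDs(x)
  T_ <- nSessions(x)
  a <- SummarizedExperiment::assay(x, assay)
  cube <- array(NA_real_,
                dim = c(length(subjects), T_, nrow(x)),
                dimnames = list(subjects, seq_len(T_), rownames(x)))
  si <- match(cd$subject, subjects)
  for (m in seq_len(nrow(x)))
    cube[cbind(si, cd$session, m)] <- a[m, ]
  cube
})

#' @rdname zsens-generics
#' @export
setMethod("asLongDataFrame", "SensitivityStudy", function(x, assay = 1L) {
  cd <- SummarizedExperiment::colData(x)
  a <- SummarizedExperiment::assay(x, assay)
  long <- data.frame(
    subject = rep(cd$subject, each = nrow(x)),
    session = rep(cd$session, each = nrow(x)),
    measure = rep(rownames(x), times = ncol(x)),
    value   = as.vector(a),
    stringsAsFactors = FALSE
  )
  long[!is.na(long$value), , drop = FALSE]
})
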