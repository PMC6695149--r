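#' Pooled z-score standardization of every measure
#'
#' For each measure, all `n_subjects x n_sessions` observations are pooled —
#' deliberately ignoring the repeated-measures structure — to obtain a grand
#' mean and grand SD, and every value is replaced by `z = (X - mean) / sd`.
#' This places all measures on a common unitless scale so their responses to
#' the study manipulation can be compared directly. After standardization
#' each measure has mean 0 and SD 1 (to floating-point precision).
#'
#' The grand SD uses the sample (`n-1`) denominator by default. The choice
#' is immaterial for every F, t and p statistic downstream (they are
#' invariant under positive affine rescaling); it only scales the z-score
#' magnitudes by `sqrt(n/(n-1))`.
#'
#' @param x a balanced [SensitivityStudy-class] (run [filterCompleteCases()]
#'   first if needed).
#' @param sdDenominator `"n-1"` (sample SD, default) or `"n"` (population
#'   SD).
#' @return a `SensitivityStudy` whose first assay `"z"` holds the z-scores
#'   (the original `"values"` assay is retained second); per-measure grand
#'   means/SDs are recorded and available via [standardization()].
#'   A measure with zero pooled variance raises an error naming it.
#' @examples
#' z <- standardizeMeasures(simulateStressStudy(seed = 1))
#' standardization(z)
#' @rdname zsens-generics
#' @export
setMethod("standardizeMeasures", "SensitivityStudy",
          function(x, sdDenominator = c("n-1", "n")) {
  sdDenominator <- match.arg(sdDenominator)
  if (!isBalanced(x))
    stop("standardization requires a balanced study; ",
         "apply filterCompleteCases() first")
  a <- SummarizedExperiment::assay(x, "values")
  n <- ncol(a)
  gm <- rowMeans(a)
  centered <- a - gm
  gsd <- sqrt(rowSums(centered^2) /
                (if (sdDenominator == "n-1") n - 1L else n))
  degenerate <- which(gsd <= .Machine$double.eps * 100)
  if (length(degenerate))
    stop("degenerate measure with zero pooled variance: ",
         paste(rownames(a)[degenerate], collapse = ", "))
  z <- centered / gsd

  out <- x
  SummarizedExperiment::assays(out) <- list(
    z = z, values = SummarizedExperiment::assay(x, "values"))
  SummarizedExperiment::rowData(out)$grand_mean <- gm
  SummarizedExperiment::rowData(out)$grand_sd <- gsd
  SummarizedExperiment::rowData(out)$n_pooled <- n
  S4Vectors::metadata(out)$standardized <- TRUE
  S4Vectors::metadata(out)$sd_denominator <- sdDenominator
  out
})

#' Standardization records
#'
#' @param x a standardized [SensitivityStudy-class].
#' @return data.frame with one row per measure: `measure`, `grand_mean`,
#'   `grand_sd`, `n_pooled`.
#' @rdname zsens-generics
#' @export
setMethod("standardization", "SensitivityStudy", function(x) {
  if (!isStandardized(x))
    stop("study has not been standardized; run standardizeMeasures()")
  rd <- SummarizedExperiment::rowData(x)
  data.frame(measure = rownames(x),
             grand_mean = rd$grand_mean,
             grand_sd = rd$grand_sd,
             n_pooled = rd$n_pooled,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Quality-control check: standardization must not change inference
#'
#' Re-applies the repeated-measures layout to the standardized data and runs
#' the per-measure one-way within-subject ANOVA on both the raw and the
#' z-scored values. Because z-scoring is a positive affine transform, the F
#' and p values must be identical up to floating-point round-off; the check
#' also confirms each measure's z-scores have mean 0 and SD 1. A failure
#' indicates data corruption between the two analysis stages.
#'
#' @param raw the original balanced [SensitivityStudy-class].
#' @param z its standardized counterpart from [standardizeMeasures()].
#' @param alpha significance level recorded alongside (does not affect the
#'   equality check).
#' @param tolerance maximum allowed |F_raw - F_z|, |p_raw - p_z|, |mean(z)|
#'   and |sd(z) - 1|; default `1e-9`, i.e. "identical" up to round-off.
#' @return data.frame, one row per measure: `measure`, `F_raw`, `p_raw`,
#'   `F_z`, `p_z`, `max_abs_F_diff`, `max_abs_p_diff`, `z_mean`, `z_sd`,
#'   `passed`.
#' @export
qcEquivalence <- function(raw, z, alpha = 0.05, tolerance = 1e-9) {
  if (!identical(rownames(raw), rownames(z)) ||
      !identical(subjectIDs(raw), subjectIDs(z)) ||
      nSessions(raw) != nSessions(z))
    stop("raw and standardized studies do not share the same ",
         "subjects/sessions/measures")
  if (!isStandardized(z))
    stop("'z' must be a standardized study (see standardizeMeasures)")
  n_den <- if (identical(S4Vectors::metadata(z)$sd_denominator, "n"))
    0L else 1L
  rows <- lapply(measureNames(raw), function(m) {
    ar <- rmAnovaOneway(measureMatrix(raw, m, assay = "values"), alpha = alpha)
    az <- rmAnovaOneway(measureMatrix(z, m, assay = "z"), alpha = alpha)
    zv <- SummarizedExperiment::assay(z, "z")[m, ]
    # treat a shared degenerate F (Inf vs Inf) as equal
    fd <- if (identical(ar$F, az$F)) 0 else abs(ar$F - az$F)
    pd <- abs(ar$p_uncorrected - az$p_uncorrected)
    zm <- mean(zv)
    zs <- sqrt(sum((zv - zm)^2) / (length(zv) - n_den))
    data.frame(measure = m,
               F_raw = ar$F, p_raw = ar$p_uncorrected,
               F_z = az$F, p_z = az$p_uncorrected,
               max_abs_F_diff = fd, max_abs_p_diff = pd,
               z_mean = zm, z_sd = zs,
               passed = fd <= tolerance && pd <= tolerance &&
                 abs(zm) <= tolerance && abs(zs - 1) <= tolerance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
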