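#' Standardized magnitude of change between two sessions
#'
#' For each measure, the absolute difference between the mean z-score at
#' two sessions: `|mean z(to) - mean z(from)|`. Because all measures are on
#' the common z scale, these magnitudes are directly comparable across
#' measures with wildly different native units — the core purpose of the
#' standardization step.
#'
#' @param z a standardized [SensitivityStudy-class].
#' @param from,to session indices (defaults 1 and 2: baseline vs first
#'   stress session).
#' @return named numeric vector, one non-negative entry per measure.
#' @export
magnitudeOfChange <- function(z, from = 1L, to = 2L) {
  if (!isStandardized(z))
    stop("magnitudeOfChange expects a standardized study")
  T_ <- nSessions(z)
  for (s in c(from, to))
    if (!(s %in% seq_len(T_)))
      stop("invalid session index: ", s, " (study has sessions 1..", T_, ")")
  cd <- SummarizedExperiment::colData(z)
  a <- SummarizedExperiment::assay(z, "z")
  abs(rowMeans(a[, cd$session == to, drop = FALSE]) -
        rowMeans(a[, cd$session == from, drop = FALSE]))
}

#' Per-measure sensitivity summary
#'
#' Collates, for every measure, the one-way within-subject ANOVA across
#' sessions, the polynomial trend tests and the LSD pairwise comparisons
#' into one summary row: the evidence classes used to judge which measures
#' respond to the study manipulation. Significance counts are computed at
#' `alpha` for all measures regardless of whether the omnibus one-way test
#' was itself significant. One-way significance is judged on the
#' Greenhouse-Geisser corrected p-value.
#'
#' @param oneway data.frame of [rmAnovaOneway()] rows with a `measure`
#'   column (one row per measure).
#' @param trends data.frame of [trendTable()] rows with a `measure` column.
#' @param pairwise data.frame of [lsdPairwise()] rows with a `measure`
#'   column.
#' @param z the standardized [SensitivityStudy-class] the results came
#'   from (used for the |delta z| change magnitudes).
#' @param alpha significance level for all counts (default 0.05).
#' @param deltaPairs list of `c(from, to)` session pairs for which the
#'   standardized change magnitude is reported. Default `(1,2)` and
#'   `(1,3)`: baseline against each stress session. Baseline-vs-recovery is
#'   deliberately not a default — a return toward baseline is expected
#'   there, so it carries no extra information about sensitivity.
#' @param directions optional named vector (`+1`/`-1`) giving each
#'   measure's expected direction of change under the manipulation;
#'   metadata for report grouping only, never used in any statistic.
#' @return data.frame with one row per measure: `oneway_F`, `oneway_p`
#'   (GG-corrected), `oneway_p_uncorrected`, `oneway_significant`, one
#'   `p_<trend>` column per trend degree, one `p_<a>_<b>` column per
#'   session pair, `n_sig_contrasts`, `n_sig_pairwise`, one
#'   `delta_z_<a>_<b>` column per requested pair, `max_delta_z`,
#'   `expected_direction`.
#' @seealso [analyzeSensitivity()] for the one-call version,
#'   [rankMeasures()] for the ranking.
#' @export
summarizeSensitivity <- function(oneway, trends, pairwise, z, alpha = 0.05,
                                 deltaPairs = list(c(1L, 2L), c(1L, 3L)),
                                 directions = NULL) {
  measures <- measureNames(z)
  for (nm in c("oneway", "trends", "pairwise")) {
    d <- get(nm)
    if (!"measure" %in% colnames(d))
      stop("'", nm, "' must carry a 'measure' column")
    if (!setequal(unique(d$measure), measures))
      stop("consistency error: '", nm, "' does not cover the same measures ",
           "as the study")
  }
  dz <- lapply(deltaPairs, function(pr)
    magnitudeOfChange(z, from = pr[1L], to = pr[2L]))
  names(dz) <- vapply(deltaPairs, function(pr)
    sprintf("delta_z_%d_%d", pr[1L], pr[2L]), character(1L))

  rows <- lapply(measures, function(m) {
    ow <- oneway[oneway$measure == m, , drop = FALSE]
    tr <- trends[trends$measure == m, , drop = FALSE]
    pw <- pairwise[pairwise$measure == m, , drop = FALSE]
    row <- data.frame(measure = m,
                      oneway_F = ow$F,
                      oneway_p = ow$p_gg,
                      oneway_p_uncorrected = ow$p_uncorrected,
                      oneway_significant = ow$p_gg < alpha,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tr)))
      row[[paste0("p_", tr$trend[i])]] <- tr$p[i]
    for (i in seq_len(nrow(pw)))
      row[[sprintf("p_%d_%d", pw$session_a[i], pw$session_b[i])]] <- pw$p[i]
    row$n_sig_contrasts <- sum(tr$p < alpha)
    row$n_sig_pairwise <- sum(pw$p < alpha)
    for (nm in names(dz)) row[[nm]] <- unname(dz[[nm]][m])
    row$max_delta_z <- max(vapply(dz, function(v) v[[m]], numeric(1L)))
    row$expected_direction <- if (is.null(directions)) 0L else
      as.integer(directions[[m]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run all per-measure follow-up analyses in one call
#'
#' Convenience wrapper: per-measure one-way RM-ANOVA across sessions,
#' polynomial trend tests, LSD pairwise comparisons and the sensitivity
#' summary, all computed from a standardized study.
#'
#' @param z a balanced, standardized [SensitivityStudy-class].
#' @param alpha significance level.
#' @param errorTerm `"separate"` (default) or `"pooled"`; see [testTrend()].
#' @inheritParams summarizeSensitivity
#' @return list with elements `oneway`, `trends`, `pairwise` (per-measure
#'   stacked data.frames) and `summary` (the [summarizeSensitivity()]
#'   table).
#' @export
analyzeSensitivity <- function(z, alpha = 0.05,
                               errorTerm = c("separate", "pooled"),
                               deltaPairs = list(c(1L, 2L), c(1L, 3L)),
                               directions = NULL) {
  errorTerm <- match.arg(errorTerm)
  if (!isStandardized(z))
    stop("analyzeSensitivity expects a standardized study")
  measures <- measureNames(z)
  per <- lapply(measures, function(m) {
    mat <- measureMatrix(z, m, assay = "z")
    list(
      oneway = cbind(measure = m, rmAnovaOneway(mat, alpha = alpha)),
      trends = cbind(measure = m,
                     trendTable(mat, alpha = alpha, errorTerm = errorTerm)),
      pairwise = cbind(measure = m,
                       lsdPairwise(mat, alpha = alpha, errorTerm = errorTerm))
    )
  })
  oneway <- do.call(rbind, lapply(per, `[[`, "oneway"))
  trends <- do.call(rbind, lapply(per, `[[`, "trends"))
  pairwise <- do.call(rbind, lapply(per, `[[`, "pairwise"))
  summary <- summarizeSensitivity(oneway, trends, pairwise, z, alpha = alpha,
                                  deltaPairs = deltaPairs,
                                  directions = directions)
  list(oneway = oneway, trends = trends, pairwise = pairwise,
       summary = summary)
}

#' Rank measures by sensitivity
#'
#' Orders measures by a descending lexicographic key built from the three
#' evidence classes of the sensitivity summary: (1) omnibus one-way
#' significance, (2) total number of significant follow-up tests
#' (`n_sig_contrasts + n_sig_pairwise`), (3) the largest standardized
#' change magnitude over the designated stress pairs. The key is recorded
#' in the output so the ordering is auditable; measures with identical keys
#' share a rank. The key is one explicit operationalization of a judgment
#' that is otherwise qualitative — it weighs the same evidence an analyst
#' would, in a fixed order.
#'
#' @param summaries output of [summarizeSensitivity()] (or the `summary`
#'   element of [analyzeSensitivity()]).
#' @return data.frame ordered best-first: `measure`, `rank`,
#'   `oneway_significant`, `n_sig_total`, `max_delta_z`.
#' @export
rankMeasures <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no measures to rank")
  key <- data.frame(
    measure = summaries$measure,
    oneway_significant = summaries$oneway_significant,
    n_sig_total = summaries$n_sig_contrasts + summaries$n_sig_pairwise,
    max_delta_z = summaries$max_delta_z,
    stringsAsFactors = FALSE
  )
  ord <- order(-key$oneway_significant, -key$n_sig_total, -key$max_delta_z,
               key$measure)
  key <- key[ord, , drop = FALSE]
  tuple <- paste(key$oneway_significant, key$n_sig_total,
                 signif(key$max_delta_z, 12L))
  # ties share the rank of the first (best) member of their group
  grp_first <- which(!duplicated(tuple))
  key$rank <- grp_first[match(tuple, tuple[grp_first])]
  rownames(key) <- NULL
  key[, c("measure", "rank", "oneway_significant", "n_sig_total",
          "max_delta_z")]
}
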