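#' Orthogonal polynomial contrast coefficients
#'
#' Integer-scaled orthogonal polynomial contrasts of degrees `1..k-1` for
#' `k` equally spaced levels (sessions). Rows sum to zero and are mutually
#' orthogonal; the classical tables are recovered, e.g. for `k = 4`:
#' linear `(-3, -1, 1, 3)`, quadratic `(1, -1, -1, 1)`,
#' cubic `(-1, 3, -3, 1)`. Signs follow the convention that the linear
#' contrast increases with level.
#'
#' @param k number of levels, `k >= 2`.
#' @return `(k-1) x k` integer matrix; rows named `linear`, `quadratic`,
#'   `cubic`, then `degree4`, `degree5`, ...
#' @examples
#' polyContrasts(4)
#' @export
polyContrasts <- function(k) {
  if (k < 2L) stop("design error: need at least 2 levels")
  pc <- stats::contr.poly(k)   # orthonormal columns on equally spaced points
  rows <- t(apply(pc, 2L, .smallestIntegerVector))
  deg_names <- c("linear", "quadratic", "cubic",
                 if (k > 4L) paste0("degree", 4:(k - 1L)))
  rownames(rows) <- deg_names[seq_len(k - 1L)]
  colnames(rows) <- NULL
  storage.mode(rows) <- "integer"
  rows
}

# rescale an orthonormal contrast column to its smallest-integer form
.smallestIntegerVector <- function(v) {
  u <- v / min(abs(v[abs(v) > 1e-10]))
  for (mult in 1:1000) {
    w <- mult * u
    if (max(abs(w - round(w))) < 1e-6) return(round(w))
  }
  stop("could not reduce contrast to integer coefficients")
}

#' Test one trend contrast across sessions
#'
#' Forms the per-subject contrast score `L_i = sum_j c_j x_ij` and tests its
#' mean against zero. With the default separate error term this is a
#' one-sample t-test on the `L_i` with `df = n - 1`, so each contrast uses
#' its own error variance and is robust to sphericity violation. The pooled
#' alternative divides by the omnibus RM-ANOVA error mean square
#' (`df = (n-1)(k-1)`), which assumes sphericity.
#'
#' @param values `subjects x levels` matrix, balanced.
#' @param contrast numeric coefficient vector of length `ncol(values)`,
#'   summing to zero.
#' @param alpha two-sided significance level.
#' @param errorTerm `"separate"` (default) or `"pooled"`.
#' @param trend optional label stored in the result.
#' @return one-row data.frame: `trend`, `estimate` (mean contrast score),
#'   `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
testTrend <- function(values, contrast, alpha = 0.05,
                      errorTerm = c("separate", "pooled"), trend = NA_character_) {
  errorTerm <- match.arg(errorTerm)
  values <- as.matrix(values)
  if (length(contrast) != ncol(values))
    stop("contrast length must equal the number of levels")
  if (abs(sum(contrast)) > 1e-8 * max(abs(contrast)))
    stop("contrast coefficients must sum to zero")
  n <- nrow(values)
  L <- as.vector(values %*% contrast)
  est <- mean(L)
  if (errorTerm == "separate") {
    se <- stats::sd(L) / sqrt(n)
    df <- n - 1
  } else {
    k <- ncol(values)
    ms_err <- rmAnovaOneway(values)$ms_error
    se <- sqrt(ms_err * sum(contrast^2) / n)
    df <- (n - 1) * (k - 1)
  }
  .pairedT(trend_label = trend, est = est, se = se, df = df, alpha = alpha)
}

# shared t-vs-zero machinery with degenerate (zero SE) handling
.pairedT <- function(trend_label, est, se, df, alpha) {
  tiny <- .Machine$double.eps * 100
  if (se <= tiny * max(1, abs(est))) {
    if (abs(est) <= tiny) {
      tval <- 0; p <- 1; degen <- FALSE
    } else {
      tval <- sign(est) * Inf; p <- 0; degen <- TRUE
    }
  } else {
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df)
    degen <- FALSE
  }
  .fastRow(list(trend = trend_label, estimate = est, t = tval, df = df,
                p = p, significant = p < alpha, degenerate = degen))
}

#' All polynomial trend tests for one measure
#'
#' Runs [testTrend()] for every orthogonal polynomial contrast of degree
#' `1..k-1` from [polyContrasts()].
#'
#' @inheritParams testTrend
#' @return data.frame with one row per trend degree.
#' @export
trendTable <- function(values, alpha = 0.05,
                       errorTerm = c("separate", "pooled")) {
  errorTerm <- match.arg(errorTerm)
  cm <- polyContrasts(ncol(as.matrix(values)))
  out <- do.call(rbind, lapply(rownames(cm), function(tr)
    testTrend(values, cm[tr, ], alpha = alpha, errorTerm = errorTerm,
              trend = tr)))
  rownames(out) <- NULL
  out
}

#' Fisher's LSD pairwise session comparisons
#'
#' Unadjusted paired comparisons for every unordered session pair `(a, b)`:
#' paired differences `d_i = x_ia - x_ib`, `t = mean(d) / (sd(d)/sqrt(n))`
#' with `df = n - 1`, two-sided p. No multiplicity adjustment is applied —
#' the unprotected per-comparison error rate is deliberate when the goal is
#' counting which measures respond, not confirmatory hypothesis testing.
#' The pooled variant uses the omnibus RM-ANOVA error mean square
#' (`t = diff / sqrt(2 MS_err / n)`, `df = (n-1)(k-1)`).
#'
#' @inheritParams testTrend
#' @return data.frame with `k(k-1)/2` rows: `session_a`, `session_b`,
#'   `mean_diff`, `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
lsdPairwise <- function(values, alpha = 0.05,
                        errorTerm = c("separate", "pooled")) {
  errorTerm <- match.arg(errorTerm)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L) stop("design error: need at least 2 subjects")
  pairs <- utils::combn(k, 2L)
  ms_err <- if (errorTerm == "pooled") rmAnovaOneway(values)$ms_error else NA
  rows <- lapply(seq_len(ncol(pairs)), function(p_) {
    a <- pairs[1L, p_]; b <- pairs[2L, p_]
    d <- values[, a] - values[, b]
    est <- mean(d)
    if (errorTerm == "separate") {
      se <- stats::sd(d) / sqrt(n); df <- n - 1
    } else {
      se <- sqrt(2 * ms_err / n); df <- (n - 1) * (k - 1)
    }
    r <- .pairedT(NA_character_, est, se, df, alpha)
    .fastRow(list(session_a = a, session_b = b, mean_diff = r$estimate,
                  t = r$t, df = r$df, p = r$p, significant = r$significant,
                  degenerate = r$degenerate))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
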