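#' Greenhouse-Geisser epsilon from a level covariance matrix
#'
#' Box's sphericity correction factor for a within-subject factor with `k`
#' levels, estimated from the `k x k` covariance matrix of the level
#' scores. Computed via the eigenvalues of the double-centered covariance:
#' `epsilon = (sum lambda)^2 / ((k - 1) * sum lambda^2)`, clamped to the
#' admissible interval `[1/(k-1), 1]`. Under compound symmetry (and always
#' for `k = 2`) epsilon equals 1.
#'
#' @param cov symmetric `k x k` covariance matrix, `k >= 2`.
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
ggEpsilon <- function(cov) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("'cov' must be a square matrix")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("'cov' must be symmetric")
  k <- nrow(cov)
  if (k < 2L) stop("need at least 2 levels")
  ctr <- diag(k) - 1 / k
  d <- ctr %*% cov %*% ctr
  lambda <- eigen(d, symmetric = TRUE, only.values = TRUE)$values
  num <- sum(lambda)^2
  den <- (k - 1) * sum(lambda^2)
  if (den <= .Machine$double.eps * max(1, num)) return(1)
  min(1, max(1 / (k - 1), num / den))
}

# epsilon on an effect-specific orthonormal contrast basis C ((q x p) rows):
# (tr CSC')^2 / (q tr (CSC')^2). Used for the interaction term of the
# two-way design, where no single level covariance exists.
.ggEpsilonContrast <- function(sigma, C) {
  A <- C %*% sigma %*% t(C)
  q <- nrow(C)
  num <- sum(diag(A))^2
  den <- q * sum(A * A)
  if (den <= .Machine$double.eps * max(1, num)) return(1)
  min(1, max(1 / q, num / den))
}

# orthonormal basis of the contrast space (rows orthogonal to the constant)
.orthonormalContrasts <- function(k) {
  h <- stats::contr.helmert(k)
  q <- qr.Q(qr(h))
  t(q)
}

.anovaRow <- function(effect, ss_e, ss_err, df_e, df_err, eps) {
  ms_e <- ss_e / df_e
  ms_err <- ss_err / df_err
  tiny <- .Machine$double.eps * 100
  degenerate <- FALSE
  if (ms_err <= tiny * max(1, ms_e)) {
    if (ms_e <= tiny) {
      f <- 0; p <- 1; p_gg <- 1
    } else {
      f <- Inf; p <- 0; p_gg <- 0
      degenerate <- TRUE
      warning("degenerate design for effect '", effect,
              "': zero error variance; F reported as Inf")
    }
  } else {
    f <- ms_e / ms_err
    p <- stats::pf(f, df_e, df_err, lower.tail = FALSE)
    p_gg <- stats::pf(f, eps * df_e, eps * df_err, lower.tail = FALSE)
  }
  .fastRow(list(effect = effect,
                ss_effect = ss_e, ss_error = ss_err,
                df_effect = df_e, df_error = df_err,
                ms_effect = ms_e, ms_error = ms_err,
                F = f, p_uncorrected = p,
                epsilon_gg = eps,
                df_effect_gg = eps * df_e, df_error_gg = eps * df_err,
                p_gg = p_gg, degenerate = degenerate))
}

# one-row data.frame without the overhead of data.frame()
.fastRow <- function(x) {
  structure(x, class = "data.frame", row.names = 1L)
}

#' One-way within-subject (repeated-measures) ANOVA
#'
#' Standard fully within-subject decomposition
#' `SS_total = SS_subjects + SS_level + SS_error`, with
#' `F = MS_level / MS_error` on `(k-1, (k-1)(n-1))` degrees of freedom, plus
#' the Greenhouse-Geisser epsilon estimated from the level covariance matrix
#' and the sphericity-corrected p-value. Reported F and p are invariant
#' under any positive affine transform of the data (the property the
#' z-scoring QC gate relies on).
#'
#' A design in which the error mean square is exactly zero is reported
#' rather than raised: `F = Inf, p = 0` with `degenerate = TRUE` (or
#' `F = 0, p = 1` when the level effect is zero too), so batch runs over
#' many measures do not abort.
#'
#' @param values numeric `subjects x levels` matrix, no missing cells,
#'   at least 2 subjects and 2 levels.
#' @param alpha significance level recorded in the result.
#' @param effect label for the within factor (default `"time"`).
#' @return one-row data.frame: `effect`, `ss_effect`, `ss_error`,
#'   `df_effect`, `df_error`, `ms_effect`, `ms_error`, `F`,
#'   `p_uncorrected`, `epsilon_gg`, `df_effect_gg`, `df_error_gg`, `p_gg`,
#'   `degenerate`, plus `ss_subjects` and `alpha`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 5)  # 5 subjects x 4 sessions
#' rmAnovaOneway(m)
#' @export
rmAnovaOneway <- function(values, alpha = 0.05, effect = "time") {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("design error: need at least 2 subjects and 2 levels")
  if (anyNA(values))
    stop("design error: missing cells are not supported")
  g <- mean(values)
  subj <- rowMeans(values)
  lvl <- colMeans(values)
  ss_total <- sum((values - g)^2)
  ss_subj <- k * sum((subj - g)^2)
  ss_lvl <- n * sum((lvl - g)^2)
  ss_err <- ss_total - ss_subj - ss_lvl
  ss_err <- max(ss_err, 0)  # guard round-off
  eps <- if (k == 2L) 1 else ggEpsilon(stats::cov(values))
  out <- .anovaRow(effect, ss_lvl, ss_err, k - 1, (k - 1) * (n - 1), eps)
  out$ss_subjects <- ss_subj
  out$alpha <- alpha
  out
}

#' Two-way fully within-subject (time x measure) ANOVA
#'
#' Decomposes a balanced `subjects x sessions x measures` data cube into
#' the two main effects and their interaction, each tested against its own
#' subject-by-effect error stratum: time against subject x time, measure
#' against subject x measure, and the interaction against
#' subject x time x measure. Each effect receives its own
#' Greenhouse-Geisser epsilon, estimated from the covariance of that
#' effect's contrast variables (the collapsed level covariance for the main
#' effects; a Kronecker-product orthonormal contrast basis for the
#' interaction), and a corrected p-value.
#'
#' Applied to z-standardized data, the measure main effect is analytically
#' null — every measure's marginal mean is exactly the grand mean 0 — so its
#' sum of squares is zero up to floating-point noise and `p = 1`. The
#' scientific signal of interest is the time x measure interaction:
#' differential responsiveness of the measures across sessions.
#'
#' @param x a balanced [SensitivityStudy-class] (its first assay is used)
#'   or a numeric 3-d array `subjects x sessions x measures`.
#' @param alpha significance level recorded in the result.
#' @param assay assay used when `x` is a `SensitivityStudy`.
#' @return data.frame with rows `time`, `measure`, `time:measure` and the
#'   same columns as [rmAnovaOneway()].
#' @examples
#' z <- standardizeMeasures(simulateStressStudy(seed = 1))
#' rmAnovaTwoWay(z)
#' @export
rmAnovaTwoWay <- function(x, alpha = 0.05, assay = 1L) {
  cube <- if (methods::is(x, "SensitivityStudy")) {
    if (!isBalanced(x)) stop("design error: study has missing cells")
    studyCube(x, assay = assay)
  } else x
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("'x' must be a SensitivityStudy or a 3-d array")
  if (anyNA(cube)) stop("design error: missing cells are not supported")
  n <- dim(cube)[1L]; J <- dim(cube)[2L]; M <- dim(cube)[3L]
  if (n < 2L || J < 2L || M < 2L)
    stop("design error: need >= 2 subjects, sessions and measures")

  g <- mean(cube)
  s_i <- apply(cube, 1L, mean)
  t_j <- apply(cube, 2L, mean)
  m_m <- apply(cube, 3L, mean)
  st <- apply(cube, c(1L, 2L), mean)   # n x J
  sm <- apply(cube, c(1L, 3L), mean)   # n x M
  tm <- apply(cube, c(2L, 3L), mean)   # J x M

  ss_T <- n * M * sum((t_j - g)^2)
  ss_M <- n * J * sum((m_m - g)^2)
  ss_ST <- M * sum((st - outer(s_i, t_j, "+") + g)^2)
  ss_SM <- J * sum((sm - outer(s_i, m_m, "+") + g)^2)
  ss_TM <- n * sum((tm - outer(t_j, m_m, "+") + g)^2)

  resid <- cube
  for (i in seq_len(n)) for (j in seq_len(J))
    resid[i, j, ] <- cube[i, j, ] - st[i, j] - sm[i, ] - tm[j, ] +
      s_i[i] + t_j[j] + m_m - g
  ss_STM <- sum(resid^2)

  eps_T <- if (J == 2L) 1 else ggEpsilon(stats::cov(st))
  eps_M <- if (M == 2L) 1 else ggEpsilon(stats::cov(sm))
  # interaction: covariance of the vectorized cells, measure index fastest
  flat <- matrix(aperm(cube, c(3L, 2L, 1L)), nrow = n, byrow = TRUE)
  C_int <- kronecker(.orthonormalContrasts(J), .orthonormalContrasts(M))
  eps_TM <- if (J == 2L && M == 2L) 1 else
    .ggEpsilonContrast(stats::cov(flat), C_int)

  out <- rbind(
    .anovaRow("time", ss_T, ss_ST, J - 1, (n - 1) * (J - 1), eps_T),
    .anovaRow("measure", ss_M, ss_SM, M - 1, (n - 1) * (M - 1), eps_M),
    .anovaRow("time:measure", ss_TM, ss_STM,
              (J - 1) * (M - 1), (n - 1) * (J - 1) * (M - 1), eps_TM)
  )
  out$alpha <- alpha
  rownames(out) <- NULL
  out
}
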