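#' Default measure profiles for a multi-metric stress study
#'
#' Eighteen measure profiles emulating a four-session graded-stress study
#' design: four Psychomotor Vigilance Task (PVT) metrics, the seven Profile
#' of Mood States (POMS) sub-scales, three Match-to-Sample (MTS) short-term
#' memory metrics, and four salivary hormones (cortisol, testosterone,
#' BDNF, NPY). Baseline means and SDs are in each measure's native units
#' and span four orders of magnitude — precisely the heterogeneity the
#' z-score method exists to bridge.
#'
#' Each profile carries an inverted-U effect trajectory in baseline-SD
#' units: `(0, d, d, r*d)` across sessions baseline, stress 1, stress 2,
#' recovery — change under stress, near-return to baseline at recovery.
#' The per-measure effect size `d` is assigned by sensitivity class
#' (`strong` for the mood sub-scales and cortisol, `moderate` for the
#' response-timing metrics, testosterone and NPY, `weak` for the accuracy
#' counts, `none` for BDNF), and `direction` encodes whether the measure is
#' expected to rise or fall under stress.
#'
#' @param effectSizes named numeric vector of per-class effect sizes in
#'   baseline-SD units.
#' @param recoveryFraction fraction of `d` remaining at the recovery
#'   session (default 0.25: near-return to baseline).
#' @return data.frame with columns `measure`, `test`, `class`,
#'   `baseline_mean`, `baseline_sd`, `direction`, `delta_1..delta_4`.
#' @examples
#' defaultProfiles()
#' @export
defaultProfiles <- function(effectSizes = c(strong = 0.9, moderate = 0.45,
                                            weak = 0.15, none = 0),
                            recoveryFraction = 0.25) {
  stopifnot(all(c("strong", "moderate", "weak", "none") %in%
                  names(effectSizes)))
  p <- data.frame(
    measure = c("PVT_Premature", "PVT_TimeOut", "PVT_Correct", "PVT_RT",
                "POMS_TMD", "POMS_TensionAnxiety", "POMS_DepressionDejection",
                "POMS_AngerHostility", "POMS_VigorActivity",
                "POMS_FatigueInertia", "POMS_ConfusionBewilderment",
                "MTS_Correct", "MTS_TimeOut", "MTS_RT",
                "Cortisol", "Testosterone", "BDNF", "NPY"),
    test = c(rep("PVT", 4L), rep("POMS", 7L), rep("MTS", 3L),
             rep("Hormone", 4L)),
    class = c("weak", "weak", "weak", "moderate",
              rep("strong", 7L),
              "weak", "moderate", "moderate",
              "strong", "moderate", "none", "moderate"),
    baseline_mean = c(10.7, 11.5, 114.6, 0.30,
                      20.0, 6.6, 3.7, 7.2, 10.7, 7.1, 6.2,
                      15.4, 0.09, 4.5,
                      0.2, 56.7, 11.6, 84.5),
    baseline_sd = c(9.5, 20.6, 22.4, 0.03,
                    17.8, 3.8, 4.4, 6.3, 5.7, 5.0, 3.1,
                    3.4, 0.3, 1.6,
                    0.1, 25.0, 24.8, 29.4),
    direction = c(1L, 1L, -1L, 1L,
                  1L, 1L, 1L, 1L, -1L, 1L, 1L,
                  -1L, 1L, 1L,
                  1L, -1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  d <- unname(effectSizes[p$class])
  p$delta_1 <- 0
  p$delta_2 <- d
  p$delta_3 <- d
  p$delta_4 <- recoveryFraction * d
  p
}

#' Simulate a balanced multi-metric repeated-measures study
#'
#' Generates `X_ijm = mu_m + sd_m * (delta_jm * dir_m + b_im + e_ijm)` with
#' subject random intercepts `b_im ~ N(0, subjectSD^2)` (independent across
#' measures) and residuals `e_ijm ~ N(0, withinSD^2)`, so that within each
#' measure the sessions are compound-symmetric with between-session
#' correlation `subjectSD^2 / (subjectSD^2 + withinSD^2)` — sphericity
#' holds by construction. In the default variance-normalized mode
#' `subjectSD^2 + withinSD^2 = 1`, so `baseline_sd` is the total SD and the
#' injected `delta` values are effect sizes in total-SD units, directly
#' comparable across measures.
#'
#' Supplying a `withinSD` vector of length `n_sessions` gives
#' session-specific residual SDs — a sphericity-violating mode for
#' exercising the Greenhouse-Geisser machinery (variance normalization is
#' not enforced there). `family = "lognormal"` replaces the Gaussian
#' residual with a mean-zero, variance-matched shifted log-normal, for
#' robustness checks against hormone-like skew.
#'
#' @param profiles profile data.frame as from [defaultProfiles()]; columns
#'   `measure`, `baseline_mean`, `baseline_sd`, `direction`,
#'   `delta_1..delta_T`.
#' @param nSubjects number of subjects.
#' @param nSessions number of sessions `T`; the profile must carry a
#'   `delta_j` column for each.
#' @param subjectSD random-intercept SD (in baseline-SD units).
#' @param withinSD residual SD (scalar, or one value per session).
#' @param seed optional integer seed; identical seeds and configs give
#'   byte-identical studies.
#' @param family `"gaussian"` (default) or `"lognormal"` residuals.
#' @param varianceNormalized require `subjectSD^2 + withinSD^2 = 1`
#'   (default TRUE; ignored when `withinSD` is a vector).
#' @return a balanced [SensitivityStudy-class].
#' @examples
#' s <- simulateStudy(defaultProfiles(), nSubjects = 8, seed = 7)
#' @export
simulateStudy <- function(profiles = defaultProfiles(),
                          nSubjects = 34L, nSessions = 4L,
                          subjectSD = sqrt(0.5), withinSD = sqrt(0.5),
                          seed = NULL,
                          family = c("gaussian", "lognormal"),
                          varianceNormalized = TRUE) {
  family <- match.arg(family)
  delta_cols <- paste0("delta_", seq_len(nSessions))
  needed <- c("measure", "baseline_mean", "baseline_sd", "direction",
              delta_cols)
  if (!all(needed %in% colnames(profiles)))
    stop("config error: profiles must carry columns ",
         paste(setdiff(needed, colnames(profiles)), collapse = ", "))
  if (any(profiles$baseline_sd <= 0))
    stop("config error: baseline_sd must be > 0")
  if (subjectSD < 0 || any(withinSD <= 0))
    stop("config error: subjectSD must be >= 0 and withinSD > 0")
  if (!(length(withinSD) %in% c(1L, nSessions)))
    stop("config error: withinSD must be a scalar or one value per session")
  if (varianceNormalized && length(withinSD) == 1L &&
      abs(subjectSD^2 + withinSD^2 - 1) > 1e-8)
    stop("config error: variance-normalized mode requires ",
         "subjectSD^2 + withinSD^2 = 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- as.integer(nSubjects); T_ <- as.integer(nSessions)
  M <- nrow(profiles)
  wsd <- rep(withinSD, length.out = T_)
  subjects <- sprintf("S%0*d", nchar(as.character(n)), seq_len(n))

  a <- matrix(NA_real_, nrow = M, ncol = n * T_,
              dimnames = list(profiles$measure, NULL))
  for (m in seq_len(M)) {
    mu <- profiles$baseline_mean[m]
    s  <- profiles$baseline_sd[m]
    dir <- profiles$direction[m]
    delta <- as.numeric(profiles[m, delta_cols])
    b <- stats::rnorm(n, 0, subjectSD)
    e <- matrix(0, n, T_)
    for (j in seq_len(T_)) {
      e[, j] <- if (family == "gaussian") stats::rnorm(n, 0, wsd[j]) else
        .shiftedLognormal(n, wsd[j])
    }
    vals <- mu + s * (matrix(delta * dir, n, T_, byrow = TRUE) + b + e)
    a[m, ] <- as.vector(t(vals))   # subject-major, session within
  }
  .newStudy(a, subjects, T_)
}

# mean-zero, variance sd^2 shifted log-normal (fixed shape sdlog = 1)
.shiftedLognormal <- function(n, sd) {
  sdlog <- 1
  raw <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  mu <- exp(sdlog^2 / 2)
  v <- (exp(sdlog^2) - 1) * exp(sdlog^2)
  (raw - mu) / sqrt(v) * sd
}

#' The canonical end-to-end study fixture
#'
#' Convenience wrapper for the default study design: 34 subjects, 4
#' sessions, the 18 [defaultProfiles()] measures, compound-symmetric
#' Gaussian noise with an equal split of subject and residual variance.
#'
#' @param seed integer seed (default 1).
#' @return a balanced 34 x 4 x 18 [SensitivityStudy-class] (2448
#'   observations).
#' @examples
#' simulateStressStudy(seed = 1)
#' @export
simulateStressStudy <- function(seed = 1L) {
  simulateStudy(defaultProfiles(), nSubjects = 34L, nSessions = 4L,
                subjectSD = sqrt(0.5), withinSD = sqrt(0.5), seed = seed)
}
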