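test_that("magnitude of change is the absolute session-mean z difference", {
  # two subjects, two measures; built so session means are known exactly
  long <- make_long(c("a", "b"), 1:2, c("m1", "m2"),
                    values = c(1, 3, 2, 4, 2, 2, 4, 8))
  z <- standardizeMeasures(SensitivityStudy(long))
  a <- SummarizedExperiment::assay(z, "z")
  cd <- SummarizedExperiment::colData(z)
  expected <- abs(rowMeans(a[, cd$session == 2]) -
                    rowMeans(a[, cd$session == 1]))
  expect_equal(magnitudeOfChange(z, 1, 2), expected)
  expect_true(all(magnitudeOfChange(z, 1, 2) >= 0))
  expect_error(magnitudeOfChange(z, 1, 9), "invalid session")
  raw <- SensitivityStudy(long)
  expect_error(magnitudeOfChange(raw, 1, 2), "standardized")
})

test_that("injected effect magnitude is recovered from a large simulation", {
  d <- 0.6
  prof <- effect_profiles(d, per_group = 1L)
  z <- standardizeMeasures(simulateStudy(prof, nSubjects = 400, seed = 31))
  got <- magnitudeOfChange(z, 1, 2)[["m01"]]
  # session-mean difference has SE sqrt(2 * within_var / n) = 0.1 in SD
  # units; allow 3 SEs
  expect_lt(abs(got - d), 3 * sqrt(2 * 0.5 / 400) + 0.05)
})

test_that("sensitivity summary counts significances at alpha", {
  z <- standardizeMeasures(simulateStudy(defaultProfiles(), nSubjects = 10,
                                         seed = 32))
  res <- analyzeSensitivity(z)
  s <- res$summary
  expect_identical(nrow(s), 18L)
  expect_true(all(s$n_sig_contrasts >= 0 & s$n_sig_contrasts <= 3))
  expect_true(all(s$n_sig_pairwise >= 0 & s$n_sig_pairwise <= 6))
  for (m in s$measure) {
    expect_identical(s$n_sig_contrasts[s$measure == m],
                     sum(res$trends$p[res$trends$measure == m] < 0.05))
    expect_identical(s$n_sig_pairwise[s$measure == m],
                     sum(res$pairwise$p[res$pairwise$measure == m] < 0.05))
  }
  expect_true(all(s$delta_z_1_2 >= 0) && all(s$delta_z_1_3 >= 0))

  # a measure present in one input but not another is a consistency error
  bad <- res$oneway[res$oneway$measure != "Cortisol", ]
  expect_error(summarizeSensitivity(bad, res$trends, res$pairwise, z),
               "consistency error")
})

test_that("significance counts are monotone in alpha", {
  z <- standardizeMeasures(simulateStudy(defaultProfiles(), nSubjects = 12,
                                         seed = 33))
  alphas <- c(0.01, 0.05, 0.2)
  res <- lapply(alphas, function(a) analyzeSensitivity(z, alpha = a)$summary)
  for (i in 1:2) {
    expect_true(all(res[[i + 1]]$n_sig_contrasts >= res[[i]]$n_sig_contrasts))
    expect_true(all(res[[i + 1]]$n_sig_pairwise >= res[[i]]$n_sig_pairwise))
  }
})

test_that("ranking orders by the lexicographic evidence key", {
  base <- data.frame(
    measure = c("none", "all"),
    oneway_significant = c(FALSE, TRUE),
    n_sig_contrasts = c(0L, 3L), n_sig_pairwise = c(0L, 6L),
    max_delta_z = c(0.05, 0.9), stringsAsFactors = FALSE)
  rk <- rankMeasures(base)
  expect_identical(rk$measure, c("all", "none"))
  expect_identical(rk$rank, c(1L, 2L))

  # identical evidence -> shared rank; next distinct key skips ranks
  tied <- base[c(2, 2, 1), ]; tied$measure <- c("a", "b", "c")
  rk2 <- rankMeasures(tied)
  expect_identical(rk2$rank, c(1L, 1L, 3L))

  # ranking is invariant to input row order
  z <- standardizeMeasures(simulateStudy(defaultProfiles(), nSubjects = 10,
                                         seed = 34))
  s <- analyzeSensitivity(z)$summary
  r1 <- rankMeasures(s)
  r2 <- rankMeasures(s[sample(nrow(s)), ])
  expect_identical(r1, r2)
  expect_setequal(r1$measure, s$measure)
})

test_that("ranking recovers a graded effect-size ordering at large n", {
  prof <- effect_profiles(c(0, 0.3, 0.8), per_group = 2L)
  z <- standardizeMeasures(simulateStudy(prof, nSubjects = 200, seed = 35))
  rk <- rankMeasures(analyzeSensitivity(z)$summary)
  pos <- match(prof$measure, rk$measure)
  d <- prof$d
  expect_lt(median(pos[d == 0.8]), median(pos[d == 0.3]))
  expect_lt(median(pos[d == 0.3]), median(pos[d == 0]))
})
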