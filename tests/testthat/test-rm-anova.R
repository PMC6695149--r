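test_that("one-way RM-ANOVA matches brute-force and aov on a worked fixture", {
  mat <- rbind(s1 = c(1, 2, 3), s2 = c(2, 3, 5), s3 = c(0, 1, 2))
  r <- rmAnovaOneway(mat)
  o <- oracle_oneway(mat)
  expect_equal(r$ss_effect, o$ss_level, tolerance = 1e-12)
  expect_equal(r$ss_subjects, o$ss_subjects, tolerance = 1e-12)
  expect_equal(r$ss_error, o$ss_error, tolerance = 1e-12)
  expect_equal(r$F, o$F, tolerance = 1e-12)
  expect_equal(r$p_uncorrected, o$p, tolerance = 1e-12)
  a <- aov_oneway(mat)
  expect_equal(r$F, a$F, tolerance = 1e-8)
  expect_equal(r$p_uncorrected, a$p, tolerance = 1e-8)
})

test_that("one-way agrees with the aov reference stratum on random designs", {
  set.seed(82)
  for (rep in 1:25) {
    mat <- random_matrix(sample(4:10, 1), sample(3:6, 1))
    r <- rmAnovaOneway(mat)
    a <- aov_oneway(mat)
    expect_equal(r$F, a$F, tolerance = 1e-8)
    expect_equal(r$p_uncorrected, a$p, tolerance = 1e-8)
  }
})

test_that("degenerate one-way designs are reported, not raised", {
  # subjects constant across levels: no level effect, no error variance
  flat <- matrix(rep(c(1, 4, -2), times = 3), nrow = 3)
  r <- rmAnovaOneway(flat)
  expect_equal(r$ss_effect, 0)
  expect_equal(r$F, 0)
  expect_equal(r$p_uncorrected, 1)
  expect_false(r$degenerate)

  # exact level effect with zero residual: F = Inf, p = 0, flagged
  exact <- outer(c(0, 1, 2, 5), c(1, 2, 3), "+")
  expect_warning(r2 <- rmAnovaOneway(exact), "zero error variance")
  expect_identical(r2$F, Inf)
  expect_equal(r2$p_uncorrected, 0)
  expect_true(r2$degenerate)

  expect_error(rmAnovaOneway(matrix(1:3, 1)), "design error")
  expect_error(rmAnovaOneway(matrix(c(1, 2, NA, 4), 2)), "missing cells")
})

test_that("Greenhouse-Geisser epsilon obeys its bounds and oracles", {
  # compound symmetry -> sphericity -> epsilon = 1
  cs <- matrix(0.4, 5, 5); diag(cs) <- 1
  expect_equal(ggEpsilon(cs), 1)
  # two levels: bound forces epsilon = 1
  expect_equal(ggEpsilon(matrix(c(2, 0.1, 0.1, 5), 2)), 1)
  expect_error(ggEpsilon(matrix(rnorm(6), 2, 3)), "square")
  asym <- matrix(c(1, 0.5, 0, 1), 2); expect_error(ggEpsilon(asym), "symmetric")

  set.seed(9)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.1
    e <- ggEpsilon(S)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
    expect_equal(e, oracle_gg_epsilon(S), tolerance = 1e-10)
  }
  # epsilon = 1 for any 2-level data matrix through the one-way route
  expect_equal(rmAnovaOneway(random_matrix(6, 2))$epsilon_gg, 1)
})

test_that("GG correction is conservative where decisions are made", {
  # shrinking both df by epsilon <= 1 inflates the p-value of any effect in
  # the rejection region (it can deflate only far into the null region)
  set.seed(10)
  hits <- 0
  for (rep in 1:200) {
    mat <- random_matrix(sample(4:8, 1), sample(3:5, 1))
    # add a random session profile so a fair share of fixtures land in the
    # rejection region
    mat <- mat + matrix(rnorm(ncol(mat)), nrow(mat), ncol(mat), byrow = TRUE)
    r <- rmAnovaOneway(mat)
    expect_lte(r$epsilon_gg, 1)
    expect_gte(r$epsilon_gg, 1 / (ncol(mat) - 1))
    if (is.finite(r$F) && r$p_uncorrected <= 0.1) {
      hits <- hits + 1
      expect_gte(r$p_gg, r$p_uncorrected)
    }
  }
  expect_gt(hits, 0)
})

test_that("two-way decomposition matches brute-force oracle and conserves SS", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(4:6, 1); J <- sample(3:4, 1); M <- sample(2:3, 1)
    cube <- array(rnorm(n * J * M), dim = c(n, J, M))
    r <- rmAnovaTwoWay(cube)
    o <- oracle_twoway(cube)
    expect_equal(r$F, unname(o$F), tolerance = 1e-10)
    expect_equal(r$p_uncorrected, unname(o$p), tolerance = 1e-10)
    expect_equal(r$ss_effect, unname(c(o$ss$T, o$ss$M, o$ss$TM)),
                 tolerance = 1e-10)
    # conservation: all seven components recover the total SS
    ss_total <- sum((cube - mean(cube))^2)
    parts <- sum(r$ss_effect) + sum(r$ss_error) + o$ss$S
    expect_equal(parts, ss_total, tolerance = 1e-9 * max(1, ss_total))
  }
})

test_that("identical measure copies collapse the two-way to the one-way", {
  set.seed(13)
  mat <- random_matrix(6, 4)
  cube <- array(rep(mat, 3), dim = c(6, 4, 3))
  r <- rmAnovaTwoWay(cube)
  expect_lt(r$ss_effect[r$effect == "measure"], 1e-10)
  expect_lt(r$ss_effect[r$effect == "time:measure"], 1e-10)
  one <- rmAnovaOneway(mat)
  tm <- r[r$effect == "time", ]
  expect_equal(tm$F, one$F, tolerance = 1e-10)
  expect_equal(tm$p_uncorrected, one$p_uncorrected, tolerance = 1e-10)
  expect_equal(tm$epsilon_gg, one$epsilon_gg, tolerance = 1e-10)
})

test_that("z-standardized data force a null measure main effect", {
  z <- standardizeMeasures(simulateStudy(defaultProfiles(), nSubjects = 12,
                                         seed = 14))
  r <- rmAnovaTwoWay(z)
  ss_total <- sum((studyCube(z) - mean(studyCube(z)))^2)
  m <- r[r$effect == "measure", ]
  expect_lt(m$ss_effect, 1e-10 * ss_total)
  expect_lt(m$F, 1e-3)
  expect_equal(m$p_uncorrected, 1, tolerance = 1e-6)
  expect_error(rmAnovaTwoWay(array(c(NA, rnorm(23)), dim = c(3, 4, 2))),
               "missing cells")
})
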