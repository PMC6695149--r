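test_that("polynomial contrasts recover the classical integer tables", {
  expect_identical(unname(polyContrasts(2)), rbind(c(-1L, 1L)))
  c4 <- polyContrasts(4)
  expect_identical(unname(c4["linear", ]), c(-3L, -1L, 1L, 3L))
  expect_identical(unname(c4["quadratic", ]), c(1L, -1L, -1L, 1L))
  expect_identical(unname(c4["cubic", ]), c(-1L, 3L, -3L, 1L))
  # even-degree contrasts are symmetric about the center point
  c5 <- polyContrasts(5)
  expect_identical(unname(c5["quadratic", ]), rev(unname(c5["quadratic", ])))
  expect_error(polyContrasts(1), "design error")
})

test_that("contrast rows are zero-sum and mutually orthogonal, exactly", {
  for (k in 2:8) {
    cm <- polyContrasts(k)
    expect_identical(dim(cm), c(k - 1L, as.integer(k)))
    expect_true(all(rowSums(cm) == 0L))
    g <- cm %*% t(cm)
    expect_true(all(g[upper.tri(g)] == 0L))
  }
})

test_that("trend tests isolate the injected polynomial shape", {
  # constant rows -> every estimate exactly 0
  flat <- matrix(rep(c(2, -1, 3, 0), times = 4), nrow = 4)
  cm <- polyContrasts(4)
  for (tr in rownames(cm)) {
    r <- testTrend(flat, cm[tr, ], trend = tr)
    expect_identical(r$estimate, 0)
    expect_equal(r$p, 1)
  }
  # exact inverted-U (0, d, d, 0): quadratic loads, linear does not
  d <- 0.7
  u <- matrix(rep(c(0, d, d, 0), each = 5), nrow = 5) +
    matrix(rep(rnorm(5), 4), nrow = 5)  # subject offsets cancel in contrasts
  expect_equal(testTrend(u, cm["quadratic", ])$estimate, -2 * d)
  expect_equal(testTrend(u, cm["linear", ])$estimate, 0)
})

test_that("trend t and p match the brute-force oracle", {
  set.seed(21)
  for (rep in 1:20) {
    mat <- random_matrix(10, 4)
    cm <- polyContrasts(4)
    for (tr in rownames(cm)) {
      r <- testTrend(mat, cm[tr, ], trend = tr)
      o <- oracle_trend(mat, cm[tr, ])
      expect_equal(r$estimate, o$estimate, tolerance = 1e-12)
      expect_equal(r$t, o$t, tolerance = 1e-10)
      expect_equal(r$p, o$p, tolerance = 1e-10)
      expect_identical(r$df, nrow(mat) - 1)
    }
  }
  expect_error(testTrend(random_matrix(5, 4), c(1, 1, 1, 1)), "sum to zero")
  expect_error(testTrend(random_matrix(5, 4), c(-1, 1)), "length")
})

test_that("pooled-error trend tests use the omnibus error mean square", {
  set.seed(22)
  mat <- random_matrix(8, 4)
  cm <- polyContrasts(4)
  ms_err <- oracle_oneway(mat)$ss_error / (7 * 3)
  for (tr in rownames(cm)) {
    r <- testTrend(mat, cm[tr, ], errorTerm = "pooled", trend = tr)
    L <- mat %*% cm[tr, ]
    t_exp <- mean(L) / sqrt(ms_err * sum(cm[tr, ]^2) / 8)
    expect_equal(r$t, t_exp, tolerance = 1e-10)
    expect_identical(r$df, 7 * 3)
  }
})

test_that("orthonormalized contrast SS reassembles the omnibus level SS", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:10, 1); k <- sample(3:6, 1)
    mat <- random_matrix(n, k)
    cm <- polyContrasts(k)
    ss_contrasts <- 0
    for (r_ in seq_len(nrow(cm))) {
      cc <- cm[r_, ] / sqrt(sum(cm[r_, ]^2))
      ss_contrasts <- ss_contrasts + n * mean(mat %*% cc)^2
    }
    ss_level <- rmAnovaOneway(mat)$ss_effect
    expect_equal(ss_contrasts, ss_level, tolerance = 1e-9 * max(1, ss_level))
  }
})

test_that("LSD pairwise comparisons enumerate all pairs and match the oracle", {
  set.seed(24)
  mat <- random_matrix(8, 3)
  res <- lsdPairwise(mat)
  expect_identical(nrow(res), 3L)
  for (r_ in seq_len(nrow(res))) {
    o <- oracle_pairwise(mat, res$session_a[r_], res$session_b[r_])
    expect_equal(res$mean_diff[r_], o$mean_diff, tolerance = 1e-12)
    expect_equal(res$t[r_], o$t, tolerance = 1e-10)
    expect_equal(res$p[r_], o$p, tolerance = 1e-10)
  }
  expect_identical(nrow(lsdPairwise(random_matrix(5, 4))), 6L)

  # two identical columns -> exact null comparison
  dup <- cbind(mat[, 1], mat[, 1], mat[, 2])
  r12 <- lsdPairwise(dup)[1, ]
  expect_identical(r12$mean_diff, 0)
  expect_identical(r12$t, 0)
  expect_equal(r12$p, 1)

  # p is two-sided: swapping the pair flips t but not p
  swapped <- mat[, c(2, 1, 3)]
  expect_equal(lsdPairwise(swapped)$p[1], res$p[1], tolerance = 1e-12)
  expect_equal(lsdPairwise(swapped)$t[1], -res$t[1], tolerance = 1e-12)
})

test_that("null trend and pairwise tests reject at the nominal rate", {
  set.seed(25)
  n_rep <- 400
  rej_trend <- 0L; rej_pair <- 0L
  for (r_ in seq_len(n_rep)) {
    mat <- random_matrix(12, 4)
    rej_trend <- rej_trend +
      (testTrend(mat, polyContrasts(4)["quadratic", ])$p < 0.05)
    rej_pair <- rej_pair + (lsdPairwise(mat)$p[1] < 0.05)
  }
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rej_trend, ci[1]); expect_lte(rej_trend, ci[2])
  expect_gte(rej_pair, ci[1]); expect_lte(rej_pair, ci[2])
})
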