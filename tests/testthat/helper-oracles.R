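# Independent brute-force oracles, implemented from the textbook formulas
# with explicit loops over cell and marginal means. They deliberately share
# no code with the package internals.

oracle_oneway <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_total <- 0
  for (i in 1:n) for (j in 1:k) ss_total <- ss_total + (mat[i, j] - grand)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(mat[i, ]) - grand)^2
  ss_lvl <- 0
  for (j in 1:k) ss_lvl <- ss_lvl + n * (mean(mat[, j]) - grand)^2
  ss_err <- unname(ss_total - ss_subj - ss_lvl)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_lvl / df1) / (ss_err / df2)
  list(ss_level = unname(ss_lvl), ss_subjects = unname(ss_subj),
       ss_error = ss_err, F = unname(f),
       p = unname(pf(f, df1, df2, lower.tail = FALSE)))
}

# GG epsilon via an orthonormal polynomial contrast basis:
# eps = (tr CSC')^2 / ((k-1) tr (CSC')^2). Independent of the package's
# eigenvalue route on the double-centered covariance.
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  C <- t(contr.poly(k))          # rows already orthonormal
  A <- C %*% S %*% t(C)
  eps <- sum(diag(A))^2 / ((k - 1) * sum(diag(A %*% A)))
  min(1, max(1 / (k - 1), eps))
}

oracle_trend <- function(mat, coef) {
  n <- nrow(mat)
  L <- numeric(n)
  for (i in 1:n) L[i] <- sum(coef * mat[i, ])
  m <- mean(L)
  s <- sqrt(sum((L - m)^2) / (n - 1))
  tval <- m / (s / sqrt(n))
  list(estimate = m, t = tval, p = 2 * pt(-abs(tval), n - 1))
}

oracle_pairwise <- function(mat, a, b) {
  n <- nrow(mat)
  d <- mat[, a] - mat[, b]
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tval <- m / (s / sqrt(n))
  list(mean_diff = m, t = tval, p = 2 * pt(-abs(tval), n - 1))
}

oracle_twoway <- function(cube) {
  n <- dim(cube)[1]; J <- dim(cube)[2]; M <- dim(cube)[3]
  g <- mean(cube)
  ss <- list(T = 0, M = 0, TM = 0, ST = 0, SM = 0, STM = 0, S = 0)
  s_i <- sapply(1:n, function(i) mean(cube[i, , ]))
  t_j <- sapply(1:J, function(j) mean(cube[, j, ]))
  m_m <- sapply(1:M, function(m) mean(cube[, , m]))
  for (i in 1:n) ss$S <- ss$S + J * M * (s_i[i] - g)^2
  for (j in 1:J) ss$T <- ss$T + n * M * (t_j[j] - g)^2
  for (m in 1:M) ss$M <- ss$M + n * J * (m_m[m] - g)^2
  for (i in 1:n) for (j in 1:J)
    ss$ST <- ss$ST + M * (mean(cube[i, j, ]) - s_i[i] - t_j[j] + g)^2
  for (i in 1:n) for (m in 1:M)
    ss$SM <- ss$SM + J * (mean(cube[i, , m]) - s_i[i] - m_m[m] + g)^2
  for (j in 1:J) for (m in 1:M)
    ss$TM <- ss$TM + n * (mean(cube[, j, m]) - t_j[j] - m_m[m] + g)^2
  for (i in 1:n) for (j in 1:J) for (m in 1:M)
    ss$STM <- ss$STM + (cube[i, j, m] -
                          mean(cube[i, j, ]) - mean(cube[i, , m]) -
                          mean(cube[, j, m]) +
                          s_i[i] + t_j[j] + m_m[m] - g)^2
  f_T <- (ss$T / (J - 1)) / (ss$ST / ((n - 1) * (J - 1)))
  f_M <- (ss$M / (M - 1)) / (ss$SM / ((n - 1) * (M - 1)))
  f_TM <- (ss$TM / ((J - 1) * (M - 1))) /
    (ss$STM / ((n - 1) * (J - 1) * (M - 1)))
  list(ss = ss,
       F = c(time = f_T, measure = f_M, interaction = f_TM),
       p = c(time = pf(f_T, J - 1, (n - 1) * (J - 1), lower.tail = FALSE),
             measure = pf(f_M, M - 1, (n - 1) * (M - 1), lower.tail = FALSE),
             interaction = pf(f_TM, (J - 1) * (M - 1),
                              (n - 1) * (J - 1) * (M - 1),
                              lower.tail = FALSE)))
}

# reference implementation route: stats::aov with an Error() stratum
aov_oneway <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  subj = factor(rep(seq_len(n), times = k)),
                  lvl = factor(rep(seq_len(k), each = n)))
  fit <- summary(aov(y ~ lvl + Error(subj), data = d))
  tab <- fit[["Error: Within"]][[1]]
  list(F = tab["lvl", "F value"], p = tab["lvl", "Pr(>F)"])
}
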