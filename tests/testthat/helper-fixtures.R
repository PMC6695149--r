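# small in-code fixtures shared across test files

make_long <- function(subjects, sessions, measures, values = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(measure = measures, session = sessions,
                   subject = subjects, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("subject", "session", "measure")]
  g$value <- if (is.null(values)) rnorm(nrow(g)) else values
  g
}

random_matrix <- function(n, k) matrix(rnorm(n * k), nrow = n, ncol = k)

# flat-profile null profiles on the unit scale
null_profiles <- function(m, T_ = 4L) {
  p <- data.frame(measure = sprintf("m%02d", seq_len(m)),
                  baseline_mean = 0, baseline_sd = 1, direction = 1L,
                  stringsAsFactors = FALSE)
  for (j in seq_len(T_)) p[[paste0("delta_", j)]] <- 0
  p
}

# inverted-U profiles (0, d, d, d/4) on the unit scale
effect_profiles <- function(d_values, per_group = 1L, T_ = 4L) {
  m <- length(d_values) * per_group
  p <- null_profiles(m, T_)
  d <- rep(d_values, each = per_group)
  p$delta_2 <- d
  p$delta_3 <- d
  p$delta_4 <- d / 4
  p$d <- d
  p
}
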