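test_that("paired t matches the closed form on random pairs", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- paired_t(a, b)
    d <- a - b
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * pt(-abs(t_oracle), n - 1)
    expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_equal(res$df, n - 1)
    expect_equal(res$n, n)
  }
})

test_that("paired t handles symmetry and degenerate inputs", {
  a <- c(2, 1, 3, 2); b <- c(1, 2, 2, 3)  # differences 1,-1,1,-1
  res <- paired_t(a, b)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(paired_t(1:5, 1:5), "degenerate")
  expect_error(paired_t(1:4, 1:5), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("repeated-measures ANOVA agrees with a sum-of-squares oracle", {
  ss_oracle <- function(m) {   # rows subjects, cols conditions
    gm <- mean(m)
    ss_cond <- nrow(m) * sum((colMeans(m) - gm)^2)
    ss_subj <- ncol(m) * sum((rowMeans(m) - gm)^2)
    ss_tot <- sum((m - gm)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    df1 <- ncol(m) - 1; df2 <- (ncol(m) - 1) * (nrow(m) - 1)
    f <- (ss_cond / df1) / (ss_err / df2)
    list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
  }
  set.seed(17)
  for (i in 1:100) {
    m <- matrix(rnorm(10 * 3), 10, 3)
    res <- rm_anova(m)
    orc <- ss_oracle(m)
    expect_equal(res$statistic, orc$f, tolerance = 1e-9)
    expect_equal(res$p, orc$p, tolerance = 1e-9)
  }
})

test_that("ANOVA edge cases: null effect, t-squared equivalence, validation", {
  # no condition effect: columns are permutations of the same values, so
  # column means are identical while residual variance stays positive
  set.seed(50)
  v <- rnorm(8)
  m <- cbind(a = v, b = rev(v), c = v[c(3:8, 1:2)])
  expect_equal(rm_anova(m)$statistic, 0, tolerance = 1e-12)

  set.seed(2)
  m2 <- matrix(rnorm(20), 10, 2)
  f2 <- rm_anova(m2)$statistic
  t2 <- paired_t(m2[, 1], m2[, 2])$statistic
  expect_equal(f2, t2^2, tolerance = 1e-9)

  long <- data.frame(subject = c(1, 1, 2), condition = c("a", "b", "a"),
                     value = rnorm(3))
  expect_error(rm_anova(long), "missing cells.*2:b")
})

test_that("BH adjustment equals the min-over-suffix definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
    q
  }
  set.seed(23)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    # monotone in ranks: sorting p sorts q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("time normalization maps an epoch onto 0-100% correctly", {
  ep <- data.frame(start_s = 1, end_s = 3)
  x <- sts_ts(seq(0, 5, by = 0.001) * 2, 1000, 0)  # ramp y = 2t
  v <- time_normalize(x, ep, n = 100)
  expect_length(v, 100)
  expect_equal(v, seq(2, 6, length.out = 100), tolerance = 1e-9)
  expect_equal(time_normalize(x, ep, n = 1), 4, tolerance = 1e-9)
  expect_error(time_normalize(x, data.frame(start_s = 2, end_s = 2)),
               "empty epoch")

  # commutes with resampling up to interpolation error
  y <- resample_to(sts_ts(sin(seq(0, 5, by = 1 / 30)), 30, 0), 1000)
  x30 <- sts_ts(sin(seq(0, 5, by = 1 / 30)), 30, 0)
  expect_equal(time_normalize(y, ep), time_normalize(x30, ep),
               tolerance = 1e-3)
})

test_that("z-transform conventions and invariances hold", {
  expect_equal(z_transform(c(0, 1, 2)), c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(z_transform(c(0, 1, 2), sample_sd = TRUE), c(-1, 0, 1))
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(3:100, 1))
    z <- z_transform(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
    a <- runif(1, 0.5, 3) * sample(c(-1, 1), 1); b <- rnorm(1)
    expect_equal(z_transform(a * x + b), sign(a) * z, tolerance = 1e-9)
  }
  expect_error(z_transform(rep(2, 5)), "zero-variance")
})

test_that("the comparison battery is complete, labeled and validated", {
  ft <- simulate_feature_cohort(seed = 5)
  res <- run_sts_comparisons(ft)
  expect_equal(nrow(res), 23)
  expect_equal(sum(res$test == "rm_anova"), 2)
  expect_equal(sum(grepl("left vs right", res$comparison)), 6)
  expect_equal(sum(grepl("jacket vs none", res$comparison)), 12)
  angle_rows <- res[grepl("^max_trunk_angle", res$comparison) &
                      !grepl("jacket", res$comparison), ]
  expect_equal(nrow(angle_rows), 3)
  expect_true(all(!is.na(angle_rows$p_adjusted)))
  expect_true(all(angle_rows$p_adjusted >= angle_rows$p))
  expect_true(all(res$p >= 0 & res$p <= 1))

  # per-subject pairing: n equals the number of subjects for t rows
  expect_true(all(res$n[res$test == "paired_t"] == 10))

  expect_error(run_sts_comparisons(ft[ft$condition != "one-hand-on-table", ]),
               "one-hand-on-table")
  expect_error(run_sts_comparisons(ft[ft$jacket, ]), "jacket")
})

test_that("strong injected effects surface in the jacket comparisons", {
  ft <- simulate_feature_cohort(seed = 77)
  res <- run_sts_comparisons(ft)
  iemg_rows <- res[grepl("^iemg_mean jacket", res$comparison), ]
  cop_rows <- res[grepl("^mean_cop_ap jacket", res$comparison), ]
  angle_rows <- res[grepl("^max_trunk_angle jacket", res$comparison), ]
  expect_true(all(iemg_rows$p < 0.05))
  expect_true(all(iemg_rows$statistic > 0))   # jacket larger
  expect_true(all(cop_rows$p < 0.05))
  expect_true(all(cop_rows$statistic < 0))    # posterior shift
  expect_true(all(angle_rows$p > 0.05))       # no angle effect injected
})
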