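mk_epoch <- function(start, end) {
  data.frame(subject = 1, condition = "both-hands-on-knees", jacket = FALSE,
             rep = 1, start_s = start, end_s = end, excluded = FALSE,
             reason = NA_character_)
}

test_that("iEMG integrates the envelope over the epoch", {
  const <- sts_ts(rep(100, 2001), 1000, 0)
  expect_equal(iemg(const, mk_epoch(0.5, 1.5)), 100)
  zero <- sts_ts(rep(0, 2001), 1000, 0)
  expect_equal(iemg(zero, mk_epoch(0.5, 1.5)), 0)
  expect_error(iemg(const, mk_epoch(3, 4)), "no samples")
})

test_that("iEMG matches a 10x-resolution quadrature oracle", {
  for (i in 1:30) {
    x <- smooth_signal(dur = 4, rate = 1000, seed = i)
    hi <- smooth_signal(dur = 4, rate = 10000, seed = i)  # same analytic curve
    ep <- mk_epoch(0.5, 3.5)
    tt <- ts_time(hi)
    sel <- tt >= ep$start_s & tt <= ep$end_s
    oracle <- pracma::trapz(tt[sel], hi$values[sel])
    expect_equal(iemg(x, ep), oracle, tolerance = 1e-6)
  }
})

test_that("iEMG is additive over a partition of the epoch", {
  x <- smooth_signal(dur = 5, rate = 1000, seed = 99)
  whole <- iemg(x, mk_epoch(0.5, 4.5))
  # split at a sample boundary; both halves include the shared sample
  parts <- iemg(x, mk_epoch(0.5, 2.25)) + iemg(x, mk_epoch(2.25, 4.5))
  expect_equal(parts, whole, tolerance = 1e-9)
})

test_that("max EMG equals a brute-force scan of the interval", {
  const <- sts_ts(rep(40, 1001), 1000, 0)
  expect_equal(max_emg(const, mk_epoch(0.2, 0.8)), 40)
  v <- rep(0, 1001); v[500] <- 100
  expect_equal(max_emg(sts_ts(v, 1000, 0), mk_epoch(0.2, 0.8)), 100)
  set.seed(12)
  for (i in 1:20) {
    x <- sts_ts(runif(3000, 0, 100), 1000, 0)
    ep <- mk_epoch(0.4, 2.2)
    tt <- ts_time(x)
    oracle <- max(x$values[tt >= 0.4 & tt <= 2.2])
    expect_identical(max_emg(x, ep), oracle)
  }
})

test_that("trunk angle closed forms are exact", {
  p <- c(0, 1, 0)
  expect_equal(trunk_angle(p, p + c(0, 0.5, 0)), 0, tolerance = 1e-9)
  expect_equal(trunk_angle(p, p + c(0.3, 0, 0)), 90, tolerance = 1e-9)
  expect_equal(trunk_angle(p, p + c(1, 1, 0)), 45, tolerance = 1e-9)
  expect_true(is.na(trunk_angle(p, p)))
  expect_true(is.na(trunk_angle(c(NA, 1, 0), p)))
})

test_that("trunk angle is invariant to yaw rotation and uniform scaling", {
  set.seed(8)
  for (i in 1:25) {
    pelvis <- rnorm(3)
    neck <- pelvis + rnorm(3)
    base <- trunk_angle(pelvis, neck)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
    expect_equal(trunk_angle(as.vector(R %*% pelvis), as.vector(R %*% neck)),
                 base, tolerance = 1e-9)
    sc <- runif(1, 0.1, 5)
    expect_equal(trunk_angle(sc * pelvis, sc * neck), base, tolerance = 1e-9)
  }
})

test_that("max trunk angle recovers the scripted peak flexion", {
  al <- fixture_aligned()
  gt <- fixture_session()$ground_truth$epochs
  ft <- fixture_features()
  expect_lt(max(abs(ft$max_trunk_angle - gt$true_max_angle)), 1)
  # agrees with a frame-by-frame scan
  skel <- al$session$skel
  ep <- fixture_epochs()[3, ]
  inside <- which(skel$time >= ep$start_s & skel$time <= ep$end_s)
  oracle <- max(vapply(inside, function(i)
    trunk_angle(skel$pos[i, "pelvis", ], skel$pos[i, "neck", ]), numeric(1)),
    na.rm = TRUE)
  expect_equal(max_trunk_angle(skel, ep), oracle)
})

test_that("an upright pose gives a near-zero angle and absent joints warn", {
  n <- 30
  pos <- array(0, dim = c(n, 2, 3),
               dimnames = list(NULL, c("pelvis", "neck"), c("x", "y", "z")))
  pos[, "neck", 2] <- 0.5  # neck straight above pelvis
  sk <- sts_skel(seq(0, by = 1 / 30, length.out = n), pos)
  ep <- mk_epoch(0, 0.9)
  expect_equal(max_trunk_angle(sk, ep), 0, tolerance = 1e-9)
  pos[, , ] <- NA_real_
  sk2 <- sts_skel(seq(0, by = 1 / 30, length.out = n), pos)
  expect_warning(res <- max_trunk_angle(sk2, ep), "missing")
  expect_true(is.na(res))
})

test_that("mean AP COP averages the epoch and recovers the jacket shift", {
  const <- sts_ts(rep(-20, 301), 100, 0)
  expect_equal(mean_cop_ap(const, mk_epoch(0.5, 2.5)), -20)
  t <- seq(0, 3, by = 0.01)
  osc <- sts_ts(sin(2 * pi * 5 * t), 100, 0)
  expect_lt(abs(mean_cop_ap(osc, mk_epoch(0, 3))), 1e-10)

  ft <- fixture_features()
  gt <- fixture_session()$ground_truth$epochs
  diff_est <- mean(ft$mean_cop_ap[ft$jacket]) - mean(ft$mean_cop_ap[!ft$jacket])
  expect_equal(diff_est, -15, tolerance = 0.15)
})

test_that("the feature table has one row per retained epoch", {
  ft <- fixture_features()
  ep <- fixture_epochs()
  expect_equal(nrow(ft), sum(!ep$excluded))
  expect_equal(nrow(ft), 18)   # 6 blocks x 3 reps, none excluded
  expect_true(all(ft$iemg_left >= 0 & ft$iemg_right >= 0))
  expect_true(all(ft$max_emg_left >= 0 & ft$max_emg_left <= 100))
  expect_true(all(ft$max_trunk_angle >= 0 & ft$max_trunk_angle <= 180))

  # excluded epochs are dropped
  al <- fixture_aligned()
  ep2 <- ep; ep2$excluded[1:2] <- TRUE
  ft2 <- build_feature_table(al$session, ep2)
  expect_equal(nrow(ft2), 16)

  ep0 <- ep[0, ]
  expect_equal(nrow(build_feature_table(al$session, ep0)), 0)
})

test_that("computed iEMG tracks the injected per-epoch activation scale", {
  # 3 sessions x 18 epochs at low noise; rank correlation against truth
  ii <- tt <- numeric(0)
  for (sd in 1:3) {
    s <- generate_session(sim_config(seed = 100 + sd, emg_noise_sd = 0.02), sd)
    al <- align_session(s)
    ep <- segment_session(al$session, al$skel_native)
    ft <- build_feature_table(al$session, ep)
    gt <- s$ground_truth$epochs
    ii <- c(ii, (ft$iemg_left + ft$iemg_right) / 2)
    tt <- c(tt, (gt$iemg_scale_left + gt$iemg_scale_right) / 2)
  }
  expect_gt(cor(ii, tt, method = "spearman"), 0.9)
})
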