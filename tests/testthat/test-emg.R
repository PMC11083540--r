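test_that("rectification centers then takes magnitudes", {
  expect_equal(emg_rectify(sts_ts(c(2, 4, 6), 1000))$values, c(2, 0, 2))
  expect_equal(emg_rectify(sts_ts(rep(3.7, 50), 1000))$values, rep(0, 50))

  # independent two-step oracle on random vectors; signed variant stays
  # zero-mean
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(sample(5:300, 1), mean = runif(1, -5, 5))
    x <- sts_ts(v, 1000)
    oracle <- abs(v - mean(v))
    expect_identical(emg_rectify(x)$values, oracle)
    expect_true(all(emg_rectify(x)$values >= 0))
    signed <- emg_rectify(x, abs = FALSE)$values
    expect_lt(abs(mean(signed)), 1e-9 * max(sd(v), 1))
  }

  expect_error(emg_rectify(sts_ts(c(1, NA, 3), 1000)), "non-finite")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  t <- seq(0, 5, by = 1e-3)
  amp_of <- function(freq) {
    x <- sts_ts(sin(2 * pi * freq * t), 1000)
    y <- emg_bandpass(x)$values
    # FFT peak amplitude, ignoring edge transients
    core <- y[501:4500]
    sp <- abs(fft(core)) / length(core) * 2
    max(sp)
  }
  expect_gt(amp_of(15), 0.9)
  expect_lt(amp_of(15), 1.1)
  expect_lt(amp_of(1), 0.1)
  expect_lt(amp_of(100), 0.1)

  z <- emg_bandpass(sts_ts(rep(0, 2000), 1000))
  expect_equal(z$values, rep(0, 2000))

  expect_error(emg_bandpass(sts_ts(rnorm(100), 50)), "infeasible")
})

test_that("moving average matches its definition and a brute-force oracle", {
  expect_equal(emg_moving_average(sts_ts(rep(4.2, 30), 1000), 7)$values,
               rep(4.2, 30))

  imp <- rep(0, 101); imp[51] <- 1
  out <- emg_moving_average(sts_ts(imp, 1000), 10)$values
  expect_equal(out[41:61], rep(1 / 21, 21))
  expect_equal(out[c(1:30, 72:101)], rep(0, 60))

  naive_ma <- function(v, L) {
    n <- length(v)
    vapply(seq_len(n), function(t) {
      idx <- max(1, t - L):min(n, t + L)
      mean(v[idx])
    }, numeric(1))
  }
  set.seed(7)
  for (i in 1:100) {
    v <- rnorm(sample(1:200, 1))
    L <- sample(0:15, 1)
    expect_equal(emg_moving_average(sts_ts(v, 100), L)$values,
                 naive_ma(v, L), tolerance = 1e-12)
  }

  expect_error(emg_moving_average(sts_ts(1:5, 100), -1), "nonnegative")
})

test_that("min-max scaling hits exactly 0 and 100 and is idempotent", {
  expect_equal(emg_normalize(sts_ts(c(0, 5, 10), 100))$values, c(0, 50, 100))

  set.seed(3)
  for (i in 1:25) {
    v <- rnorm(sample(3:500, 1)) * runif(1, 0.1, 50)
    x <- sts_ts(v, 100)
    y <- emg_normalize(x)$values
    expect_identical(max(y), 100)
    expect_identical(min(y), 0)
    expect_equal(order(y), order(v))
    # idempotence and positive-affine invariance
    expect_equal(emg_normalize(emg_normalize(x))$values, y)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(emg_normalize(sts_ts(a * v + b, 100))$values, y,
                 tolerance = 1e-12)
  }

  expect_error(emg_normalize(sts_ts(rep(2, 10), 100)), "degenerate")
})

test_that("envelope equals its stage-by-stage composition in both orders", {
  set.seed(21)
  x <- sts_ts(rnorm(5000), 1000)
  cfg <- emg_config()
  expect_equal(
    sts_envelope(x, cfg)$values,
    emg_normalize(emg_moving_average(emg_rectify(emg_bandpass(x, cfg)),
                                     cfg$L))$values)
  expect_equal(
    sts_envelope(x, cfg, order = "rectify-first")$values,
    emg_normalize(emg_moving_average(emg_bandpass(emg_rectify(x), cfg),
                                     cfg$L))$values)
  expect_error(sts_envelope(sts_ts(rep(1, 1000), 1000)), "degenerate")
})

test_that("a two-burst recording yields a two-peak envelope", {
  set.seed(5)
  rate <- 1000
  t <- seq(0, 8, by = 1 / rate)
  bf <- signal::butter(4, c(5, 30) / (rate / 2), type = "pass")
  carrier <- signal::filtfilt(bf, rnorm(length(t)))
  w <- exp(-0.5 * ((t - 3) / 0.2)^2) + exp(-0.5 * ((t - 5) / 0.2)^2)
  x <- sts_ts(w * carrier * 4 + rnorm(length(t), 0, 0.02), rate)
  env <- sts_envelope(x)
  sm <- emg_moving_average(env, 100)  # peak counting on a steadier trace
  pk <- detect_peaks(sm, n = 2, prominence_frac = 0.3, min_separation_s = 1)
  expect_equal(pk, c(3, 5), tolerance = 0.15)
  trough <- min(sm$values[ts_time(sm) > pk[1] & ts_time(sm) < pk[2]])
  at_peaks <- approx(ts_time(sm), sm$values, pk)$y
  expect_true(all(at_peaks > trough))
})

test_that("out-of-band energy contributes little pre-normalization envelope", {
  t <- seq(0, 6, by = 1e-3)
  inband <- sts_ts(sin(2 * pi * 15 * t), 1000)
  outband <- sts_ts(sin(2 * pi * 70 * t), 1000)
  core <- function(x) {
    v <- sts_envelope(x, normalize = FALSE)$values
    max(v[1000:5000])
  }
  expect_lt(core(outband), 0.1 * core(inband))
})
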