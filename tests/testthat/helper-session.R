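# Shared synthetic fixtures, generated once per test run and cached: a full
# default-condition session plus its aligned/segmented products.

.fixture_cache <- new.env(parent = emptyenv())

fixture_session <- function() {
  if (is.null(.fixture_cache$session))
    .fixture_cache$session <- generate_session(sim_config(seed = 42L), 1L)
  .fixture_cache$session
}

fixture_aligned <- function() {
  if (is.null(.fixture_cache$aligned))
    .fixture_cache$aligned <- align_session(fixture_session())
  .fixture_cache$aligned
}

fixture_epochs <- function() {
  if (is.null(.fixture_cache$epochs)) {
    al <- fixture_aligned()
    .fixture_cache$epochs <- segment_session(al$session, al$skel_native)
  }
  .fixture_cache$epochs
}

fixture_features <- function() {
  if (is.null(.fixture_cache$features)) {
    al <- fixture_aligned()
    .fixture_cache$features <- build_feature_table(al$session,
                                                   fixture_epochs())
  }
  .fixture_cache$features
}

# a smooth low-frequency "envelope-like" test signal on [0, dur]
smooth_signal <- function(dur = 4, rate = 1000, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / rate)
  a <- runif(3, 0.5, 2); f <- runif(3, 0.2, 2); ph <- runif(3, 0, 2 * pi)
  v <- 10 + a[1] * sin(2 * pi * f[1] * t + ph[1]) +
    a[2] * sin(2 * pi * f[2] * t + ph[2]) +
    a[3] * sin(2 * pi * f[3] * t + ph[3])
  sts_ts(v, rate, 0)
}
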