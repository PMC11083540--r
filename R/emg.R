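#' EMG preprocessing configuration
#'
#' Parameters of the envelope-extraction chain applied to each raw EMG
#' channel before any feature is computed. The defaults are the ones used
#' throughout the package: a 5-30 Hz pass band, a 4th-order zero-phase
#' Butterworth realization, and a centered moving average of half-width
#' `L = 10` samples (21-sample window at 1000 Hz).
#'
#' @param band_low Lower pass-band edge, Hz.
#' @param band_high Upper pass-band edge, Hz.
#' @param L Moving-average half-width in samples (window is `2L + 1`).
#' @param order Butterworth filter order.
#' @return Object of class `emg_config`.
#' @export
emg_config <- function(band_low = 5, band_high = 30, L = 10, order = 4) {
  if (!is.numeric(band_low) || band_low <= 0)
    stop("`band_low` must be > 0", call. = FALSE)
  if (!is.numeric(band_high) || band_high <= band_low)
    stop("`band_high` must exceed `band_low`", call. = FALSE)
  if (!is.numeric(L) || L < 0 || L != round(L))
    stop("`L` must be a nonnegative integer", call. = FALSE)
  if (!is.numeric(order) || order < 1 || order != round(order))
    stop("`order` must be a positive integer", call. = FALSE)
  structure(list(band_low = band_low, band_high = band_high,
                 L = as.integer(L), order = as.integer(order)),
            class = "emg_config")
}

#' Full-wave rectification of a raw EMG signal
#'
#' Centers the signal on its mean and takes the absolute value, converting
#' the signed interference pattern into a magnitude trace. The mean of the
#' centered (pre-absolute) signal is zero by construction. Setting
#' `abs = FALSE` skips the absolute value and returns the mean-centered
#' signal only (the literal equation some protocols print for this step);
#' the default performs true full-wave rectification.
#'
#' @param x An `sts_ts` (single channel).
#' @param abs Apply the absolute value after centering (default `TRUE`).
#' @return Rectified `sts_ts`, same rate and `t0`.
#' @examples
#' sts_envelope  # rectification is the first stage of the envelope chain
#' emg_rectify(sts_ts(c(2, 4, 6), 1000))$values  # 2 0 2
#' @export
emg_rectify <- function(x, abs = TRUE) {
  stopifnot(inherits(x, "sts_ts"))
  v <- x$values
  if (is.matrix(v)) stop("emg_rectify expects a single channel", call. = FALSE)
  if (!all(is.finite(v)))
    stop("EMG signal contains non-finite values", call. = FALSE)
  centered <- v - mean(v)
  sts_ts(if (abs) base::abs(centered) else centered, x$rate, x$t0)
}

#' Band-pass filter an EMG signal
#'
#' Zero-phase (forward-backward) Butterworth band-pass. Zero-phase
#' filtering preserves burst timing, which the segmentation and
#' visualization stages rely on; the effective magnitude response is the
#' squared single-pass response.
#'
#' @param x An `sts_ts`.
#' @param cfg An [emg_config()].
#' @return Filtered `sts_ts`, same length, rate and `t0`.
#' @export
emg_bandpass <- function(x, cfg = emg_config()) {
  stopifnot(inherits(x, "sts_ts"), inherits(cfg, "emg_config"))
  nyq <- x$rate / 2
  if (cfg$band_high >= nyq)
    stop(sprintf("band edge %g Hz infeasible at rate %g Hz (Nyquist %g Hz)",
                 cfg$band_high, x$rate, nyq), call. = FALSE)
  bf <- signal::butter(cfg$order, c(cfg$band_low, cfg$band_high) / nyq,
                       type = "pass")
  sts_ts(signal::filtfilt(bf, x$values), x$rate, x$t0)
}

#' Centered moving average
#'
#' Smooths a signal with the symmetric window
#' `(1 / (2L + 1)) * sum_{i = -L..L} x(t - i)`. At the edges the window is
#' truncated to the available samples (the mean is taken over however many
#' of the `2L + 1` positions fall inside the signal), preserving length
#' without inventing padding values.
#'
#' @param x An `sts_ts`.
#' @param L Half-width in samples; window length is `2L + 1`.
#' @return Smoothed `sts_ts`.
#' @export
emg_moving_average <- function(x, L = 10) {
  stopifnot(inherits(x, "sts_ts"))
  if (!is.numeric(L) || length(L) != 1L || L < 0 || L != round(L))
    stop("`L` must be a nonnegative integer", call. = FALSE)
  sts_ts(moving_average_vec(x$values, as.integer(L)), x$rate, x$t0)
}

# cumulative-sum moving mean with truncated edges; O(n)
moving_average_vec <- function(v, L) {
  n <- length(v)
  if (L == 0L || n == 1L) return(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - L, 1L)
  hi <- pmin(seq_len(n) + L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min-max scale a signal to the 0-100 range
#'
#' Affine rescaling so the recording's maximum maps to exactly 100 and its
#' minimum to exactly 0. Used in place of %MVC scaling when no maximum
#' voluntary contraction reference is available; applied per channel over
#' the whole recording, before segmentation, so between-epoch amplitude
#' comparisons remain meaningful.
#'
#' @param x An `sts_ts`.
#' @return Scaled `sts_ts` with values in `[0, 100]`.
#' @export
emg_normalize <- function(x) {
  stopifnot(inherits(x, "sts_ts"))
  rng <- range(x$values)
  if (!all(is.finite(rng)))
    stop("signal contains non-finite values", call. = FALSE)
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1))
    stop("degenerate range: constant signal cannot be min-max scaled",
         call. = FALSE)
  sts_ts((x$values - rng[1]) / (rng[2] - rng[1]) * 100, x$rate, x$t0)
}

#' EMG envelope: band-pass, rectify, smooth, scale
#'
#' The composition of the four preprocessing stages. The default order is
#' `emg_normalize(emg_moving_average(emg_rectify(emg_bandpass(x, cfg)), cfg$L))`:
#' band-limit the raw interference signal, full-wave rectify, smooth,
#' min-max scale. Band-limiting must precede rectification for the result
#' to be an activation envelope: rectification is what moves burst energy
#' to low frequencies, so applying the 5-30 Hz band-pass *after* it
#' (`order = "rectify-first"`) strips the slowly varying envelope
#' component and leaves a zero-mean residual whose integral no longer
#' tracks burst amplitude. The rectify-first variant is retained for
#' comparison with protocols that list the stages in that order.
#'
#' @param x Raw single-channel `sts_ts`.
#' @param cfg An [emg_config()].
#' @param order Stage order: `"filter-first"` (default) or
#'   `"rectify-first"`.
#' @param normalize Apply the final min-max scaling (default `TRUE`);
#'   `FALSE` returns the smoothed rectified signal in raw units.
#' @return Envelope `sts_ts` in `[0, 100]` (or raw units when
#'   `normalize = FALSE`).
#' @export
sts_envelope <- function(x, cfg = emg_config(),
                         order = c("filter-first", "rectify-first"),
                         normalize = TRUE) {
  order <- match.arg(order)
  rng <- range(x$values)
  if (normalize && rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1))
    stop("degenerate range: constant signal cannot be min-max scaled",
         call. = FALSE)
  sm <- if (order == "filter-first")
    emg_moving_average(emg_rectify(emg_bandpass(x, cfg)), cfg$L)
  else
    emg_moving_average(emg_bandpass(emg_rectify(x), cfg), cfg$L)
  if (normalize) emg_normalize(sm) else sm
}
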