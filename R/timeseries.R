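#' Uniformly sampled time series
#'
#' Light-weight container for a uniformly sampled signal: a numeric vector
#' (or a k-column matrix for multi-channel streams such as the COP board's
#' anterior-posterior / medio-lateral / load channels), a sampling rate in
#' Hz, and the clock time of the first sample. All times in the package are
#' seconds; streams recorded on different device clocks differ only in `t0`
#' once synchronized.
#'
#' @param values Numeric vector or matrix (rows = samples).
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `sts_ts`.
#' @examples
#' x <- sts_ts(sin(seq(0, 1, by = 0.001)), rate = 1000)
#' head(ts_time(x))
#' @export
sts_ts <- function(values, rate, t0 = 0) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (n < 1L) stop("`values` must contain at least one sample", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number", call. = FALSE)
  structure(list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0)),
            class = "sts_ts")
}

#' Sample times of a time series
#'
#' @param x An `sts_ts`.
#' @return Numeric vector `t0 + (0:(n-1)) / rate`.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "sts_ts"))
  x$t0 + (seq_len(ts_length(x)) - 1L) / x$rate
}

#' Number of samples in a time series
#' @param x An `sts_ts`.
#' @return Integer sample count.
#' @export
ts_length <- function(x) {
  if (is.matrix(x$values)) nrow(x$values) else length(x$values)
}

#' @export
print.sts_ts <- function(x, ...) {
  k <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<sts_ts> %d samples x %d channel(s) @ %g Hz, t0 = %g s\n",
              ts_length(x), k, x$rate, x$t0))
  invisible(x)
}

#' Extract one channel of a multi-channel time series
#'
#' @param x An `sts_ts` whose `values` is a matrix with named columns.
#' @param channel Column name.
#' @return Single-channel `sts_ts` with the same rate and `t0`.
#' @export
ts_channel <- function(x, channel) {
  stopifnot(inherits(x, "sts_ts"))
  if (!is.matrix(x$values) || !channel %in% colnames(x$values))
    stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  sts_ts(x$values[, channel], x$rate, x$t0)
}

#' Skeleton joint-coordinate series
#'
#' Per-frame 3D joint positions from a body-tracking camera. Positions are
#' stored as a 3-dimensional array `[frame, joint, axis]` with axes
#' `(x, y, z)`, y vertical-up, units meters. A joint is *missing* in a frame
#' iff any of its three coordinates is `NA`; missing frames are preserved as
#' missing through resampling and file round-trips, never silently zeroed.
#'
#' @param time Strictly increasing numeric vector of frame timestamps
#'   (seconds).
#' @param pos Numeric array `n_frames x n_joints x 3`, with joint names on
#'   `dimnames(pos)[[2]]`.
#' @return Object of class `sts_skel`.
#' @export
sts_skel <- function(time, pos) {
  if (!is.numeric(time) || length(time) < 1L)
    stop("`time` must be a non-empty numeric vector", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("skeleton timestamps must be strictly increasing", call. = FALSE)
  if (!is.array(pos) || length(dim(pos)) != 3L || dim(pos)[3] != 3L)
    stop("`pos` must be an n_frames x n_joints x 3 array", call. = FALSE)
  if (dim(pos)[1] != length(time))
    stop("`pos` first dimension must match length(time)", call. = FALSE)
  if (is.null(dimnames(pos)[[2]]))
    stop("`pos` must carry joint names on its second dimension", call. = FALSE)
  dimnames(pos)[[3]] <- c("x", "y", "z")
  structure(list(time = as.numeric(time), pos = pos), class = "sts_skel")
}

#' Joint names of a skeleton series
#' @param x An `sts_skel`.
#' @return Character vector of joint names.
#' @export
skel_joints <- function(x) dimnames(x$pos)[[2]]

#' Per-frame missing-joint indicator
#'
#' @param x An `sts_skel`.
#' @return Logical matrix `n_frames x n_joints`; `TRUE` where the joint is
#'   missing (any coordinate `NA`) in that frame.
#' @export
skel_missing <- function(x) {
  stopifnot(inherits(x, "sts_skel"))
  apply(is.na(x$pos), c(1, 2), any)
}

#' One joint coordinate as a (non-uniform) value/time pair
#'
#' Convenience accessor used by synchronization and segmentation: returns
#' one axis of one joint together with the frame timestamps.
#'
#' @param x An `sts_skel`.
#' @param joint Joint name.
#' @param axis One of "x", "y", "z".
#' @return List with `time` and `values` (NA where the joint is missing).
#' @export
skel_coord <- function(x, joint, axis = "y") {
  stopifnot(inherits(x, "sts_skel"))
  if (!joint %in% skel_joints(x))
    stop(sprintf("joint '%s' not present", joint), call. = FALSE)
  axis <- match.arg(axis, c("x", "y", "z"))
  list(time = x$time, values = x$pos[, joint, axis])
}

#' @export
print.sts_skel <- function(x, ...) {
  cat(sprintf("<sts_skel> %d frames, joints: %s, %.1f-%.1f s\n",
              length(x$time), paste(skel_joints(x), collapse = ", "),
              min(x$time), max(x$time)))
  invisible(x)
}
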