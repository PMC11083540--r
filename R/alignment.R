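#' Resample a stream to a target rate
#'
#' Linear interpolation onto a uniform grid at `rate` Hz spanning the
#' input's time range (the canonical use is bringing the 100 Hz COP and
#' 30 Hz skeleton streams onto the 1000 Hz EMG clock, i.e. reassigning the
#' time points every 1 ms). Linear interpolation is exact for piecewise
#' linear signals and is the minimal-assumption choice for the smooth
#' kinematics handled here.
#'
#' For skeleton input, a joint is missing at an output time whenever either
#' of the two source frames bracketing that time has the joint missing:
#' missingness widens to the frames it covers and is never interpolated
#' across.
#'
#' @param x An `sts_ts` or `sts_skel`.
#' @param rate Target sampling rate, Hz.
#' @return Object of the same class as `x`, sampled at `rate`.
#' @export
resample_to <- function(x, rate) UseMethod("resample_to")

#' @export
resample_to.sts_ts <- function(x, rate) {
  check_target_rate(rate)
  n <- ts_length(x)
  if (n < 2L) stop("cannot resample a single-sample stream", call. = FALSE)
  tin <- ts_time(x)
  tout <- uniform_grid(tin[1], tin[n], rate)
  v <- x$values
  if (is.matrix(v)) {
    out <- apply(v, 2, function(col) interp_linear(tin, col, tout))
    colnames(out) <- colnames(v)
  } else {
    out <- interp_linear(tin, v, tout)
  }
  sts_ts(out, rate, tout[1])
}

#' @export
resample_to.sts_skel <- function(x, rate) {
  check_target_rate(rate)
  if (length(x$time) < 2L)
    stop("cannot resample a single-frame skeleton", call. = FALSE)
  tin <- x$time
  tout <- uniform_grid(tin[1], tin[length(tin)], rate)
  joints <- skel_joints(x)
  pos <- array(NA_real_, dim = c(length(tout), length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  miss <- skel_missing(x)
  # index of the source interval each output time falls in
  iv <- findInterval(tout, tin, rightmost.closed = TRUE)
  iv[iv < 1L] <- 1L
  iv[iv >= length(tin)] <- length(tin) - 1L
  for (j in joints) {
    bad <- miss[iv, j] | miss[iv + 1L, j]
    for (ax in 1:3) {
      y <- interp_linear(tin, x$pos[, j, ax], tout, na_ok = TRUE)
      y[bad] <- NA_real_
      pos[, j, ax] <- y
    }
  }
  # the output is uniform; keep sts_skel's explicit timestamps
  sts_skel(tout, pos)
}

check_target_rate <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("target rate must be a single positive number", call. = FALSE)
}

uniform_grid <- function(from, to, rate) {
  n <- floor((to - from) * rate + 1e-9) + 1L
  from + (seq_len(n) - 1L) / rate
}

# stats::approx with NA-tolerant plumbing; callers handle NA semantics
interp_linear <- function(tin, v, tout, na_ok = FALSE) {
  if (anyNA(v)) {
    if (!na_ok) stop("non-finite values in stream being resampled",
                     call. = FALSE)
    keep <- !is.na(v)
    if (sum(keep) < 2L) return(rep(NA_real_, length(tout)))
    stats::approx(tin[keep], v[keep], xout = tout, rule = 2)$y
  } else {
    stats::approx(tin, v, xout = tout, rule = 2)$y
  }
}

#' Detect the first n prominent peaks of a signal
#'
#' Finds local maxima, filters them by topographic prominence and a minimum
#' separation, and returns the apex times of the first `n` surviving peaks
#' in temporal order. Deliberate synchronization gestures (hand raises, toe
#' stands) and the per-repetition extrema used in segmentation are large
#' and slow, so the defaults ask for peaks standing out by at least a
#' quarter of the signal's range and at least one second apart.
#'
#' Apex times are refined to sub-sample precision by a least-squares
#' parabola fitted around the discrete argmax (`refine_halfwidth_s` wide on
#' each side), which localizes a smooth apex far better than the sample
#' grid of a 30 Hz stream allows; set `refine = FALSE` to return grid
#' times.
#'
#' @param time Numeric vector of sample times (seconds), or an `sts_ts` in
#'   which case `values` is ignored.
#' @param values Numeric vector of samples.
#' @param n Number of peaks required.
#' @param prominence_frac Minimum prominence as a fraction of the signal
#'   range over the searched window.
#' @param min_separation_s Minimum time between accepted peaks, seconds.
#' @param window Optional `c(start, end)` restricting the search, seconds.
#' @param refine Quadratic sub-sample apex refinement (default `TRUE`).
#' @param refine_halfwidth_s Half-width of the parabola fit, seconds.
#' @return Numeric vector of `n` apex times, increasing.
#' @export
detect_peaks <- function(time, values = NULL, n,
                         prominence_frac = 0.25, min_separation_s = 1,
                         window = NULL, refine = TRUE,
                         refine_halfwidth_s = 0.15) {
  if (inherits(time, "sts_ts")) {
    values <- time$values
    time <- ts_time(time)
  }
  stopifnot(length(time) == length(values))
  keep <- !is.na(values)
  if (!is.null(window)) keep <- keep & time >= window[1] & time <= window[2]
  tt <- time[keep]; vv <- values[keep]
  if (length(vv) < 3L)
    stop(sprintf("found 0 peaks (need %d): too few usable samples", n),
         call. = FALSE)

  cand <- which(diff(sign(diff(vv))) < 0) + 1L
  rng <- diff(range(vv))
  # a numerically flat trace has no peaks, only floating-point dust
  if (length(cand) == 0L || rng <= 1e-12 * max(abs(vv), 1))
    stop(sprintf("found 0 peaks (need %d)", n), call. = FALSE)
  prom <- vapply(cand, function(i) peak_prominence(vv, i), numeric(1))
  ok <- cand[prom >= prominence_frac * rng]

  # enforce separation greedily from the tallest down
  ok <- ok[order(vv[ok], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ok) {
    if (all(abs(tt[i] - tt[chosen]) >= min_separation_s)) chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  if (length(chosen) < n)
    stop(sprintf("found %d qualifying peaks (need %d)", length(chosen), n),
         call. = FALSE)
  chosen <- chosen[seq_len(n)]

  if (!refine) return(tt[chosen])
  vapply(chosen, function(i) refine_apex(tt, vv, i, refine_halfwidth_s),
         numeric(1))
}

# height above the higher of the two saddles separating the peak from
# higher terrain (or from the window edge)
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- v[seq_len(i - 1L)]
  right <- v[seq.int(i + 1L, length(v))]
  hl <- which(left > h); hr <- which(right > h)
  base_l <- if (length(hl)) min(left[seq.int(max(hl), i - 1L)]) else min(left)
  base_r <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
  h - max(base_l, base_r)
}

# least-squares parabola around the discrete argmax; falls back to the grid
# time when the fit is not concave
refine_apex <- function(tt, vv, i, halfwidth) {
  sel <- which(tt >= tt[i] - halfwidth & tt <= tt[i] + halfwidth)
  if (length(sel) < 3L) return(tt[i])
  ts_ <- tt[sel] - tt[i]
  fit <- stats::lm.fit(cbind(1, ts_, ts_^2), vv[sel])
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a >= 0) return(tt[i])
  apex <- -b / (2 * a)
  if (abs(apex) > halfwidth) return(tt[i])
  tt[i] + apex
}

#' Average offset between two event triplets
#'
#' The synchronization protocol produces exactly three paired events per
#' stream pair (three hand raises matched to three button presses; three
#' toe-stand head apexes matched to three forward COP apexes). The offset
#' between the two clocks is the arithmetic mean of the three per-event
#' time differences `reference_k - target_k`.
#'
#' @param reference_events Three event times on the reference clock,
#'   sorted, seconds.
#' @param target_events Three matching event times on the target clock.
#' @return List with `offset` (mean difference, seconds) and `per_event`
#'   (the three differences).
#' @export
estimate_offset <- function(reference_events, target_events) {
  if (length(reference_events) != 3L || length(target_events) != 3L)
    stop("the synchronization protocol fixes exactly 3 events per pair",
         call. = FALSE)
  if (is.unsorted(reference_events) || is.unsorted(target_events))
    stop("event times must be sorted", call. = FALSE)
  d <- reference_events - target_events
  list(offset = mean(d), per_event = d)
}

#' Estimate both inter-stream offsets of a session
#'
#' Runs the event-based synchronization: hand-raise apexes are detected on
#' the left hand's height coordinate (axis declared by the manifest) and
#' paired with the recorded button-press timestamps to give the
#' joint-vs-EMG offset; toe-stand apexes of head height are paired with
#' forward-COP apexes to give the joint-vs-COP offset. Detection is
#' restricted to the manifest's pre-trial synchronization window and runs
#' on each stream at its native rate with sub-sample apex refinement.
#'
#' @param session An `sts_session` (see [read_session()] /
#'   [generate_session()]).
#' @param prominence_frac,min_separation_s Peak-detection thresholds, see
#'   [detect_peaks()].
#' @return Object of class `sts_sync`: offsets `D_cj_emg` and `D_cj_cop`
#'   (seconds; add to the stream's local clock to obtain joint-clock time),
#'   the per-event differences, and the event times used.
#' @export
sync_session <- function(session, prominence_frac = 0.25,
                         min_separation_s = 1) {
  stopifnot(inherits(session, "sts_session"))
  win <- session$manifest$sync_window_s
  axis <- session$manifest$axis_map$hand_raise

  # light smoothing (~80 ms) before detection so single-sample sensor noise
  # cannot reach the prominence threshold; symmetric, so apexes don't shift
  smooth_vals <- function(v, rate) {
    keep <- !is.na(v)
    if (!all(keep)) v[!keep] <- stats::approx(which(keep), v[keep],
                                              xout = which(!keep),
                                              rule = 2)$y
    moving_average_vec(v, max(1L, round(0.04 * rate)))
  }
  skel_rate <- 1 / stats::median(diff(session$skel$time))

  hand <- skel_coord(session$skel, "left_hand", axis)
  hand_t <- detect_peaks(hand$time, smooth_vals(hand$values, skel_rate),
                         n = 3, prominence_frac = prominence_frac,
                         min_separation_s = min_separation_s, window = win)
  button_t <- sort(session$events$time[session$events$kind == "button"])
  if (length(button_t) != 3L)
    stop(sprintf("expected 3 button events, found %d", length(button_t)),
         call. = FALSE)
  emg <- estimate_offset(hand_t, button_t)

  head <- skel_coord(session$skel, "head", "y")
  head_t <- detect_peaks(head$time, smooth_vals(head$values, skel_rate),
                         n = 3, prominence_frac = prominence_frac,
                         min_separation_s = min_separation_s, window = win)
  ap <- ts_channel(session$cop, session$manifest$axis_map$cop_anterior)
  cop_t <- detect_peaks(ts_time(ap), smooth_vals(ap$values, ap$rate), n = 3,
                        prominence_frac = prominence_frac,
                        min_separation_s = min_separation_s, window = win)
  cop <- estimate_offset(head_t, cop_t)

  structure(list(D_cj_emg = emg$offset, D_cj_cop = cop$offset,
                 per_event_emg = emg$per_event, per_event_cop = cop$per_event,
                 events = list(hand_raise = hand_t, button = button_t,
                               toe_stand_head = head_t, toe_stand_cop = cop_t)),
            class = "sts_sync")
}

#' @export
print.sts_sync <- function(x, ...) {
  cat(sprintf("<sts_sync> D_cj,EMG = %.4f s  D_cj,COP = %.4f s\n",
              x$D_cj_emg, x$D_cj_cop))
  invisible(x)
}

#' Shift streams onto the joint-coordinate (master) clock
#'
#' Adds the estimated offsets to the EMG and COP clocks so that all three
#' streams share the skeleton stream's time base. Applying zero offsets is
#' the identity; applying then subtracting an offset restores the original
#' timestamps.
#'
#' @param session An `sts_session`.
#' @param sync An `sts_sync` from [sync_session()], or a list with numeric
#'   `D_cj_emg` and `D_cj_cop`.
#' @return The session with `emg_left`, `emg_right`, `cop` and the button
#'   event times shifted onto the master clock.
#' @export
apply_offsets <- function(session, sync) {
  stopifnot(inherits(session, "sts_session"))
  d_emg <- sync$D_cj_emg; d_cop <- sync$D_cj_cop
  if (!is.finite(d_emg) || !is.finite(d_cop))
    stop("offsets must be finite", call. = FALSE)
  session$emg_left$t0 <- session$emg_left$t0 + d_emg
  session$emg_right$t0 <- session$emg_right$t0 + d_emg
  session$cop$t0 <- session$cop$t0 + d_cop
  if (nrow(session$events))
    session$events$time <- session$events$time + d_emg
  session
}

#' Resample and synchronize a whole session
#'
#' The alignment stage of the pipeline: estimates the two inter-stream
#' offsets from the synchronization events, shifts the EMG and COP clocks
#' onto the skeleton clock, and resamples every stream to the master rate
#' (1000 Hz). Envelope extraction is performed on the native-rate EMG
#' before resampling would be irrelevant here: this function aligns
#' whatever channels it is given; feature code decides what to align.
#'
#' @param session An `sts_session`.
#' @param master_rate Target common rate, Hz (default 1000).
#' @return List: the aligned session (all streams at `master_rate`, master
#'   clock), the `sts_sync` used, and the native-rate skeleton (kept for
#'   the frame-based missing-data exclusion rule).
#' @export
align_session <- function(session, master_rate = 1000) {
  sync <- sync_session(session)
  shifted <- apply_offsets(session, sync)
  aligned <- shifted
  aligned$emg_left <- resample_to(shifted$emg_left, master_rate)
  aligned$emg_right <- resample_to(shifted$emg_right, master_rate)
  aligned$cop <- resample_to(shifted$cop, master_rate)
  aligned$skel <- resample_to(shifted$skel, master_rate)
  list(session = aligned, sync = sync, skel_native = shifted$skel)
}
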