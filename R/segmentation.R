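#' Segment the stand-up repetitions of one condition block
#'
#' Each repetition of a block runs sit-down, ~1 s pause, stand-up. The
#' stand-up epoch is delimited by the sitting instant — a local minimum of
#' pelvis height — and the standing instant — the subsequent local maximum
#' of head height. Both traces are lightly smoothed before extremum search
#' so frame-level sensor noise does not split an apex; extrema are located
#' with the same prominence/separation machinery used for synchronization,
#' with sub-sample refinement.
#'
#' @param pelvis_y `sts_ts` of pelvis height over the block, master clock.
#' @param head_y `sts_ts` of head height over the block, master clock.
#' @param n_reps Number of repetitions expected (default 3).
#' @param condition,jacket,subject Labels copied onto the returned epochs.
#' @param smooth_s Moving-average smoothing window (seconds) applied before
#'   extremum detection.
#' @param min_separation_s Minimum spacing between same-kind extrema.
#' @return Data frame of class `sts_epochs`: one row per repetition with
#'   `subject`, `condition`, `jacket`, `rep`, `start_s`, `end_s`,
#'   `excluded`, `reason`.
#' @export
segment_block <- function(pelvis_y, head_y, n_reps = 3,
                          condition = NA_character_, jacket = NA,
                          subject = NA_integer_,
                          smooth_s = 0.15, min_separation_s = 2) {
  stopifnot(inherits(pelvis_y, "sts_ts"), inherits(head_y, "sts_ts"))
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)

  Lp <- max(1L, round(smooth_s * pelvis_y$rate / 2))
  Lh <- max(1L, round(smooth_s * head_y$rate / 2))
  # missing frames are bridged by interpolation for extremum search only
  pel <- emg_moving_average(na_interp_ts(pelvis_y), Lp)
  hed <- emg_moving_average(na_interp_ts(head_y), Lh)

  sit <- tryCatch(
    detect_peaks(ts_time(pel), -pel$values, n = n_reps,
                 prominence_frac = 0.25, min_separation_s = min_separation_s),
    error = function(e) stop(sprintf(
      "sitting minima: %s", conditionMessage(e)), call. = FALSE))

  # standing instant: interior maximum of head height between this sitting
  # instant and the next (classic prominence is useless against the terminal
  # standing plateau, so the rule is applied as a windowed argmax)
  ends <- numeric(n_reps)
  ht <- ts_time(hed)
  for (k in seq_len(n_reps)) {
    upper <- if (k < n_reps) sit[k + 1L] else max(ht)
    sel <- which(ht > sit[k] & ht <= upper)
    if (length(sel) < 3L)
      stop(sprintf("no head samples between %.2f and %.2f s", sit[k], upper),
           call. = FALSE)
    im <- sel[which.max(hed$values[sel])]
    if (im <= sel[1] || im >= sel[length(sel)])
      stop(sprintf(
        "no interior standing maximum after t = %.2f s (head height monotone)",
        sit[k]), call. = FALSE)
    ends[k] <- refine_apex(ht, hed$values, im, 0.15)
  }
  if (any(ends <= sit))
    stop("standing instant precedes sitting instant", call. = FALSE)

  structure(data.frame(subject = subject, condition = condition,
                       jacket = jacket, rep = seq_len(n_reps),
                       start_s = sit, end_s = ends,
                       excluded = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("sts_epochs", "data.frame"))
}

#' Missing-data exclusion rule
#'
#' An epoch is discarded when the body-tracking output is unusable for at
#' least half of it: if the fraction of skeleton frames inside
#' `[start, end]` in which *every* joint is missing is >= 0.5, the epoch's
#' `excluded` flag is set and the reason recorded. Frames in which only
#' some joints are missing count as present for this rule (feature code
#' handles partial missingness per frame). The half threshold is
#' inclusive. The rule is evaluated on the native-rate skeleton, since
#' "frames" are camera frames.
#'
#' @param epoch One-row epoch data frame (or a row of an `sts_epochs`).
#' @param skel Native-rate `sts_skel` covering the epoch.
#' @return The epoch with `excluded`/`reason` updated.
#' @export
apply_exclusion <- function(epoch, skel) {
  stopifnot(inherits(skel, "sts_skel"))
  inside <- skel$time >= epoch$start_s & skel$time <= epoch$end_s
  n <- sum(inside)
  if (n == 0L) {
    epoch$excluded <- TRUE
    epoch$reason <- "no skeleton frames in epoch"
    return(epoch)
  }
  all_missing <- rowSums(!skel_missing(skel)[inside, , drop = FALSE]) == 0L
  frac <- mean(all_missing)
  if (frac >= 0.5) {
    epoch$excluded <- TRUE
    epoch$reason <- sprintf("all joints missing in %.0f%% of frames",
                            100 * frac)
  }
  epoch
}

#' Segment and screen every block of a session
#'
#' Runs [segment_block()] on each condition block declared in the manifest
#' and applies the missing-frame exclusion rule to every epoch.
#'
#' @param aligned An aligned session (element `session` of
#'   [align_session()]'s result).
#' @param skel_native The native-rate skeleton (for the exclusion rule).
#' @return `sts_epochs` data frame, one row per repetition of every block.
#' @export
segment_session <- function(aligned, skel_native) {
  blocks <- aligned$manifest$blocks
  skel <- aligned$skel
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    win <- c(blocks$start_s[b], blocks$end_s[b])
    pel <- crop_ts(skel_ts(skel, "pelvis", "y"), win)
    hed <- crop_ts(skel_ts(skel, "head", "y"), win)
    ep <- segment_block(pel, hed, n_reps = blocks$n_reps[b],
                        condition = blocks$condition[b],
                        jacket = blocks$jacket[b],
                        subject = aligned$manifest$subject_id)
    for (i in seq_len(nrow(ep))) ep[i, ] <- apply_exclusion(ep[i, ], skel_native)
    out[[b]] <- ep
  }
  res <- do.call(rbind, out)
  class(res) <- c("sts_epochs", "data.frame")
  res
}

# one joint axis of a (resampled, uniform) skeleton as an sts_ts
skel_ts <- function(skel, joint, axis = "y") {
  co <- skel_coord(skel, joint, axis)
  dt <- diff(co$time)
  rate <- 1 / stats::median(dt)
  sts_ts(co$values, rate, co$time[1])
}

na_interp_ts <- function(x) {
  v <- x$values
  if (!anyNA(v)) return(x)
  if (all(is.na(v))) stop("trace entirely missing", call. = FALSE)
  keep <- which(!is.na(v))
  tt <- ts_time(x)
  x$values <- stats::approx(tt[keep], v[keep], xout = tt, rule = 2)$y
  x
}

crop_ts <- function(x, window) {
  tt <- ts_time(x)
  keep <- tt >= window[1] & tt <= window[2]
  if (!any(keep)) stop("empty crop window", call. = FALSE)
  v <- if (is.matrix(x$values)) x$values[keep, , drop = FALSE] else x$values[keep]
  sts_ts(v, x$rate, tt[which(keep)[1]])
}
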