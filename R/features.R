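#' Integrated EMG over an epoch
#'
#' Trapezoidal time-integral of the normalized EMG envelope over
#' `[start, end]`, in percent-seconds. Integration uses the envelope's own
#' sample times, so the result is additive over any partition of the epoch
#' at sample boundaries.
#'
#' @param envelope Envelope `sts_ts` (0-100 scale, see [sts_envelope()]).
#' @param epoch One-row epoch data frame with `start_s`, `end_s`.
#' @return iEMG in %*s, nonnegative.
#' @export
iemg <- function(envelope, epoch) {
  seg <- epoch_samples(envelope, epoch)
  pracma::trapz(seg$time, seg$values)
}

#' Maximum EMG over an epoch
#'
#' Largest envelope sample inside `[start, end]`, in percent of the
#' recording's min-max range.
#'
#' @inheritParams iemg
#' @return Maximum envelope value in the epoch.
#' @export
max_emg <- function(envelope, epoch) {
  seg <- epoch_samples(envelope, epoch)
  max(seg$values)
}

epoch_samples <- function(x, epoch) {
  stopifnot(inherits(x, "sts_ts"))
  tt <- ts_time(x)
  keep <- tt >= epoch$start_s & tt <= epoch$end_s
  if (sum(keep) < 2L)
    stop(sprintf("epoch [%.3f, %.3f] s contains no samples of the stream",
                 epoch$start_s, epoch$end_s), call. = FALSE)
  list(time = tt[keep], values = x$values[keep])
}

#' Trunk flexion angle of a single pose
#'
#' Angle, in degrees, between the pelvis-to-neck segment and the world
#' vertical-up unit vector anchored at the pelvis: 0 for an upright trunk,
#' 90 for a horizontal one. Invariant to rotations about the vertical axis
#' and to uniform scaling of the skeleton.
#'
#' @param pelvis,neck Numeric 3-vectors `(x, y, z)`, y up.
#' @return Angle in `[0, 180]` degrees, or `NA` if either joint is missing
#'   or the two coincide.
#' @export
trunk_angle <- function(pelvis, neck) {
  if (anyNA(pelvis) || anyNA(neck)) return(NA_real_)
  v <- neck - pelvis
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NA_real_)
  ang <- acos(min(1, max(-1, v[2] / nv))) * 180 / pi
  min(180, max(0, ang))
}

#' Maximum trunk flexion angle over an epoch
#'
#' Largest per-frame [trunk_angle()] over the frames of `[start, end]` in
#' which both pelvis and neck are present; frames missing either joint are
#' skipped, not interpolated.
#'
#' @param skel An `sts_skel` covering the epoch.
#' @param epoch One-row epoch data frame with `start_s`, `end_s`.
#' @return Maximum angle in degrees, or `NA` (with a warning) when no
#'   frame has both joints.
#' @export
max_trunk_angle <- function(skel, epoch) {
  stopifnot(inherits(skel, "sts_skel"))
  inside <- which(skel$time >= epoch$start_s & skel$time <= epoch$end_s)
  if (!length(inside)) {
    warning("no skeleton frames in epoch; trunk angle missing")
    return(NA_real_)
  }
  ang <- vapply(inside, function(i)
    trunk_angle(skel$pos[i, "pelvis", ], skel$pos[i, "neck", ]), numeric(1))
  if (all(is.na(ang))) {
    warning("pelvis or neck missing in every frame of the epoch")
    return(NA_real_)
  }
  max(ang, na.rm = TRUE)
}

#' Mean anterior-posterior COP position over an epoch
#'
#' Arithmetic mean of the anterior-posterior COP coordinate across the
#' epoch's samples, in the board's length units (negative = posterior of
#' the board origin). The jacket comparison uses within-subject
#' differences, so the origin convention cancels.
#'
#' @param cop COP `sts_ts`; either single-channel or a matrix with an
#'   `ap` column.
#' @param epoch One-row epoch data frame with `start_s`, `end_s`.
#' @return Mean AP position.
#' @export
mean_cop_ap <- function(cop, epoch) {
  if (is.matrix(cop$values)) cop <- ts_channel(cop, "ap")
  seg <- epoch_samples(cop, epoch)
  mean(seg$values)
}

#' Assemble the per-epoch feature table
#'
#' Computes every feature for every retained (non-excluded) epoch of an
#' aligned, segmented session: left and right iEMG and maximum EMG from
#' the normalized envelopes, mean anterior-posterior COP, and maximum
#' trunk flexion angle. Excluded epochs are dropped from the table (their
#' rows remain in the epoch table with the exclusion reason).
#'
#' @param aligned Aligned session (element `session` of [align_session()]).
#' @param epochs `sts_epochs` table from [segment_session()].
#' @param cfg [emg_config()] used for envelope extraction.
#' @return Data frame with one row per retained epoch: `subject`,
#'   `condition`, `jacket`, `rep`, `iemg_left`, `iemg_right`,
#'   `max_emg_left`, `max_emg_right`, `mean_cop_ap`, `max_trunk_angle`.
#' @export
build_feature_table <- function(aligned, epochs, cfg = emg_config()) {
  env_l <- sts_envelope(aligned$emg_left, cfg)
  env_r <- sts_envelope(aligned$emg_right, cfg)
  skel <- aligned$skel
  keep <- which(!epochs$excluded)
  rows <- lapply(keep, function(i) {
    ep <- epochs[i, ]
    data.frame(subject = ep$subject, condition = ep$condition,
               jacket = ep$jacket, rep = ep$rep,
               iemg_left = iemg(env_l, ep), iemg_right = iemg(env_r, ep),
               max_emg_left = max_emg(env_l, ep),
               max_emg_right = max_emg(env_r, ep),
               mean_cop_ap = mean_cop_ap(aligned$cop, ep),
               max_trunk_angle = max_trunk_angle(skel, ep),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(subject = integer(0), condition = character(0),
                      jacket = logical(0), rep = integer(0),
                      iemg_left = numeric(0), iemg_right = numeric(0),
                      max_emg_left = numeric(0), max_emg_right = numeric(0),
                      mean_cop_ap = numeric(0), max_trunk_angle = numeric(0)))
  }
  do.call(rbind, rows)
}
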