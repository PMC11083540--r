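#' Simulation configuration for synthetic STS sessions
#'
#' Describes one recording session of the study protocol: a pre-trial
#' synchronization phase (three left-hand raises with button presses,
#' then three toe stands), followed by six condition blocks — the three
#' hand-support conditions, each performed with and without the weighted
#' maternity-simulation jacket — of `reps_per_condition` stand-ups each.
#' Streams are generated at the devices' native rates on their own clocks:
#' the EMG and COP clocks lag/lead the skeleton (master) clock by the
#' configured true offsets, which the alignment stage must recover.
#'
#' The jacket's effects are injected as known ground truth: EMG burst
#' amplitude multiplied by `jacket_iemg_multiplier`, anterior-posterior
#' COP baseline shifted by `jacket_cop_shift` (negative = posterior), and
#' maximum trunk flexion changed by `jacket_angle_delta` (default 0: the
#' jacket leaves the trunk angle unchanged). Two-hand conditions produce
#' EMG bursts with two activation peaks per rise (forward lean, then
#' extension); the one-hand condition produces one.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param reps_per_condition Stand-ups per block (default 3).
#' @param emg_rate,cop_rate,skel_rate Native sampling rates, Hz.
#' @param true_offset_emg,true_offset_cop Clock offsets in seconds: master
#'   time = stream-local time + offset.
#' @param jacket_iemg_multiplier Multiplicative EMG amplitude effect of
#'   the jacket (>= 1).
#' @param jacket_cop_shift Additive AP-COP effect, mm (negative =
#'   posterior).
#' @param jacket_angle_delta Additive trunk-angle effect, degrees.
#' @param emg_noise_sd Baseline EMG noise, arbitrary units (burst carrier
#'   has unit amplitude scale).
#' @param skel_noise_sd Per-coordinate skeleton noise, meters.
#' @param cop_noise_sd AP/ML COP noise, mm.
#' @param peak_count_map Named integer vector: activation peaks per rise
#'   for each condition.
#' @param cond_angle Named numeric vector: peak trunk flexion (degrees)
#'   per condition; the one-hand condition flexes least.
#' @param lr_asym_one_hand Right/left EMG amplitude ratio in the one-hand
#'   condition (right hand on the table loads the right side more).
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   byte-identical sessions.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       reps_per_condition = 3,
                       emg_rate = 1000, cop_rate = 100, skel_rate = 30,
                       true_offset_emg = 0.5, true_offset_cop = -0.3,
                       jacket_iemg_multiplier = 1.5,
                       jacket_cop_shift = -15,
                       jacket_angle_delta = 0,
                       emg_noise_sd = 0.05,
                       skel_noise_sd = 0.003,
                       cop_noise_sd = 2,
                       peak_count_map = c("both-hands-on-knees" = 2L,
                                          "one-hand-on-table" = 1L,
                                          "both-hands-on-table" = 2L),
                       cond_angle = c("both-hands-on-knees" = 42,
                                      "one-hand-on-table" = 30,
                                      "both-hands-on-table" = 40),
                       lr_asym_one_hand = 1.25,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, reps_per_condition = reps_per_condition,
              conditions = c("both-hands-on-knees", "one-hand-on-table",
                             "both-hands-on-table"),
              jacket_levels = c(FALSE, TRUE),
              emg_rate = emg_rate, cop_rate = cop_rate, skel_rate = skel_rate,
              true_offset_emg = true_offset_emg,
              true_offset_cop = true_offset_cop,
              jacket_iemg_multiplier = jacket_iemg_multiplier,
              jacket_cop_shift = jacket_cop_shift,
              jacket_angle_delta = jacket_angle_delta,
              emg_noise_sd = emg_noise_sd, skel_noise_sd = skel_noise_sd,
              cop_noise_sd = cop_noise_sd,
              peak_count_map = peak_count_map, cond_angle = cond_angle,
              lr_asym_one_hand = lr_asym_one_hand,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid configuration field `%s`: %s", field, why),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1, "n_subjects", ">= 1")
  chk(is.numeric(cfg$reps_per_condition) && cfg$reps_per_condition >= 1,
      "reps_per_condition", ">= 1")
  for (f in c("emg_rate", "cop_rate", "skel_rate"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] > 0, f, "must be positive")
  chk(cfg$emg_rate >= cfg$cop_rate && cfg$cop_rate >= cfg$skel_rate,
      "emg_rate", "rates must satisfy emg >= cop >= skel")
  chk(is.numeric(cfg$jacket_iemg_multiplier) &&
        cfg$jacket_iemg_multiplier >= 1, "jacket_iemg_multiplier", ">= 1")
  for (f in c("true_offset_emg", "true_offset_cop", "jacket_cop_shift",
              "jacket_angle_delta", "emg_noise_sd", "skel_noise_sd",
              "cop_noise_sd"))
    chk(is.numeric(cfg[[f]]) && is.finite(cfg[[f]]), f, "must be finite")
  chk(all(cfg$conditions %in% names(cfg$peak_count_map)) &&
        all(cfg$peak_count_map[cfg$conditions] %in% c(1L, 2L)),
      "peak_count_map", "each condition must map to 1 or 2 peaks")
  chk(all(cfg$conditions %in% names(cfg$cond_angle)), "cond_angle",
      "must name every condition")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed",
      "must be a single integer")
  invisible(cfg)
}

# gaussian bump and smoothstep ramp (0 -> 1 over [0, w]); building blocks of
# the deterministic kinematic/COP/EMG-envelope profiles, defined for all t
gbump <- function(t, center, sd) exp(-0.5 * ((t - center) / sd)^2)
sramp <- function(t, start, w) {
  u <- pmin(1, pmax(0, (t - start) / w))
  u * u * (3 - 2 * u)
}

# session timeline: sync gestures, block windows, per-epoch instants
session_timeline <- function(cfg) {
  hand_raises <- c(3, 6, 9)
  toe_stands <- c(13, 16, 19)
  sync_end <- 22
  reps <- cfg$reps_per_condition
  block_len <- reps * 7 + 2
  blocks <- expand.grid(condition = cfg$conditions,
                        jacket = cfg$jacket_levels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$jacket), ]  # no-jacket pattern first
  blocks$start_s <- sync_end + (seq_len(nrow(blocks)) - 1L) * block_len
  blocks$end_s <- blocks$start_s + block_len
  blocks$n_reps <- reps
  rownames(blocks) <- NULL
  epochs <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    sit <- blocks$start_s[b] + 4 + (seq_len(reps) - 1L) * 7
    data.frame(block = b, condition = blocks$condition[b],
               jacket = blocks$jacket[b], rep = seq_len(reps),
               start_s = sit, end_s = sit + 1.6, stringsAsFactors = FALSE)
  }))
  list(hand_raises = hand_raises, toe_stands = toe_stands,
       sync_window = c(0, sync_end), blocks = blocks, epochs = epochs,
       duration = blocks$end_s[nrow(blocks)] + 1.5)
}

#' Generate one synthetic multimodal STS session
#'
#' Produces the three sensor streams of one subject's session — bilateral
#' lumbar EMG at `emg_rate`, balance-board COP at `cop_rate`, and a
#' four-joint skeleton (pelvis, neck, head, left hand) at `skel_rate` —
#' plus the button-press event list and a ground-truth record. Pelvis
#' height shows a small settling dip at each sitting instant and head
#' height a small extension overshoot at each standing instant, so each
#' repetition has a unique extremum for the segmentation rule to find.
#' EMG bursts are Gaussian-windowed 5-30 Hz band-limited noise with one or
#' two activation peaks per rise depending on the condition.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject index (seeds the subject's random effects
#'   together with `config$seed`).
#' @return Object of class `sts_session` with elements `emg_left`,
#'   `emg_right`, `cop`, `skel`, `events`, `manifest`, and `ground_truth`
#'   (class `sts_truth`: true offsets, event times, epoch boundaries, and
#'   per-epoch true iEMG scales, mean AP COP, and peak trunk angle).
#' @export
generate_session <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  tl <- session_timeline(config)
  set.seed((config$seed * 1009L + as.integer(subject_id) * 7919L) %% 2147483629L)

  # subject-level random effects
  amp_subj <- stats::rlnorm(1, 0, 0.2)          # EMG amplitude scale
  cop_base <- 5 + stats::rnorm(1, 0, 3)         # mm anterior of origin
  angle_subj <- stats::rnorm(1, 0, 2.5)         # degrees
  weight <- stats::rnorm(1, 48.7, 4.8)          # kg

  ep <- tl$epochs
  n_ep <- nrow(ep)
  mult <- ifelse(ep$jacket, config$jacket_iemg_multiplier, 1)
  n_peaks <- config$peak_count_map[ep$condition]
  asym <- ifelse(ep$condition == "one-hand-on-table",
                 config$lr_asym_one_hand, 1)
  amp_left <- amp_subj * mult * stats::rlnorm(n_ep, 0, 0.1)
  amp_right <- amp_subj * mult * asym * stats::rlnorm(n_ep, 0, 0.1)
  angle_peak <- config$cond_angle[ep$condition] + angle_subj +
    ifelse(ep$jacket, config$jacket_angle_delta, 0) +
    stats::rnorm(n_ep, 0, 1)
  angle_peak <- pmax(5, angle_peak)
  tmid <- (ep$start_s + ep$end_s) / 2

  # ---- skeleton (master clock) -------------------------------------------
  ts_skel <- seq(0, tl$duration, by = 1 / config$skel_rate)
  stand_pelvis <- 0.95; sit_pelvis <- 0.45
  stand_head <- 1.55; sit_head <- 1.10
  base_profile <- function(t, hi, lo, up_lag = 0) {
    y <- rep(hi, length(t))
    for (k in seq_len(n_ep)) {
      y <- y + (lo - hi) * (sramp(t, ep$start_s[k] - 2.0, 1.2) -
                              sramp(t, ep$start_s[k] + up_lag,
                                    1.6 - up_lag))
    }
    y
  }
  pelvis_y <- base_profile(ts_skel, stand_pelvis, sit_pelvis)
  for (k in seq_len(n_ep))
    pelvis_y <- pelvis_y - 0.05 * gbump(ts_skel, ep$start_s[k], 0.12)
  head_y <- base_profile(ts_skel, stand_head, sit_head, up_lag = 0.05)
  for (k in seq_len(n_ep))
    head_y <- head_y + 0.04 * gbump(ts_skel, ep$end_s[k], 0.12)
  for (tk in tl$toe_stands)
    head_y <- head_y + 0.08 * gbump(ts_skel, tk, 0.25)

  theta <- rep(0, length(ts_skel))
  for (k in seq_len(n_ep))
    theta <- theta + angle_peak[k] * gbump(ts_skel, tmid[k], 0.35)
  theta_rad <- theta * pi / 180
  trunk_len <- 0.52
  neck_x <- rep(0, length(ts_skel))
  neck_y <- pelvis_y + trunk_len * cos(theta_rad)
  neck_z <- trunk_len * sin(theta_rad)

  hand_y <- rep(0.80, length(ts_skel))
  for (tk in tl$hand_raises)
    hand_y <- hand_y + 0.45 * gbump(ts_skel, tk, 0.3)

  nz <- function() stats::rnorm(length(ts_skel), 0, config$skel_noise_sd)
  pos <- array(NA_real_, dim = c(length(ts_skel), 4, 3),
               dimnames = list(NULL, c("pelvis", "neck", "head", "left_hand"),
                               c("x", "y", "z")))
  pos[, "pelvis", ] <- cbind(0 + nz(), pelvis_y + nz(), 0 + nz())
  pos[, "neck", ] <- cbind(neck_x + nz(), neck_y + nz(), neck_z + nz())
  pos[, "head", ] <- cbind(0 + nz(), head_y + nz(), 0.05 + nz())
  pos[, "left_hand", ] <- cbind(0.30 + nz(), hand_y + nz(), 0.10 + nz())
  skel <- sts_skel(ts_skel, pos)

  # ---- COP (its own clock: master = local + true_offset_cop) -------------
  ts_cop <- seq(0, tl$duration, by = 1 / config$cop_rate)
  ap_det <- function(t) {    # deterministic AP profile on the master clock
    y <- rep(cop_base, length(t))
    for (b in seq_len(nrow(tl$blocks))) {
      if (tl$blocks$jacket[b])
        y <- y + config$jacket_cop_shift *
          (t >= tl$blocks$start_s[b] & t < tl$blocks$end_s[b])
    }
    for (k in seq_len(n_ep)) y <- y + 25 * gbump(t, tmid[k], 0.30)
    for (tk in tl$toe_stands) y <- y + 40 * gbump(t, tk, 0.25)
    y
  }
  ap <- ap_det(ts_cop + config$true_offset_cop) +
    stats::rnorm(length(ts_cop), 0, config$cop_noise_sd)
  ml <- stats::rnorm(length(ts_cop), 0, config$cop_noise_sd)
  load_det <- weight + 7.2 * vapply(ts_cop + config$true_offset_cop,
                                    function(t) any(tl$blocks$jacket &
                                                      t >= tl$blocks$start_s &
                                                      t < tl$blocks$end_s),
                                    logical(1))
  load <- load_det + stats::rnorm(length(ts_cop), 0, 0.2)
  cop <- sts_ts(cbind(ap = ap, ml = ml, load = load), config$cop_rate, 0)

  # ---- EMG (its own clock: master = local + true_offset_emg) -------------
  ts_emg <- seq(0, tl$duration, by = 1 / config$emg_rate)
  t_master <- ts_emg + config$true_offset_emg
  burst_sd <- 0.18
  peak_times <- lapply(seq_len(n_ep), function(k) {
    if (n_peaks[k] == 1L) tmid[k]
    else c(ep$start_s[k] + 0.35, ep$end_s[k] - 0.25)
  })
  window_for <- function(amps) {
    w <- rep(0, length(t_master))
    for (k in seq_len(n_ep))
      for (tp in peak_times[[k]])
        w <- w + amps[k] * gbump(t_master, tp, burst_sd)
    w
  }
  bf <- signal::butter(4, c(5, 30) / (config$emg_rate / 2), type = "pass")
  carrier <- function() signal::filtfilt(bf, stats::rnorm(length(ts_emg))) * 4
  emg_left <- sts_ts(window_for(amp_left) * carrier() +
                       stats::rnorm(length(ts_emg), 0, config$emg_noise_sd),
                     config$emg_rate, 0)
  emg_right <- sts_ts(window_for(amp_right) * carrier() +
                        stats::rnorm(length(ts_emg), 0, config$emg_noise_sd),
                      config$emg_rate, 0)

  # button presses: exact timestamps on the EMG clock, at hand-raise apexes
  events <- data.frame(kind = "button",
                       time = tl$hand_raises - config$true_offset_emg,
                       stringsAsFactors = FALSE)

  # ---- ground truth -------------------------------------------------------
  cop_fine <- seq(0, tl$duration, by = 1e-3)
  ap_fine <- ap_det(cop_fine)
  truth_ep <- ep
  truth_ep$iemg_scale_left <- amp_left * as.integer(n_peaks)
  truth_ep$iemg_scale_right <- amp_right * as.integer(n_peaks)
  truth_ep$true_mean_cop <- vapply(seq_len(n_ep), function(k)
    mean(ap_fine[cop_fine >= ep$start_s[k] & cop_fine <= ep$end_s[k]]),
    numeric(1))
  truth_ep$true_max_angle <- angle_peak
  truth <- structure(list(true_offset_emg = config$true_offset_emg,
                          true_offset_cop = config$true_offset_cop,
                          hand_raises = tl$hand_raises,
                          toe_stands = tl$toe_stands,
                          buttons = tl$hand_raises,  # master-clock times
                          epochs = truth_ep),
                     class = "sts_truth")

  manifest <- list(subject_id = as.integer(subject_id),
                   rates = list(emg = config$emg_rate, cop = config$cop_rate,
                                skeleton = config$skel_rate),
                   units = list(skeleton = "m", cop = "mm", emg = "a.u."),
                   sync_window_s = tl$sync_window,
                   axis_map = list(vertical = "y", hand_raise = "y",
                                   cop_anterior = "ap"),
                   blocks = tl$blocks)

  structure(list(emg_left = emg_left, emg_right = emg_right, cop = cop,
                 skel = skel, events = events, manifest = manifest,
                 ground_truth = truth),
            class = "sts_session")
}

#' @export
print.sts_session <- function(x, ...) {
  cat(sprintf("<sts_session> subject %s: EMG %g Hz x2, COP %g Hz, skeleton %g Hz, %d blocks\n",
              x$manifest$subject_id, x$emg_left$rate, x$cop$rate,
              1 / stats::median(diff(x$skel$time)),
              nrow(x$manifest$blocks)))
  invisible(x)
}

#' Inject missing frames into a skeleton series
#'
#' Marks exactly `round(fraction * n_frames)` frames as missing, either
#' across every joint (`mode = "all-joints"`, the case the epoch-exclusion
#' rule counts) or in one randomly chosen joint per selected frame
#' (`mode = "random-joint"`).
#'
#' @param skel An `sts_skel`.
#' @param fraction Fraction of frames to alter, in `[0, 1]`.
#' @param mode `"all-joints"` or `"random-joint"`.
#' @param seed Integer seed for the frame choice.
#' @return The skeleton with the selected coordinates set to missing.
#' @export
inject_missing_frames <- function(skel, fraction,
                                  mode = c("all-joints", "random-joint"),
                                  seed = 1L) {
  stopifnot(inherits(skel, "sts_skel"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  n <- length(skel$time)
  k <- round(fraction * n)
  if (k == 0L) return(skel)
  set.seed(as.integer(seed))
  frames <- sample.int(n, k)
  if (mode == "all-joints") {
    skel$pos[frames, , ] <- NA_real_
  } else {
    joints <- sample(skel_joints(skel), k, replace = TRUE)
    for (i in seq_len(k)) skel$pos[frames[i], joints[i], ] <- NA_real_
  }
  skel
}

#' Simulate a per-epoch feature table directly
#'
#' Draws feature rows from the same effect structure the raw-signal
#' generator injects — subject random effects, condition-level means,
#' multiplicative jacket effect on EMG amplitude, additive jacket effects
#' on AP COP and trunk angle, right-side loading in the one-hand condition
#' — without synthesizing raw signals. This is the cohort model used for
#' large-replicate calibration studies (type-I error, power), where
#' thousands of cohorts are needed; full raw-signal sessions validate the
#' signal-processing stages on fewer replicates.
#'
#' @param n_subjects Subjects per cohort.
#' @param reps Repetitions per condition block.
#' @param cond_iemg,cond_max_emg,cond_angle Named per-condition means
#'   (iEMG in %*s, max EMG in %, angle in degrees).
#' @param jacket_iemg_multiplier,jacket_cop_shift,jacket_angle_delta
#'   Injected jacket effects (as in [sim_config()]).
#' @param lr_asym_one_hand Right/left EMG ratio in the one-hand condition.
#' @param seed Integer seed.
#' @return Feature table with the same columns as
#'   [build_feature_table()].
#' @export
simulate_feature_cohort <- function(n_subjects = 10, reps = 3,
                                    cond_iemg = c("both-hands-on-knees" = 60,
                                                  "one-hand-on-table" = 35,
                                                  "both-hands-on-table" = 55),
                                    cond_max_emg = c("both-hands-on-knees" = 65,
                                                     "one-hand-on-table" = 55,
                                                     "both-hands-on-table" = 62),
                                    cond_angle = c("both-hands-on-knees" = 42,
                                                   "one-hand-on-table" = 30,
                                                   "both-hands-on-table" = 40),
                                    jacket_iemg_multiplier = 1.5,
                                    jacket_cop_shift = -15,
                                    jacket_angle_delta = 0,
                                    lr_asym_one_hand = 1.25,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  conds <- names(cond_iemg)
  amp_subj <- stats::rlnorm(n_subjects, 0, 0.2)
  cop_subj <- 5 + stats::rnorm(n_subjects, 0, 4)
  angle_subj <- stats::rnorm(n_subjects, 0, 2.5)
  mult_subj <- stats::rlnorm(n_subjects, log(jacket_iemg_multiplier), 0.08)
  shift_subj <- jacket_cop_shift + stats::rnorm(n_subjects, 0, 3)

  g <- expand.grid(rep = seq_len(reps), jacket = c(FALSE, TRUE),
                   condition = conds, subject = seq_len(n_subjects),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(g)
  s <- g$subject
  asym <- ifelse(g$condition == "one-hand-on-table", lr_asym_one_hand, 1)
  m <- ifelse(g$jacket, mult_subj[s], 1)
  sh <- ifelse(g$jacket, shift_subj[s], 0)
  ad <- ifelse(g$jacket, jacket_angle_delta, 0)

  out <- data.frame(
    subject = s, condition = g$condition, jacket = g$jacket, rep = g$rep,
    iemg_left = cond_iemg[g$condition] * amp_subj[s] * m *
      stats::rlnorm(n, 0, 0.12),
    iemg_right = cond_iemg[g$condition] * amp_subj[s] * m * asym *
      stats::rlnorm(n, 0, 0.12),
    max_emg_left = pmin(100, cond_max_emg[g$condition] * amp_subj[s] * m *
                          stats::rlnorm(n, 0, 0.10)),
    max_emg_right = pmin(100, cond_max_emg[g$condition] * amp_subj[s] * m *
                           asym * stats::rlnorm(n, 0, 0.10)),
    mean_cop_ap = cop_subj[s] + sh + stats::rnorm(n, 0, 8),
    max_trunk_angle = cond_angle[g$condition] + angle_subj[s] + ad +
      stats::rnorm(n, 0, 2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Null-effect arguments for cohort simulation
#'
#' Convenience list of [simulate_feature_cohort()] arguments under the
#' global null: no jacket effects, no left-right asymmetry, identical
#' condition means. Used for type-I-error calibration.
#'
#' @return Named list of arguments to splice into
#'   [simulate_feature_cohort()].
#' @export
null_effects <- function() {
  flat <- function(v) stats::setNames(rep(mean(v), 3), names(v))
  defaults <- formals(simulate_feature_cohort)
  list(cond_iemg = flat(eval(defaults$cond_iemg)),
       cond_max_emg = flat(eval(defaults$cond_max_emg)),
       cond_angle = flat(eval(defaults$cond_angle)),
       jacket_iemg_multiplier = 1,
       jacket_cop_shift = 0,
       jacket_angle_delta = 0,
       lr_asym_one_hand = 1)
}
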