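#' Run the full analysis pipeline over a cohort of sessions
#'
#' For each session: estimate inter-stream offsets from the
#' synchronization events, resample everything to the 1000 Hz master
#' clock, segment the stand-up epochs of every condition block, apply the
#' missing-frame exclusion rule, and compute the per-epoch features. The
#' per-subject feature rows are pooled and the statistical battery run on
#' the cohort table. Optionally writes the feature table, epoch table,
#' statistics, sync results, and time-normalized per-epoch traces (the
#' data behind overlay plots) under `out_dir`.
#'
#' @param sessions List of `sts_session` objects, or a character vector of
#'   manifest paths to read.
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @param cfg [emg_config()] for envelope extraction.
#' @param master_rate Common rate after alignment, Hz.
#' @param unit Statistical analysis unit, see [run_sts_comparisons()].
#' @return List: `features`, `epochs`, `stats`, `sync` (per-session),
#'   `traces` (per-epoch 100-point z-scored overlays).
#' @export
run_pipeline <- function(sessions, out_dir = NULL, cfg = emg_config(),
                         master_rate = 1000, unit = "subject") {
  if (is.character(sessions)) sessions <- lapply(sessions, read_session)
  feats <- list(); eps <- list(); syncs <- list(); traces <- list()
  for (s in sessions) {
    al <- align_session(s, master_rate)
    epochs <- segment_session(al$session, al$skel_native)
    ft <- build_feature_table(al$session, epochs, cfg)
    subj <- s$manifest$subject_id
    feats[[length(feats) + 1L]] <- ft
    eps[[length(eps) + 1L]] <- epochs
    syncs[[as.character(subj)]] <- al$sync
    traces[[length(traces) + 1L]] <- epoch_traces(al$session, epochs, cfg)
  }
  features <- do.call(rbind, feats)
  epochs <- do.call(rbind, eps)
  stats_tab <- run_sts_comparisons(features, unit = unit)
  traces <- do.call(rbind, traces)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    data.table::fwrite(features, file.path(out_dir, "features.csv"))
    data.table::fwrite(as.data.frame(epochs),
                       file.path(out_dir, "epochs.csv"))
    data.table::fwrite(as.data.frame(stats_tab),
                       file.path(out_dir, "stats.csv"))
    data.table::fwrite(traces, file.path(out_dir, "traces.csv"))
    jsonlite::write_json(
      lapply(syncs, function(x) x[c("D_cj_emg", "D_cj_cop",
                                    "per_event_emg", "per_event_cop")]),
      file.path(out_dir, "sync.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(features = features, epochs = epochs, stats = stats_tab,
       sync = syncs, traces = traces)
}

# per-epoch 100-point overlays of right EMG envelope, board load and head
# height, each z-scored within the epoch for same-scale visual comparison
epoch_traces <- function(aligned, epochs, cfg) {
  env_r <- sts_envelope(aligned$emg_right, cfg)
  load <- ts_channel(aligned$cop, "load")
  head_y <- skel_ts(aligned$skel, "head", "y")
  head_y <- na_interp_ts(head_y)
  keep <- which(!epochs$excluded)
  out <- lapply(keep, function(i) {
    ep <- epochs[i, ]
    data.frame(subject = ep$subject, condition = ep$condition,
               jacket = ep$jacket, rep = ep$rep, pct = 1:100,
               emg_right = z_transform(time_normalize(env_r, ep)),
               load = z_transform(time_normalize(load, ep)),
               head_y = z_transform(time_normalize(head_y, ep)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic cohort of sessions
#'
#' Convenience wrapper producing one [generate_session()] per subject of
#' the configuration.
#'
#' @param config A [sim_config()].
#' @return List of `sts_session` objects, one per subject.
#' @export
simulate_cohort <- function(config = sim_config()) {
  lapply(seq_len(config$n_subjects), function(s)
    generate_session(config, subject_id = s))
}
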