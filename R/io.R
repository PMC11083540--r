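#' Write a session bundle to disk
#'
#' Serializes a session as inspectable delimited text plus a JSON
#' manifest: `emg.csv` (time + two channels), `cop.csv` (time, `ap`, `ml`,
#' `load`), `skeleton.csv` (time + `<joint>_<axis>` columns, missing
#' joints as empty fields), `events.csv`, and `manifest.json` describing
#' files, rates, units, the axis map, the synchronization window, and the
#' condition-block order with jacket flags. Values are written with full
#' double precision so a read-back reproduces the streams to at least nine
#' significant digits.
#'
#' @param session An `sts_session`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sts_session"))
  for (s in c("emg_left", "emg_right"))
    if (ts_length(session[[s]]) < 1L)
      stop(sprintf("empty stream '%s'", s), call. = FALSE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)

  emg <- data.frame(time_s = ts_time(session$emg_left),
                    left = session$emg_left$values,
                    right = session$emg_right$values)
  data.table::fwrite(emg, file.path(dir, "emg.csv"))

  cop <- data.frame(time_s = ts_time(session$cop), session$cop$values)
  data.table::fwrite(cop, file.path(dir, "cop.csv"))

  skel <- session$skel
  sk <- data.frame(time_s = skel$time)
  for (j in skel_joints(skel))
    for (ax in c("x", "y", "z"))
      sk[[paste0(j, "_", ax)]] <- skel$pos[, j, ax]
  data.table::fwrite(sk, file.path(dir, "skeleton.csv"), na = "")

  data.table::fwrite(session$events, file.path(dir, "events.csv"))

  man <- session$manifest
  man$streams <- list(
    emg = list(file = "emg.csv", rate_hz = session$emg_left$rate,
               columns = names(emg), units = man$units$emg),
    cop = list(file = "cop.csv", rate_hz = session$cop$rate,
               columns = names(cop), units = man$units$cop),
    skeleton = list(file = "skeleton.csv",
                    rate_hz = man$rates$skeleton,
                    columns = names(sk), units = man$units$skeleton))
  man$events_file <- "events.csv"
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a session bundle
#'
#' Loads the streams referenced by a session manifest, checking that every
#' referenced file exists, headers match the declared column schemas,
#' declared rates are positive, and skeleton timestamps increase strictly.
#' Empty skeleton fields come back as missing joints, never as zeros.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return An `sts_session` (without ground truth).
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' does not exist", manifest_path),
         call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)

  get_file <- function(name) {
    f <- file.path(dir, name)
    if (!file.exists(f))
      stop(sprintf("manifest references missing file '%s'", name),
           call. = FALSE)
    f
  }
  check_schema <- function(df, declared, name) {
    if (!identical(names(df), as.character(declared)))
      stop(sprintf("%s: header (%s) does not match declared schema (%s)",
                   name, paste(names(df), collapse = ","),
                   paste(declared, collapse = ",")), call. = FALSE)
  }
  check_rate <- function(r, name) {
    if (!is.numeric(r) || r <= 0)
      stop(sprintf("%s: declared rate must be positive", name),
           call. = FALSE)
  }

  st <- man$streams
  emg <- as.data.frame(data.table::fread(get_file(st$emg$file)))
  check_schema(emg, st$emg$columns, "emg.csv")
  check_rate(st$emg$rate_hz, "emg")
  if (any(diff(emg$time_s) <= 0))
    stop("emg.csv: timestamps not strictly increasing", call. = FALSE)
  emg_left <- sts_ts(emg$left, st$emg$rate_hz, emg$time_s[1])
  emg_right <- sts_ts(emg$right, st$emg$rate_hz, emg$time_s[1])

  copd <- as.data.frame(data.table::fread(get_file(st$cop$file)))
  check_schema(copd, st$cop$columns, "cop.csv")
  check_rate(st$cop$rate_hz, "cop")
  cop <- sts_ts(as.matrix(copd[-1]), st$cop$rate_hz, copd$time_s[1])

  skd <- as.data.frame(data.table::fread(get_file(st$skeleton$file),
                                         na.strings = ""))
  check_schema(skd, st$skeleton$columns, "skeleton.csv")
  check_rate(st$skeleton$rate_hz, "skeleton")
  if (any(diff(skd$time_s) <= 0))
    stop("skeleton.csv: timestamps not strictly increasing", call. = FALSE)
  joints <- unique(sub("_[xyz]$", "", names(skd)[-1]))
  pos <- array(NA_real_, dim = c(nrow(skd), length(joints), 3),
               dimnames = list(NULL, joints, c("x", "y", "z")))
  for (j in joints)
    for (ax in c("x", "y", "z"))
      pos[, j, ax] <- skd[[paste0(j, "_", ax)]]
  skel <- sts_skel(skd$time_s, pos)

  events <- as.data.frame(data.table::fread(get_file(man$events_file)))

  manifest <- list(subject_id = man$subject_id,
                   rates = man$rates, units = man$units,
                   sync_window_s = as.numeric(man$sync_window_s),
                   axis_map = man$axis_map,
                   blocks = as.data.frame(man$blocks))

  structure(list(emg_left = emg_left, emg_right = emg_right, cop = cop,
                 skel = skel, events = events, manifest = manifest,
                 ground_truth = NULL),
            class = "sts_session")
}

#' Validate a session bundle without loading it into the pipeline
#'
#' Runs the full manifest/file/schema validation of [read_session()] and
#' reports the outcome instead of returning the data.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return Invisibly `TRUE` on success; stops with a descriptive error
#'   otherwise.
#' @export
validate_session <- function(manifest_path) {
  s <- read_session(manifest_path)
  message(sprintf("session OK: subject %s, %d blocks, EMG %d samples, COP %d samples, skeleton %d frames",
                  s$manifest$subject_id, nrow(s$manifest$blocks),
                  ts_length(s$emg_left), ts_length(s$cop),
                  length(s$skel$time)))
  invisible(TRUE)
}
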