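# On-disk formats: a plain-text CSV bundle (one CSV per signal stream, a
# markers CSV and a meta JSON) holds a synchronized recording without any
# binary dependency; the ground-truth manifest of a synthetic session is
# JSON. Configs are YAML or JSON.

#' Write a recording as a CSV bundle
#'
#' Layout under `dir`: `<stream>.csv` (column `t` plus one column per
#' channel), `markers.csv`, `meta.json` (stream names, rates, labels,
#' start times), and for synthetic sessions `truth.json` with the
#' generative parameters and realized SNR.
#'
#' @param recording a `synthetic_session`, or a list with `streams` (named
#'   list of `signal_stream`s) and `markers`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(recording, "synthetic_session")) {
    streams <- list(eeg = recording$eeg, com = recording$kinematics)
    markers <- recording$markers
    truth <- recording$truth
    truth$com_step_displacement_m <- lapply(truth$com_step_displacement_m, as.numeric)
    jsonlite::write_json(c(unclass(truth), list(realized_snr = recording$snr)),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    streams <- recording$streams
    markers <- recording$markers
  }
  meta <- list(streams = lapply(streams, function(s) {
    list(name = s$name, fs_hz = s$fs_hz, start_time_s = s$start_time_s,
         channel_labels = s$channel_labels)
  }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    df <- data.frame(t = stream_times(s), t(s$samples))
    names(df) <- c("t", s$channel_labels)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(markers), file.path(dir, "markers.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a recording
#'
#' @param path directory of a CSV bundle written by
#'   [write_session_bundle()].
#' @param format only `"csv-bundle"` is supported; `"xdf"` raises an
#'   informative error (no XDF reader is bundled).
#' @return list `streams` (named list of `signal_stream`s), `markers`, and
#'   `truth` (NULL unless a `truth.json` is present).
#' @export
read_recording <- function(path, format = c("csv-bundle", "xdf")) {
  format <- match.arg(format)
  if (format == "xdf") {
    stop_invalid("XDF containers are not supported; export the recording as a CSV bundle")
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_invalid("no meta.json under '%s'", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mk_path <- file.path(path, "markers.csv")
  if (!file.exists(mk_path)) stop_invalid("missing marker stream (markers.csv) under '%s'", path)
  mk <- utils::read.csv(mk_path)
  markers <- marker_stream(mk$label, mk$timestamp_s, mk$trial_index, mk$block)
  streams <- list()
  for (nm in names(meta$streams)) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop_invalid("stream '%s' listed in meta.json but %s is missing", nm, f)
    df <- utils::read.csv(f, check.names = FALSE)
    info <- meta$streams[[nm]]
    labels <- unlist(info$channel_labels)
    if (!all(labels %in% names(df))) {
      stop_invalid("stream '%s' has an unknown layout: expected channels %s",
                   nm, paste(labels, collapse = ", "))
    }
    streams[[nm]] <- signal_stream(info$name, labels, info$fs_hz,
                                   info$start_time_s,
                                   t(as.matrix(df[, labels, drop = FALSE])))
  }
  truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  list(streams = streams, markers = markers, truth = truth)
}

#' Read a pipeline configuration
#'
#' YAML or JSON; unknown keys are kept. See [run_pipeline()] for the keys
#' that matter.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`, or a list passed
#'   through unchanged.
#' @return named list.
#' @export
read_config <- function(path) {
  if (is.list(path)) return(path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_invalid("config must be .yaml/.yml or .json: %s", path)
  }
}

#' Write a session schedule as CSV + JSON manifest
#'
#' @param session a `session_schedule`.
#' @param dir output directory.
#' @return `dir`, invisibly; writes `schedule.csv` (one row per trial) and
#'   `schedule_manifest.json` (seeds, break structure, step count).
#' @export
write_schedule <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session_trials(session), file.path(dir, "schedule.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    seed = session$seed, participant_index = session$participant_index,
    n_blocks = length(session$blocks),
    interblock_break_s = session$interblock_break_s,
    long_break_after_block = session$long_break_after_block,
    long_break_s = session$long_break_s,
    total_go_steps = session_step_count(session)
  ), file.path(dir, "schedule_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
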