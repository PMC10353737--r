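# Plain-text file dialects: per-subject raw recordings as paired CSVs plus a
# JSON sidecar, and feature cohorts as a single CSV.

#' Write a raw recording to disk
#'
#' Produces `<id>_emg.csv` (columns `time_s`, `TA_L`, `TA_R`, `LG_L`,
#' `LG_R`; microvolts), `<id>_events.csv` (columns `side`,
#' `heel_strike_time_s`) and `<id>_meta.json` (group, symptomatic side,
#' seed if known).
#'
#' @param rec A `raw_recording`.
#' @param dir Output directory (created if missing).
#' @param id Subject identifier used as file prefix; defaults to `rec$id`.
#' @param seed Optional seed to record in the metadata.
#' @return Invisibly, the three file paths.
#' @export
write_recording <- function(rec, dir, id = rec$id, seed = NULL) {
  stopifnot(inherits(rec, "raw_recording"), !is.null(id))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- rec$traces[[1]]$fs
  n <- length(rec$traces[[1]]$samples)
  emg <- data.frame(time_s = (seq_len(n) - 1) / fs,
                    TA_L = rec$traces$TA_left$samples,
                    TA_R = rec$traces$TA_right$samples,
                    LG_L = rec$traces$LG_left$samples,
                    LG_R = rec$traces$LG_right$samples)
  ev <- data.frame(
    side = rep(c("left", "right"),
               c(length(rec$events$left), length(rec$events$right))),
    heel_strike_time_s = c(rec$events$left, rec$events$right))
  paths <- file.path(dir, paste0(id, c("_emg.csv", "_events.csv", "_meta.json")))
  write.csv(emg, paths[1], row.names = FALSE)
  write.csv(ev, paths[2], row.names = FALSE)
  meta <- list(id = id, group = rec$group,
               symptomatic_side = rec$symptomatic_side,
               fs = fs, seed = seed)
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(paths)
}

#' Read a raw recording written by [write_recording()]
#'
#' @param dir Directory containing the files.
#' @param id Subject identifier (file prefix).
#' @return A `raw_recording`.
#' @export
read_recording <- function(dir, id) {
  paths <- file.path(dir, paste0(id, c("_emg.csv", "_events.csv", "_meta.json")))
  if (!all(file.exists(paths)))
    stop("missing recording files for subject ", id, " in ", dir)
  emg <- read.csv(paths[1])
  ev <- read.csv(paths[2])
  meta <- jsonlite::read_json(paths[3])
  fs <- meta$fs %||% round(1 / median(diff(emg$time_s)))
  traces <- list(
    TA_left = emg_trace(emg$TA_L, fs, "TA", "left"),
    TA_right = emg_trace(emg$TA_R, fs, "TA", "right"),
    LG_left = emg_trace(emg$LG_L, fs, "LG", "left"),
    LG_right = emg_trace(emg$LG_R, fs, "LG", "right"))
  structure(list(traces = traces,
                 events = gait_events(
                   ev$heel_strike_time_s[ev$side == "left"],
                   ev$heel_strike_time_s[ev$side == "right"]),
                 group = meta$group %||% NA_character_,
                 symptomatic_side = meta$symptomatic_side %||% NA_character_,
                 id = meta$id %||% id),
            class = "raw_recording")
}

#' Write / read a feature cohort CSV
#'
#' The cohort table has `subject_id`, `group` and the eight
#' [diff_feature_names()] columns.
#'
#' @param cohort Cohort `data.frame` (see [sample_feature_cohort()]).
#' @param path CSV file path.
#' @return `write_feature_cohort`: invisibly, `path`.
#' @export
write_feature_cohort <- function(cohort, path) {
  stopifnot(all(c("subject_id", "group", diff_feature_names()) %in%
                  names(cohort)))
  write.csv(cohort[, c("subject_id", "group", diff_feature_names())],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_cohort
#' @return `read_feature_cohort`: the cohort `data.frame` with `group`
#'   restored as a factor with levels [semg_classes()].
#' @export
read_feature_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", diff_feature_names()) %in% names(df)))
  df$group <- factor(df$group, levels = semg_classes())
  df
}
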