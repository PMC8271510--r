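# CSV / YAML input-output for recordings, annotations and cohorts.

#' Read a gyroscope recording CSV
#'
#' Expected dialect: comma-separated, "." decimal, header row with columns
#' `sample`, `t` (s), `gx`, `gy`, `gz` (deg/s) and, for a combined
#' two-sensor file, `sensor_id` (`wrist` / `humerus`). When `t` is absent
#' the sample index column provides the implicit time base at `1/fs`.
#'
#' @param path CSV file path (one sensor, or combined with `sensor_id`).
#' @param fs sampling rate (Hz).
#' @return a [sensor_pair()] for a combined file, otherwise a
#'   [gyro_trace()].
#' @export
read_gyro_csv <- function(path, fs = 128) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gx", "gy", "gz")
  if (!all(need %in% names(d))) {
    stop_qpass("missing gyroscope columns in %s", path,
               class = "qpass_input_error")
  }
  one <- function(dd, sensor_id) {
    t <- if ("t" %in% names(dd)) dd$t else (dd$sample - dd$sample[1]) / fs
    gyro_trace(dd$gx, dd$gy, dd$gz, t = t - t[1], sensor_id = sensor_id,
               fs = fs)
  }
  if ("sensor_id" %in% names(d)) {
    ids <- unique(d$sensor_id)
    if (length(ids) != 2L) {
      stop_qpass("combined file must hold exactly 2 sensors (found %d)",
                 length(ids), class = "qpass_input_error")
    }
    wrist_id <- if ("wrist" %in% ids) "wrist" else ids[1]
    other_id <- setdiff(ids, wrist_id)[1]
    sensor_pair(one(d[d$sensor_id == wrist_id, , drop = FALSE], wrist_id),
                one(d[d$sensor_id == other_id, , drop = FALSE], other_id))
  } else {
    one(d, "wrist")
  }
}

write_gyro_csv <- function(pair, path) {
  one <- function(tr) {
    data.frame(sensor_id = tr$sensor_id, sample = seq_len(tr$n) - 1L,
               t = tr$t, gx = tr$x, gy = tr$y, gz = tr$z)
  }
  utils::write.csv(rbind(one(pair$gyr1), one(pair$gyr2)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / validate a pass-annotation table
#'
#' Expected columns: `player_id`, `group`, `pass_type`, `target_id`,
#' `trial_index`, `start_sample`, `end_sample`, `accuracy` (an accuracy
#' penalty in `{0, 25, 50, 75, 100}`, or empty when ball-impact geometry is
#' supplied in a companion table via [attach_impact_accuracy()]).
#'
#' @param x CSV path or data.frame.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(x) {
  d <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("player_id", "group", "pass_type", "target_id", "trial_index",
            "start_sample", "end_sample")
  if (!is.data.frame(d) || !all(need %in% names(d))) {
    stop_qpass("annotations must contain columns: %s",
               paste(need, collapse = ", "), class = "qpass_annotation_error")
  }
  if (!"accuracy" %in% names(d)) d$accuracy <- NA_real_
  if (!all(d$pass_type %in% PASS_TYPES)) {
    stop_qpass("unknown pass types: %s",
               paste(unique(setdiff(d$pass_type, PASS_TYPES)), collapse = ", "),
               class = "qpass_annotation_error")
  }
  if (any(d$start_sample < 0) || any(d$end_sample <= d$start_sample)) {
    stop_qpass("annotation windows must satisfy 0 <= start < end",
               class = "qpass_annotation_error")
  }
  ok <- is.na(d$accuracy) | d$accuracy %in% c(0, 25, 50, 75, 100)
  if (!all(ok)) {
    stop_qpass("accuracy values must be in {0, 25, 50, 75, 100} or empty",
               class = "qpass_annotation_error")
  }
  key <- paste(d$player_id, d$pass_type, d$target_id, d$trial_index)
  if (anyDuplicated(key)) {
    stop_qpass("trial_index must be unique within (player, pass_type, target)",
               class = "qpass_annotation_error")
  }
  d
}

#' Fill accuracy categories from ball-impact geometry
#'
#' For annotations without a discrete accuracy value, computes the
#' inside-fraction of each ball print with [overlap_fraction()] and bins it
#' with [fraction_to_penalty()]. The impact table needs columns `player_id`,
#' `pass_type`, `target_id`, `trial_index`, `ball_x`, `ball_y`, `ball_r`,
#' `sq_x`, `sq_y`, `sq_side` (metres, target-plane coordinates).
#'
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param impacts ball-impact geometry data.frame or CSV path.
#' @param bin_edges passed to [fraction_to_penalty()].
#' @return the annotations with `accuracy` filled in.
#' @export
attach_impact_accuracy <- function(annotations, impacts,
                                   bin_edges = c(1 / 3, 2 / 3)) {
  if (is.character(impacts)) {
    impacts <- utils::read.csv(impacts, stringsAsFactors = FALSE)
  }
  key_a <- paste(annotations$player_id, annotations$pass_type,
                 annotations$target_id, annotations$trial_index)
  key_i <- paste(impacts$player_id, impacts$pass_type, impacts$target_id,
                 impacts$trial_index)
  for (r in which(is.na(annotations$accuracy))) {
    m <- match(key_a[r], key_i)
    if (is.na(m)) {
      stop_qpass("no accuracy evidence for pass %s", key_a[r],
                 class = "qpass_annotation_error")
    }
    fr <- overlap_fraction(impacts$ball_x[m], impacts$ball_y[m],
                           impacts$ball_r[m], impacts$sq_x[m],
                           impacts$sq_y[m], impacts$sq_side[m])
    touch <- impact_touches_boundary(impacts$ball_x[m], impacts$ball_y[m],
                                     impacts$ball_r[m], impacts$sq_x[m],
                                     impacts$sq_y[m], impacts$sq_side[m])
    annotations$accuracy[r] <- fraction_to_penalty(fr, touch, bin_edges)
  }
  annotations
}

#' Write a synthetic cohort to disk
#'
#' Writes one combined two-sensor CSV per recording under
#' `<dir>/recordings/`, plus `annotations.csv`, `truth.csv` and
#' `config_used.yaml` (including the seed) for provenance.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "qpass_cohort")) {
    stop_qpass("cohort must be a qpass_cohort", class = "qpass_input_error")
  }
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings)) {
    write_gyro_csv(cohort$recordings[[key]],
                   file.path(rec_dir, paste0(key, ".csv")))
  }
  utils::write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(
    list(n_players_per_group = cfg$n_players_per_group,
         pass_types = cfg$pass_types, trials_per_type = cfg$trials_per_type,
         fs = cfg$fs, seed = cfg$seed, player_spread = cfg$player_spread,
         group_params = lapply(cfg$group_params, function(g)
           lapply(g, function(v) if (is.null(names(v))) v else as.list(v)))),
    file.path(dir, "config_used.yaml"))
  invisible(dir)
}

#' Read the recordings of a cohort directory
#'
#' Loads every `<player>_<pass_type>.csv` under `<dir>/recordings/` (the
#' [write_cohort()] layout) into a named list of [sensor_pair()]s.
#'
#' @param dir cohort directory.
#' @param fs sampling rate (Hz).
#' @return named list of sensor pairs keyed `<player>_<pass_type>`.
#' @export
read_recordings <- function(dir, fs = 128) {
  rec_dir <- if (dir.exists(file.path(dir, "recordings"))) {
    file.path(dir, "recordings")
  } else {
    dir
  }
  files <- sort(list.files(rec_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_qpass("no recording CSVs found under %s", rec_dir,
               class = "qpass_input_error")
  }
  recs <- lapply(files, read_gyro_csv, fs = fs)
  names(recs) <- sub("\\.csv$", "", basename(files))
  recs
}

# md5 of the serialized object, via a temp file (tools::md5sum wants paths)
hash_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

write_run_log <- function(dir, command, config, inputs = character()) {
  input_hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(h)
  } else {
    list()
  }
  jsonlite::write_json(
    list(command = command, config = config, config_hash = hash_of(config),
         input_hashes = input_hashes,
         r_version = as.character(getRversion()),
         qpass_version = as.character(utils::packageVersion("qpass"))),
    file.path(dir, paste0(command, "_log.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
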