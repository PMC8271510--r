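# Pass-execution windowing and the rectangle-rule pattern integral.

#' The five pass types of the wall-target passing test
#'
#' chest (straight two-handed), bounce (one-handed after a bounce with the
#' dominant hand), crossover, between_the_leg and behind_the_back (one-handed
#' after a change of direction by the named dribble).
#'
#' @export
PASS_TYPES <- c("chest", "bounce", "crossover", "between_the_leg",
                "behind_the_back")

#' Annotate one executed pass
#'
#' A pass window starts when the player receives the ball and ends at ball
#' release; boundaries come from the annotation (video-derived in practice)
#' as 0-based half-open sample indices `[start_sample, end_sample)`, so the
#' sample count is exactly `end_sample - start_sample`.
#'
#' @param player_id,group,target_id labels.
#' @param pass_type one of [PASS_TYPES].
#' @param trial_index positive integer, unique within
#'   (player, pass_type, target).
#' @param start_sample,end_sample 0-based window bounds, start inclusive and
#'   end exclusive.
#' @param accuracy either an accuracy penalty in `{0, 25, 50, 75, 100}` or
#'   `NA` when ball-impact geometry is supplied separately.
#' @return An object of class `pass_event` (a named list).
#' @export
pass_event <- function(player_id, group, pass_type, target_id, trial_index,
                       start_sample, end_sample, accuracy = NA_real_) {
  pass_type <- match.arg(pass_type, PASS_TYPES)
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) {
    stop_qpass("trial_index must be a positive integer",
               class = "qpass_annotation_error")
  }
  start_sample <- as.integer(start_sample)
  end_sample <- as.integer(end_sample)
  if (is.na(start_sample) || is.na(end_sample) ||
      start_sample < 0L || end_sample <= start_sample) {
    stop_qpass("need 0 <= start_sample < end_sample",
               class = "qpass_annotation_error")
  }
  if (!is.na(accuracy) && !accuracy %in% c(0, 25, 50, 75, 100)) {
    stop_qpass("accuracy must be one of 0, 25, 50, 75, 100 (or NA)",
               class = "qpass_annotation_error")
  }
  structure(
    list(player_id = as.character(player_id), group = as.character(group),
         pass_type = pass_type, target_id = as.character(target_id),
         trial_index = trial_index, start_sample = start_sample,
         end_sample = end_sample, accuracy = as.numeric(accuracy)),
    class = "pass_event")
}

#' Extract the filtered magnitude window of one pass
#'
#' Filters the combined `|gyr1 + gyr2|` magnitude of the whole recording
#' (filtering before slicing avoids per-window edge transients) and restricts
#' it to the event's half-open window.
#'
#' @param pair a [sensor_pair()].
#' @param event a [pass_event()].
#' @param cutoff,order low-pass settings, see [lowpass_filter()].
#' @param magnitude optional pre-filtered combined-magnitude vector for the
#'   full recording, to avoid re-filtering when many events share a
#'   recording.
#' @return An object of class `pass_window`: list with `event`, `magnitude`
#'   (filtered values over the window), `n` (sample count) and `dt` (s).
#' @export
extract_window <- function(pair, event, cutoff = 25, order = 4,
                           magnitude = NULL) {
  if (!inherits(event, "pass_event")) {
    stop_qpass("event must be a pass_event", class = "qpass_input_error")
  }
  if (is.null(magnitude)) {
    if (!inherits(pair, "sensor_pair")) {
      stop_qpass("pair must be a sensor_pair", class = "qpass_input_error")
    }
    magnitude <- lowpass_filter(magnitude_series(pair)$value, fs = pair$fs,
                                cutoff = cutoff, order = order)
    fs <- pair$fs
  } else {
    fs <- if (inherits(pair, "sensor_pair")) pair$fs else attr(magnitude, "fs")
    if (is.null(fs)) {
      stop_qpass("supply a sensor_pair or a magnitude vector with an fs attribute",
                 class = "qpass_input_error")
    }
  }
  len <- length(magnitude)
  if (event$end_sample > len) {
    stop_qpass("event window [%d, %d) exceeds the %d-sample trace",
               event$start_sample, event$end_sample, len,
               class = "qpass_annotation_error")
  }
  idx <- (event$start_sample + 1L):event$end_sample
  structure(
    list(event = event, magnitude = as.numeric(magnitude[idx]),
         n = event$end_sample - event$start_sample, dt = 1 / fs),
    class = "pass_window")
}

#' Elapsed time of a pass window
#'
#' `n` samples at rate `fs` span `n / fs` seconds (the `n * (1/128) s` rule
#' at the default rate).
#'
#' @param n sample count (non-negative).
#' @param fs sampling rate (Hz).
#' @return duration in seconds.
#' @export
#' @examples
#' elapsed_time(128, 128) # 1 s
elapsed_time <- function(n, fs = 128) {
  if (any(!is.finite(n)) || any(n < 0)) {
    stop_qpass("n must be non-negative", class = "qpass_input_error")
  }
  if (fs <= 0) stop_qpass("fs must be positive", class = "qpass_input_error")
  n / fs
}

#' Rectangle-rule integral of the angular-velocity magnitude
#'
#' Approximates the area under the filtered `|gyr1 + gyr2|` curve of a pass
#' window as `dt * sum(values)` (left-endpoint rectangles). The result, in
#' degrees, is the per-execution movement-pattern summary compared against
#' the per-pass-type reference for the variability factor.
#'
#' @param x a `pass_window`, or a numeric vector of magnitude values.
#' @param ... passed on to methods.
#' @return the non-negative integral approximation (deg).
#' @export
integral_approx <- function(x, ...) UseMethod("integral_approx")

#' @rdname integral_approx
#' @param dt sampling interval (s) for the numeric-vector method.
#' @export
integral_approx.numeric <- function(x, dt, ...) {
  if (length(x) == 0L) {
    stop_qpass("window is empty", class = "qpass_input_error")
  }
  assert_finite(x, "magnitude values")
  if (!is.numeric(dt) || dt <= 0) {
    stop_qpass("dt must be positive", class = "qpass_input_error")
  }
  dt * sum(x)
}

#' @rdname integral_approx
#' @export
integral_approx.pass_window <- function(x, ...) {
  integral_approx(x$magnitude, dt = x$dt)
}
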