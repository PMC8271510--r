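# Data model and kinematic primitives for two-sensor gyroscope streams.

#' Construct a gyroscope trace
#'
#' A `gyro_trace` holds one sensor's 3-axis angular-velocity time series
#' sampled at a fixed rate. Axis convention for the arm sensors in upright
#' standing: Z anteroposterior, Y mediolateral, X aligned with gravity.
#'
#' @param x,y,z numeric vectors of angular velocity about each axis (deg/s).
#' @param t optional numeric vector of sample times (s). When omitted, a
#'   uniform time base `(0, 1/fs, 2/fs, ...)` is built. When supplied it must
#'   be uniformly spaced at `1/fs` within a relative tolerance of `1e-6`.
#' @param sensor_id sensor label, typically `"wrist"` or `"humerus"`.
#' @param fs sampling rate in Hz (default 128, the rate of the arm-worn
#'   devices the score was designed around).
#'
#' @return An object of class `gyro_trace`: a list with elements
#'   `sensor_id`, `fs`, `t`, `x`, `y`, `z` and `n` (number of samples).
#' @export
#' @examples
#' tr <- gyro_trace(x = rnorm(16), y = rnorm(16), z = rnorm(16))
#' tr$n
gyro_trace <- function(x, y, z, t = NULL, sensor_id = "wrist", fs = 128) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_qpass("fs must be a positive number", class = "qpass_input_error")
  }
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n) {
    stop_qpass("x, y, z must be non-empty vectors of equal length",
               class = "qpass_input_error")
  }
  assert_finite(x, "x"); assert_finite(y, "y"); assert_finite(z, "z")
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / fs
  } else {
    if (length(t) != n) {
      stop_qpass("t must have one entry per sample",
                 class = "qpass_input_error")
    }
    assert_finite(t, "t")
    if (any(t < 0)) {
      stop_qpass("sample times must be non-negative",
                 class = "qpass_input_error")
    }
    if (n > 1L) {
      dt <- diff(t)
      if (any(abs(dt - 1 / fs) > 1e-6 / fs)) {
        stop_qpass(
          "sample times are not uniformly spaced at 1/fs (traces are rejected rather than resampled)",
          class = "qpass_alignment_error")
      }
    }
  }
  structure(
    list(sensor_id = as.character(sensor_id), fs = fs,
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), n = n),
    class = "gyro_trace")
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf("<gyro_trace> sensor '%s', %d samples @ %g Hz (%.3f s)\n",
              x$sensor_id, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' Pair the wrist and humerus traces of one recording
#'
#' Both traces must have the same length and sampling rate, and their time
#' stamps must agree within half a sample period.
#'
#' @param gyr1 `gyro_trace` of the wrist sensor.
#' @param gyr2 `gyro_trace` of the humerus sensor.
#' @return An object of class `sensor_pair` with elements `gyr1`, `gyr2`,
#'   `fs` and `n`.
#' @export
sensor_pair <- function(gyr1, gyr2) {
  if (!inherits(gyr1, "gyro_trace") || !inherits(gyr2, "gyro_trace")) {
    stop_qpass("both arguments must be gyro_trace objects",
               class = "qpass_input_error")
  }
  if (gyr1$n != gyr2$n) {
    stop_qpass("traces differ in length (%d vs %d)", gyr1$n, gyr2$n,
               class = "qpass_alignment_error")
  }
  if (gyr1$fs != gyr2$fs) {
    stop_qpass("traces differ in sampling rate", class = "qpass_alignment_error")
  }
  if (any(abs(gyr1$t - gyr2$t) > 1 / (2 * gyr1$fs))) {
    stop_qpass("trace time stamps differ by more than half a sample period",
               class = "qpass_alignment_error")
  }
  structure(list(gyr1 = gyr1, gyr2 = gyr2, fs = gyr1$fs, n = gyr1$n),
            class = "sensor_pair")
}

#' Resultant angular speed of a 3-axis sample
#'
#' Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the angular-velocity vector,
#' vectorised over samples.
#'
#' @param x,y,z angular-velocity components (deg/s).
#' @return non-negative angular speed(s) in deg/s.
#' @export
#' @examples
#' resultant_magnitude(3, 4, 0) # 5
resultant_magnitude <- function(x, y, z) {
  assert_finite(x, "x"); assert_finite(y, "y"); assert_finite(z, "z")
  sqrt(x^2 + y^2 + z^2)
}

#' Magnitude of the vector sum of two gyroscope samples
#'
#' Adds the two sensors' angular-velocity vectors componentwise and returns
#' the Euclidean norm of the sum, `|gyr1 + gyr2|`. Accepts length-3 vectors
#' `c(x, y, z)` or equal-length component vectors stacked in 3-column
#' matrices. When time stamps are supplied they must agree within `tol`.
#'
#' @param s1,s2 numeric length-3 vectors or n-by-3 matrices of components.
#' @param t1,t2 optional sample times (s) used only for an alignment check.
#' @param tol time alignment tolerance in seconds.
#' @return non-negative magnitude(s) of the componentwise sum (deg/s).
#' @export
#' @examples
#' sum_magnitude(c(1, 0, 0), c(-1, 0, 0)) # opposite vectors cancel
sum_magnitude <- function(s1, s2, t1 = NULL, t2 = NULL, tol = 1e-6) {
  if (!is.null(t1) || !is.null(t2)) {
    if (is.null(t1) || is.null(t2) || any(abs(t1 - t2) > tol)) {
      stop_qpass("sample time stamps are misaligned",
                 class = "qpass_alignment_error")
    }
  }
  as_mat <- function(s) {
    if (is.matrix(s)) {
      if (ncol(s) != 3L) stop_qpass("component matrices need 3 columns",
                                    class = "qpass_input_error")
      s
    } else {
      if (length(s) != 3L) stop_qpass("samples must have 3 components",
                                      class = "qpass_input_error")
      matrix(s, ncol = 3L)
    }
  }
  m1 <- as_mat(s1); m2 <- as_mat(s2)
  assert_finite(m1, "components"); assert_finite(m2, "components")
  if (nrow(m1) != nrow(m2)) {
    stop_qpass("sample counts differ", class = "qpass_alignment_error")
  }
  s <- m1 + m2
  out <- sqrt(rowSums(s^2))
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

#' Combined-magnitude series of a sensor pair
#'
#' Computes `|gyr1 + gyr2|` per sample over a whole recording: the pattern
#' signal the variability factor is built from.
#'
#' @param pair a [sensor_pair()].
#' @return A data.frame with columns `t` (s) and `value` (deg/s), one row per
#'   sample.
#' @export
magnitude_series <- function(pair) {
  if (!inherits(pair, "sensor_pair")) {
    stop_qpass("pair must be a sensor_pair", class = "qpass_input_error")
  }
  v <- sum_magnitude(cbind(pair$gyr1$x, pair$gyr1$y, pair$gyr1$z),
                     cbind(pair$gyr2$x, pair$gyr2$y, pair$gyr2$z))
  data.frame(t = pair$gyr1$t, value = as.numeric(v))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass design (default: 4th order, 25 Hz cut-off)
#' forward and backward, so the output has zero phase lag and event timing is
#' preserved; the effective magnitude response is the square of a single
#' pass. Edges are handled by odd-reflective padding of length
#' `3 * (order + 1)` on each side, which suppresses start/end transients on
#' short recordings.
#'
#' @param x numeric series to filter.
#' @param fs sampling rate (Hz).
#' @param cutoff cut-off frequency (Hz); must be below the Nyquist rate.
#' @param order filter order of a single pass.
#' @return filtered series, same length as `x`.
#' @export
#' @examples
#' lowpass_filter(rep(7, 256), fs = 128)[1:3] # DC passes unchanged
lowpass_filter <- function(x, fs, cutoff = 25, order = 4) {
  if (!is.numeric(fs) || fs <= 0) {
    stop_qpass("fs must be positive", class = "qpass_config_error")
  }
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop_qpass("filter cutoff must lie in (0, fs/2)", class = "qpass_config_error")
  }
  assert_finite(x, "series")
  pad <- 3L * (as.integer(order) + 1L)
  n <- length(x)
  if (n <= pad) {
    stop_qpass("series too short to filter (need more than %d samples)", pad,
               class = "qpass_input_error")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # one pass anchored at its first value, so the zero-state start of the IIR
  # recursion sees no step (the design has unit DC gain)
  one_pass <- function(v) {
    as.numeric(signal::filter(bf, v - v[1])) + v[1]
  }
  # odd reflection about the end points
  xt <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- one_pass(xt)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}
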