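# The three penalty factors: f1 accuracy, f2 time, f3 variability.

#' Accuracy penalty of a pass (factor f1)
#'
#' Maps the discrete accuracy evidence of one pass to its penalty. The five
#' admissible penalties are 0 (the ball hits fully inside the target square
#' without touching a boundary line), 25 (most of the impact area inside),
#' 50 (about half in, half out, boundary lines included), 75 (most of it
#' outside) and 100 (completely outside the boundary lines).
#'
#' @param category either a numeric penalty already in
#'   `{0, 25, 50, 75, 100}` (returned as-is) or one of the labels
#'   `"perfect"`, `"mostly_in"`, `"half"`, `"mostly_out"`, `"miss"`.
#' @return penalty value(s) in `{0, 25, 50, 75, 100}`.
#' @export
#' @examples
#' accuracy_penalty("perfect")     # 0
#' accuracy_penalty(c(50, 100))    # passthrough of valid codes
accuracy_penalty <- function(category) {
  codes <- c(perfect = 0, mostly_in = 25, half = 50, mostly_out = 75,
             miss = 100)
  if (is.numeric(category)) {
    if (!all(category %in% codes)) {
      stop_qpass("numeric accuracy categories must be in {0, 25, 50, 75, 100}",
                 class = "qpass_annotation_error")
    }
    return(as.numeric(category))
  }
  if (!all(category %in% names(codes))) {
    stop_qpass("unknown accuracy category '%s'",
               paste(setdiff(category, names(codes)), collapse = ", "),
               class = "qpass_annotation_error")
  }
  unname(codes[as.character(category)])
}

# area of the intersection of a circle (centred at cx, cy, radius r) with an
# axis-aligned rectangle [x1, x2] x [y1, y2]; exact up to quadrature on
# smooth pieces split at the points where the circle crosses y1 or y2
circle_rect_area <- function(cx, cy, r, x1, x2, y1, y2) {
  # shift circle to origin
  x1 <- x1 - cx; x2 <- x2 - cx; y1 <- y1 - cy; y2 <- y2 - cy
  # fully inside the rectangle
  if (x1 <= -r && x2 >= r && y1 <= -r && y2 >= r) return(pi * r^2)
  xa <- max(x1, -r); xb <- min(x2, r)
  if (xa >= xb || y1 >= r || y2 <= -r) return(0)
  chord <- function(x) {
    h <- sqrt(pmax(r^2 - x^2, 0))
    pmax(pmin(y2, h) - pmax(y1, -h), 0)
  }
  cuts <- c(xa, xb)
  for (y in c(y1, y2)) {
    if (abs(y) < r) {
      xc <- sqrt(r^2 - y^2)
      cuts <- c(cuts, -xc, xc)
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, xa), xb)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    if (cuts[i + 1L] - cuts[i] < 1e-14) next
    total <- total + stats::integrate(chord, cuts[i], cuts[i + 1L],
                                      rel.tol = 1e-10,
                                      subdivisions = 200L)$value
  }
  total
}

#' Fraction of the ball surface inside the target square
#'
#' Geometric stand-in for manual video scoring of the ball impact: the ball
#' print is modelled as a circle on the target plane and the target as an
#' axis-aligned square (the standard wall target is 0.61 m x 0.61 m), and the
#' fraction of the circle area falling in the square interior is returned.
#'
#' @param ball_x,ball_y centre of the ball print (m, target-plane
#'   coordinates).
#' @param ball_r ball-print radius (m), positive.
#' @param sq_x,sq_y lower-left corner of the target square (m).
#' @param sq_side side length of the square (m), positive.
#' @return fraction of the circle area inside the square, in `[0, 1]`.
#' @export
#' @examples
#' overlap_fraction(0.3, 0.3, 0.1, 0, 0, 0.61) # fully inside -> 1
overlap_fraction <- function(ball_x, ball_y, ball_r, sq_x, sq_y, sq_side) {
  if (!is.finite(ball_r) || ball_r <= 0 || !is.finite(sq_side) || sq_side <= 0) {
    stop_qpass("ball radius and square side must be positive",
               class = "qpass_geometry_error")
  }
  assert_finite(c(ball_x, ball_y, sq_x, sq_y), "impact coordinates")
  a <- circle_rect_area(ball_x, ball_y, ball_r,
                        sq_x, sq_x + sq_side, sq_y, sq_y + sq_side)
  min(max(a / (pi * ball_r^2), 0), 1)
}

#' Does the ball print touch the square's boundary lines?
#'
#' TRUE when the circle intersects the boundary curve of the square; a pass
#' whose ball print is fully inside but touches a line cannot earn the
#' perfect penalty 0.
#'
#' @inheritParams overlap_fraction
#' @return logical flag.
#' @export
impact_touches_boundary <- function(ball_x, ball_y, ball_r, sq_x, sq_y,
                                    sq_side) {
  x1 <- sq_x; x2 <- sq_x + sq_side; y1 <- sq_y; y2 <- sq_y + sq_side
  inside <- ball_x >= x1 && ball_x <= x2 && ball_y >= y1 && ball_y <= y2
  if (inside) {
    d <- min(ball_x - x1, x2 - ball_x, ball_y - y1, y2 - ball_y)
    return(d <= ball_r)
  }
  dx <- max(x1 - ball_x, 0, ball_x - x2)
  dy <- max(y1 - ball_y, 0, ball_y - y2)
  sqrt(dx^2 + dy^2) <= ball_r
}

#' Map an inside-fraction to the discrete accuracy penalty
#'
#' Operationalises the verbal accuracy bins on the inside-fraction scale:
#' penalty 0 only for a full hit that touches no boundary line, 25 for
#' "most of the area inside" (fraction at least `bin_edges[2]`), 50 for the
#' half-and-half band, 75 for "most of it outside" (positive fraction up to
#' `bin_edges[1]`) and 100 for a complete miss.
#'
#' @param frac inside fraction in `[0, 1]`, e.g. from [overlap_fraction()].
#' @param touches_boundary logical; did the ball print touch a boundary line?
#' @param bin_edges two increasing numbers in (0, 1) separating the
#'   mostly-out / half / mostly-in bands (default `c(1/3, 2/3)`).
#' @return penalty in `{0, 25, 50, 75, 100}`, monotone non-increasing
#'   quality in `frac`.
#' @export
#' @examples
#' fraction_to_penalty(1, touches_boundary = FALSE) # 0
#' fraction_to_penalty(0.5)                         # 50
fraction_to_penalty <- function(frac, touches_boundary = FALSE,
                                bin_edges = c(1 / 3, 2 / 3)) {
  if (length(bin_edges) != 2L || any(!is.finite(bin_edges)) ||
      bin_edges[1] <= 0 || bin_edges[2] >= 1 || bin_edges[1] >= bin_edges[2]) {
    stop_qpass("bin_edges must be two increasing numbers inside (0, 1)",
               class = "qpass_config_error")
  }
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    stop_qpass("frac must lie in [0, 1]", class = "qpass_input_error")
  }
  touches_boundary <- rep_len(as.logical(touches_boundary), length(frac))
  out <- numeric(length(frac))
  for (i in seq_along(frac)) {
    f <- frac[i]
    out[i] <- if (f == 0) 100
      else if (f == 1 && !touches_boundary[i]) 0
      else if (f >= bin_edges[2]) 25
      else if (f > bin_edges[1]) 50
      else 75
  }
  out
}

#' Reference execution time Ex_Tr from a reference group
#'
#' The reference execution time is the mean pass duration (in samples) of
#' the quickest pass type among the reference group's executions, rounded to
#' the nearest integer sample count. A pass lasting exactly the reference
#' earns a zero time penalty.
#'
#' @param windows a data.frame with columns `pass_type` and `n` (window
#'   sample counts), one row per executed pass of the reference group.
#' @return reference time in samples (integer-valued numeric).
#' @export
time_reference <- function(windows) {
  if (!is.data.frame(windows) || nrow(windows) == 0L ||
      !all(c("pass_type", "n") %in% names(windows))) {
    stop_qpass("need a non-empty data.frame with pass_type and n columns",
               class = "qpass_reference_error")
  }
  means <- tapply(windows$n, windows$pass_type, mean)
  round_half_up(min(means))
}

#' Raw time penalty of one pass (factor f2)
#'
#' Absolute deviation of the pass duration from the reference execution
#' time, counted in samples and rounded to the nearest natural number.
#'
#' @param n pass duration in samples.
#' @param ex_tr reference execution time in samples.
#' @return non-negative integer-valued penalty.
#' @export
#' @examples
#' time_penalty_raw(77, 64) # 13
time_penalty_raw <- function(n, ex_tr) {
  if (any(!is.finite(n)) || any(n < 0) || any(!is.finite(ex_tr)) ||
      any(ex_tr < 0)) {
    stop_qpass("n and ex_tr must be non-negative", class = "qpass_input_error")
  }
  round_half_up(abs(n - ex_tr))
}

#' Per-pass-type variability references ExPT_ir
#'
#' For each pass type, the mean of the rectangle-rule pattern integrals over
#' the reference group's executions of that type. There is one reference per
#' pass type; an execution whose integral equals its type's reference earns
#' a zero variability penalty.
#'
#' @param windows a data.frame with columns `pass_type` and `integral`
#'   (deg), one row per executed pass of the reference group.
#' @return named numeric vector mapping pass type to its reference integral.
#' @export
variability_reference <- function(windows) {
  if (!is.data.frame(windows) || nrow(windows) == 0L ||
      !all(c("pass_type", "integral") %in% names(windows))) {
    stop_qpass("need a non-empty data.frame with pass_type and integral columns",
               class = "qpass_reference_error")
  }
  means <- tapply(windows$integral, windows$pass_type, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Raw variability penalty of one pass (factor f3)
#'
#' Absolute deviation of the pass's pattern integral from its pass type's
#' reference, rounded to the nearest natural number.
#'
#' @param integral pattern integral of the pass (deg).
#' @param expt_ir_value reference integral of the same pass type (deg).
#' @return non-negative integer-valued penalty.
#' @export
variability_penalty_raw <- function(integral, expt_ir_value) {
  if (any(!is.finite(integral)) || any(integral < 0) ||
      any(!is.finite(expt_ir_value)) || any(expt_ir_value < 0)) {
    stop_qpass("integral and reference must be non-negative",
               class = "qpass_input_error")
  }
  round_half_up(abs(integral - expt_ir_value))
}

#' Normalise raw penalties to the 0-100 range
#'
#' Rescales a pool of raw penalties proportionally so the maximum penalty
#' maps to exactly 100 and zero stays at zero. An all-zero pool (a cohort of
#' perfect executions) normalises to all zeros rather than dividing by zero.
#'
#' @param raw non-negative raw penalties.
#' @return penalties rescaled into `[0, 100]`, order-preserving.
#' @export
#' @examples
#' normalize_penalties(c(0, 5, 10)) # 0 50 100
normalize_penalties <- function(raw) {
  if (length(raw) == 0L) {
    stop_qpass("penalty pool is empty", class = "qpass_input_error")
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop_qpass("raw penalties must be non-negative", class = "qpass_input_error")
  }
  mx <- max(raw)
  if (mx == 0) return(rep(0, length(raw)))
  raw * 100 / mx
}

#' Bundle the cohort references for time and variability
#'
#' A cohort reference freezes the quantities new executions are penalised
#' against: the reference execution time (samples) and the five per-pass-type
#' variability integrals, together with the provenance needed to reuse it on
#' another cohort (source group, sampling rate, filter settings).
#'
#' @param ex_tr_samples reference execution time in samples.
#' @param expt_ir named numeric vector of per-pass-type reference integrals.
#' @param source_group label of the group the references came from.
#' @param fs sampling rate (Hz) the references were computed at.
#' @param filter list with `cutoff_hz` and `order` of the low-pass used.
#' @return object of class `cohort_reference`.
#' @export
cohort_reference <- function(ex_tr_samples, expt_ir, source_group = "A",
                             fs = 128,
                             filter = list(cutoff_hz = 25, order = 4)) {
  if (!is.finite(ex_tr_samples) || ex_tr_samples < 0) {
    stop_qpass("ex_tr_samples must be non-negative",
               class = "qpass_reference_error")
  }
  if (is.null(names(expt_ir)) || any(!is.finite(expt_ir)) || any(expt_ir < 0)) {
    stop_qpass("expt_ir must be a named vector of non-negative references",
               class = "qpass_reference_error")
  }
  structure(
    list(ex_tr_samples = as.numeric(ex_tr_samples),
         expt_ir = expt_ir[order(match(names(expt_ir), PASS_TYPES))],
         source_group = as.character(source_group), fs = fs, filter = filter),
    class = "cohort_reference")
}

#' @export
print.cohort_reference <- function(x, ...) {
  cat(sprintf("<cohort_reference> from group '%s' @ %g Hz\n",
              x$source_group, x$fs))
  cat(sprintf("  Ex_Tr: %g samples (%.3f s)\n", x$ex_tr_samples,
              x$ex_tr_samples / x$fs))
  cat("  ExPT_ir (deg):\n")
  for (nm in names(x$expt_ir)) cat(sprintf("    %-16s %.2f\n", nm, x$expt_ir[[nm]]))
  invisible(x)
}

#' Write / read a cohort reference as JSON
#'
#' @param ref a [cohort_reference()].
#' @param path file path.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   returns the `cohort_reference`.
#' @export
write_reference <- function(ref, path) {
  if (!inherits(ref, "cohort_reference")) {
    stop_qpass("ref must be a cohort_reference", class = "qpass_input_error")
  }
  jsonlite::write_json(
    list(ex_tr_samples = ref$ex_tr_samples, expt_ir = as.list(ref$expt_ir),
         source_group = ref$source_group, fs = ref$fs, filter = ref$filter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_reference(ex_tr_samples = obj$ex_tr_samples,
                   expt_ir = unlist(obj$expt_ir),
                   source_group = obj$source_group, fs = obj$fs,
                   filter = obj$filter)
}
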