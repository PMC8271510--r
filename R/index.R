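# Penalties -> qualities -> weighted Q-Pass index, and the modified mean.

#' Validate factor weights
#'
#' The three factor weights must be non-negative and sum to 1 (within 1e-9).
#' Setting a single weight to 1 focuses the score on that factor alone, e.g.
#' `c(0, 0, 1)` evaluates movement-pattern variability exclusively.
#'
#' @param w numeric length-3 vector `(x1, x2, x3)` weighting accuracy, time
#'   and variability.
#' @return the validated weights, named `x1`, `x2`, `x3`.
#' @export
qp_weights <- function(w = c(1, 1, 1) / 3) {
  if (length(w) != 3L || any(!is.finite(w)) || any(w < 0)) {
    stop_qpass("weights must be three non-negative numbers",
               class = "qpass_config_error")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop_qpass("weights must sum to 1 (got %g)", sum(w),
               class = "qpass_config_error")
  }
  stats::setNames(as.numeric(w), c("x1", "x2", "x3"))
}

#' Convert a normalised penalty to a quality value
#'
#' Penalties count what went wrong; the score rewards what went right. A
#' normalised penalty `p` in `[0, 100]` becomes the quality `100 - p`, so a
#' zero-penalty execution scores 100.
#'
#' @param p normalised penalty or penalties in `[0, 100]`.
#' @return quality value(s) in `[0, 100]`.
#' @export
quality_from_penalty <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    stop_qpass("penalties must lie in [0, 100]", class = "qpass_input_error")
  }
  100 - p
}

#' The Q-Pass index of one execution
#'
#' Weighted combination `x1*q1 + x2*q2 + x3*q3` of the three factor
#' qualities (accuracy, time, variability), each in `[0, 100]`. Vectorised
#' over executions.
#'
#' @param q1,q2,q3 factor qualities in `[0, 100]`.
#' @param weights factor weights, see [qp_weights()].
#' @return Q-Pass score(s) in `[0, 100]`.
#' @export
#' @examples
#' qpass_index(100, 100, 100)                       # 100
#' qpass_index(10, 20, 77, weights = c(0, 0, 1))    # 77
qpass_index <- function(q1, q2, q3, weights = c(1, 1, 1) / 3) {
  w <- qp_weights(weights)
  for (q in list(q1, q2, q3)) {
    if (any(!is.finite(q)) || any(q < 0) || any(q > 100)) {
      stop_qpass("qualities must lie in [0, 100]", class = "qpass_input_error")
    }
  }
  w[["x1"]] * q1 + w[["x2"]] * q2 + w[["x3"]] * q3
}

#' Modified mean of repeated executions
#'
#' Mean after discarding exactly one maximal, one minimal and one median
#' element (positions in the sorted order; for an even length the lower of
#' the two middle order statistics is taken as the median). Requires at
#' least four values so the remainder is non-empty.
#'
#' @param values numeric vector, length >= 4.
#' @return the trimmed mean.
#' @export
#' @examples
#' modified_mean(c(1, 2, 3, 4, 5)) # drops 1, 5 and 3 -> 3
modified_mean <- function(values) {
  m <- length(values)
  if (m < 4L) {
    stop_qpass("modified mean needs at least 4 values (got %d)", m,
               class = "qpass_input_error")
  }
  assert_finite(values, "values")
  s <- sort(values)
  med_idx <- if (m %% 2L == 1L) (m + 1L) %/% 2L else m %/% 2L
  mean(s[-unique(c(1L, med_idx, m))])
}

#' Aggregate per-execution scores per player and pass type
#'
#' Applies the modified mean to each quality column and the index within
#' every (player, pass type) cell; every cell must contain at least four
#' executions.
#'
#' @param results data.frame with columns `player_id`, `group`, `pass_type`
#'   and the value columns to aggregate.
#' @param value_cols columns to aggregate with the modified mean.
#' @return data.frame with one row per (player, pass type): the identifying
#'   columns, the modified means and `n_executions`.
#' @export
aggregate_scores <- function(results,
                             value_cols = c("q1", "q2", "q3", "qpass_index")) {
  need <- c("player_id", "group", "pass_type", value_cols)
  if (!is.data.frame(results) || !all(need %in% names(results))) {
    stop_qpass("results must contain columns: %s", paste(need, collapse = ", "),
               class = "qpass_input_error")
  }
  key <- interaction(results$player_id, results$pass_type, drop = TRUE,
                     sep = " / ")
  sizes <- table(key)
  if (any(sizes < 4L)) {
    stop_qpass("groups with fewer than 4 executions: %s",
               paste(names(sizes)[sizes < 4L], collapse = ", "),
               class = "qpass_aggregation_error")
  }
  rows <- lapply(split(results, key), function(d) {
    out <- d[1L, c("player_id", "group", "pass_type"), drop = FALSE]
    for (col in value_cols) out[[col]] <- modified_mean(d[[col]])
    out$n_executions <- nrow(d)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$player_id, match(out$pass_type, PASS_TYPES)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
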