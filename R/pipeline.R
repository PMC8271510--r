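# End-to-end pipeline: references -> per-pass penalties -> Q-Pass scores ->
# group report. Used directly or through the `qpass` command-line script.

# recording key an annotation row points into
rec_key <- function(annotations) {
  paste(annotations$player_id, annotations$pass_type, sep = "_")
}

# per-pass duration (samples) and pattern integral (deg); each recording is
# filtered once, before slicing, so windows share a transient-free signal
measure_passes <- function(annotations, recordings, cutoff = 25, order = 4) {
  annotations <- read_annotations(annotations)
  keys <- rec_key(annotations)
  orphans <- setdiff(unique(keys), names(recordings))
  if (length(orphans)) {
    stop_qpass("annotations without a matching recording: %s",
               paste(orphans, collapse = ", "),
               class = "qpass_reconciliation_error")
  }
  annotations$n <- annotations$end_sample - annotations$start_sample
  annotations$integral <- NA_real_
  for (key in unique(keys)) {
    pair <- recordings[[key]]
    mag <- lowpass_filter(magnitude_series(pair)$value, fs = pair$fs,
                          cutoff = cutoff, order = order)
    rows <- which(keys == key)
    if (any(annotations$end_sample[rows] > length(mag))) {
      stop_qpass("annotation window exceeds recording '%s'", key,
                 class = "qpass_annotation_error")
    }
    dt <- 1 / pair$fs
    for (r in rows) {
      idx <- (annotations$start_sample[r] + 1L):annotations$end_sample[r]
      annotations$integral[r] <- dt * sum(mag[idx])
    }
  }
  annotations
}

#' Build the cohort references from a reference group
#'
#' Computes the reference execution time (mean duration, in samples, of the
#' quickest pass type) and the five per-pass-type variability references
#' (mean pattern integrals) from the reference group's annotated passes —
#' by default the experienced A-level group, so every other player is
#' penalised by their deviation from skilled executions.
#'
#' @param annotations annotation table (data.frame or CSV path), see
#'   [read_annotations()].
#' @param recordings named list of [sensor_pair()]s keyed
#'   `<player>_<pass_type>`, e.g. from [read_recordings()] or
#'   [generate_cohort()].
#' @param group reference group label (default `"A"`).
#' @param cutoff,order low-pass filter settings.
#' @param out optional directory; when given, the reference JSON and a run
#'   log are written there.
#' @return a [cohort_reference()].
#' @export
qp_reference <- function(annotations, recordings, group = "A", cutoff = 25,
                         order = 4, out = NULL) {
  meas <- measure_passes(annotations, recordings, cutoff, order)
  ref_rows <- meas[meas$group == group, , drop = FALSE]
  if (nrow(ref_rows) == 0L) {
    stop_qpass("reference group '%s' has no annotated passes", group,
               class = "qpass_reference_error")
  }
  missing_types <- setdiff(unique(meas$pass_type), unique(ref_rows$pass_type))
  if (length(missing_types)) {
    stop_qpass("reference group '%s' lacks pass type(s): %s", group,
               paste(missing_types, collapse = ", "),
               class = "qpass_reference_error")
  }
  fs <- recordings[[1L]]$fs
  ref <- cohort_reference(
    ex_tr_samples = time_reference(ref_rows),
    expt_ir = variability_reference(ref_rows),
    source_group = group, fs = fs,
    filter = list(cutoff_hz = cutoff, order = order))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_reference(ref, file.path(out, "reference.json"))
    write_run_log(out, "reference",
                  list(group = group, fs = fs,
                       filter = list(cutoff_hz = cutoff, order = order)))
  }
  ref
}

#' Score every annotated pass and aggregate per player and pass type
#'
#' Runs the full penalty framework: per-pass raw penalties for accuracy
#' (f1), time deviation from the reference execution time (f2, in samples)
#' and pattern-integral deviation from the per-pass-type variability
#' reference (f3); max-to-100 normalisation of f2 (pooled over the whole
#' cohort by default) and f3 (per pass type); conversion to qualities
#' (100 - penalty); the weighted Q-Pass index; and modified-mean aggregation
#' per player and pass type.
#'
#' @inheritParams qp_reference
#' @param reference a [cohort_reference()] (or path to its JSON), e.g. from
#'   [qp_reference()].
#' @param weights factor weights `(x1, x2, x3)`, see [qp_weights()].
#' @param f2_pool normalisation pool for the time factor: `"cohort"`
#'   (default) pools all executions of all pass types, `"per_pass_type"`
#'   normalises each type separately (the variability factor is always
#'   normalised per pass type).
#' @param precision `"1dp"` rounds the written summary table to 1 decimal,
#'   `"full"` writes full precision (in-memory tables are never rounded).
#' @param out optional directory for `penalties.csv`, `scores.csv`,
#'   `summary.csv` and a run log.
#' @return object of class `qpass_scores`: list with `penalties` (per-pass
#'   raw and normalised penalties), `results` (per-pass qualities and
#'   index), `summary` (modified means per player x pass type), `weights`
#'   and `reference`.
#' @export
qp_score <- function(annotations, recordings, reference,
                     weights = c(1, 1, 1) / 3, f2_pool = c("cohort",
                                                           "per_pass_type"),
                     precision = c("1dp", "full"), out = NULL) {
  f2_pool <- match.arg(f2_pool)
  precision <- match.arg(precision)
  w <- qp_weights(weights)
  if (is.character(reference)) reference <- read_reference(reference)
  if (!inherits(reference, "cohort_reference")) {
    stop_qpass("reference must be a cohort_reference or a JSON path",
               class = "qpass_input_error")
  }
  meas <- measure_passes(annotations, recordings,
                         cutoff = reference$filter$cutoff_hz,
                         order = reference$filter$order)
  if (anyNA(meas$accuracy)) {
    stop_qpass("passes without accuracy evidence; supply categories or impact geometry",
               class = "qpass_annotation_error")
  }
  missing_ref <- setdiff(unique(meas$pass_type), names(reference$expt_ir))
  if (length(missing_ref)) {
    stop_qpass("reference lacks pass type(s): %s",
               paste(missing_ref, collapse = ", "),
               class = "qpass_reference_error")
  }
  pen <- meas[, c("player_id", "group", "pass_type", "target_id",
                  "trial_index", "n", "integral")]
  pen$f1_raw <- accuracy_penalty(meas$accuracy)
  pen$f2_raw <- time_penalty_raw(meas$n, reference$ex_tr_samples)
  pen$f3_raw <- variability_penalty_raw(
    meas$integral, as.numeric(reference$expt_ir[meas$pass_type]))
  # f1 is born on the 0-100 scale; f2/f3 are rescaled over their pools
  pen$f1 <- pen$f1_raw
  pen$f2 <- if (f2_pool == "cohort") {
    normalize_penalties(pen$f2_raw)
  } else {
    stats::ave(pen$f2_raw, pen$pass_type, FUN = normalize_penalties)
  }
  pen$f3 <- stats::ave(pen$f3_raw, pen$pass_type, FUN = normalize_penalties)
  res <- pen[, c("player_id", "group", "pass_type", "target_id",
                 "trial_index")]
  res$q1 <- quality_from_penalty(pen$f1)
  res$q2 <- quality_from_penalty(pen$f2)
  res$q3 <- quality_from_penalty(pen$f3)
  res$qpass_index <- qpass_index(res$q1, res$q2, res$q3, weights = w)
  summary <- aggregate_scores(res)
  scores <- structure(
    list(penalties = pen, results = res, summary = summary, weights = w,
         reference = reference),
    class = "qpass_scores")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pen, file.path(out, "penalties.csv"), row.names = FALSE)
    utils::write.csv(res, file.path(out, "scores.csv"), row.names = FALSE)
    sm <- summary
    if (precision == "1dp") {
      for (col in c("q1", "q2", "q3", "qpass_index")) {
        sm[[col]] <- round(sm[[col]], 1)
      }
    }
    utils::write.csv(sm, file.path(out, "summary.csv"), row.names = FALSE)
    write_run_log(out, "score",
                  list(weights = as.list(w), f2_pool = f2_pool,
                       precision = precision,
                       reference = list(
                         ex_tr_samples = reference$ex_tr_samples,
                         expt_ir = as.list(reference$expt_ir),
                         source_group = reference$source_group)))
  }
  scores
}

#' @export
print.qpass_scores <- function(x, ...) {
  cat(sprintf("<qpass_scores> %d passes, weights (%.2f, %.2f, %.2f)\n",
              nrow(x$results), x$weights[1], x$weights[2], x$weights[3]))
  print(utils::head(x$summary))
  invisible(x)
}

#' Reliability and group-comparison report
#'
#' Per pass type and group: mean and SD over the players' modified-mean
#' Q-Pass scores, the SEM (square root of the mean-square error of the
#' players-by-trials repeated-measures ANOVA on per-execution scores) and
#' the CV (SEM / group mean x 100). When two or more groups are present the
#' first two (alphabetically, or `groups` as supplied) are compared per pass
#' type: mean difference with Student's 95% CI and p, percent change
#' (second group as base), and Hedge's g with its qualitative label. With a
#' single group, a reliability-only report is returned with a message.
#'
#' @param scores a [qp_score()] result (needed for the per-execution SEM),
#'   or a list with elements `results` and `summary` shaped like its
#'   components.
#' @param value score column to report on (default `"qpass_index"`).
#' @param groups optional length-2 character vector choosing and ordering
#'   the compared groups.
#' @param out optional directory for `report.csv` and a run log.
#' @return data.frame with one row per group x pass type: `pass_type`,
#'   `group`, `mean`, `sd`, `n`, `sem`, `cv_pct`, and (identical on both
#'   rows of a pass type) `mean_diff`, `ci_low`, `ci_high`, `p`,
#'   `pct_change`, `hedges_g`, `label`.
#' @export
qp_report <- function(scores, value = "qpass_index", groups = NULL,
                      out = NULL) {
  if (!all(c("results", "summary") %in% names(scores))) {
    stop_qpass("scores must carry per-execution results and a summary table",
               class = "qpass_input_error")
  }
  results <- scores$results
  summary <- scores$summary
  if (!value %in% names(results) || !value %in% names(summary)) {
    stop_qpass("no score column '%s'", value, class = "qpass_input_error")
  }
  if (is.null(groups)) groups <- sort(unique(summary$group))
  single_group <- length(groups) < 2L
  if (single_group) {
    message("single group: reporting reliability only, no comparisons")
  } else {
    groups <- groups[1:2]
  }
  pass_types <- intersect(PASS_TYPES, unique(summary$pass_type))
  rows <- list()
  for (pt in pass_types) {
    cmp <- list(mean_diff = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = NA_real_)
    g <- NA_real_; lab <- NA_character_; pct <- NA_real_
    if (!single_group) {
      va <- summary[[value]][summary$pass_type == pt &
                               summary$group == groups[1]]
      vb <- summary[[value]][summary$pass_type == pt &
                               summary$group == groups[2]]
      cmp <- ttest_mean_difference(va, vb)
      g <- hedges_g(group_summary(mean(va), stats::sd(va), length(va)),
                    group_summary(mean(vb), stats::sd(vb), length(vb)))
      lab <- effect_label(g)
      pct <- percent_change(mean(va), mean(vb), base = "b")
    }
    for (grp in groups) {
      v <- summary[[value]][summary$pass_type == pt & summary$group == grp]
      r <- results[results$pass_type == pt & results$group == grp, ,
                   drop = FALSE]
      sem <- sem_repeated_measures(
        data.frame(subject = r$player_id, trial = r$trial_index,
                   value = r[[value]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pass_type = pt, group = grp, mean = mean(v), sd = stats::sd(v),
        n = length(v), sem = sem, cv_pct = cv_percent(sem, mean(v)),
        mean_diff = cmp$mean_diff, ci_low = cmp$ci95[1],
        ci_high = cmp$ci95[2], p = cmp$p, pct_change = pct, hedges_g = g,
        label = lab)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
    write_run_log(out, "report", list(value = value, groups = groups))
  }
  report
}

#' Simulate a synthetic cohort (pipeline entry point)
#'
#' Thin wrapper over [cohort_config()] + [generate_cohort()] that optionally
#' writes the dataset to disk in the layout [qp_reference()] and
#' [qp_score()] consume.
#'
#' @param seed integer seed.
#' @param config optional [cohort_config()]; when omitted the default study
#'   design is used with `seed`.
#' @param out optional output directory, see [write_cohort()].
#' @return the generated `qpass_cohort`, invisibly when written to disk.
#' @export
qp_simulate <- function(seed = 1, config = NULL, out = NULL) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  cohort <- generate_cohort(config)
  if (!is.null(out)) {
    write_cohort(cohort, out)
    write_run_log(out, "simulate", list(seed = config$seed))
    return(invisible(cohort))
  }
  cohort
}
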