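test_that("accuracy penalties take only the five admissible values", {
  expect_equal(accuracy_penalty("perfect"), 0)
  expect_equal(accuracy_penalty("miss"), 100)
  expect_equal(accuracy_penalty(c(0, 25, 50, 75, 100)), c(0, 25, 50, 75, 100))
  expect_error(accuracy_penalty("grazed"), class = "qpass_annotation_error")
  expect_error(accuracy_penalty(60), class = "qpass_annotation_error")
})

test_that("overlap fraction handles containment, edge symmetry and geometry errors", {
  # circle strictly inside the square
  expect_equal(overlap_fraction(0.3, 0.3, 0.1, 0, 0, 0.61), 1.0)
  # no overlap at all
  expect_equal(overlap_fraction(5, 5, 0.1, 0, 0, 0.61), 0.0)
  # centred on an edge far from corners: half in, half out
  expect_equal(overlap_fraction(0, 0.3, 0.05, 0, 0, 0.61), 0.5,
               tolerance = 1e-3)
  expect_error(overlap_fraction(0, 0, -1, 0, 0, 0.61),
               class = "qpass_geometry_error")
})

test_that("overlap fraction matches a Monte-Carlo area oracle", {
  set.seed(42)
  for (i in 1:8) {
    cx <- runif(1, -0.4, 0.9); cy <- runif(1, -0.4, 0.9)
    r <- runif(1, 0.05, 0.3)
    got <- overlap_fraction(cx, cy, r, 0, 0, 0.61)
    mc <- mc_overlap_fraction(cx, cy, r, 0, 0, 0.61, n_points = 2e5)
    expect_lt(abs(got - mc), 5e-3)
  }
})

test_that("fraction-to-penalty bins follow the verbal rules and are monotone", {
  expect_equal(fraction_to_penalty(1, touches_boundary = FALSE), 0)
  expect_equal(fraction_to_penalty(1, touches_boundary = TRUE), 25)
  expect_equal(fraction_to_penalty(0), 100)
  expect_equal(fraction_to_penalty(0.5), 50)
  expect_equal(fraction_to_penalty(0.8), 25)
  expect_equal(fraction_to_penalty(0.2), 75)
  fr <- seq(0, 1, by = 0.01)
  pen <- fraction_to_penalty(fr, touches_boundary = TRUE)
  expect_true(all(diff(pen) <= 0))
  expect_error(fraction_to_penalty(1.2), class = "qpass_input_error")
})

test_that("time reference is the quickest pass type's mean duration", {
  d <- data.frame(
    pass_type = rep(c("chest", "bounce", "crossover"), each = 2),
    n = c(40, 40, 90, 90, 100, 100))
  expect_equal(time_reference(d), 40)
  # single pass type: that type's mean, halves rounding away from zero
  expect_equal(time_reference(data.frame(pass_type = "bounce", n = c(90, 95))),
               93)
  expect_error(time_reference(data.frame()), class = "qpass_reference_error")
})

test_that("time reference equals the brute-force min-over-types oracle", {
  set.seed(8)
  for (i in 1:20) {
    d <- data.frame(
      pass_type = sample(PASS_TYPES, 60, replace = TRUE),
      n = sample(40:150, 60, replace = TRUE))
    oracle <- min(sapply(split(d$n, d$pass_type), mean))
    expect_equal(time_reference(d), floor(oracle + 0.5))
  }
})

test_that("raw time and variability penalties are symmetric absolute deviations", {
  expect_equal(time_penalty_raw(64, 64), 0)
  expect_equal(time_penalty_raw(77, 64), 13)
  expect_equal(time_penalty_raw(51, 64), 13)
  expect_equal(variability_penalty_raw(50, 50), 0)
  expect_equal(variability_penalty_raw(57.4, 50), 7)
  expect_equal(variability_penalty_raw(42.6, 50), 7)
  # triangle inequality in the first argument
  set.seed(9)
  a <- runif(50, 0, 200); b <- runif(50, 0, 200); ref <- 70
  expect_true(all(time_penalty_raw(a, ref) <=
                    time_penalty_raw(b, ref) + round(abs(a - b)) + 1))
})

test_that("variability references are per-type means of the integrals", {
  d <- data.frame(pass_type = c("chest", "chest", "bounce"),
                  integral = c(40, 60, 50))
  ref <- variability_reference(d)
  expect_equal(unname(ref[c("chest", "bounce")]), c(50, 50))
  set.seed(10)
  d2 <- data.frame(pass_type = sample(PASS_TYPES, 100, replace = TRUE),
                   integral = runif(100, 100, 500))
  ref2 <- variability_reference(d2)
  oracle <- sapply(split(d2$integral, d2$pass_type), mean)
  expect_equal(ref2[names(oracle)], oracle)
})

test_that("normalisation maps the max to 100, keeps zeros and ratios", {
  expect_equal(normalize_penalties(c(0, 5, 10)), c(0, 50, 100))
  expect_equal(normalize_penalties(c(0, 0, 0)), c(0, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    raw <- sample(0:500, 30, replace = TRUE)
    nrm <- normalize_penalties(raw)
    expect_equal(max(nrm), 100)
    expect_equal(order(nrm), order(raw))
    nz <- raw > 0
    expect_equal(nrm[nz] / raw[nz], rep(100 / max(raw), sum(nz)),
                 tolerance = 1e-12)
    # scale invariance
    expect_equal(normalize_penalties(3 * raw), nrm, tolerance = 1e-12)
  }
  expect_error(normalize_penalties(numeric(0)), class = "qpass_input_error")
  expect_error(normalize_penalties(c(-1, 2)), class = "qpass_input_error")
})

test_that("the mean raw penalty is minimised at the reference on symmetric cohorts", {
  set.seed(12)
  deltas <- c(-40, -25, -10, -5, 5, 10, 25, 40)
  ref <- 300
  integrals <- ref + deltas  # symmetric: mean and median coincide
  at_ref <- mean(variability_penalty_raw(integrals, ref))
  for (alt in ref + seq(-30, 30, by = 5)) {
    expect_gte(mean(variability_penalty_raw(integrals, alt)) + 1e-9, at_ref)
  }
})

test_that("cohort references survive a JSON round trip", {
  ref <- cohort_reference(64, setNames(c(100, 200, 300, 400, 500), PASS_TYPES),
                          source_group = "A")
  path <- tempfile(fileext = ".json")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$ex_tr_samples, ref$ex_tr_samples)
  expect_equal(back$expt_ir, ref$expt_ir)
  expect_equal(back$source_group, "A")
  expect_equal(back$filter$cutoff_hz, 25)
})
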