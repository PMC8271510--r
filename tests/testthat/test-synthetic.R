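# deterministic group parameters: every pass identical unless spread is added
det_params <- function(duration = 0.5, peak = 600, duration_sd = 0,
                       peak_sd = 0, jitter = 0, noise_sd = 0,
                       accuracy_probs = c(1, 0, 0, 0, 0)) {
  list(duration_mean = duration, duration_sd = duration_sd,
       peak_mean = peak, peak_sd = peak_sd, jitter = jitter,
       accuracy_probs = accuracy_probs, noise_sd = noise_sd)
}

test_that("cohort generation is deterministic given the seed and restores the RNG", {
  cfg <- cohort_config(n_players_per_group = 2, trials_per_type = 4, seed = 5)
  set.seed(1234); before <- rnorm(1)
  set.seed(1234)
  c1 <- generate_cohort(cfg)
  after <- rnorm(1)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$annotations, c2$annotations)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(before, after)  # caller's RNG stream untouched
  # different seeds: different truths, same schema
  c3 <- generate_cohort(cohort_config(n_players_per_group = 2,
                                      trials_per_type = 4, seed = 6))
  expect_identical(names(c3$truth), names(c1$truth))
  expect_false(identical(c3$truth$duration, c1$truth$duration))
})

test_that("generated annotations and traces satisfy the data-model invariants", {
  co <- small_cohort(seed = 21)
  a <- read_annotations(co$annotations)  # validator passes
  expect_true(all(a$end_sample > a$start_sample))
  for (key in names(co$recordings)) {
    pair <- co$recordings[[key]]
    expect_s3_class(pair, "sensor_pair")  # uniform-spacing checked on build
    rows <- a[paste(a$player_id, a$pass_type, sep = "_") == key, ]
    expect_true(all(rows$end_sample <= pair$n))
  }
})

test_that("a noise-free raised-cosine burst integrates to peak x duration / 2", {
  set.seed(22)
  prof <- deterministic_profile(duration = 1.0, peak = 500)
  g <- generate_pass_trace(prof, "chest")
  w <- extract_window(g$pair, g$event)
  expect_equal(w$n, 128)
  expect_equal(integral_approx(w), 500 * 1.0 / 2, tolerance = 0.02)
})

test_that("zero variability collapses the f3 penalties to a constant", {
  cfg <- cohort_config(n_players_per_group = 1, trials_per_type = 5,
                       pass_types = "chest", seed = 3,
                       group_params = list(A = det_params(),
                                           B = det_params(duration = 0.7)),
                       player_spread = 0)
  co <- generate_cohort(cfg)
  ref <- qp_reference(co$annotations, co$recordings)
  sc <- qp_score(co$annotations, co$recordings, ref)
  for (grp in split(sc$penalties, paste(sc$penalties$player_id))) {
    expect_equal(length(unique(grp$f3_raw)), 1L)
    expect_equal(length(unique(grp$f3)), 1L)
  }
  # reference-matching durations earn a zero time penalty
  expect_true(all(sc$penalties$f2_raw[sc$penalties$group == "A"] == 0))
})

test_that("with time-only weights the player ranking follows the duration deviation", {
  cfg <- cohort_config(
    n_players_per_group = 4, trials_per_type = 5, seed = 31,
    group_params = list(
      A = det_params(duration = c(chest = 0.50, bounce = 0.80,
                                  crossover = 0.90, between_the_leg = 1.00,
                                  behind_the_back = 1.05)),
      B = det_params(duration = c(chest = 0.58, bounce = 0.92,
                                  crossover = 1.04, between_the_leg = 1.15,
                                  behind_the_back = 1.21))),
    player_spread = 0.1)
  co <- generate_cohort(cfg)
  ref <- qp_reference(co$annotations, co$recordings)
  sc <- qp_score(co$annotations, co$recordings, ref, weights = c(0, 1, 0))
  ann_n <- co$annotations$end_sample - co$annotations$start_sample
  for (pt in PASS_TYPES) {
    sm <- sc$summary[sc$summary$pass_type == pt, ]
    dev <- sapply(sm$player_id, function(p) {
      rows <- co$annotations$player_id == p & co$annotations$pass_type == pt
      abs(mean(ann_n[rows]) - ref$ex_tr_samples)
    })
    # smaller deviation from Ex_Tr never scores lower
    for (i in seq_len(nrow(sm))) {
      for (j in seq_len(nrow(sm))) {
        if (dev[i] < dev[j]) {
          expect_gte(sm$qpass_index[i] + 1e-9, sm$qpass_index[j])
        }
      }
    }
  }
})

test_that("raising one player's duration SD never improves their time quality", {
  q2_at <- function(sd_b) {
    cfg <- cohort_config(
      n_players_per_group = 1, trials_per_type = 25, pass_types = "chest",
      seed = 77, player_spread = 0,
      group_params = list(
        A = det_params(duration = 0.5),
        B = det_params(duration = 0.5, duration_sd = sd_b),
        C = det_params(duration = 1.0)))  # fixed pool maximum
    co <- generate_cohort(cfg)
    ref <- qp_reference(co$annotations, co$recordings)
    sc <- qp_score(co$annotations, co$recordings, ref, weights = c(0, 1, 0))
    sc$summary$q2[sc$summary$group == "B"]
  }
  qs <- vapply(c(0, 0.02, 0.05, 0.1), q2_at, numeric(1))
  expect_true(all(diff(qs) <= 1e-9))
})

test_that("identical group parameters give a near-zero median effect size", {
  gs <- vapply(1:100, function(s) {
    cfg <- cohort_config(n_players_per_group = 8, trials_per_type = 6,
                         pass_types = c("chest", "bounce"), seed = s,
                         group_params = list(A = default_group_params()$A,
                                             B = default_group_params()$A))
    co <- generate_cohort(cfg)
    ref <- qp_reference(co$annotations, co$recordings)
    sc <- qp_score(co$annotations, co$recordings, ref)
    a <- sc$summary$qpass_index[sc$summary$group == "A"]
    b <- sc$summary$qpass_index[sc$summary$group == "B"]
    hedges_g(group_summary(mean(a), sd(a), length(a)),
             group_summary(mean(b), sd(b), length(b)))
  }, numeric(1))
  expect_lt(abs(median(gs)), 0.4)
})
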