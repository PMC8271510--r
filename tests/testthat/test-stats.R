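test_that("SEM from the repeated-measures decomposition matches hand computation", {
  # subjects differ, trials identical within subject: no within-subject error
  m <- rbind(c(5, 5, 5), c(9, 9, 9), c(2, 2, 2))
  expect_equal(sem_repeated_measures(m), 0)
  # hand-computed 2x2 decomposition: SS_res = 1 on 1 df
  expect_equal(sem_repeated_measures(matrix(c(0, 0, 2, 0), nrow = 2)), 1.0)
  expect_error(sem_repeated_measures(matrix(c(1, 2, NA, 4), nrow = 2)),
               class = "qpass_design_error")
  expect_error(sem_repeated_measures(
    data.frame(subject = c(1, 1, 2), trial = c(1, 2, 1), value = 1:3)),
    class = "qpass_design_error")
})

test_that("SEM absorbs constant and subject-specific shifts", {
  set.seed(16)
  m <- matrix(rnorm(40, 50, 4), nrow = 8)
  base <- sem_repeated_measures(m)
  expect_equal(sem_repeated_measures(m + 17), base)
  expect_equal(sem_repeated_measures(m + rnorm(8, 0, 20)), base)
})

test_that("SEM recovers an injected within-subject SD", {
  set.seed(17)
  sigma <- 2.5
  sems <- replicate(20, {
    m <- matrix(rnorm(30 * 10, 0, sigma), nrow = 30) + rnorm(30, 60, 8)
    sem_repeated_measures(m)
  })
  expect_lt(abs(mean(sems) - sigma) / sigma, 0.1)
})

test_that("CV is SEM relative to the mean, in percent", {
  expect_equal(cv_percent(0, 50), 0)
  expect_equal(cv_percent(3, 60), 5)
  expect_equal(cv_percent(2 * 3, 2 * 60), cv_percent(3, 60))
  expect_error(cv_percent(1, 0), class = "qpass_input_error")
})

test_that("Hedge's g matches an independently coded formula and is antisymmetric", {
  expect_equal(hedges_g(group_summary(50, 5, 8), group_summary(50, 5, 8)), 0)
  set.seed(18)
  for (i in 1:50) {
    ma <- runif(1, 40, 90); mb <- runif(1, 40, 90)
    sa <- runif(1, 2, 12); sb <- runif(1, 2, 12)
    na <- sample(4:30, 1); nb <- sample(4:30, 1)
    a <- group_summary(ma, sa, na); b <- group_summary(mb, sb, nb)
    sp <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
    oracle <- (1 - 3 / (4 * (na + nb) - 9)) * (ma - mb) / sp
    expect_equal(hedges_g(a, b), oracle, tolerance = 1e-12)
    expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
  }
  # exact gamma-function correction agrees closely at moderate n
  a <- group_summary(60, 6, 10); b <- group_summary(55, 6, 10)
  expect_equal(hedges_g(a, b, exact = TRUE), hedges_g(a, b),
               tolerance = 0.01)
  expect_error(hedges_g(group_summary(1, 0, 5), group_summary(2, 0, 5)),
               class = "qpass_undefined_effect_error")
})

test_that("Hedge's g recovers the true standardised gap on simulated cohorts", {
  set.seed(19)
  delta <- 6; sigma <- 8
  gs <- replicate(200, {
    a <- rnorm(50, 60 + delta, sigma)
    b <- rnorm(50, 60, sigma)
    hedges_g(group_summary(mean(a), sd(a), 50),
             group_summary(mean(b), sd(b), 50))
  })
  expect_lt(abs(mean(gs) - delta / sigma) / (delta / sigma), 0.15)
})

test_that("pooled Student's t mean difference matches the textbook formula", {
  same <- ttest_mean_difference(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_true(same$ci95[1] <= 0 && same$ci95[2] >= 0)
  shifted <- ttest_mean_difference(c(1, 2, 3), c(11, 12, 13))
  expect_equal(shifted$mean_diff, -10)
  expect_true(shifted$ci95[2] < 0)
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(sample(5:15, 1), 60, 6)
    b <- rnorm(sample(5:15, 1), 55, 6)
    got <- ttest_mean_difference(a, b)
    na <- length(a); nb <- length(b); df <- na + nb - 2
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    d <- mean(a) - mean(b)
    tcrit <- qt(0.975, df)
    expect_equal(got$mean_diff, d, tolerance = 1e-10)
    expect_equal(got$ci95, c(d - tcrit * se, d + tcrit * se),
                 tolerance = 1e-10)
    expect_equal(got$p, 2 * pt(-abs(d / se), df), tolerance = 1e-10)
  }
  expect_warning(deg <- ttest_mean_difference(c(2, 2), c(5, 5)))
  expect_equal(deg$mean_diff, -3)
  expect_equal(deg$ci95, c(-3, -3))
})

test_that("percent change uses the configured base", {
  expect_equal(percent_change(110, 100), 10)
  expect_equal(percent_change(70, 70), 0)
  expect_equal(percent_change(68.1, 52.6), (68.1 - 52.6) / 52.6 * 100)
  expect_equal(percent_change(110, 100, base = "a"),
               (110 - 100) / 110 * 100)
  expect_error(percent_change(1, 0), class = "qpass_input_error")
})

test_that("z-score outlier screen flags gross outliers at the normal rate", {
  expect_equal(zscore_outliers(c(0, 0, 0, 0, 100), threshold = 1.5),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_warning(flags <- zscore_outliers(rep(3, 5)))
  expect_false(any(flags))
  set.seed(21)
  rate <- mean(zscore_outliers(rnorm(1e4), threshold = 3))
  expect_lt(abs(rate - 0.0027), 0.002)
})

test_that("effect-size labels follow the published thresholds", {
  expect_equal(effect_label(c(0.1, 0.3, 0.58, 0.82, 1.91)),
               c("negligible", "small", "medium", "large", "extra-large"))
  expect_equal(effect_label(c(0.2, 0.5, 0.8, 1.2)),
               c("small", "medium", "large", "extra-large"))
  expect_equal(effect_label(-0.9), "large")
})
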