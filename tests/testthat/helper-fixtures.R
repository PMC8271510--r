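# fixture builders shared across the test files; everything is generated in
# code, no data files

# sensor pair with constant per-sensor component vectors v1, v2
make_constant_pair <- function(n = 10, v1 = c(1, 0, 0), v2 = c(0, 1, 0),
                               fs = 128) {
  sensor_pair(
    gyro_trace(rep(v1[1], n), rep(v1[2], n), rep(v1[3], n),
               sensor_id = "wrist", fs = fs),
    gyro_trace(rep(v2[1], n), rep(v2[2], n), rep(v2[3], n),
               sensor_id = "humerus", fs = fs))
}

# sensor pair whose combined |gyr1 + gyr2| equals `mag` exactly (both
# sensors aligned along x, split 65/35)
make_pair_from_mag <- function(mag, fs = 128) {
  z <- rep(0, length(mag))
  sensor_pair(
    gyro_trace(0.65 * mag, z, z, sensor_id = "wrist", fs = fs),
    gyro_trace(0.35 * mag, z, z, sensor_id = "humerus", fs = fs))
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# deterministic noise-free player profile, one fixed duration/peak per type
deterministic_profile <- function(player_id = "A01", group = "A",
                                  duration = 0.5, peak = 600,
                                  accuracy_probs = c(1, 0, 0, 0, 0)) {
  player_profile(
    player_id = player_id, group = group,
    duration_mean = setNames(rep(duration, 5), PASS_TYPES),
    duration_sd = setNames(rep(0, 5), PASS_TYPES),
    peak_mean = setNames(rep(peak, 5), PASS_TYPES),
    peak_sd = setNames(rep(0, 5), PASS_TYPES),
    jitter = 0, accuracy_probs = accuracy_probs, noise_sd = 0)
}

# reduced cohort for fast pipeline tests: 2 players per group, 5 trials
small_cohort <- function(seed = 11, trials = 5, ...) {
  generate_cohort(cohort_config(n_players_per_group = 2,
                                trials_per_type = trials, seed = seed, ...))
}

# FFT amplitude of an integer-cycle sinusoid over the middle of a series
fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  mid <- x[(n / 4 + 1):(3 * n / 4)]
  m <- length(mid)
  sp <- abs(fft(mid)) * 2 / m
  sp[round(freq * m / fs) + 1]
}

# Monte-Carlo oracle for the circle-in-square inside fraction
mc_overlap_fraction <- function(ball_x, ball_y, ball_r, sq_x, sq_y, sq_side,
                                n_points = 1e6) {
  th <- runif(n_points, 0, 2 * pi)
  rr <- ball_r * sqrt(runif(n_points))
  px <- ball_x + rr * cos(th)
  py <- ball_y + rr * sin(th)
  mean(px > sq_x & px < sq_x + sq_side & py > sq_y & py < sq_y + sq_side)
}
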