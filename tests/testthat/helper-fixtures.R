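# Shared fixtures. Simulated sprints are cached per parameter set so the
# suite pays for each simulation once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Clean sprint: no artefact, no noise (pure kinematics).
clean_sprint <- function(effort = "100", seed = 1) {
  cached(paste0("clean_", effort, "_", seed),
         simulate_sprint(make_profile(effort), fs = 500, seed = seed,
                         artefact = artefact_config(enabled = FALSE),
                         noise = noise_off()))
}

# Default study conditions: impact artefacts and sensor noise on.
default_sprint <- function(effort = "100", seed = 1) {
  cached(paste0("default_", effort, "_", seed),
         simulate_sprint(make_profile(effort), fs = 500, seed = seed))
}

# Body-frame recording of a prescribed pitch oscillation about the global
# z-axis after 0.5 s of quiet standing, with the exact angle as truth.
# Gyroscope is exact; accelerometer senses rotated gravity only.
rotation_recording <- function(duration = 4, fs = 500, amp_deg = 40,
                               freq_hz = 0.8, g = 9.81) {
  t <- seq(0, duration, by = 1 / fs)
  theta <- ifelse(t < 0.5, 0, amp_deg * pi / 180 * sin(2 * pi * freq_hz * (t - 0.5)))
  thetadot <- ifelse(t < 0.5, 0,
                     amp_deg * pi / 180 * 2 * pi * freq_hz * cos(2 * pi * freq_hz * (t - 0.5)))
  acc <- t(vapply(seq_along(t), function(i) {
    q <- quat_from_axis_angle(c(0, 0, 1), theta[i])
    quat_rotate(quat_conjugate(q), c(0, g, 0))
  }, numeric(3)))
  list(rec = imu_recording(t, acc, cbind(0, 0, thetadot), fs = fs, foot = "left"),
       theta = theta)
}

# Identity orientation series of length n (for frame-change tests).
identity_orientation <- function(n, fs = 500) {
  structure(list(q = matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4),
                 beta = 0, fs = fs),
            class = "orientation_series")
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
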