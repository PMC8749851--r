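# Synthetic sprint generator with exact ground truth.
#
# Body speed follows the mono-exponential sprint-acceleration profile
# v(t) = v_max * (1 - exp(-t / tau)). Footfalls alternate between feet at a
# cadence that rises with speed while ground contact time shortens; each
# foot is exactly stationary during its stance (the premise of the
# zero-velocity update) and travels between consecutive footfall positions
# along a minimum-jerk trajectory during swing. Global-frame foot
# acceleration is evaluated from the closed-form second derivative of the
# trajectory, optionally with a touch-down impact transient (damped
# high-frequency burst confined to the first ~15 ms of contact, with a
# configurable net velocity integral - the artefact the ZVU corrects),
# white sensor noise, a slowly-varying per-sprint accelerometer bias, and
# ±16 g range clipping. A synthetic medial-lateral angular-rate trace with
# a positive mid-swing burst and sharp negative troughs exactly at
# touch-down and toe-off supports event-detection validation.

#' Sprint speed profile for an effort level
#'
#' Mono-exponential profile `v(t) = v_max * (1 - exp(-t / tau))` over a
#' fixed distance. Default maximal speeds per subjective effort level
#' (7.0, 7.65 and 8.4 m/s at 60, 80 and 100%) follow reported group means
#' for recreational sprinters; `tau = 1.3 s` is a typical sprint
#' acceleration time constant.
#'
#' @param effort effort label: 60, 80 or 100 (percent of maximal effort).
#' @param v_max maximal speed, m/s (default depends on `effort`).
#' @param tau time constant, s.
#' @param distance sprint distance, m.
#' @return object of class `sprint_profile`.
#' @export
make_profile <- function(effort = c("100", "80", "60"), v_max = NULL,
                         tau = 1.3, distance = 35) {
  effort <- match.arg(as.character(effort), c("100", "80", "60"))
  v_max <- v_max %||% c("60" = 7.0, "80" = 7.65, "100" = 8.4)[[effort]]
  if (v_max <= 0 || tau <= 0 || distance <= 0) {
    stop("v_max, tau and distance must be positive")
  }
  structure(list(v_max = v_max, tau = tau, distance = distance,
                 effort = effort), class = "sprint_profile")
}

#' Body speed of a sprint profile at time t
#' @param profile [make_profile()].
#' @param t time since the start, s.
#' @export
profile_speed <- function(profile, t) {
  profile$v_max * (1 - exp(-t / profile$tau))
}

#' Body position of a sprint profile at time t
#' @inheritParams profile_speed
#' @export
profile_position <- function(profile, t) {
  profile$v_max * (t - profile$tau * (1 - exp(-t / profile$tau)))
}

#' Time to cover the profile distance (numeric root)
#' @param profile [make_profile()].
#' @export
profile_duration <- function(profile) {
  f <- function(t) profile_position(profile, t) - profile$distance
  upper <- profile$distance / profile$v_max + 10 * profile$tau
  stats::uniroot(f, c(1e-6, upper), tol = 1e-10)$root
}

#' Impact-artefact configuration for the simulator
#'
#' A damped sinusoidal burst (center frequency `freq_hz`, decay ~5 ms)
#' confined to the first `duration_s` of ground contact, with peak
#' amplitude `peak_g`. Its zero-mean shape carries no net velocity; the net
#' velocity integral of the artefact is injected separately as a smooth
#' unit-integral pulse scaled per axis: by default drawn per touch-down
#' from N(0, `net_dv_sd_*`), or fixed in magnitude (random sign) via
#' `net_dv_x` / `net_dv_z`. A nonzero net integral is precisely what makes
#' the zero-velocity update necessary.
#'
#' @param enabled logical.
#' @param duration_s burst duration, s.
#' @param freq_hz burst center frequency, Hz.
#' @param peak_g burst peak amplitude, g.
#' @param net_dv_sd_x,net_dv_sd_z SD of the per-touch-down net velocity
#'   integral, m/s.
#' @param net_dv_x,net_dv_z optional fixed net-integral magnitudes, m/s
#'   (sign randomized per touch-down); overrides the SDs when set.
#' @export
artefact_config <- function(enabled = TRUE, duration_s = 0.015, freq_hz = 120,
                            peak_g = 25, net_dv_sd_x = 0.3, net_dv_sd_z = 0.15,
                            net_dv_x = NULL, net_dv_z = NULL) {
  list(enabled = enabled, duration_s = duration_s, freq_hz = freq_hz,
       peak_g = peak_g, net_dv_sd_x = net_dv_sd_x, net_dv_sd_z = net_dv_sd_z,
       net_dv_x = net_dv_x, net_dv_z = net_dv_z)
}

#' Sensor-noise configuration for the simulator
#'
#' @param acc_white_sd white accelerometer noise SD, m/s^2.
#' @param acc_bias_sd SD of a constant per-sprint, per-axis accelerometer
#'   bias, m/s^2 (a surrogate for residual orientation error, the dominant
#'   low-frequency error of the global-frame acceleration).
#' @param gyr_white_sd white gyroscope noise SD, rad/s.
#' @param step_jitter_sd SD of lateral footfall placement jitter, m.
#' @export
noise_config <- function(acc_white_sd = 0.3, acc_bias_sd = 0.15,
                         gyr_white_sd = 0.05, step_jitter_sd = 0.02) {
  list(acc_white_sd = acc_white_sd, acc_bias_sd = acc_bias_sd,
       gyr_white_sd = gyr_white_sd, step_jitter_sd = step_jitter_sd)
}

#' Noise-free configuration shortcut
#' @export
noise_off <- function() noise_config(0, 0, 0, 0)

# Minimum-jerk position/acceleration between x0 and x1 over normalized
# phase u in [0, 1] of duration T.
.minjerk_pos <- function(u, x0, x1) x0 + (x1 - x0) * (10 * u^3 - 15 * u^4 + 6 * u^5)
.minjerk_acc <- function(u, x0, x1, T) (x1 - x0) * (60 * u - 180 * u^2 + 120 * u^3) / T^2

#' Simulate a sprint with ground truth
#'
#' @param profile [make_profile()].
#' @param fs sampling frequency, Hz (>= 200).
#' @param seed RNG seed; the same seed reproduces the sprint exactly.
#' @param artefact [artefact_config()]; set `enabled = FALSE` for clean
#'   signals.
#' @param noise [noise_config()] or [noise_off()].
#' @param clip logical: clip acceleration at ±16 g (with flags) as a
#'   range-limited sensor would.
#' @param quiet_s standstill duration before the first toe-off, s (must
#'   exceed the 280 ms pre-toe-off interval of the first stride).
#' @param tail_s signal retained after the last touch-down, s.
#' @return object of class `synthetic_sprint`: list with `left` and
#'   `right` [global_sprint()] objects (events attached), `gyr_x` (list of
#'   per-foot medial-lateral angular-rate traces), `truth` (data.frame with
#'   per-foot, per-stride `dx_m`, `dz_m`, `length_m` and event times),
#'   `profile`, `seed`, and the parameter sets used.
#' @export
simulate_sprint <- function(profile, fs = 500, seed = 1,
                            artefact = artefact_config(),
                            noise = noise_config(), clip = FALSE,
                            quiet_s = 1.0, tail_s = 0.5) {
  if (fs < 200) stop("fs must be at least 200 Hz")
  if (quiet_s <= 0.3) stop("quiet_s must exceed the 280 ms pre-toe-off interval")
  with_seed(seed, {
    stride_freq <- function(v) 1.4 + 0.08 * v              # Hz, rises with speed
    contact_time <- function(v) pmin(0.30, pmax(0.09, 0.25 - 0.015 * v))

    # --- footfall sequence (steps alternate feet; rear foot steps first) ---
    t_start <- quiet_s
    feet <- c("left", "right")                 # left = rear foot at the start
    init_x <- c(left = -0.35, right = 0)
    side_z <- c(left = -0.06, right = 0.06)
    step_t <- numeric(0); step_x <- numeric(0); step_z <- numeric(0)
    step_foot <- character(0)
    t_cur <- t_start; k <- 0L
    repeat {
      v_now <- profile_speed(profile, t_cur - t_start)
      t_next <- t_cur + 1 / (2 * stride_freq(v_now))
      x_next <- profile_position(profile, t_next - t_start)
      if (x_next > profile$distance) break
      k <- k + 1L
      foot <- feet[(k - 1L) %% 2L + 1L]
      step_t <- c(step_t, t_next); step_x <- c(step_x, x_next)
      step_z <- c(step_z, side_z[[foot]] + rnorm(1L, 0, noise$step_jitter_sd))
      step_foot <- c(step_foot, foot)
      t_cur <- t_next
    }
    if (k < 4L) stop("infeasible profile: fewer than 4 footfalls before the distance")

    t_end <- max(step_t) + tail_s
    n <- floor(t_end * fs) + 1L
    t <- (seq_len(n) - 1L) / fs

    out <- list()
    truth_rows <- list()
    gyr_list <- list()
    for (foot in feet) {
      sel <- which(step_foot == foot)
      td_t <- step_t[sel]; px <- step_x[sel]; pz <- step_z[sel]
      # first toe-off: rear foot leaves at the start signal, front foot when
      # the rear foot first lands
      to1 <- if (foot == "left") t_start else step_t[1L]
      to_t <- c(to1, td_t[-length(td_t)] +
                  contact_time(profile_speed(profile, td_t[-length(td_t)] - t_start)))
      # guard: toe-off must precede the next touch-down
      to_t <- pmin(to_t, td_t - 0.05)
      x0 <- c(init_x[[foot]], px[-length(px)])
      z0 <- c(side_z[[foot]], pz[-length(pz)])

      pos_x <- rep(init_x[[foot]], n); pos_z <- rep(side_z[[foot]], n)
      acc_x <- numeric(n); acc_y <- numeric(n); acc_z <- numeric(n)
      h_swing <- 0.12   # vertical swing amplitude, m
      for (j in seq_along(td_t)) {
        Tj <- td_t[j] - to_t[j]
        in_swing <- t >= to_t[j] & t < td_t[j]
        u <- (t[in_swing] - to_t[j]) / Tj
        pos_x[in_swing] <- .minjerk_pos(u, x0[j], px[j])
        pos_z[in_swing] <- .minjerk_pos(u, z0[j], pz[j])
        acc_x[in_swing] <- .minjerk_acc(u, x0[j], px[j], Tj)
        acc_z[in_swing] <- .minjerk_acc(u, z0[j], pz[j], Tj)
        acc_y[in_swing] <- h_swing * 2 * pi^2 / Tj^2 * cos(2 * pi * u)
        after <- t >= td_t[j]
        pos_x[after] <- px[j]; pos_z[after] <- pz[j]
      }

      # --- touch-down impact artefacts -----------------------------------
      if (isTRUE(artefact$enabled)) {
        for (j in seq_along(td_t)) {
          w_idx <- which(t >= td_t[j] & t < td_t[j] + artefact$duration_s)
          if (length(w_idx) < 3L) next
          w <- t[w_idx] - td_t[j]
          burst <- artefact$peak_g * 9.81 * exp(-w / 0.005) *
            sin(2 * pi * artefact$freq_hz * w)
          burst <- burst - mean(burst)            # zero net velocity shape
          pulse <- (2 / artefact$duration_s) * sin(pi * w / artefact$duration_s)^2
          pulse <- pulse / (sum(pulse) / fs)      # exact unit integral on the grid
          dv_x <- if (!is.null(artefact$net_dv_x)) {
            sample(c(-1, 1), 1L) * artefact$net_dv_x
          } else rnorm(1L, 0, artefact$net_dv_sd_x)
          dv_z <- if (!is.null(artefact$net_dv_z)) {
            sample(c(-1, 1), 1L) * artefact$net_dv_z
          } else rnorm(1L, 0, artefact$net_dv_sd_z)
          acc_x[w_idx] <- acc_x[w_idx] + burst + dv_x * pulse
          acc_z[w_idx] <- acc_z[w_idx] + 0.5 * burst + dv_z * pulse
          acc_y[w_idx] <- acc_y[w_idx] + 2 * burst
        }
      }

      # --- sensor noise ---------------------------------------------------
      if (noise$acc_white_sd > 0) {
        acc_x <- acc_x + rnorm(n, 0, noise$acc_white_sd)
        acc_y <- acc_y + rnorm(n, 0, noise$acc_white_sd)
        acc_z <- acc_z + rnorm(n, 0, noise$acc_white_sd)
      }
      if (noise$acc_bias_sd > 0) {
        acc_x <- acc_x + rnorm(1L, 0, noise$acc_bias_sd)
        acc_z <- acc_z + rnorm(1L, 0, noise$acc_bias_sd)
      }
      if (clip) {
        lim <- 16 * 9.81
        acc_x <- pmin(pmax(acc_x, -lim), lim)
        acc_y <- pmin(pmax(acc_y, -lim), lim)
        acc_z <- pmin(pmax(acc_z, -lim), lim)
      }

      # --- medial-lateral angular rate with event signatures -------------
      gyr <- numeric(n)
      spike_w <- 0.015
      add_trough <- function(gyr, t0, depth) {
        idx <- which(t >= t0 - spike_w & t <= t0 + spike_w)
        gyr[idx] <- gyr[idx] - depth * sin(pi * (t[idx] - t0 + spike_w) / (2 * spike_w))^2
        gyr
      }
      for (j in seq_along(td_t)) {
        Tj <- td_t[j] - to_t[j]
        in_swing <- t >= to_t[j] & t < td_t[j]
        u <- (t[in_swing] - to_t[j]) / Tj
        v_mid <- profile_speed(profile, (to_t[j] + td_t[j]) / 2 - t_start)
        gyr[in_swing] <- gyr[in_swing] + (7 + 0.5 * v_mid) * sin(pi * u)^2
        depth <- 6 + 0.4 * v_mid
        gyr <- add_trough(gyr, to_t[j], depth)
        gyr <- add_trough(gyr, td_t[j], depth)
      }
      if (noise$gyr_white_sd > 0) gyr <- gyr + rnorm(n, 0, noise$gyr_white_sd)

      td_idx <- round(td_t * fs) + 1L
      to_idx <- round(to_t * fs) + 1L
      ev <- gait_events(td = td_idx, to = to_idx, foot = foot)
      out[[foot]] <- global_sprint(t, acc_x, acc_y, acc_z, fs = fs,
                                   foot = foot, events = ev)
      gyr_list[[foot]] <- gyr

      prev_x <- c(init_x[[foot]], px[-length(px)])
      prev_z <- c(side_z[[foot]], pz[-length(pz)])
      truth_rows[[foot]] <- data.frame(
        foot = foot, stride_index = seq_along(td_t),
        td_time_s = td_t, to_time_s = to_t,
        dx_m = px - prev_x, dz_m = pz - prev_z,
        length_m = sqrt((px - prev_x)^2 + (pz - prev_z)^2),
        stringsAsFactors = FALSE)
    }
    structure(list(left = out$left, right = out$right, gyr_x = gyr_list,
                   truth = do.call(rbind, truth_rows), profile = profile,
                   seed = seed, artefact = artefact, noise = noise,
                   clip = clip),
              class = "synthetic_sprint")
  })
}

#' @export
print.synthetic_sprint <- function(x, ...) {
  cat(sprintf("<synthetic_sprint> effort=%s%%  v_max=%.2f m/s  fs=%g Hz  seed=%d\n",
              x$profile$effort, x$profile$v_max, x$left$fs, x$seed))
  cat(sprintf("  %d strides (left %d, right %d), total %.1f m per foot\n",
              nrow(x$truth), sum(x$truth$foot == "left"),
              sum(x$truth$foot == "right"),
              sum(x$truth$length_m[x$truth$foot == "left"])))
  invisible(x)
}

#' Write simulator fixtures to a directory
#'
#' Emits deposit-style per-foot global-frame files (with events sidecars),
#' per-foot medial-lateral angular-rate traces, and a ground-truth sidecar.
#' All files are plain CSV and round-trip through [read_global_sprint()].
#'
#' @param sprint [simulate_sprint()] output.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
emit_fixtures <- function(sprint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (foot in c("left", "right")) {
    p <- file.path(dir, sprintf("sprint_%s.csv", foot))
    write_global_sprint(sprint[[foot]], p)
    files <- c(files, p, paste0(tools::file_path_sans_ext(p), "_events.csv"))
    gp <- file.path(dir, sprintf("sprint_%s_gyro.csv", foot))
    write_precise_csv(data.frame(t = sprint[[foot]]$t,
                                 gyr_x = sprint$gyr_x[[foot]]),
                      gp, provenance_header())
    files <- c(files, gp)
  }
  tp <- file.path(dir, "truth.csv")
  write_precise_csv(sprint$truth, tp, provenance_header())
  files <- c(files, tp)
  invisible(files)
}

#' Per-stride recovery errors of the pipeline on a synthetic sprint
#'
#' Runs [process_sprint()] on both feet of a synthetic sprint and returns
#' the percentage error of every estimated stride length against the
#' simulator ground truth.
#'
#' @param sprint [simulate_sprint()] output.
#' @param cfg configuration passed to [process_sprint()].
#' @return numeric vector of signed percentage errors, one per stride.
#' @export
stride_recovery_errors <- function(sprint, cfg = ss_config()) {
  unlist(lapply(c("left", "right"), function(foot) {
    tab <- process_sprint(sprint[[foot]], cfg = cfg)
    tr <- sprint$truth[sprint$truth$foot == foot, , drop = FALSE]
    m <- merge(as.data.frame(tab)[c("stride_index", "length_m")],
               tr[c("stride_index", "length_m")], by = "stride_index",
               suffixes = c("_est", "_true"))
    100 * (m$length_m_est - m$length_m_true) / m$length_m_true
  }), use.names = FALSE)
}
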