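# Stride segmentation, touch-down-artefact correction and double
# integration.

test_that("strides are segmented TD-to-TD with a 280 ms pre-start interval", {
  ev <- gait_events(td = c(600, 1100, 1650), to = c(400, 680, 1180),
                    foot = "left")
  segs <- segment_strides(ev, fs = 500, n_samples = 2000)
  expect_length(segs, 3)
  expect_equal(segs[[1]]$start_idx, 400 - 140)  # 0.280 s * 500 Hz
  expect_equal(segs[[1]]$end_idx, 600)
  expect_true(is.na(segs[[1]]$td_idx))
  expect_equal(segs[[2]]$start_idx, 600)
  expect_equal(segs[[2]]$end_idx, 1100)
  expect_equal(segs[[2]]$td_idx, 600)
  expect_equal(segs[[2]]$contact_end_idx, 680)
  expect_equal(segs[[3]]$start_idx, 1100)
  expect_equal(segs[[3]]$end_idx, 1650)

  # a stride truncated by the end of the signal is dropped with a warning
  expect_warning(segs2 <- segment_strides(ev, fs = 500, n_samples = 1500),
                 "dropped")
  expect_length(segs2, 2)

  # standing start required: not enough samples before the first toe-off
  ev2 <- gait_events(td = 300, to = 100, foot = "left")
  expect_error(segment_strides(ev2, fs = 500, n_samples = 1000),
               "insufficient pre-start")
  # first event must be a toe-off
  ev3 <- gait_events(td = 500, to = 700, foot = "left")
  expect_error(segment_strides(ev3, fs = 500, n_samples = 1000), "toe-off")
})

test_that("integration is trapezoid with mirroring of negative-running axes", {
  fs <- 500
  n <- round(0.5 * fs) + 1
  sp <- global_sprint((0:(n - 1)) / fs, acc_x = rep(2, n),
                      acc_y = numeric(n), acc_z = numeric(n), fs = fs)
  seg <- structure(list(foot = "left", stride_index = 2L, start_idx = 1L,
                        end_idx = n + 1L, td_idx = 1L,
                        contact_end_idx = 60L), class = "stride_segment")
  v <- integrate_and_mirror(seg, sp)
  expect_equal(v$vx[length(v$vx)], 1.0, tolerance = 1e-12)
  expect_false(v$mirrored_x)
  expect_equal(v$vx[1], 0)

  sp_neg <- sp
  sp_neg$acc_x <- -sp_neg$acc_x
  v2 <- integrate_and_mirror(seg, sp_neg)
  expect_equal(v2$vx, v$vx)
  expect_true(v2$mirrored_x)

  # sign-flip symmetry on arbitrary signals, per axis
  set.seed(5)
  sp_r <- global_sprint((0:(n - 1)) / fs, rnorm(n), numeric(n), rnorm(n), fs = fs)
  sp_rn <- sp_r
  sp_rn$acc_x <- -sp_rn$acc_x
  sp_rn$acc_z <- -sp_rn$acc_z
  va <- integrate_and_mirror(seg, sp_r)
  vb <- integrate_and_mirror(seg, sp_rn)
  expect_equal(va$vx, vb$vx)
  expect_equal(va$vz, vb$vz)
  expect_identical(va$mirrored_x, !vb$mirrored_x)
})

test_that("temporary velocity applies the 20 ms clamp with a +1 m/s guard", {
  fs <- 500
  v0 <- numeric(300)
  tmp <- temporary_velocity(v0, fs)
  expect_equal(tmp[1:10], rep(1.0, 10))       # guard on a zero signal
  expect_lt(max(tmp[11:300]), 0.5)            # declines after the clamp

  # guard value equals the (filtered) tenth sample + 1; on a smooth,
  # slowly-varying signal that is the raw tenth sample to high accuracy
  v1 <- 0.3 + 0.001 * sin(2 * pi * 0.8 * (0:299) / fs)
  tmp1 <- temporary_velocity(v1, fs)
  filt <- lowpass_zero_phase(v1, 40, fs)
  expect_equal(tmp1[1:10], rep(filt[10] + 1, 10))
  expect_equal(tmp1[1], 1.3, tolerance = 1e-2)

  expect_error(temporary_velocity(numeric(8), fs), "clamp")
})

test_that("the 40 Hz low-pass attenuates high-frequency power by >= 20 dB", {
  fs <- 500
  set.seed(9)
  x <- rnorm(4096)
  y <- lowpass_zero_phase(x, 40, fs)
  pw <- function(s) {
    sp <- Mod(stats::fft(s))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    mean(sp[f > 80 & f < 250])
  }
  expect_lt(10 * log10(pw(y) / pw(x)), -20)
})

test_that("offset search scans the inclusive window and honours ties", {
  fs <- 500
  # monotonically increasing -> forced to the first window sample (20 ms)
  v_up <- seq(0, 1, length.out = 200)
  off <- find_offset(v_up, fs)
  expect_equal(off$idx, round(0.020 * fs) + 1)

  # unique minimum of 0.42 m/s at 31 ms
  v <- 1 + numeric(200)
  v[round(0.031 * fs) + 1] <- 0.42
  off2 <- find_offset(v, fs)
  expect_equal(off2$value, 0.42)
  expect_equal(off2$idx, round(0.031 * fs) + 1)

  # stride-2 window: a minimum at 140 ms is only reachable with hi = 160 ms
  v3 <- seq(1, 0, length.out = 71)              # falls until 140 ms
  v3 <- c(v3, seq(0, 1, length.out = 129))
  off_std <- find_offset(v3, fs, lo = 0.020, hi = 0.100)
  off_s2 <- find_offset(v3, fs, lo = 0.020, hi = 0.160)
  expect_equal(off_std$idx, round(0.100 * fs) + 1)  # pinned to window end
  expect_equal(off_s2$idx, 71)
  expect_equal(off_s2$value, 0)

  # ties take the earliest sample
  v4 <- rep(1, 200)
  v4[c(20, 30)] <- 0.1
  expect_equal(find_offset(v4, fs)$idx, 20)

  expect_error(find_offset(numeric(30), fs), "window")
})

test_that("zero-velocity update zeroes history and shifts the remainder", {
  v <- c(0.5, 0.6, 0.7, 0.9)
  out <- zero_velocity_update(v, 0.7, 3)
  expect_equal(out, c(0, 0, 0.0, 0.2))
  expect_equal(zero_velocity_update(v, 0, 1), v)
  set.seed(3)
  vr <- rnorm(100)
  outr <- zero_velocity_update(vr, 0.3, 40)
  expect_true(all(outr[1:39] == 0))
  expect_identical(outr[40:100], vr[40:100] - 0.3)
  expect_error(zero_velocity_update(vr, 0, 200), "range")
})

test_that("stride length is the norm of the integrated displacement", {
  fs <- 500
  n <- round(0.8 * fs) + 1
  res <- stride_length(rep(5, n), numeric(n), fs)
  expect_equal(res$length, 4.0, tolerance = 1e-12)
  n2 <- fs + 1
  res2 <- stride_length(rep(3 / sqrt(2), n2), rep(3 / sqrt(2), n2), fs)
  expect_equal(res2$length, 3.0, tolerance = 1e-12)
  expect_error(stride_length(numeric(10), numeric(9), fs), "equal length")
})

test_that("stride 2 uses the extended 20-160 ms search window", {
  # velocity minimum engineered at 140 ms in every stride: acc = 2(t - 0.14)
  fs <- 500
  n <- 1600
  acc <- numeric(n)
  td <- c(500, 800, 1100, 1400)
  for (k in 1:3) {
    tt <- (0:(td[k + 1] - td[k] - 1)) / fs
    acc[td[k]:(td[k + 1] - 1)] <- 2 * (tt - 0.14)
  }
  ev <- gait_events(td = td, to = c(300, 560, 860, 1160), foot = "left")
  sp <- global_sprint((0:(n - 1)) / fs, acc, numeric(n), numeric(n), fs = fs)
  tab <- process_sprint(sp, ev)
  s2 <- tab[tab$stride_index == 2, ]
  s3 <- tab[tab$stride_index == 3, ]
  expect_equal(s2$offset_index_x, round(0.140 * fs) + 1)  # found at 140 ms
  expect_equal(s3$offset_index_x, round(0.100 * fs) + 1)  # capped at 100 ms
})

test_that("the pipeline recovers noiseless simulated stride lengths", {
  for (eff in c("60", "80", "100")) {
    errs <- stride_recovery_errors(clean_sprint(eff))
    expect_lt(max(abs(errs)), 0.5)
  }
})

test_that("stride length is invariant to heading rotation and axis mirroring", {
  sp <- clean_sprint("100")
  cfg_raw <- ss_config("zvu.enabled" = FALSE)
  base <- process_sprint(sp$left)$length_m
  base_raw <- suppressWarnings(process_sprint(sp$left, cfg = cfg_raw)$length_m)
  for (phi in c(0.4, 1.2, 2.9)) {
    rot <- sp$left
    rot$acc_x <- cos(phi) * sp$left$acc_x - sin(phi) * sp$left$acc_z
    rot$acc_z <- sin(phi) * sp$left$acc_x + cos(phi) * sp$left$acc_z
    # pure double integration is an exact isometry of the horizontal norm
    expect_equal(suppressWarnings(process_sprint(rot, cfg = cfg_raw)$length_m),
                 base_raw, tolerance = 1e-12)
    # the per-axis offset correction is heading-stable to well below the
    # method's own noiseless accuracy
    expect_equal(process_sprint(rot)$length_m, base, tolerance = 1e-3)
  }
  mir <- sp$left
  mir$acc_x <- -mir$acc_x
  expect_equal(process_sprint(mir)$length_m, base, tolerance = 1e-12)
})

test_that("stride lengths grow with stride number during the acceleration", {
  sp <- clean_sprint("100")
  for (foot in c("left", "right")) {
    tru <- sp$truth[sp$truth$foot == foot, ]
    expect_true(all(diff(tru$length_m) > 0))
    est <- process_sprint(sp[[foot]])$length_m
    expect_true(all(diff(est) > 0))
  }
})

test_that("stride numbering, durations and maximal stride speed are coherent", {
  sp <- clean_sprint("80")
  tab <- process_sprint(sp$left, effort = "80")
  expect_identical(tab$stride_index, seq_len(nrow(tab)))
  expect_equal(tab$speed_m_s, tab$length_m / tab$duration_s)
  expect_equal(max_stride_speed(tab), max(tab$speed_m_s))
  expect_lt(max_stride_speed(tab), sp$profile$v_max)
  # TD-to-TD durations for strides >= 2
  ev <- sp$left$events
  expect_equal(tab$duration_s[-1], diff(ev$td) / sp$left$fs)
})

test_that("optional linear dedrifting runs and barely moves clean strides", {
  sp <- clean_sprint("100")
  base <- process_sprint(sp$left)
  dd <- process_sprint(sp$left, cfg = ss_config("dedrift.linear" = TRUE))
  expect_true(all(grepl("linear_dedrift", dd$qc_flags)))
  expect_equal(dd$length_m, base$length_m, tolerance = 5e-3)
})

test_that("processing without events fails loudly", {
  sp <- clean_sprint("100")
  naked <- global_sprint(sp$left$t, sp$left$acc_x, sp$left$acc_y,
                         sp$left$acc_z, fs = sp$left$fs, foot = "left")
  expect_error(process_sprint(naked), "no gait events")
  expect_error(process_sprint(sp$left, effort = "95"), "effort")
})
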