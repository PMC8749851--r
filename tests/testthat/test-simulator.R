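# Synthetic sprint generator: profiles, determinism, conservation laws and
# the artefact model.

test_that("effort profiles carry the expected defaults and limits", {
  p <- make_profile("100")
  expect_equal(p$v_max, 8.4)
  expect_equal(make_profile("80")$v_max, 7.65)
  expect_equal(make_profile("60")$v_max, 7.0)
  expect_equal(p$distance, 35)
  # v(t) -> v_max
  expect_equal(profile_speed(p, 1e3), p$v_max, tolerance = 1e-12)
  expect_error(make_profile("100", v_max = -1), "positive")
})

test_that("profile duration matches the Lambert-W closed form", {
  p <- make_profile("100", v_max = 8, tau = 1.3, distance = 35)
  # closed form: with c = d/(v_max*tau), T/tau = 1 + c + W0(-exp(-(1+c)))
  cc <- p$distance / (p$v_max * p$tau)
  T_closed <- p$tau * (1 + cc + pracma::lambertWp(-exp(-(1 + cc))))
  T_num <- profile_duration(p)
  expect_equal(T_num, T_closed, tolerance = 1e-6)
  expect_equal(profile_position(p, T_num), 35, tolerance = 1e-6)
})

test_that("the same seed reproduces a sprint exactly", {
  a <- simulate_sprint(make_profile("80"), seed = 7)
  b <- simulate_sprint(make_profile("80"), seed = 7)
  expect_identical(a$left$acc_x, b$left$acc_x)
  expect_identical(a$right$acc_z, b$right$acc_z)
  expect_identical(a$gyr_x$left, b$gyr_x$left)
  expect_identical(a$truth, b$truth)
  c <- simulate_sprint(make_profile("80"), seed = 8)
  expect_false(identical(a$left$acc_x, c$left$acc_x))
})

test_that("per-foot stride displacements sum to the net displacement", {
  sp <- default_sprint("100", seed = 4)
  for (foot in c("left", "right")) {
    tru <- sp$truth[sp$truth$foot == foot, ]
    # forward displacements telescope to the closed-form body position at
    # the last footfall (the run starts after 1 s of standing)
    init <- c(left = -0.35, right = 0)[[foot]]
    final_x <- profile_position(sp$profile, max(tru$td_time_s) - 1.0)
    expect_equal(sum(tru$dx_m), final_x - init, tolerance = 1e-9)
    # scalar stride lengths bound the net path from above, tightly on a
    # near-straight run
    net <- sqrt(sum(tru$dx_m)^2 + sum(tru$dz_m)^2)
    expect_gte(sum(tru$length_m) + 1e-12, net)
    expect_lt((sum(tru$length_m) - net) / net, 1e-3)
  }
})

test_that("the stance foot is exactly stationary (zero-velocity premise)", {
  sp <- clean_sprint("100")
  g <- sp$left
  ev <- g$events
  for (j in seq_along(ev$td)) {
    nxt_to <- ev$to[ev$to > ev$td[j]]
    end <- if (length(nxt_to)) nxt_to[1] else length(g$t)
    idx <- (ev$td[j] + 1):(end - 1)
    expect_equal(max(abs(g$acc_x[idx])), 0)
    expect_equal(max(abs(g$acc_z[idx])), 0)
  }
})

test_that("clean TD-to-TD double integration reproduces the true lengths", {
  sp <- clean_sprint("80")
  g <- sp$left
  tru <- sp$truth[sp$truth$foot == "left", ]
  td <- g$events$td
  dt <- 1 / g$fs
  for (k in 2:length(td)) {
    idx <- td[k - 1]:(td[k] - 1)
    dx <- pracma::trapz(cumsum(c(0, (g$acc_x[idx][-1] + g$acc_x[idx][-length(idx)]) / 2)) * dt) * dt
    dz <- pracma::trapz(cumsum(c(0, (g$acc_z[idx][-1] + g$acc_z[idx][-length(idx)]) / 2)) * dt) * dt
    est <- sqrt(dx^2 + dz^2)
    expect_lt(abs(est - tru$length_m[k]) / tru$length_m[k], 0.005)
  }
})

test_that("a fixed-magnitude artefact biases naive integration by ~dv * duration", {
  dv <- 0.4
  sp <- simulate_sprint(make_profile("100"), seed = 6,
                        artefact = artefact_config(net_dv_x = dv, net_dv_z = 0),
                        noise = noise_off())
  tab <- suppressWarnings(
    process_sprint(sp$left, cfg = ss_config("zvu.enabled" = FALSE)))
  tru <- sp$truth[sp$truth$foot == "left", ]
  m <- merge(as.data.frame(tab), tru, by = "stride_index")
  s <- m[m$stride_index >= 2, ]
  bias <- abs(abs(s$dx_m.x - s$dx_m.y) - dv * s$duration_s) / (dv * s$duration_s)
  expect_lt(median(bias), 0.1)
})

test_that("range clipping caps the signal at ±16 g", {
  sp_free <- simulate_sprint(make_profile("100"), seed = 2,
                             artefact = artefact_config(peak_g = 25),
                             noise = noise_off())
  expect_gt(max(abs(sp_free$left$acc_x)), 16 * 9.81)
  sp_clip <- simulate_sprint(make_profile("100"), seed = 2,
                             artefact = artefact_config(peak_g = 25),
                             noise = noise_off(), clip = TRUE)
  expect_lte(max(abs(sp_clip$left$acc_x)), 16 * 9.81)
})

test_that("fixture emission writes consistent truth sidecars", {
  sp <- clean_sprint("60")
  dir <- tempfile()
  files <- emit_fixtures(sp, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "sprint_left.csv", "sprint_left_events.csv", "sprint_right.csv",
    "sprint_right_events.csv", "truth.csv")))))
  tru <- utils::read.csv(file.path(dir, "truth.csv"), comment.char = "#")
  expect_equal(nrow(tru), nrow(sp$truth))
  expect_equal(tru$length_m, sp$truth$length_m)
})

test_that("infeasible simulator inputs are rejected", {
  expect_error(simulate_sprint(make_profile("100"), fs = 100), "200 Hz")
  expect_error(simulate_sprint(make_profile("100"), quiet_s = 0.2), "280 ms")
  expect_error(simulate_sprint(make_profile("100", distance = 2)), "footfalls")
})
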