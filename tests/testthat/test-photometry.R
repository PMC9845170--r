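test_that("baseline estimation is robust and drift-tolerant", {
  # flat context
  slice <- rep(5000, 3000)
  expect_equal(as.numeric(estimate_baseline(slice, c(2000, 2500))), 5000)
  # one dropout sample cannot move the median
  slice2 <- slice; slice2[100] <- 0
  expect_equal(as.numeric(estimate_baseline(slice2, c(2000, 2500))), 5000)
  # linear drift of 1%/min: estimate within 0.05% of truth at event onset
  fs <- FS
  n <- round(0.3 * fs)
  drift <- 5000 * (1 + 0.01 / 60 * ((seq_len(n) - 1) / fs))
  ev_start <- n - 100L                 # event at the end: pre-context only
  b <- estimate_baseline(drift, c(ev_start, n), window_s = 0.05,
                         sample_rate = fs)
  expect_equal(as.numeric(b), drift[ev_start], tolerance = 5e-4)
  expect_false(attr(b, "flagged"))
  # no pre-context: post-event side used, flagged
  b2 <- estimate_baseline(rep(4000, 2000), c(1, 500), sample_rate = fs)
  expect_true(attr(b2, "flagged"))
  expect_equal(as.numeric(b2), 4000)
  expect_error(estimate_baseline(rep(1, 10), c(1, 10)), "context")
})

test_that("the flat-top conversion maps fractional drop to area", {
  g <- probe_geometry()                 # 72 mm beam
  expect_equal(g$sigma_pv_mm2, pi * 36^2)
  expect_equal(g$delta_v_m3, pi * 0.036^2 * 36)
  expect_equal(to_extinction_cross_section(5000, 5000, g), 0)
  expect_equal(to_extinction_cross_section(5000, 4500, g), 407.150,
               tolerance = 1e-5)
  expect_error(to_extinction_cross_section(5000, 5001, g), "negative")
  expect_error(to_extinction_cross_section(5000, 0, g), "occlusion")
  # inverse consistency: solve back for ib
  i0 <- 4321.5; ib <- 3987.2
  s <- to_extinction_cross_section(i0, ib, g)
  expect_equal(i0 * (1 - s / g$sigma_pv_mm2), ib, tolerance = 1e-12)
  # invariance to baseline scale
  for (c_ in c(0.1, 3, 42)) {
    expect_equal(to_extinction_cross_section(c_ * i0, c_ * ib, g), s,
                 tolerance = 1e-12)
  }
})

test_that("a simulated opaque disk recovers its geometric cross section", {
  # numerical analogue of dropping an opaque sphere through the beam:
  # a 10 mm disk crossing the 72 mm flat-top beam at 0.5 m/s
  withr::local_seed(71)
  fs <- FS
  g <- probe_geometry()
  r_mm <- 5; R_mm <- 36; v_mms <- 500
  t <- seq(-0.25, 0.25, by = 1 / fs)
  occluded <- disk_occlusion(abs(v_mms * t), r_mm, R_mm)
  baseline <- 5000
  slice <- baseline * (1 - occluded / g$sigma_pv_mm2) +
    rnorm(length(t), 0, noise_total(noise_budget()))
  ev <- range(which(occluded > 0))
  i0 <- estimate_baseline(slice, ev, sample_rate = fs)
  body <- stats::filter(slice, rep(1 / 1501, 1501), sides = 2)
  ib <- min(body[ev[1]:ev[2]], na.rm = TRUE)
  sigma <- to_extinction_cross_section(as.numeric(i0), ib, g)
  expect_equal(sigma, pi * r_mm^2, tolerance = 0.01)
})

test_that("transit time is the full width at 10% of peak extinction", {
  fs <- 1e4
  t <- seq(-0.5, 0.5, by = 1 / fs)
  gauss <- exp(-4 * log(2) * (t / 0.10)^2)       # FWHM 0.10 s
  tt <- transit_time(gauss, fs)
  expect_equal(as.numeric(tt), 0.10 * sqrt(log(10) / log(2)),
               tolerance = 1e-3)
  expect_false(attr(tt, "truncated"))
  # rectangular profile: width equals its own length
  rect <- c(rep(0, 100), rep(1, 3000), rep(0, 100))
  expect_lt(abs(as.numeric(transit_time(rect, fs)) - 0.3), 2.5 / fs)
  # truncated at the record edge: flagged
  half <- gauss[t >= 0]
  th <- transit_time(half, fs)
  expect_true(attr(th, "truncated"))
  expect_lt(as.numeric(th), 0.15)
})

test_that("event kurtosis follows the Pearson convention (Gaussian = 3)", {
  t <- seq(-6, 6, length.out = 20001)
  gauss <- exp(-t^2 / 2)
  expect_equal(event_kurtosis(gauss), 3, tolerance = 0.01)
  expect_equal(event_kurtosis(rep(1, 5001)), 9 / 5, tolerance = 1e-3)
  two_spike <- c(1, rep(0, 999), 1)
  expect_equal(event_kurtosis(two_spike), 1)
  expect_error(event_kurtosis(rep(0, 10)), "positive sum")
  expect_error(event_kurtosis(c(1, -1, 1)), "non-negative")
})

test_that("photometry recovers ledger depth and transit within tolerance", {
  # SNR >= 10 events: body depth within 2%, transit within 5%
  withr::local_seed(72)
  led <- data.frame(center_s = c(6, 14, 22),
                    transit_time_s = c(0.08, 0.2, 0.4),
                    body_depth = c(0.02, 0.05, 0.1),
                    wing_depth = c(0.015, 0.04, 0.08),
                    wingbeat_hz = c(400, 200, 110), kind = "insect",
                    start_time_s = c(6, 14, 22))
  ses <- simulate_session(28, truths = led, seed = 73)
  res <- run_pipeline(ses$record)
  ev <- res$events[res$events$is_insect, ]
  expect_equal(nrow(ev), 3)
  depth_hat <- ev$sigma_b_mm2 / probe_geometry()$sigma_pv_mm2
  expect_equal(depth_hat, led$body_depth, tolerance = 0.02)
  expect_equal(ev$transit_time_s,
               led$transit_time_s * sqrt(log(10) / log(2)),
               tolerance = 0.05)
  # wing glints deeper than the body dip do not contaminate IB
  expect_true(all(ev$ib_mv > 4000 * (1 - led$body_depth - led$wing_depth)))
})
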