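make_events <- function(transits, masses,
                        times = seq_along(transits) * 10,
                        insect = TRUE,
                        origin = as.POSIXct("2021-08-01", tz = "UTC")) {
  data.frame(start_time_utc = origin + times, transit_time_s = transits,
             mass_dry_mg = masses, mass_wet_mg = masses * 2,
             is_insect = rep_len(insect, length(transits)))
}

test_that("the density estimator implements the transit-time weighting", {
  expect_equal(biomass_density(make_events(numeric(0), numeric(0)),
                               10, 0.1466), 0)
  # one event, dt = 0.1 s, m = 10 mg, t_tot = 10 s, dV = 0.1466 m^3
  ev <- make_events(0.1, 10)
  expect_equal(biomass_density(ev, 10, 0.1466), 0.6821, tolerance = 1e-4)
  # non-insect events never contribute
  expect_equal(biomass_density(make_events(0.1, 10, insect = FALSE),
                               10, 0.1466), 0)
  # the transit cut-off gates the sum by default
  short <- make_events(c(0.005, 0.1), c(10, 10))
  expect_equal(biomass_density(short, 10, 0.1466),
               biomass_density(make_events(0.1, 10), 10, 0.1466))
  expect_gt(biomass_density(short, 10, 0.1466, min_transit_s = 0),
            biomass_density(short, 10, 0.1466))
  expect_error(biomass_density(ev, 10, -1), "delta_v")
  expect_error(biomass_density(ev, 0, 0.1), "t_tot")
})

test_that("density is additive over partitions and linear in mass", {
  withr::local_seed(91)
  n <- 60
  ev <- make_events(runif(n, 0.02, 0.6), rexp(n, 0.2),
                    times = runif(n, 0, 3600))
  dv <- probe_geometry()$delta_v_m3
  whole <- biomass_density(ev, 3600, dv)
  origin <- as.POSIXct("2021-08-01", tz = "UTC")
  parts <- vapply(0:3, function(k) {
    sel <- ev$start_time_utc >= origin + k * 900 &
      ev$start_time_utc < origin + (k + 1) * 900
    biomass_density(ev[sel, ], 900, dv)
  }, 0)
  expect_equal(whole, mean(parts), tolerance = 1e-12)   # equal-length parts
  # linearity in mass
  ev3 <- ev; ev3$mass_dry_mg <- 3 * ev3$mass_dry_mg
  expect_equal(biomass_density(ev3, 3600, dv), 3 * whole, tolerance = 1e-12)
  expect_gte(whole, 0)
})

test_that("time-binned series are consistent with the scalar estimator", {
  withr::local_seed(92)
  origin <- as.POSIXct("2021-08-01", tz = "UTC")
  n <- 40
  ev <- make_events(runif(n, 0.02, 0.5), rexp(n, 0.5),
                    times = sort(runif(n, 0, 86400)))
  dv <- 0.1466
  one <- time_binned_density(ev, 86400, span = c(origin, origin + 86400),
                             delta_v_m3 = dv)
  expect_equal(nrow(one), 1)
  expect_equal(one$rho_b, biomass_density(ev, 86400, dv))
  expect_equal(one$n_events, n)
  # events land in the bin containing their start time
  ev2 <- make_events(c(0.1, 0.1), c(5, 7), times = c(30, 90))
  two <- time_binned_density(ev2, 60, span = c(origin, origin + 120),
                             delta_v_m3 = dv)
  expect_equal(two$n_events, c(1L, 1L))
  expect_equal(two$rho_b[1], biomass_density(ev2[1, ], 60, dv))
  # fractional apportioning conserves the total mass-time
  ev3 <- make_events(1.0, 12, times = 59.5)   # straddles the boundary
  frac <- time_binned_density(ev3, 60, span = c(origin, origin + 120),
                              delta_v_m3 = dv, fractional = TRUE)
  expect_equal(sum(frac$rho_b * frac$t_tot_s),
               1.0 * 12 / dv, tolerance = 1e-9)
  whole3 <- time_binned_density(ev3, 60, span = c(origin, origin + 120),
                                delta_v_m3 = dv)
  expect_equal(whole3$rho_b[1], 1.0 / 60 * 12 / dv)
  expect_equal(whole3$rho_b[2], 0)
})

test_that("rolling averages behave as convolution with a box kernel", {
  origin <- as.POSIXct("2021-08-01", tz = "UTC")
  s <- structure(data.frame(bin_start = origin + (0:9) * 60, t_tot_s = 60,
                            n_events = 0L, rho_b = rep(2.5, 10)),
                 class = c("density_series", "data.frame"))
  expect_equal(rolling_average(s, 1)$rho_b, s$rho_b)
  expect_equal(rolling_average(s, 4)$rho_b, s$rho_b)
  imp <- s; imp$rho_b <- c(rep(0, 4), 1, rep(0, 5))
  r <- rolling_average(imp, 3)$rho_b
  expect_equal(r, c(0, 0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0, 0, 0))
})

test_that("diel profiles average across days and find injected peaks", {
  origin <- as.POSIXct("2021-08-01", tz = "UTC")
  # constant traffic over 3 days -> flat profile
  bins <- origin + seq(0, 3 * 86400 - 3600, by = 3600)
  s <- structure(data.frame(bin_start = bins, t_tot_s = 3600, n_events = 1L,
                            rho_b = rep(0.4, length(bins))),
                 class = c("density_series", "data.frame"))
  prof <- diel_profile(s)
  expect_equal(nrow(prof), 24)
  expect_true(all(prof$rho_b == 0.4))
  expect_true(all(prof$n_days == 3))
  # dawn/dusk peaks injected at 05:00 and 21:00
  rho <- rep(0.1, length(bins))
  tod <- (as.numeric(bins) %% 86400) / 3600
  rho[tod == 5] <- 1.0
  rho[tod == 21] <- 0.8
  s2 <- s; s2$rho_b <- rho
  p2 <- diel_profile(s2)
  top2 <- p2$tod_s[order(p2$rho_b, decreasing = TRUE)][1:2]
  expect_setequal(top2 / 3600, c(5, 21))
  # a one-day input is returned unchanged (up to ordering)
  oneday <- structure(
    data.frame(bin_start = origin + seq(0, 86340, by = 60), t_tot_s = 60,
               n_events = 0L, rho_b = runif(1440)),
    class = c("density_series", "data.frame"))
  p1 <- diel_profile(oneday)
  expect_equal(p1$rho_b, oneday$rho_b)
  expect_error(diel_profile(oneday[1:10, ]), "at least one day")
})

test_that("event summaries apply the transit cut-off before statistics", {
  ev <- make_events(c(0.005, 0.015, 0.020), c(1, 3, 100))
  s <- summarize_events(ev, min_transit_s = 0.010)
  expect_equal(s$n_after_cutoff, 2)
  # without cut-off: mean and median of all three masses
  s0 <- summarize_events(ev, min_transit_s = 0)
  expect_equal(s0$mass_dry_mg$mean, 104 / 3, tolerance = 1e-12)
  expect_equal(s0$mass_dry_mg$median, 3)
  # heavy-tailed mass sample: mean far above median
  withr::local_seed(93)
  evh <- make_events(runif(500, 0.02, 0.5), rlnorm(500, log(3), 1.3),
                     times = seq_len(500))
  sh <- summarize_events(evh)
  expect_gt(sh$mass_dry_mg$mean, 2 * sh$mass_dry_mg$median)
  expect_s3_class(sh$hist$mass_dry_mg, "histogram")
})
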