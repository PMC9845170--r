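test_that("signal container round-trips records bit-exactly", {
  withr::local_seed(11)
  t0 <- as.POSIXct("2021-07-13 04:30:00", tz = "UTC")
  for (i in 1:5) {
    n <- sample(100:2000, 1)
    codes <- sample(0:65535, n, replace = TRUE)
    rec <- signal_record(codes * 5000 / 65536, FS, t0 + i,
                         label = paste("rep", i), raw = TRUE)
    p <- withr::local_tempfile(fileext = ".ebs")
    write_signal(rec, p, dtype = "uint16")
    back <- read_signal(p)
    expect_identical(back$samples, rec$samples)
    expect_equal(back$sample_rate, rec$sample_rate)
    expect_equal(as.numeric(back$start_time), as.numeric(rec$start_time))
    expect_identical(back$label, rec$label)
    expect_true(back$raw)
  }
  # float payload, arbitrary millivolt values
  rec <- signal_record(rnorm(1000, 4000, 3), FS, t0, label = "")
  p <- withr::local_tempfile(fileext = ".ebs")
  write_signal(rec, p)
  back <- read_signal(p)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$label, "")
})

test_that("16-bit digitizer codes convert as code * range / 2^16", {
  rec <- signal_record(c(0, 1, 32768, 65535) * 5000 / 65536, FS,
                       as.POSIXct("2021-07-13", tz = "UTC"), raw = TRUE)
  p <- withr::local_tempfile(fileext = ".ebs")
  write_signal(rec, p, dtype = "uint16")
  expect_equal(read_signal(p)$samples,
               c(0, 1, 32768, 65535) * 5000 / 65536)
})

test_that("container refuses overwrite and reports missing metadata", {
  rec <- signal_record(1:100, FS, as.POSIXct("2021-07-13", tz = "UTC"))
  p <- withr::local_tempfile(fileext = ".ebs")
  write_signal(rec, p)
  expect_error(write_signal(rec, p), "overwrite")
  write_signal(rec, p, overwrite = TRUE)

  # corrupt the header: drop the sample_rate_hz field
  con <- file(p, "rb")
  magic <- readBin(con, "raw", 8)
  hlen <- readBin(con, "integer", size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  payload <- readBin(con, "raw", 1e6)
  close(con)
  hdr$sample_rate_hz <- NULL
  hj <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE))
  con <- file(p, "wb")
  writeBin(magic, con)
  writeBin(length(hj), con, size = 4, endian = "little")
  writeBin(hj, con); writeBin(payload, con)
  close(con)
  expect_error(read_signal(p), "sample_rate_hz")

  expect_error(read_signal(withr::local_tempfile()), "no such file")
})

test_that("signal_record enforces its invariants", {
  t0 <- as.POSIXct("2021-07-13", tz = "UTC")
  expect_error(signal_record(numeric(0), FS, t0), "non-empty")
  expect_error(signal_record(c(1, NA), FS, t0), "finite")
  expect_error(signal_record(1:10, -5, t0), "positive")
  expect_error(signal_record(c(100, 5200), FS, t0, raw = TRUE),
               "acquisition range")
  # index i maps to start_time + i / sample_rate, 0-based
  rec <- signal_record(1:4, 2, t0)
  expect_equal(sample_times(rec), c(0, 0.5, 1, 1.5))
  expect_equal(as.numeric(sample_times(rec, absolute = TRUE)[3] - t0,
                          units = "secs"), 1)
})

test_that("calibration tables validate physically impossible rows", {
  df <- data.frame(group = c("a", "a", "b", "b", "c"),
                   sigma_mm2 = c(2, 3, 10, 12, 50),
                   mass_wet_mg = c(1, 1.2, 5, 6, 40),
                   mass_dry_mg = c(0.4, 0.5, 2, 2.5, 18))
  p <- withr::local_tempfile(fileext = ".csv")
  write_calibration_table(df, p)
  back <- read_calibration_table(p)
  expect_equal(nrow(back), 5)
  expect_equal(back$sigma_mm2, df$sigma_mm2)

  bad <- df
  bad$mass_dry_mg[3] <- 99   # dry > wet
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_calibration_table(pb), "row 3")

  bad2 <- df
  bad2$sigma_mm2[2] <- -1
  pb2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, pb2, row.names = FALSE)
  expect_error(read_calibration_table(pb2), "row 2")
})

test_that("a synthetic 187-specimen table keeps the field group sizes", {
  withr::local_seed(3)
  df <- simulate_calibration_samples()
  expect_equal(nrow(df), 187)
  expect_equal(as.vector(table(df$group)[c("mosquito", "fly", "bee", "wasp",
                                           "bumblebee")]),
               c(122L, 50L, 6L, 5L, 4L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_calibration_table(df, p)
  expect_equal(as.vector(table(read_calibration_table(p)$group)),
               as.vector(table(df$group)))
})

test_that("run configuration round-trips through its TOML file", {
  cfg <- run_config(band_low_hz = 15, band_high_hz = 800,
                    threshold_multiplier = 3,
                    geometry = probe_geometry(0.05, 20), seed = 9L)
  p <- withr::local_tempfile(fileext = ".toml")
  write_run_config(cfg, p)
  back <- read_run_config(p)
  expect_equal(back$band_low_hz, 15)
  expect_equal(back$band_high_hz, 800)
  expect_equal(back$threshold_multiplier, 3)
  expect_equal(back$geometry$sigma_pv_mm2, pi * 25^2)
  expect_equal(back$min_crossing_s, cfg$min_crossing_s)
  # defaults are the field operating values
  d <- run_config()
  expect_equal(c(d$band_low_hz, d$band_high_hz, d$threshold_window_s,
                 d$threshold_multiplier, d$min_crossing_s,
                 d$harmonic_max_hz, d$min_transit_s),
               c(10, 900, 5, 2.5, 1e-4, 2000, 0.010))
})

test_that("event tables round-trip with the fixed header", {
  ev <- data.frame(event_id = 1:2,
                   start_time_utc = as.POSIXct("2021-08-01 12:00:00",
                                               tz = "UTC") + c(0, 60),
                   transit_time_s = c(0.1, 0.2), i0_mv = c(4000, 4001),
                   ib_mv = c(3800, 3900), sigma_b_mm2 = c(203, 101),
                   wingbeat_hz = c(136, NA), kurtosis = c(3, 2.5),
                   mass_wet_mg = c(1, NA), mass_dry_mg = c(0.5, NA),
                   is_insect = c(TRUE, FALSE))
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, p)
  hdr <- readLines(p, n = 1)
  expect_match(hdr, "event_id")
  expect_match(hdr, "sigma_b_mm2")
  back <- read_event_table(p)
  expect_equal(back$transit_time_s, ev$transit_time_s)
  expect_equal(back$is_insect, ev$is_insect)
  expect_equal(as.numeric(back$start_time_utc),
               as.numeric(ev$start_time_utc))
})
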