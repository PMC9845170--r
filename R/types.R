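#' Construct a uniformly sampled voltage record
#'
#' The raw material of the whole analysis chain: a single-channel
#' photodetector voltage time series, uniformly sampled, with its sample
#' rate and the UTC timestamp of sample 0. Voltages are held internally in
#' millivolts. Sample index `i` (0-based) maps to time
#' `start_time + i / sample_rate`; all index ranges in the package are
#' half-open `[start, end)`.
#'
#' @param samples numeric vector of voltages, mV. Must be finite and
#'   non-empty.
#' @param sample_rate samples per second, Hz. The field instrument digitizes
#'   at 30,517 Hz.
#' @param start_time `POSIXct` UTC timestamp of sample 0.
#' @param label free-text provenance string.
#' @param acquisition_range_mv full-scale range of the digitizer, mV
#'   (default 5000, i.e. a 5 V range).
#' @param raw logical; if `TRUE` the record is flagged as raw digitizer
#'   output and samples are validated to lie within
#'   `[0, acquisition_range_mv]`.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sample_rate, start_time,
                          label = "", acquisition_range_mv = 5000,
                          raw = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal_record: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("signal_record: 'samples' must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("signal_record: 'sample_rate' must be a single positive number")
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  attr(start_time, "tzone") <- "UTC"
  if (isTRUE(raw)) {
    if (any(samples < 0 | samples > acquisition_range_mv))
      stop("signal_record: raw samples outside the acquisition range [0, ",
           acquisition_range_mv, "] mV")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         start_time = start_time, label = as.character(label)[1],
         acquisition_range_mv = as.numeric(acquisition_range_mv),
         raw = isTRUE(raw)),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<signal_record> %d samples @ %.6g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate, dur))
  cat(sprintf("  start: %s UTC | range: %g mV | raw: %s\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%OS3"),
              x$acquisition_range_mv, x$raw))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Time axis of a signal record
#'
#' @param record a [signal_record()].
#' @param absolute if `TRUE` return `POSIXct` timestamps, otherwise seconds
#'   from the start of the record.
#' @return numeric vector (seconds) or `POSIXct`.
#' @export
sample_times <- function(record, absolute = FALSE) {
  stopifnot(inherits(record, "signal_record"))
  t <- (seq_along(record$samples) - 1L) / record$sample_rate
  if (absolute) record$start_time + t else t
}

#' Probe-volume geometry
#'
#' The probe volume is the intersection of the expanded laser beam and the
#' receiver field of view; for this instrument it is essentially the beam
#' itself, a cylinder of diameter `beam_diameter_m` and length
#' `path_length_m`. Its cross section `sigma_pv_mm2` scales fractional
#' extinction into an absolute extinction cross section, and its volume
#' `delta_v_m3` normalises biomass into a volumetric density.
#'
#' @param beam_diameter_m beam diameter, m (default 0.072, i.e. a 72 mm
#'   expanded beam).
#' @param path_length_m optical path length, m (default 36).
#' @return An object of class `probe_geometry` with derived fields
#'   `sigma_pv_mm2` (probe-volume cross section, mm^2) and `delta_v_m3`
#'   (probed air volume, m^3).
#' @examples
#' g <- probe_geometry()
#' g$sigma_pv_mm2  # pi * 36^2 = 4071.5 mm^2
#' @export
probe_geometry <- function(beam_diameter_m = 0.072, path_length_m = 36) {
  if (beam_diameter_m <= 0 || path_length_m <= 0)
    stop("probe_geometry: dimensions must be strictly positive")
  area_m2 <- pi * (beam_diameter_m / 2)^2
  structure(
    list(beam_diameter_m = beam_diameter_m,
         path_length_m = path_length_m,
         sigma_pv_mm2 = area_m2 * 1e6,
         delta_v_m3 = area_m2 * path_length_m),
    class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(paste0("<probe_geometry> beam %.3g m x path %.3g m | ",
                     "sigma_pv = %.2f mm^2 | dV = %.4f m^3\n"),
              x$beam_diameter_m, x$path_length_m,
              x$sigma_pv_mm2, x$delta_v_m3))
  invisible(x)
}

#' Analysis-chain configuration
#'
#' Collects the tunable parameters of the detection and classification
#' chain. Defaults are the instrument's operating values: a 10--900 Hz
#' band-pass, 5 s sliding windows, a threshold of mean + 2.5 sd, a 0.1 ms
#' minimum crossing, a 2 kHz harmonic-search ceiling, and a 10 ms minimum
#' transit time for event summaries.
#'
#' @param band_low_hz,band_high_hz band-pass filter edges, Hz.
#' @param threshold_window_s sliding-window length for the adaptive
#'   threshold, s.
#' @param threshold_multiplier number of sliding standard deviations added
#'   to the sliding mean.
#' @param min_crossing_s minimum duration a crossing must stay above
#'   threshold to seed a region of interest, s.
#' @param harmonic_max_hz upper limit of the wingbeat fundamental search, Hz.
#' @param min_transit_s hard transit-time cut-off applied to event
#'   summaries (and, by default, the density sum), s.
#' @param smoothing_s moving-average window applied to the filtered
#'   extinction series before thresholding, s.
#' @param merge_gap_s threshold crossings separated by less than this gap
#'   are merged into one region (successive wing glints of one insect), s.
#' @param pad_s symmetric raw-context padding around each region, s.
#' @param accept_ratio minimum harmonic-comb power fraction for an event to
#'   be classified as an insect.
#' @param n_harmonics number of comb teeth used by the harmonic score.
#' @param geometry a [probe_geometry()].
#' @param seed optional integer seed recorded with the configuration.
#' @return An object of class `run_config`.
#' @export
run_config <- function(band_low_hz = 10, band_high_hz = 900,
                       threshold_window_s = 5, threshold_multiplier = 2.5,
                       min_crossing_s = 1e-4, harmonic_max_hz = 2000,
                       min_transit_s = 0.010,
                       smoothing_s = 1e-3, merge_gap_s = 0.020,
                       pad_s = 0.050, accept_ratio = 0.2, n_harmonics = 5L,
                       geometry = probe_geometry(), seed = NULL) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz))
    stop("run_config: need 0 < band_low_hz < band_high_hz")
  if (threshold_multiplier <= 0)
    stop("run_config: 'threshold_multiplier' must be positive")
  if (threshold_window_s <= 0 || min_crossing_s <= 0 || harmonic_max_hz <= 0)
    stop("run_config: window, crossing and harmonic limits must be positive")
  stopifnot(inherits(geometry, "probe_geometry"))
  structure(
    list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         threshold_window_s = threshold_window_s,
         threshold_multiplier = threshold_multiplier,
         min_crossing_s = min_crossing_s,
         harmonic_max_hz = harmonic_max_hz,
         min_transit_s = min_transit_s,
         smoothing_s = smoothing_s, merge_gap_s = merge_gap_s,
         pad_s = pad_s, accept_ratio = accept_ratio,
         n_harmonics = as.integer(n_harmonics),
         geometry = geometry, seed = seed),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  band-pass: %g-%g Hz | threshold: mean + %g sd over %g s\n",
              x$band_low_hz, x$band_high_hz, x$threshold_multiplier,
              x$threshold_window_s))
  cat(sprintf("  min crossing: %g ms | harmonic ceiling: %g Hz | transit cut-off: %g ms\n",
              x$min_crossing_s * 1e3, x$harmonic_max_hz, x$min_transit_s * 1e3))
  print(x$geometry)
  invisible(x)
}
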