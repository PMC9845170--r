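# Event detection: band-pass filtering, adaptive sliding threshold,
# region-of-interest extraction. Insects produce a drop in voltage, so the
# filtered series is negated before thresholding and an upward spike is
# never detected.

#' Zero-phase band-pass filter
#'
#' A Butterworth band-pass (2 poles per edge) applied forward-backward
#' (`signal::filtfilt`), giving zero group delay and an effective 4th-order
#' response per direction. Removes slow baseline drift below `low` and
#' noise above `high`; DC is rejected entirely.
#'
#' @param x numeric vector (mV) or a [signal_record()].
#' @param sample_rate Hz; ignored when `x` is a record.
#' @param low,high band edges, Hz; must satisfy `0 < low < high < Nyquist`.
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass <- function(x, sample_rate = NULL, low = 10, high = 900) {
  if (inherits(x, "signal_record")) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) stop("bandpass: 'sample_rate' required")
  nyq <- sample_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("bandpass: need 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  # odd-reflection padding suppresses the start/end transients that
  # forward-backward filtering otherwise leaves at the record edges
  n <- length(x)
  np <- min(n - 1L, as.integer(round(3 * sample_rate / low)))
  if (np > 0L) {
    xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    y[(np + 1L):(np + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

# Centered moving average; edges take the nearest fully supported value.
.moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  m <- data.table::frollmean(x, n, align = "center")
  .fill_edges(m)
}

.fill_edges <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) stop("internal: all-NA sliding statistic")
  if (ok[1] > 1L) x[seq_len(ok[1] - 1L)] <- x[ok[1]]
  last <- ok[length(ok)]
  if (last < length(x)) x[(last + 1L):length(x)] <- x[last]
  x
}

#' Sliding mean and standard deviation
#'
#' Centered, unweighted sliding windows computed in O(n) via rolling first
#' and second moments; edges are padded with the nearest fully supported
#' value. Matches a brute-force O(n w) computation to rounding error.
#'
#' @param x numeric vector.
#' @param n window length, samples (>= 2).
#' @return List with elements `mean` and `sd`, each the length of `x`.
#' @export
sliding_stats <- function(x, n) {
  n <- as.integer(n)
  if (n < 2L) stop("sliding_stats: window must span at least 2 samples")
  if (n > length(x)) stop("sliding_stats: window longer than the record")
  m1 <- data.table::frollmean(x, n, align = "center")
  m2 <- data.table::frollmean(x * x, n, align = "center")
  v <- pmax(0, (m2 - m1 * m1)) * n / (n - 1)
  list(mean = .fill_edges(m1), sd = .fill_edges(sqrt(v)))
}

#' Adaptive detection threshold
#'
#' `threshold[i] = sliding_mean[i] + multiplier * sliding_sd[i]` over a
#' centered window. With the default 5 s window and multiplier 2.5 the
#' threshold tracks slow drift while staying insensitive to the fast
#' excursions that are events.
#'
#' @param x the (rectified, smoothed) extinction series.
#' @param sample_rate Hz.
#' @param window_s sliding-window length, s.
#' @param multiplier standard-deviation multiplier.
#' @return Numeric threshold sequence, same length as `x`.
#' @export
adaptive_threshold <- function(x, sample_rate, window_s = 5,
                               multiplier = 2.5) {
  n <- as.integer(round(window_s * sample_rate))
  if (n < 2L) stop("adaptive_threshold: window spans fewer than 2 samples")
  if (n > length(x)) stop("adaptive_threshold: window longer than the record")
  s <- sliding_stats(x, n)
  s$mean + multiplier * s$sd
}

#' Find regions of interest in a raw record
#'
#' Detection chain: band-pass filter, negate (a voltage drop becomes a
#' positive extinction excursion), smooth with a short moving average,
#' threshold against [adaptive_threshold()]. Above-threshold runs lasting
#' longer than `min_crossing_s` seed regions; runs separated by less than
#' `merge_gap_s` are merged (one insect's wing glints cross the threshold
#' repeatedly). Indices are 0-based and half-open.
#'
#' @param record a [signal_record()].
#' @param config a [run_config()].
#' @return `data.frame` of class `roi_table`: `start_index, end_index`
#'   (the merged above-threshold run), `slice_start, slice_end` (run plus
#'   `pad_s` context, clipped at record edges), `peak_mv` (peak smoothed
#'   extinction), `duration_s`. Empty on a quiet signal.
#' @export
find_regions <- function(record, config = run_config()) {
  stopifnot(inherits(record, "signal_record"), inherits(config, "run_config"))
  fs <- record$sample_rate
  if (config$band_high_hz >= fs / 2)
    stop("find_regions: band_high_hz must be below the Nyquist frequency")
  filt <- bandpass(record$samples, fs, config$band_low_hz, config$band_high_hz)
  ext <- .moving_average(-filt, round(config$smoothing_s * fs))
  thr <- adaptive_threshold(ext, fs, config$threshold_window_s,
                            config$threshold_multiplier)
  tr <- threshold_runs(ext > thr, fs, config$min_crossing_s,
                       config$merge_gap_s)
  if (!nrow(tr)) return(.empty_roi())
  out_s <- tr$start; out_e <- tr$end
  n <- length(record$samples)
  # padding scales with the run: the band-pass attenuates the slow
  # envelope, so the above-threshold run undershoots the transit extent
  # by roughly its own duration on each side
  pad <- as.integer(round(config$pad_s * fs)) + (out_e - out_s + 1L)
  peak <- vapply(seq_along(out_s),
                 function(i) max(ext[out_s[i]:out_e[i]]), 0)
  structure(
    data.frame(start_index = out_s - 1L,          # 0-based, half-open
               end_index = out_e,
               slice_start = pmax(out_s - 1L - pad, 0L),
               slice_end = pmin(out_e + pad, n),
               peak_mv = peak,
               duration_s = (out_e - out_s + 1L) / fs),
    class = c("roi_table", "data.frame"))
}

#' Above-threshold runs surviving the minimum-crossing rule
#'
#' Extracts runs of `TRUE` from a logical exceedance vector, discards
#' runs whose duration does not exceed `min_crossing_s` (the crossing
#' must last strictly more than the minimum), and merges surviving runs
#' separated by less than `merge_gap_s`.
#'
#' @param above logical vector (extinction > threshold).
#' @param sample_rate Hz.
#' @param min_crossing_s minimum crossing duration, s (default 0.1 ms).
#' @param merge_gap_s merge gap, s (0 disables merging).
#' @return `data.frame` with 1-based inclusive `start`/`end` columns.
#' @examples
#' # 2 samples at 30,517 Hz last 0.066 ms: below the 0.1 ms minimum
#' threshold_runs(c(FALSE, TRUE, TRUE, FALSE), 30517)
#' @export
threshold_runs <- function(above, sample_rate, min_crossing_s = 1e-4,
                           merge_gap_s = 0) {
  runs <- rle(as.logical(above))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & (runs$lengths / sample_rate > min_crossing_s)
  rs <- starts[keep]; re <- ends[keep]
  if (!length(rs))
    return(data.frame(start = integer(0), end = integer(0)))
  gap <- round(merge_gap_s * sample_rate)
  out_s <- integer(0); out_e <- integer(0)
  ms <- rs[1]; me <- re[1]
  for (i in seq_along(rs)[-1]) {
    if (rs[i] - me < gap) {
      me <- re[i]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- rs[i]; me <- re[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

.empty_roi <- function() {
  structure(
    data.frame(start_index = integer(0), end_index = integer(0),
               slice_start = integer(0), slice_end = integer(0),
               peak_mv = numeric(0), duration_s = numeric(0)),
    class = c("roi_table", "data.frame"))
}

#' Extract the padded raw slice of a region
#'
#' @param record a [signal_record()].
#' @param region one row of the table returned by [find_regions()].
#' @return Numeric vector of raw millivolts with attributes `offset`
#'   (0-based index of the first slice sample) and `event_rel` (1-based
#'   first/last sample of the above-threshold run within the slice).
#' @export
extract_region <- function(record, region) {
  sl <- record$samples[(region$slice_start + 1L):region$slice_end]
  attr(sl, "offset") <- region$slice_start
  attr(sl, "event_rel") <- c(region$start_index - region$slice_start + 1L,
                             region$end_index - region$slice_start)
  sl
}
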