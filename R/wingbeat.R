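# Wingbeat analysis: spectra, harmonic-series detection (insect vs
# non-insect classification), wing/body separation.

#' One-sided power spectrum of an event segment
#'
#' The segment is mean-removed, Hann-windowed (to suppress leakage from
#' the transit envelope) and zero-padded to the next power of two at least
#' `zero_pad` times the segment length. Zero-padding interpolates the
#' spectrum; the intrinsic frequency resolution remains
#' `sample_rate / length(segment)` and is returned as `resolution_hz`.
#'
#' @param segment numeric voltage segment (>= 16 samples).
#' @param sample_rate Hz.
#' @param zero_pad zero-padding factor (>= 1).
#' @return List: `frequency` (Hz), `power` (one-sided), `resolution_hz`
#'   (intrinsic), `bin_hz` (spacing of the padded grid).
#' @export
event_spectrum <- function(segment, sample_rate, zero_pad = 4) {
  n <- length(segment)
  if (n < 16L) stop("event_spectrum: segment must have >= 16 samples")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xw <- (segment - mean(segment)) * w
  nfft <- 2^ceiling(log2(n * max(1, zero_pad)))
  p <- abs(stats::fft(c(xw, numeric(nfft - n))))^2
  half <- nfft %/% 2 + 1L
  list(frequency = (seq_len(half) - 1L) * sample_rate / nfft,
       power = p[seq_len(half)],
       resolution_hz = sample_rate / n,
       bin_hz = sample_rate / nfft)
}

# Sum of spectral power within +/- hw bins of frequency f (Hz).
.comb_tooth_power <- function(power, bin_hz, f, hw) {
  i <- as.integer(round(f / bin_hz)) + 1L
  lo <- max(1L, i - hw); hi <- min(length(power), i + hw)
  sum(power[lo:hi])
}

#' Detect a harmonic series and classify insect vs non-insect
#'
#' Well-defined harmonic series are the signature of wing glints; passive
#' targets (leaves, pollen) produce an envelope with no periodicity. The
#' fundamental is found by maximising a harmonic-comb score over candidate
#' fundamentals in `band`: the summed power within one intrinsic
#' resolution of `k * f` (k = 1..`n_harmonics`, teeth above
#' `harmonic_max` ignored), normalised by the total power in
#' `[band[1], harmonic_max]`. The candidate grid is the padded spectral
#' grid restricted to `band`; the winning fundamental is refined by
#' quadratic interpolation of the spectral peak. An event is classified as
#' an insect when the score reaches `accept_ratio` and at least two comb
#' teeth are distinct spectral peaks.
#'
#' @param spec spectrum as returned by [event_spectrum()].
#' @param band numeric length-2: fundamental search band, Hz. The lower
#'   limit should be `2 / duration` so at least two full wingbeat periods
#'   fit in the event; the upper limit is fixed at 2 kHz in the field
#'   configuration.
#' @param n_harmonics comb teeth (default 5).
#' @param accept_ratio minimum score for insect classification.
#' @param harmonic_max upper frequency bound of the comb and of the
#'   normalisation band, Hz (defaults to `band[2]`).
#' @return List of class `harmonic_result`: `fundamental_hz`, `score`,
#'   `n_peaks` (comb teeth that are distinct spectral maxima),
#'   `harmonic_power` (per-tooth power), `is_insect`, `band`, `reason`
#'   (`"ok"`, `"band_empty"`, `"low_score"`, or `"few_harmonics"`).
#' @export
detect_harmonic_series <- function(spec, band, n_harmonics = 5L,
                                   accept_ratio = 0.2,
                                   harmonic_max = band[2]) {
  res <- .non_insect_result(band)
  fmax <- spec$frequency[length(spec$frequency)]
  hi <- min(band[2], harmonic_max, fmax)
  if (band[1] >= hi) {
    res$reason <- "band_empty"
    return(res)
  }
  inband <- which(spec$frequency >= band[1] & spec$frequency <= hi)
  norm_band <- which(spec$frequency >= band[1] &
                       spec$frequency <= min(harmonic_max, fmax))
  total <- sum(spec$power[norm_band])
  if (length(inband) < 3L || total <= 0) {
    res$reason <- "band_empty"
    return(res)
  }
  # a pure transit envelope (no glints, no noise) leaves only numerical
  # leakage in the search band; relative comb scores are then meaningless
  if (total < 1e-4 * sum(spec$power)) {
    res$reason <- "no_band_power"
    return(res)
  }
  hw <- max(1L, as.integer(ceiling(spec$resolution_hz / spec$bin_hz)))
  # comb sums only see in-band power, so the score stays within [0, 1]
  # (up to boundary-bin overlap of adjacent teeth)
  pb <- numeric(length(spec$power))
  pb[norm_band] <- spec$power[norm_band]
  cand <- spec$frequency[inband]
  score <- numeric(length(cand))
  for (k in seq_len(n_harmonics)) {
    fk <- k * cand
    ok <- fk <= min(harmonic_max, fmax)
    if (!any(ok)) break
    idx <- as.integer(round(fk[ok] / spec$bin_hz)) + 1L
    tooth <- numeric(sum(ok))
    for (d in -hw:hw) {
      j <- pmin(pmax(idx + d, 1L), length(pb))
      tooth <- tooth + pb[j]
    }
    score[ok] <- score[ok] + tooth
  }
  score <- score / total
  # octave disambiguation: a pulse train with strong high harmonics can
  # score higher at 2 f0 (its comb reaches further up the series); take
  # the lowest candidate scoring within 75% of the maximum
  best_score <- max(score)
  best <- which(score >= 0.75 * best_score)[1]
  f0 <- cand[best]
  # quadratic refinement on the spectral peak nearest the fundamental
  i <- as.integer(round(f0 / spec$bin_hz)) + 1L
  win <- max(1L, i - hw):min(length(spec$power), i + hw)
  i <- win[which.max(spec$power[win])]
  if (i > 1L && i < length(spec$power)) {
    p <- spec$power[(i - 1L):(i + 1L)]
    den <- p[1] - 2 * p[2] + p[3]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (p[1] - p[3]) / den
      if (abs(delta) <= 1) f0 <- (i - 1L + delta) * spec$bin_hz
    }
  }
  hp <- vapply(seq_len(n_harmonics), function(k) {
    if (k * f0 > min(harmonic_max, fmax)) return(NA_real_)
    .comb_tooth_power(spec$power, spec$bin_hz, k * f0, hw)
  }, 0)
  med <- stats::median(spec$power[norm_band])
  np <- length(spec$power)
  # a tooth counts as a harmonic peak only if its window maximum stands
  # well above the noise floor AND above the spectrum just outside the
  # window on both sides (rejects monotone envelope leakage)
  n_peaks <- 0L
  for (k in seq_len(n_harmonics)) {
    fk <- k * f0
    if (fk > min(harmonic_max, fmax)) break
    i0 <- as.integer(round(fk / spec$bin_hz)) + 1L
    lo <- max(1L, i0 - hw); hi_i <- min(np, i0 + hw)
    wmax <- max(spec$power[lo:hi_i])
    l <- max(1L, i0 - 3L * hw); r <- min(np, i0 + 3L * hw)
    if (wmax > 5 * med && wmax > spec$power[l] && wmax > spec$power[r])
      n_peaks <- n_peaks + 1L
  }
  res$fundamental_hz <- f0
  res$score <- score[best]
  res$harmonic_power <- hp
  res$n_peaks <- n_peaks
  if (score[best] < accept_ratio) {
    res$reason <- "low_score"
  } else if (n_peaks < 2L) {
    res$reason <- "few_harmonics"
  } else {
    res$is_insect <- TRUE
    res$reason <- "ok"
  }
  res
}

.non_insect_result <- function(band) {
  structure(list(fundamental_hz = NA_real_, score = 0, n_peaks = 0L,
                 harmonic_power = numeric(0), is_insect = FALSE,
                 band = band, reason = "none"),
            class = "harmonic_result")
}

#' @export
print.harmonic_result <- function(x, ...) {
  if (x$is_insect)
    cat(sprintf("<harmonic_result> insect: f0 = %.2f Hz, score %.3f, %d peaks\n",
                x$fundamental_hz, x$score, x$n_peaks))
  else
    cat(sprintf("<harmonic_result> non-insect (%s)\n", x$reason))
  invisible(x)
}

#' Fundamental search band for an event
#'
#' The lower limit guarantees at least two full wingbeat periods fit in
#' the event; the upper limit is the fixed harmonic-search ceiling.
#'
#' @param duration_s event duration, s.
#' @param harmonic_max_hz search ceiling, Hz (default 2000).
#' @return numeric length-2 band, Hz. May be empty (`band[1] >= band[2]`)
#'   for very short events.
#' @examples
#' harmonic_band(0.020)  # c(100, 2000)
#' @export
harmonic_band <- function(duration_s, harmonic_max_hz = 2000) {
  c(2 / duration_s, harmonic_max_hz)
}

#' Separate wing and body contributions of an event
#'
#' The body contribution is the slowly varying transit envelope: a
#' zero-phase low-pass at half the wingbeat fundamental, applied in the
#' frequency domain with a raised-cosine roll-off (stable at arbitrarily
#' low cut-offs, where low-order IIR realisations are not; the segment is
#' endpoint-detrended first so the circular wrap introduces no edge
#' artefact). Samples identified as wing glints (strong negative residual
#' after the first pass) are interpolated across before a second
#' low-pass, so the glint train's nonzero mean does not bleed into the
#' body estimate. The wing contribution is the residual, so the two
#' components always sum to the original segment. When half the
#' fundamental is not comfortably above the envelope bandwidth
#' (about `2 / duration`), the filter cannot split the two and the
#' function falls back to an envelope estimate that interpolates across
#' the glints (rolling maximum over one wingbeat period, smoothed --
#' glints dip below the body envelope), flagged in the result.
#'
#' @param segment raw voltage slice, mV.
#' @param fundamental_hz wingbeat fundamental, Hz.
#' @param sample_rate Hz.
#' @return List: `body`, `wing` (numeric, `body + wing == segment`),
#'   `flagged` (logical; `TRUE` when the fallback was used).
#' @export
separate_wing_body <- function(segment, fundamental_hz, sample_rate) {
  if (!is.finite(fundamental_hz) || fundamental_hz <= 0)
    stop("separate_wing_body: a positive wingbeat fundamental is required")
  duration <- length(segment) / sample_rate
  cutoff <- fundamental_hz / 2
  if (cutoff > 2.5 * (2 / duration) && cutoff < sample_rate / 2) {
    # first pass: plain low-pass. The glint train has a nonzero mean
    # (pulses of ~10% duty), which a low-pass folds into the body and
    # thereby overstates the body dip; second pass interpolates across
    # the glint samples before low-passing, removing that bias.
    body <- .fft_lowpass(segment, sample_rate, cutoff)
    wing0 <- segment - body
    mask <- wing0 < -3 * stats::mad(wing0)
    if (any(mask) && mean(mask) < 0.5) {
      keep <- which(!mask)
      x2 <- segment
      x2[mask] <- stats::approx(keep, segment[keep], xout = which(mask),
                                rule = 2)$y
      body <- .fft_lowpass(x2, sample_rate, cutoff)
    }
    flagged <- FALSE
  } else {
    w <- max(3L, as.integer(round(sample_rate / fundamental_hz)))
    body <- .rolling_max(segment, w)
    body <- .moving_average(body, w)
    flagged <- TRUE
  }
  list(body = body, wing = segment - body, flagged = flagged)
}

# Zero-phase low-pass via the DFT: unity gain below 0.8 * cutoff,
# raised-cosine transition to zero at 1.2 * cutoff. The linear trend
# between the segment endpoints is removed before the transform and added
# back, so the circular extension is continuous.
.fft_lowpass <- function(x, sample_rate, cutoff) {
  n <- length(x)
  idx <- seq_len(n) - 1L
  trend <- x[1] + (x[n] - x[1]) * idx / (n - 1L)
  f <- idx * sample_rate / n
  f <- pmin(f, sample_rate - f)          # two-sided frequency magnitude
  lo <- 0.8 * cutoff; hi <- 1.2 * cutoff
  h <- ifelse(f <= lo, 1,
              ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / (hi - lo)))))
  trend + Re(stats::fft(stats::fft(x - trend) * h, inverse = TRUE)) / n
}

.rolling_max <- function(x, w) {
  m <- data.table::frollapply(x, w, max, align = "center")
  .fill_edges(m)
}
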