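# Extinction photometry: baseline I0, body minimum IB, extinction cross
# section (flat-top beam approximation), transit time and the kurtosis
# shape statistic.

#' Estimate the baseline intensity I0 of an event
#'
#' The baseline is a robust location (median) of the context samples
#' farthest from the event -- the start of the padded slice on the
#' pre-event side and its end on the post-event side, where the transit
#' envelope (which extends beyond the above-threshold run) has decayed.
#' When both sides are available their medians are averaged, which
#' cancels linear baseline drift to first order at the event centre;
#' with no pre-event context (event at the start of a record) the
#' post-event side alone is used and the result is flagged.
#'
#' @param slice padded raw slice from [extract_region()] (or any numeric
#'   vector, with `event_rel` given explicitly).
#' @param event_rel 1-based first/last sample of the event within the
#'   slice; defaults to the slice's `event_rel` attribute.
#' @param window_s context window length, s (default 50 ms).
#' @param sample_rate Hz; required when `window_s` should limit the
#'   context (otherwise all available context is used).
#' @return Baseline, mV, with attribute `flagged` (`TRUE` when post-event
#'   context had to be used).
#' @export
estimate_baseline <- function(slice, event_rel = attr(slice, "event_rel"),
                              window_s = 0.05, sample_rate = NULL) {
  if (is.null(event_rel))
    stop("estimate_baseline: 'event_rel' not supplied and not an attribute")
  n <- length(slice)
  wn <- if (is.null(sample_rate)) n else
    max(1L, as.integer(round(window_s * sample_rate)))
  pre <- utils::head(seq_len(max(0L, event_rel[1] - 1L)), wn)
  post <- if (event_rel[2] < n) (event_rel[2] + 1L):n else integer(0)
  post <- utils::tail(post, wn)
  have_pre <- length(pre) >= 8L
  have_post <- length(post) >= 8L
  if (have_pre && have_post) {
    out <- (stats::median(slice[pre]) + stats::median(slice[post])) / 2
    attr(out, "flagged") <- FALSE
  } else if (have_pre) {
    out <- stats::median(slice[pre])
    attr(out, "flagged") <- FALSE
  } else if (length(post)) {
    out <- stats::median(slice[post])
    attr(out, "flagged") <- TRUE
  } else {
    stop("estimate_baseline: no context samples on either side of the event")
  }
  out
}

#' Body extinction cross section (flat-top beam approximation)
#'
#' Under the flat-top approximation the beam's energy density is uniform
#' across the probe volume, so the fractional drop in intensity maps
#' linearly to the occluded area:
#' `sigma_B = sigma_pv * (I0 - IB) / I0`.
#'
#' @param i0 baseline intensity, mV.
#' @param ib body-minimum intensity, mV; must satisfy `0 < ib <= i0`.
#' @param geometry a [probe_geometry()].
#' @return Body extinction cross section, mm^2 (vectorised over
#'   `i0`/`ib`).
#' @examples
#' to_extinction_cross_section(5000, 4500, probe_geometry())  # 407.15 mm^2
#' @export
to_extinction_cross_section <- function(i0, ib, geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  if (any(ib > i0))
    stop("to_extinction_cross_section: ib > i0 (negative extinction)")
  if (any(ib <= 0))
    stop("to_extinction_cross_section: ib <= 0 (full occlusion exceeds the ",
         "flat-top model)")
  geometry$sigma_pv_mm2 * (i0 - ib) / i0
}

#' Body-minimum intensity IB
#'
#' @param body body component of an event (from [separate_wing_body()]).
#' @return Minimum of the body component, mV: the signal value when the
#'   insect body is fully centred in the probe volume.
#' @export
body_minimum <- function(body) min(body)

#' Transit time of an event
#'
#' Defined as the full width of the body extinction profile at `frac`
#' (default 10%) of its peak, with sub-sample linear interpolation at the
#' crossings. For a Gaussian envelope of FWHM `w` this gives
#' `w * sqrt(log(10) / log(2)) = 1.823 w`. If the profile is still above
#' the level at either edge (event truncated at a record boundary), the
#' width is computed on the available support and flagged.
#'
#' @param profile non-negative extinction profile (e.g. `i0 - body`), mV.
#' @param sample_rate Hz.
#' @param frac threshold fraction of the peak (default 0.1).
#' @return Transit time, s, with attribute `truncated`.
#' @export
transit_time <- function(profile, sample_rate, frac = 0.1) {
  n <- length(profile)
  pk_i <- which.max(profile)
  level <- frac * profile[pk_i]
  truncated <- FALSE
  # walk left from the peak to the first sub-level sample
  i <- pk_i
  while (i > 1L && profile[i - 1L] >= level) i <- i - 1L
  if (i == 1L && profile[1L] >= level) {
    t_left <- 0
    truncated <- TRUE
  } else {
    # interpolate between samples i-1 (below) and i (above)
    t_left <- (i - 1L) - (profile[i] - level) /
      (profile[i] - profile[i - 1L])
  }
  j <- pk_i
  while (j < n && profile[j + 1L] >= level) j <- j + 1L
  if (j == n && profile[n] >= level) {
    t_right <- n - 1L
    truncated <- TRUE
  } else {
    t_right <- (j - 1L) + (profile[j] - level) /
      (profile[j] - profile[j + 1L])
  }
  out <- (t_right - t_left) / sample_rate
  attr(out, "truncated") <- truncated
  attr(out, "bounds") <- c(t_left, t_right) + 1  # 1-based sample positions
  out
}

#' Kurtosis of an event shape
#'
#' Pearson kurtosis (Gaussian reference value 3, not excess) of the time
#' variable weighted by the extinction profile, i.e. the profile is
#' treated as an unnormalised density over time and `mu4 / mu2^2` of that
#' density is returned. A Gaussian-shaped event gives 3, a rectangular
#' one 9/5, a symmetric two-spike profile 1.
#'
#' @param profile non-negative extinction profile with positive sum.
#' @return Pearson kurtosis, dimensionless.
#' @export
event_kurtosis <- function(profile) {
  if (any(profile < 0))
    stop("event_kurtosis: profile must be non-negative")
  s <- sum(profile)
  if (s <= 0) stop("event_kurtosis: profile must have positive sum")
  t <- seq_along(profile)
  mu <- sum(profile * t) / s
  m2 <- sum(profile * (t - mu)^2) / s
  m4 <- sum(profile * (t - mu)^4) / s
  m4 / m2^2
}

#' Full photometry of one detected region
#'
#' Orchestrates the per-event measurements: baseline `I0`, wing/body
#' separation (insects) or plain smoothing (non-insects), body minimum
#' `IB`, extinction cross section, transit time and kurtosis.
#'
#' @param slice padded raw slice from [extract_region()].
#' @param harmonic a `harmonic_result` for the region.
#' @param sample_rate Hz.
#' @param geometry a [probe_geometry()].
#' @param transit_frac threshold fraction for [transit_time()].
#' @return List: `i0_mv, ib_mv, sigma_b_mm2, transit_time_s, kurtosis,
#'   extinction_frac, baseline_flagged, truncated, separation_flagged`.
#' @export
region_photometry <- function(slice, harmonic, sample_rate,
                              geometry = probe_geometry(),
                              transit_frac = 0.1) {
  event_rel <- attr(slice, "event_rel")
  i0 <- estimate_baseline(slice, event_rel, sample_rate = sample_rate)
  if (isTRUE(harmonic$is_insect)) {
    sep <- separate_wing_body(slice, harmonic$fundamental_hz, sample_rate)
    body <- sep$body
    sep_flag <- sep$flagged
  } else {
    body <- .moving_average(slice, max(1L, round(0.001 * sample_rate)))
    sep_flag <- FALSE
  }
  ib <- body_minimum(body[event_rel[1]:event_rel[2]])
  ib_eff <- min(ib, as.numeric(i0))     # noise can push IB above I0
  sigma <- if (ib_eff > 0 && ib_eff < i0)
    to_extinction_cross_section(as.numeric(i0), ib_eff, geometry) else 0
  profile <- pmax(0, as.numeric(i0) - body)
  tt <- transit_time(profile, sample_rate, transit_frac)
  # kurtosis over the transit support (10%-of-peak crossings grown by
  # half a width each side): residual baseline ripple far out in the
  # padded slice would otherwise dominate the 4th moment
  b <- attr(tt, "bounds")
  grow <- (b[2] - b[1]) / 2
  kw <- max(1L, floor(b[1] - grow)):min(length(profile), ceiling(b[2] + grow))
  list(i0_mv = as.numeric(i0), ib_mv = ib,
       sigma_b_mm2 = sigma,
       transit_time_s = as.numeric(tt),
       kurtosis = event_kurtosis(profile[kw]),
       extinction_frac = (as.numeric(i0) - ib_eff) / as.numeric(i0),
       baseline_flagged = isTRUE(attr(i0, "flagged")),
       truncated = isTRUE(attr(tt, "truncated")),
       separation_flagged = sep_flag)
}
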