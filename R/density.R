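# Volumetric biomass density: transit-time-weighted aggregation of event
# masses, rho_b = sum_n (dt_n / t_tot) * m_n / dV, in mg/m^3, plus the
# time-binned, rolling and diel aggregation products and event summaries.

.mass_col <- function(basis) {
  switch(match.arg(basis, c("dry", "wet")),
         dry = "mass_dry_mg", wet = "mass_wet_mg")
}

.density_events <- function(events, basis, min_transit_s) {
  mc <- .mass_col(basis)
  keep <- events$is_insect %in% TRUE &
    is.finite(events[[mc]]) &
    events$transit_time_s >= min_transit_s
  events[keep, , drop = FALSE]
}

#' Volumetric biomass density over one window
#'
#' Each insect contributes its mass weighted by the fraction of the
#' window it spent inside the probe volume:
#' `rho_b = sum_n (dt_n / t_tot) * m_n / dV` (mg/m^3). Only events
#' classified as insects are counted; by default events shorter than
#' `min_transit_s` are excluded from the sum as well as from summaries.
#'
#' @param events event `data.frame` (see [run_pipeline()] /
#'   [read_event_table()]); all events assumed within the window.
#' @param t_tot_s window length, s.
#' @param delta_v_m3 probed air volume, m^3 (see [probe_geometry()]).
#' @param basis `"dry"` (reporting standard) or `"wet"`.
#' @param min_transit_s transit-time cut-off gating the sum, s (default
#'   10 ms; set 0 to disable).
#' @return Biomass density, mg/m^3 (never negative; 0 with no events).
#' @examples
#' ev <- data.frame(transit_time_s = 0.1, mass_dry_mg = 10, is_insect = TRUE)
#' biomass_density(ev, t_tot_s = 10, delta_v_m3 = 0.1466)  # 0.682 mg/m^3
#' @export
biomass_density <- function(events, t_tot_s, delta_v_m3,
                            basis = c("dry", "wet"), min_transit_s = 0.010) {
  basis <- match.arg(basis)
  if (t_tot_s <= 0) stop("biomass_density: 't_tot_s' must be > 0")
  if (delta_v_m3 <= 0) stop("biomass_density: 'delta_v_m3' must be > 0")
  if (!nrow(events)) return(0)
  ev <- .density_events(events, basis, min_transit_s)
  if (!nrow(ev)) return(0)
  sum(ev$transit_time_s / t_tot_s * ev[[.mass_col(basis)]]) / delta_v_m3
}

#' Time-binned biomass density series
#'
#' Applies [biomass_density()] per uniform bin. By default an event is
#' assigned wholly to the bin containing its start time; with
#' `fractional = TRUE` its transit time is apportioned across the bins it
#' overlaps.
#'
#' @param events event `data.frame` with a `start_time_utc` column
#'   (`POSIXct`).
#' @param bin_s bin length, s.
#' @param span length-2 `POSIXct`: start and end of the series; defaults
#'   to the event range aligned to whole bins.
#' @param delta_v_m3 probed air volume, m^3.
#' @param basis mass basis.
#' @param min_transit_s transit cut-off, s.
#' @param fractional apportion transit time across bin boundaries.
#' @return `data.frame` of class `density_series`: `bin_start`
#'   (`POSIXct`), `t_tot_s`, `n_events`, `rho_b` (mg/m^3); attributes
#'   `delta_v_m3` and `basis`.
#' @export
time_binned_density <- function(events, bin_s, span = NULL, delta_v_m3,
                                basis = c("dry", "wet"),
                                min_transit_s = 0.010, fractional = FALSE) {
  basis <- match.arg(basis)
  if (bin_s <= 0) stop("time_binned_density: 'bin_s' must be > 0")
  if (delta_v_m3 <= 0) stop("time_binned_density: 'delta_v_m3' must be > 0")
  ev <- .density_events(events, basis, min_transit_s)
  if (is.null(span)) {
    if (!nrow(ev)) stop("time_binned_density: no events and no 'span'")
    t0 <- min(ev$start_time_utc)
    span <- c(t0, max(ev$start_time_utc) + 1)
  }
  origin <- as.POSIXct(span[1], tz = "UTC")
  nbin <- max(1L, as.integer(ceiling(
    as.numeric(difftime(span[2], origin, units = "secs")) / bin_s)))
  bins <- origin + (seq_len(nbin) - 1L) * bin_s
  rho <- numeric(nbin)
  cnt <- integer(nbin)
  if (nrow(ev)) {
    off <- as.numeric(difftime(ev$start_time_utc, origin, units = "secs"))
    mvals <- ev[[.mass_col(basis)]]
    if (!fractional) {
      ib <- floor(off / bin_s) + 1L
      inside <- ib >= 1L & ib <= nbin
      contrib <- ev$transit_time_s / bin_s * mvals / delta_v_m3
      agg <- tapply(contrib[inside], ib[inside], sum)
      rho[as.integer(names(agg))] <- as.numeric(agg)
      cc <- tapply(rep(1L, sum(inside)), ib[inside], sum)
      cnt[as.integer(names(cc))] <- as.integer(cc)
    } else {
      for (i in seq_len(nrow(ev))) {
        a <- off[i]; b <- off[i] + ev$transit_time_s[i]
        j0 <- max(1L, floor(a / bin_s) + 1L)
        j1 <- min(nbin, floor(max(b - 1e-12, a) / bin_s) + 1L)
        if (j1 < j0) next
        for (j in j0:j1) {
          ov <- min(b, j * bin_s) - max(a, (j - 1) * bin_s)
          if (ov <= 0) next
          rho[j] <- rho[j] + ov / bin_s * mvals[i] / delta_v_m3
        }
        cnt[j0] <- cnt[j0] + 1L
      }
    }
  }
  structure(
    data.frame(bin_start = bins, t_tot_s = bin_s, n_events = cnt,
               rho_b = rho),
    delta_v_m3 = delta_v_m3, basis = basis,
    class = c("density_series", "data.frame"))
}

#' Centered rolling average of a density series
#'
#' Unweighted centered moving mean over `window` bins; edge bins average
#' over their available support.
#'
#' @param series a `density_series` (or any data frame with `rho_b`).
#' @param window window length, bins (>= 1).
#' @return The series with `rho_b` replaced by its rolling average.
#' @export
rolling_average <- function(series, window) {
  window <- as.integer(window)
  if (window < 1L) stop("rolling_average: 'window' must be >= 1")
  x <- series$rho_b
  n <- length(x)
  h_lo <- (window - 1L) %/% 2L
  h_hi <- window - 1L - h_lo
  out <- vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h_lo):min(n, i + h_hi)]), 0)
  series$rho_b <- out
  series
}

#' Diel (time-of-day) profile of a density series
#'
#' Averages the density across days for each time-of-day slot, producing
#' the mean 24 h activity pattern (e.g. dawn/dusk activity peaks).
#'
#' @param series a `density_series` spanning at least one day.
#' @return `data.frame`: `tod_s` (slot start, seconds since UTC
#'   midnight), `rho_b` (mean over days), `n_days` (days contributing).
#' @export
diel_profile <- function(series) {
  span_s <- as.numeric(difftime(series$bin_start[nrow(series)],
                                series$bin_start[1], units = "secs")) +
    series$t_tot_s[1]
  if (span_s < 86400 - 1e-6)
    stop("diel_profile: series must span at least one day")
  tod <- as.numeric(series$bin_start) %% 86400
  m <- tapply(series$rho_b, tod, mean)
  k <- tapply(series$rho_b, tod, length)
  out <- data.frame(tod_s = as.numeric(names(m)),
                    rho_b = as.numeric(m), n_days = as.integer(k))
  out[order(out$tod_s), , drop = FALSE]
}

#' Summary statistics of an event table
#'
#' Events with transit time below `min_transit_s` are removed before any
#' statistic is computed (the field analysis applies a hard 10 ms
#' cut-off: shorter crossings carry too little waveform to be reliable).
#' Only insect-classified events are summarised.
#'
#' @param events event `data.frame`.
#' @param min_transit_s transit-time cut-off, s.
#' @param hist_breaks number of histogram cells per distribution.
#' @return List of class `event_summary`: counts (`n_total`, `n_insect`,
#'   `n_after_cutoff`), per-quantity `mean`/`median` for dry and wet
#'   mass, transit time, wingbeat and kurtosis, and `hist` (a list of
#'   `hist()` objects, computed without plotting).
#' @export
summarize_events <- function(events, min_transit_s = 0.010,
                             hist_breaks = 30) {
  ins <- events[events$is_insect %in% TRUE, , drop = FALSE]
  kept <- ins[ins$transit_time_s >= min_transit_s, , drop = FALSE]
  stat <- function(x) {
    x <- if (is.null(x)) numeric(0) else x[is.finite(x)]
    list(mean = if (length(x)) mean(x) else NA_real_,
         median = if (length(x)) stats::median(x) else NA_real_)
  }
  safe_hist <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NULL)
    graphics::hist(x, breaks = hist_breaks, plot = FALSE)
  }
  hists <- list()
  if (nrow(kept)) {
    hists <- list(mass_dry_mg = safe_hist(kept$mass_dry_mg),
                  transit_time_s = safe_hist(kept$transit_time_s),
                  wingbeat_hz = safe_hist(kept$wingbeat_hz),
                  kurtosis = safe_hist(kept$kurtosis))
  }
  structure(
    list(n_total = nrow(events), n_insect = nrow(ins),
         n_after_cutoff = nrow(kept),
         min_transit_s = min_transit_s,
         mass_dry_mg = stat(kept$mass_dry_mg),
         mass_wet_mg = stat(kept$mass_wet_mg),
         transit_time_s = stat(kept$transit_time_s),
         wingbeat_hz = stat(kept$wingbeat_hz),
         kurtosis = stat(kept$kurtosis),
         hist = hists),
    class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("<event_summary> %d events, %d insect, %d after %g ms cut-off\n",
              x$n_total, x$n_insect, x$n_after_cutoff,
              x$min_transit_s * 1e3))
  fmt <- function(nm, s, unit)
    cat(sprintf("  %-16s mean %.4g %s | median %.4g %s\n",
                nm, s$mean, unit, s$median, unit))
  fmt("dry mass", x$mass_dry_mg, "mg")
  fmt("wet mass", x$mass_wet_mg, "mg")
  fmt("transit time", x$transit_time_s, "s")
  fmt("wingbeat", x$wingbeat_hz, "Hz")
  fmt("kurtosis", x$kurtosis, "")
  invisible(x)
}
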