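# Synthetic session generator: baseline + drift + noise + transit events,
# with a ground-truth ledger so every downstream stage can be verified
# without instrument data.

#' Instrument noise budget
#'
#' Five independent, normally distributed noise sources (digitizer,
#' ambient infrared, emitter- and receiver-side mechanical vibration,
#' laser power), each given as a standard deviation in mV. Their combined
#' standard deviation is the root sum of squares. The relative magnitudes
#' are generator defaults, not measured values.
#'
#' @param digitizer,ambient_ir,emitter_vibration,receiver_vibration,laser_power
#'   per-source standard deviations, mV (all >= 0).
#' @return An object of class `noise_budget` (named numeric of length 5).
#' @export
noise_budget <- function(digitizer = 2.0, ambient_ir = 1.5,
                         emitter_vibration = 1.2,
                         receiver_vibration = 0.6, laser_power = 0.4) {
  x <- c(digitizer = digitizer, ambient_ir = ambient_ir,
         emitter_vibration = emitter_vibration,
         receiver_vibration = receiver_vibration,
         laser_power = laser_power)
  if (any(!is.finite(x)) || any(x < 0))
    stop("noise_budget: standard deviations must be finite and >= 0")
  structure(x, class = "noise_budget")
}

#' Combined noise level
#'
#' @param noise a [noise_budget()].
#' @return Root-sum-square of the five per-source standard deviations, mV.
#' @examples
#' noise_total(noise_budget(3, 4, 0, 0, 0))  # 5
#' @export
noise_total <- function(noise) {
  stopifnot(inherits(noise, "noise_budget"))
  sqrt(sum(unclass(noise)^2))
}

#' Ground-truth description of one transit event
#'
#' @param start_time_s nominal entry time into the probe volume, seconds
#'   from session start.
#' @param transit_time_s transit duration (the FWHM of the Gaussian-like
#'   envelope), s; field transits run from about 20 ms to 1 s.
#' @param body_depth fractional extinction at envelope peak,
#'   `(I0 - IB) / I0`, in (0, 1).
#' @param wingbeat_hz wingbeat fundamental, Hz; 0 for non-insect targets.
#' @param wing_depth fractional extra extinction at wing-glint peaks.
#' @param kind `"insect"` or `"non_insect"`.
#' @return One-row `data.frame` (an event-truth ledger row).
#' @export
event_truth <- function(start_time_s, transit_time_s, body_depth,
                        wingbeat_hz = 0, wing_depth = 0,
                        kind = c("insect", "non_insect")) {
  kind <- match.arg(kind)
  if (!(body_depth > 0 && body_depth < 1))
    stop("event_truth: 'body_depth' must lie in (0, 1)")
  if (transit_time_s <= 0) stop("event_truth: 'transit_time_s' must be > 0")
  if (wing_depth < 0) stop("event_truth: 'wing_depth' must be >= 0")
  if ((kind == "insect") != (wingbeat_hz > 0))
    stop("event_truth: 'wingbeat_hz' must be > 0 iff kind = 'insect'")
  data.frame(start_time_s = start_time_s, transit_time_s = transit_time_s,
             body_depth = body_depth, wing_depth = wing_depth,
             wingbeat_hz = wingbeat_hz, kind = kind,
             stringsAsFactors = FALSE)
}

# Gaussian-like envelope, peak 1, FWHM = transit_time.
.envelope <- function(t, transit_time) exp(-4 * log(2) * (t / transit_time)^2)

# Raised-cosine glint train at `f` Hz, duty cycle `duty`, peak 1.
.glint_train <- function(t, f, duty = 0.1) {
  phase <- t * f
  frac <- phase - round(phase)              # in [-0.5, 0.5)
  ifelse(abs(frac) < duty / 2, 0.5 * (1 + cos(2 * pi * frac / duty)), 0)
}

#' Simulate the noiseless waveform of one transit event
#'
#' The event is a multiplicative dip in the baseline:
#' `baseline * (1 - body_depth * g(t) - wing_depth * g(t) * p(t))`, where
#' `g` is a Gaussian envelope with FWHM equal to the transit time
#' (normalised to peak 1) and `p` is a non-negative raised-cosine glint
#' train at the wingbeat frequency (identically 0 for non-insect targets).
#' The minimum of the body-only component is
#' `baseline * (1 - body_depth)`.
#'
#' @param truth a one-row ledger as from [event_truth()].
#' @param geometry a [probe_geometry()] (validated; the waveform itself is
#'   expressed in fractional extinction, so only used for checks).
#' @param baseline_mv baseline voltage, mV.
#' @param sample_rate Hz.
#' @param duty glint duty cycle (fraction of the wingbeat period).
#' @param support half-width of the generated segment in units of the
#'   transit time (default 2: the envelope is below 2^-16 at the edges).
#' @return Numeric vector of millivolts with attribute `t` (seconds,
#'   centred on the envelope peak).
#' @export
simulate_event_waveform <- function(truth, geometry = probe_geometry(),
                                    baseline_mv = 4000,
                                    sample_rate = 30517, duty = 0.1,
                                    support = 2) {
  stopifnot(inherits(geometry, "probe_geometry"))
  truth <- as.list(truth[1, , drop = FALSE])
  if (truth$body_depth + truth$wing_depth >= 1)
    stop("simulate_event_waveform: body_depth + wing_depth >= 1 ",
         "(signal would go negative)")
  half <- support * truth$transit_time_s
  n <- max(16L, 2L * as.integer(round(half * sample_rate)))
  t <- (seq_len(n) - (n + 1) / 2) / sample_rate
  g <- .envelope(t, truth$transit_time_s)
  p <- if (truth$kind == "insect")
    .glint_train(t, truth$wingbeat_hz, duty) else 0
  seg <- baseline_mv * (1 - truth$body_depth * g - truth$wing_depth * g * p)
  attr(seg, "t") <- t
  seg
}

#' Random sampler specification for event truths
#'
#' Default ranges reflect the field conditions the generator emulates:
#' transit times log-uniform on 20 ms--1 s, fractional body extinction
#' log-uniform on 0.002--0.05 (body cross sections of roughly 8--200 mm^2
#' in a 72 mm beam, i.e. mosquito- to large-moth-sized targets whose
#' implied dry masses span about 2--200 mg with a heavy-tailed, mg-scale
#' bulk), wingbeats log-uniform on 50--600 Hz, and wing glints 0.5--1.5
#' times the body depth.
#'
#' @param transit_range transit-time range, s (log-uniform).
#' @param body_depth_range fractional-extinction range (log-uniform).
#' @param wingbeat_range wingbeat range, Hz (log-uniform).
#' @param wing_depth_rel wing-to-body depth ratio range (uniform).
#' @param p_insect probability that a target is an insect.
#' @return An object of class `truth_sampler`.
#' @export
truth_sampler <- function(transit_range = c(0.02, 1.0),
                          body_depth_range = c(0.002, 0.05),
                          wingbeat_range = c(50, 600),
                          wing_depth_rel = c(0.5, 1.5),
                          p_insect = 0.8) {
  structure(list(transit_range = transit_range,
                 body_depth_range = body_depth_range,
                 wingbeat_range = wingbeat_range,
                 wing_depth_rel = wing_depth_rel,
                 p_insect = p_insect),
            class = "truth_sampler")
}

.rlogunif <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Draw a ground-truth event ledger
#'
#' Arrivals follow a homogeneous Poisson process of the given rate, or an
#' inhomogeneous one when `rate_fn` is supplied (thinning against
#' `rate_max`). Overlapping events are allowed; events whose waveform
#' support extends past the session edges are flagged `truncated`.
#'
#' @param duration_s session length, s.
#' @param event_rate mean arrival rate, events/s.
#' @param sampler a [truth_sampler()].
#' @param rate_fn optional function of time (s) returning an instantaneous
#'   rate, for diel-profile experiments; `event_rate` is then ignored.
#' @param rate_max upper bound of `rate_fn` (required with `rate_fn`).
#' @return Ledger `data.frame`: `start_time_s, center_s, transit_time_s,
#'   body_depth, wing_depth, wingbeat_hz, kind, truncated`, sorted by
#'   start time.
#' @export
simulate_truth_ledger <- function(duration_s, event_rate,
                                  sampler = truth_sampler(),
                                  rate_fn = NULL, rate_max = NULL) {
  if (duration_s <= 0) stop("simulate_truth_ledger: 'duration_s' must be > 0")
  if (is.null(rate_fn)) {
    if (event_rate < 0) stop("simulate_truth_ledger: negative rate")
    n <- stats::rpois(1L, event_rate * duration_s)
    centers <- sort(stats::runif(n, 0, duration_s))
  } else {
    if (is.null(rate_max)) stop("simulate_truth_ledger: 'rate_max' required")
    n0 <- stats::rpois(1L, rate_max * duration_s)
    cand <- sort(stats::runif(n0, 0, duration_s))
    keep <- stats::runif(n0) < vapply(cand, rate_fn, 0) / rate_max
    centers <- cand[keep]
    n <- length(centers)
  }
  if (n == 0L) {
    return(data.frame(start_time_s = numeric(0), center_s = numeric(0),
                      transit_time_s = numeric(0), body_depth = numeric(0),
                      wing_depth = numeric(0), wingbeat_hz = numeric(0),
                      kind = character(0), truncated = logical(0),
                      stringsAsFactors = FALSE))
  }
  transit <- .rlogunif(n, sampler$transit_range)
  depth <- .rlogunif(n, sampler$body_depth_range)
  insect <- stats::runif(n) < sampler$p_insect
  wingbeat <- ifelse(insect, .rlogunif(n, sampler$wingbeat_range), 0)
  wing <- ifelse(insect,
                 pmin(depth * stats::runif(n, sampler$wing_depth_rel[1],
                                           sampler$wing_depth_rel[2]),
                      0.9 - depth),
                 0)
  data.frame(start_time_s = centers - transit / 2, center_s = centers,
             transit_time_s = transit, body_depth = depth, wing_depth = wing,
             wingbeat_hz = wingbeat,
             kind = ifelse(insect, "insect", "non_insect"),
             truncated = (centers - 2 * transit < 0) |
               (centers + 2 * transit > duration_s),
             stringsAsFactors = FALSE)
}

# Slow baseline drift: a random walk on a coarse grid, low-pass smoothed
# with a Gaussian kernel, rescaled to the requested peak amplitude.
.simulate_drift <- function(n, sample_rate, amplitude_frac, cutoff_hz = 0.005) {
  if (amplitude_frac <= 0) return(numeric(n))
  grid_dt <- 0.1
  ng <- max(8L, ceiling(n / sample_rate / grid_dt) + 2L)
  rw <- cumsum(stats::rnorm(ng))
  sd_s <- 1 / (2 * pi * cutoff_hz)
  ks <- max(1, sd_s / grid_dt)
  kx <- seq(-ceiling(3 * ks), ceiling(3 * ks))
  kern <- exp(-0.5 * (kx / ks)^2)
  kern <- kern / sum(kern)
  sm <- stats::filter(c(rep(rw[1], length(kx)), rw, rep(rw[ng], length(kx))),
                      kern, sides = 2)
  sm <- as.numeric(sm[(length(kx) + 1):(length(kx) + ng)])
  sm <- sm - mean(sm)
  pk <- max(abs(sm), .Machine$double.eps)
  d <- sm / pk * amplitude_frac
  stats::approx(x = (seq_len(ng) - 1L) * grid_dt,
                y = d, xout = (seq_len(n) - 1L) / sample_rate,
                rule = 2)$y
}

#' Simulate a full recording session with a ground-truth ledger
#'
#' The session is baseline x (1 + drift), multiplied by each event's
#' fractional-extinction waveform, plus per-sample noise drawn as the sum
#' of the five independent normal sources of the [noise_budget()]. All
#' randomness flows from `seed`; the same seed reproduces the session
#' bit-exactly.
#'
#' @param duration_s session length, s.
#' @param event_rate mean Poisson arrival rate, events/s.
#' @param sample_rate Hz (instrument default 30,517).
#' @param baseline_mv baseline voltage, mV.
#' @param noise a [noise_budget()].
#' @param drift_pct peak slow-drift amplitude, percent of baseline (the
#'   baseline wanders by a few percent over hours; default 1).
#' @param drift_cutoff_hz drift low-pass cut-off, Hz.
#' @param sampler a [truth_sampler()].
#' @param truths optional explicit ledger (as from
#'   [simulate_truth_ledger()] or [event_truth()] rows); overrides the
#'   arrival process.
#' @param rate_fn,rate_max optional inhomogeneous arrival rate, see
#'   [simulate_truth_ledger()].
#' @param geometry a [probe_geometry()]; used to annotate the ledger with
#'   implied cross sections.
#' @param start_time UTC timestamp of sample 0.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `eboss_session`: `record` (a [signal_record()])
#'   and `truth` (the ledger, annotated with `sigma_b_mm2` and
#'   `mass_dry_mg` implied by the body depth and geometry).
#' @export
simulate_session <- function(duration_s, event_rate = 0.05,
                             sample_rate = 30517, baseline_mv = 4000,
                             noise = noise_budget(), drift_pct = 1,
                             drift_cutoff_hz = 0.005,
                             sampler = truth_sampler(), truths = NULL,
                             rate_fn = NULL, rate_max = NULL,
                             geometry = probe_geometry(),
                             start_time = as.POSIXct("2021-08-01 00:00:00",
                                                     tz = "UTC"),
                             seed = NULL) {
  if (duration_s <= 0) stop("simulate_session: 'duration_s' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * sample_rate))
  if (is.null(truths))
    truths <- simulate_truth_ledger(duration_s, event_rate, sampler,
                                    rate_fn, rate_max)
  if (!"center_s" %in% names(truths))
    truths$center_s <- truths$start_time_s + truths$transit_time_s / 2
  if (!"truncated" %in% names(truths))
    truths$truncated <- (truths$center_s - 2 * truths$transit_time_s < 0) |
      (truths$center_s + 2 * truths$transit_time_s > duration_s)
  truths <- truths[order(truths$start_time_s), , drop = FALSE]
  rownames(truths) <- NULL

  base <- baseline_mv * (1 + .simulate_drift(n, sample_rate, drift_pct / 100,
                                             drift_cutoff_hz))
  x <- base
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    if (tr$body_depth + tr$wing_depth >= 1)
      stop("simulate_session: ledger row ", i,
           ": body_depth + wing_depth >= 1")
    half <- 2 * tr$transit_time_s
    i0 <- max(1L, as.integer(floor((tr$center_s - half) * sample_rate)) + 1L)
    i1 <- min(n, as.integer(ceiling((tr$center_s + half) * sample_rate)) + 1L)
    if (i1 < i0) next
    t <- ((i0:i1) - 1L) / sample_rate - tr$center_s
    g <- .envelope(t, tr$transit_time_s)
    p <- if (tr$kind == "insect") .glint_train(t, tr$wingbeat_hz) else 0
    x[i0:i1] <- x[i0:i1] * (1 - tr$body_depth * g - tr$wing_depth * g * p)
  }
  for (s in unclass(noise)) if (s > 0) x <- x + stats::rnorm(n, 0, s)

  truths$sigma_b_mm2 <- truths$body_depth * geometry$sigma_pv_mm2
  truths$mass_dry_mg <- 0.075 * truths$sigma_b_mm2^1.5
  record <- signal_record(x, sample_rate, start_time,
                          label = sprintf("synthetic session (%g s)",
                                          duration_s))
  structure(list(record = record, truth = truths), class = "eboss_session")
}

#' @export
print.eboss_session <- function(x, ...) {
  cat(sprintf("<eboss_session> %d ground-truth events (%d insect)\n",
              nrow(x$truth), sum(x$truth$kind == "insect")))
  print(x$record)
  invisible(x)
}
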