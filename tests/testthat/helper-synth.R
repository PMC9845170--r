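# Shared fixtures: all synthetic, generated in code.

FS <- 30517

# A ledger of well-separated insect events with strong wing glints,
# depths given in multiples of the total noise level over the baseline.
make_insect_ledger <- function(n_events, duration_s, baseline_mv = 4000,
                               snr = 20,
                               transits = NULL, wingbeats = NULL) {
  noise <- noise_total(noise_budget())
  centers <- seq(duration_s / (n_events + 1), duration_s,
                 length.out = n_events + 1)[seq_len(n_events)]
  if (is.null(transits))
    transits <- rep_len(c(0.05, 0.1, 0.2, 0.35), n_events)
  if (is.null(wingbeats))
    wingbeats <- rep_len(c(120, 250, 400, 80, 500), n_events)
  depth <- rep_len(snr, n_events) * noise / baseline_mv
  data.frame(start_time_s = centers - transits / 2, center_s = centers,
             transit_time_s = transits, body_depth = depth,
             wing_depth = 0.8 * depth, wingbeat_hz = wingbeats,
             kind = "insect", stringsAsFactors = FALSE)
}

# Brute-force O(n*w) centered sliding mean/sd oracle.
brute_sliding <- function(x, w) {
  n <- length(x)
  lo <- (w - 1L) %/% 2L
  m <- s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- i - lo; b <- a + w - 1L
    if (a >= 1L && b <= n) {
      m[i] <- mean(x[a:b])
      s[i] <- stats::sd(x[a:b])
    }
  }
  list(mean = m, sd = s)
}

# Occluded area of an opaque disk (radius r) whose centre is at distance d
# from the axis of a flat-top beam of radius R: circle-circle intersection.
disk_occlusion <- function(d, r, R) {
  vapply(d, function(di) {
    if (di >= r + R) return(0)
    if (di <= R - r) return(pi * r^2)
    clamp <- function(z) pmin(pmax(z, -1), 1)
    a <- r^2 * acos(clamp((di^2 + r^2 - R^2) / (2 * di * r))) +
      R^2 * acos(clamp((di^2 + R^2 - r^2) / (2 * di * R))) -
      0.5 * sqrt(pmax((-di + r + R) * (di + r - R) *
                        (di - r + R) * (di + r + R), 0))
    a
  }, 0)
}
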