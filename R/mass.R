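# Power-law mass calibration: m = eta * sigma^(3/2).
#
# The exponent follows from dimensional analysis: an insect's volume
# scales as its geometric cross section to the 3/2, mass is volume times a
# volumetric mass density, and the extinction cross section is
# proportional to the geometric one through the quasi-ballistic
# transmittance. Those latent constants (density rho, shape factor K,
# transmittance T_b) are absorbed into the single coefficient eta and are
# not separately identifiable from calibration data.

#' Construct a mass model
#'
#' @param eta coefficient, mg/mm^3 (> 0).
#' @param basis `"wet"` or `"dry"` mass basis.
#' @param exponent power-law exponent (fixed at 3/2 in the pipeline; a
#'   free-exponent diagnostic fit is available from [fit_eta()]).
#' @param r2_adj adjusted coefficient of determination of the fit, or `NA`.
#' @param n number of calibration specimens, or `NA`.
#' @param method provenance string.
#' @return Object of class `mass_model`.
#' @export
mass_model <- function(eta, basis = c("dry", "wet"), exponent = 1.5,
                       r2_adj = NA_real_, n = NA_integer_,
                       method = "manual") {
  basis <- match.arg(basis)
  if (!is.finite(eta) || eta <= 0) stop("mass_model: 'eta' must be > 0")
  structure(list(eta = eta, basis = basis, exponent = exponent,
                 r2_adj = r2_adj, n = n, method = method),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("<mass_model> m_%s = %.4g * sigma^%g  (R2_adj = %s, n = %s, %s)\n",
              x$basis, x$eta, x$exponent,
              ifelse(is.na(x$r2_adj), "NA", sprintf("%.3f", x$r2_adj)),
              ifelse(is.na(x$n), "NA", x$n), x$method))
  invisible(x)
}

#' Reference calibration constants
#'
#' The published field calibration of the instrument:
#' `m_wet = 0.157 * sigma^(3/2)` (adjusted R^2 = 96%) and
#' `m_dry = 0.075 * sigma^(3/2)` (adjusted R^2 = 98%), with sigma in mm^2
#' and mass in mg, fitted on 187 weighed specimens (mosquitoes, house
#' flies, mason bees, wasps, bumble bees).
#'
#' @param basis `"dry"` (the reporting standard) or `"wet"`.
#' @return A [mass_model()].
#' @examples
#' predict_mass(1, reference_mass_model("dry"))  # 0.075 mg
#' @export
reference_mass_model <- function(basis = c("dry", "wet")) {
  basis <- match.arg(basis)
  if (basis == "dry")
    mass_model(0.075, "dry", r2_adj = 0.98, n = 187L, method = "reference")
  else
    mass_model(0.157, "wet", r2_adj = 0.96, n = 187L, method = "reference")
}

#' Fit the mass-law coefficient eta by damped least squares
#'
#' Minimises `sum((m_i - eta * sigma_i^exponent)^2)` with the
#' Levenberg--Marquardt algorithm (`minpack.lm::nls.lm`). With the
#' exponent fixed the model is linear in eta and the closed form
#' `sum(m * sigma^1.5) / sum(sigma^3)` is the exact solution; the LM fit
#' reproduces it to numerical precision and is retained because it also
#' covers the free-exponent diagnostic and group-weighted variants.
#'
#' @param samples calibration `data.frame` with columns
#'   `group, sigma_mm2, mass_wet_mg, mass_dry_mg` (see
#'   [read_calibration_table()]).
#' @param basis `"dry"` or `"wet"` mass column.
#' @param group_means fit on per-group mean points weighted by group size
#'   instead of per-specimen points (default `FALSE`: per-specimen).
#' @param free_exponent also fit the exponent (diagnostic only; the
#'   pipeline always uses 3/2).
#' @return A [mass_model()] with `r2_adj` computed for the number of
#'   fitted parameters.
#' @export
fit_eta <- function(samples, basis = c("dry", "wet"), group_means = FALSE,
                    free_exponent = FALSE) {
  basis <- match.arg(basis)
  validate_calibration(samples)
  if (nrow(samples) < 2L) stop("fit_eta: need at least 2 samples")
  m <- samples[[if (basis == "dry") "mass_dry_mg" else "mass_wet_mg"]]
  s <- samples$sigma_mm2
  w <- rep(1, length(m))
  if (group_means) {
    agg <- stats::aggregate(cbind(m = m, s = s) ~ group,
                            data = data.frame(group = samples$group, m = m,
                                              s = s),
                            FUN = mean)
    w <- as.vector(table(samples$group)[agg$group])
    m <- agg$m; s <- agg$s
  }
  if (all(s == s[1]) && s[1] == 0) stop("fit_eta: singular fit (sigma all zero)")
  sw <- sqrt(w)
  if (free_exponent) {
    fit <- minpack.lm::nls.lm(
      par = c(eta = 0.1, b = 1.5),
      fn = function(p) sw * (m - p[1] * s^p[2]),
      jac = function(p) cbind(-sw * s^p[2],
                              -sw * p[1] * s^p[2] * log(s)),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500))
    eta <- fit$par[["eta"]]; b <- fit$par[["b"]]; npar <- 2L
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(eta = 1),
      fn = function(p) sw * (m - p[1] * s^1.5),
      jac = function(p) matrix(-sw * s^1.5, ncol = 1),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500))
    eta <- fit$par[["eta"]]; b <- 1.5; npar <- 1L
  }
  if (!is.finite(eta) || eta <= 0)
    stop("fit_eta: fit did not converge to a positive coefficient")
  pred <- eta * s^b
  ss_res <- sum(w * (m - pred)^2)
  ss_tot <- sum(w * (m - stats::weighted.mean(m, w))^2)
  n <- length(m)
  r2 <- 1 - ss_res / ss_tot
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - npar - 1)
  mod <- mass_model(eta, basis, exponent = b, r2_adj = r2_adj,
                    n = if (group_means) sum(w) else n,
                    method = if (group_means) "LM (group means)" else
                      "LM (per specimen)")
  mod$deviance <- ss_res
  mod
}

#' Predict mass from a body extinction cross section
#'
#' @param sigma_mm2 body extinction cross section(s), mm^2 (>= 0).
#' @param model a [mass_model()].
#' @return Predicted mass(es), mg: `eta * sigma^exponent`.
#' @examples
#' predict_mass(4, reference_mass_model("dry"))  # 0.075 * 8 = 0.6 mg
#' @export
predict_mass <- function(sigma_mm2, model) {
  stopifnot(inherits(model, "mass_model"))
  if (any(sigma_mm2 < 0)) stop("predict_mass: negative cross section")
  model$eta * sigma_mm2^model$exponent
}

#' Simulate a calibration table
#'
#' Draws specimen-level calibration data from the power law with
#' multiplicative Gaussian noise, using the field study's group sizes by
#' default (122 mosquitoes, 50 flies, 6 bees, 5 wasps, 4 bumble bees) and
#' group-typical cross-section ranges.
#'
#' @param eta_wet,eta_dry true coefficients, mg/mm^3.
#' @param group_sizes named integer vector of specimens per group.
#' @param sigma_ranges named list of `c(min, max)` cross-section ranges,
#'   mm^2 (log-uniform within each group).
#' @param noise_cv coefficient of variation of the multiplicative mass
#'   noise (default 0.2).
#' @return Calibration `data.frame` with the standard four columns.
#' @export
simulate_calibration_samples <- function(
    eta_wet = 0.157, eta_dry = 0.075,
    group_sizes = c(mosquito = 122L, fly = 50L, bee = 6L, wasp = 5L,
                    bumblebee = 4L),
    sigma_ranges = list(mosquito = c(2, 8), fly = c(8, 25), bee = c(25, 60),
                        wasp = c(25, 70), bumblebee = c(70, 150)),
    noise_cv = 0.2) {
  rows <- lapply(names(group_sizes), function(g) {
    ng <- group_sizes[[g]]
    s <- .rlogunif(ng, sigma_ranges[[g]])
    noise <- pmax(1 + stats::rnorm(ng, 0, noise_cv), 0.05)
    wet <- eta_wet * s^1.5 * noise
    dry <- pmin(eta_dry * s^1.5 * noise, wet)
    data.frame(group = g, sigma_mm2 = s, mass_wet_mg = wet,
               mass_dry_mg = dry, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
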