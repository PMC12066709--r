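# Diffusive-boundary-layer scaling: DBL thickness from a Sherwood-number
# law, the dimensionless Sand_DBL number (a Damkoehler-type ratio of the
# diffusive time across the DBL to the reactive time of colony O2
# consumption), and the power law linking Sand_DBL to the anoxic fraction
# of consuming colonies.

#' Diffusive boundary layer thickness around a sand grain
#'
#' delta = r / Sh with Sh = 1 + 0.62 Re^0.41 Sc^0.33, Re = U r / nu and
#' Sc = nu / D.  In the stagnant limit (U = 0) Sh = 1 and delta = r.
#'
#' @param r_m grain radius, m.
#' @param U_m_s pore-water velocity, m s^-1 (>= 0).
#' @param nu_m2_s kinematic viscosity, m^2 s^-1.
#' @param D_m2_s solute diffusion coefficient, m^2 s^-1.
#' @return DBL thickness in m; attributes `Re`, `Sc`, `Sh`.
#' @examples
#' dbl_thickness(145e-6, 100e-6)  # ~71 um
#' @export
dbl_thickness <- function(r_m, U_m_s, nu_m2_s = 1e-6, D_m2_s = 1.1e-9) {
  if (any(r_m <= 0) || any(nu_m2_s <= 0) || any(D_m2_s <= 0))
    stop("r, nu and D must be positive", call. = FALSE)
  if (any(U_m_s < 0)) stop("U must be >= 0", call. = FALSE)
  Re <- U_m_s * r_m / nu_m2_s
  Sc <- nu_m2_s / D_m2_s
  Sh <- 1 + 0.62 * Re^0.41 * Sc^0.33
  structure(r_m / Sh, Re = Re, Sc = Sc, Sh = Sh)
}

#' Roughness correction to the DBL thickness
#'
#' First-order multiplicative correction delta' = delta (1 + c * a_r / delta)
#' for a grain whose outline deviates from its convex hull by up to `a_r`.
#' The default coefficient c = 0.4 is calibrated so that the observed
#' roughness range (2-35 um) thickens the boundary layer by at most ~20 %
#' over pore-water velocities of 10-100 um s^-1.
#'
#' @param delta_m uncorrected DBL thickness, m.
#' @param roughness_max_m maximum radial hull deviation, m (>= 0).
#' @param coefficient dimensionless correction coefficient.
#' @return corrected thickness, m; always >= `delta_m`.
#' @export
roughness_corrected_dbl <- function(delta_m, roughness_max_m,
                                    coefficient = 0.4) {
  if (any(roughness_max_m < 0))
    stop("roughness must be >= 0", call. = FALSE)
  delta_m + coefficient * roughness_max_m
}

#' The Sand_DBL number
#'
#' Sand_DBL = (delta^2 / D) * (R_O2 / C0): diffusive time across the
#' boundary layer over the reactive time of the colony O2 consumption.
#' All inputs in SI units.
#'
#' @param delta_m DBL thickness, m.
#' @param D_m2_s O2 diffusivity, m^2 s^-1.
#' @param R_O2_mol_m3_s magnitude of the colony volumetric O2 consumption
#'   rate, mol m^-3 s^-1 (>= 0).
#' @param C0_mol_m3 bulk O2 concentration, mol m^-3 (> 0).
#' @return dimensionless Sand_DBL number.
#' @examples
#' sanddbl(71e-6, 1.1e-9, 955 / 3600, 0.05)  # ~24
#' @export
sanddbl <- function(delta_m, D_m2_s, R_O2_mol_m3_s, C0_mol_m3) {
  if (any(D_m2_s <= 0)) stop("D must be positive", call. = FALSE)
  if (any(R_O2_mol_m3_s < 0))
    stop("R_O2 is a magnitude and must be >= 0", call. = FALSE)
  if (any(C0_mol_m3 <= 0))
    stop("Sand_DBL is undefined at zero bulk O2", call. = FALSE)
  (delta_m^2 / D_m2_s) * (R_O2_mol_m3_s / C0_mol_m3)
}

#' Fit the anoxic-fraction power law
#'
#' Log-log least-squares fit of the anoxic fraction of consuming colonies
#' against the Sand_DBL number, restricted to partially anoxic runs
#' (fraction in (0.01, 0.99)).  Predictions are clamped to 0 below
#' `lower_threshold` (colonies mostly oxic) and to 1 above
#' `upper_threshold` (mostly anoxic).
#'
#' @param ensemble data frame with columns `sanddbl` and `anoxic_fraction`
#'   (e.g. the output of [run_ensemble()]).
#' @param lower_threshold,upper_threshold Sand_DBL clamping thresholds
#'   (defaults 10 and 1000).
#' @return an object of class `powerlaw_fit` with `prefactor`, `exponent`,
#'   `r_squared`, the thresholds and the number of runs used.
#' @export
fit_anoxic_powerlaw <- function(ensemble, lower_threshold = 10,
                                upper_threshold = 1000) {
  s <- ensemble$sanddbl
  f <- ensemble$anoxic_fraction
  ok <- is.finite(s) & is.finite(f) & s > 0 & f > 0.01 & f < 0.99
  if (sum(ok) < 5L)
    stop("need at least 5 partially anoxic runs to fit the power law (got ",
         sum(ok), ")", call. = FALSE)
  fit <- stats::lm(log(f[ok]) ~ log(s[ok]))
  structure(list(prefactor = unname(exp(stats::coef(fit)[1])),
                 exponent = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 n_runs = sum(ok)),
            class = "powerlaw_fit")
}

#' Predict the anoxic fraction from the Sand_DBL number
#'
#' Evaluates a fitted power law, clamped to \[0, 1\] and forced to 0 below
#' the lower Sand_DBL threshold and to 1 above the upper one; monotone
#' non-decreasing for a positive fitted exponent.
#'
#' @param fit a [fit_anoxic_powerlaw()] object.
#' @param sanddbl_number vector of Sand_DBL values.
#' @return predicted anoxic fractions in \[0, 1\].
#' @export
predict_anoxic_fraction <- function(fit, sanddbl_number) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  p <- clamp(fit$prefactor * sanddbl_number^fit$exponent, 0, 1)
  p[sanddbl_number <= fit$lower_threshold] <- 0
  p[sanddbl_number >= fit$upper_threshold] <- 1
  p
}

#' @export
predict.powerlaw_fit <- function(object, sanddbl_number, ...) {
  predict_anoxic_fraction(object, sanddbl_number)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Anoxic-fraction power law: f = %.4g * Sand_DBL^%.3f ",
           "(R2 = %.3f, n = %d)\n  clamped to 0 below %.3g and 1 above %.3g\n"),
    x$prefactor, x$exponent, x$r_squared, x$n_runs,
    x$lower_threshold, x$upper_threshold))
  invisible(x)
}
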