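# Seawater physical properties used by the upscaling and synthetic-site
# generators.  Standard published correlations, implemented directly.

#' Dissolved oxygen concentration at air saturation
#'
#' Garcia & Gordon (1992) combined-fit solubility of O2 in seawater at one
#' atmosphere total pressure, converted from umol kg^-1 to umol L^-1 with the
#' surface seawater density.
#'
#' @param temperature_C water temperature in degrees Celsius.
#' @param salinity practical salinity.
#' @return O2 concentration at air saturation, umol L^-1.
#' @examples
#' o2_saturation(10, 35)  # about 281 umol/L
#' @export
o2_saturation <- function(temperature_C, salinity) {
  Ts <- log((298.15 - temperature_C) / (273.15 + temperature_C))
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 +
    A[6] * Ts^5 +
    salinity * (B[1] + B[2] * Ts + B[3] * Ts^2 + B[4] * Ts^3) +
    C0 * salinity^2
  umol_kg <- exp(lnC)
  umol_kg * seawater_density(temperature_C, salinity) / 1000
}

#' Surface seawater density
#'
#' UNESCO EOS-80 one-atmosphere polynomial.
#'
#' @inheritParams o2_saturation
#' @return density in kg m^-3.
#' @export
seawater_density <- function(temperature_C, salinity) {
  t <- temperature_C
  S <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2
}

#' Seawater viscosity
#'
#' Dynamic viscosity from the Sharqawy, Lienhard & Zubair (2010) correlation;
#' kinematic viscosity divides by the EOS-80 density.
#'
#' @inheritParams o2_saturation
#' @param kinematic if `TRUE` (default) return kinematic viscosity (m^2 s^-1),
#'   otherwise dynamic viscosity (Pa s).
#' @return viscosity, see `kinematic`.
#' @export
seawater_viscosity <- function(temperature_C, salinity, kinematic = TRUE) {
  t <- temperature_C
  Sg <- salinity / 1000  # kg/kg
  mu_w <- 4.2844e-5 + 1 / (0.157 * (t + 64.993)^2 - 91.296)
  A <- 1.541 + 1.998e-2 * t - 9.52e-5 * t^2
  B <- 7.974 - 7.561e-2 * t + 4.724e-4 * t^2
  mu <- mu_w * (1 + A * Sg + B * Sg^2)
  if (!kinematic) return(mu)
  mu / seawater_density(t, salinity)
}

#' Temperature-corrected O2 diffusion coefficient
#'
#' Stokes-Einstein scaling of a reference diffusivity (default the free-water
#' O2 value at 25 degrees C) with absolute temperature and dynamic viscosity.
#'
#' @inheritParams o2_saturation
#' @param D_ref reference diffusivity, m^2 s^-1, valid at `T_ref`.
#' @param T_ref reference temperature, degrees C.
#' @return diffusivity in m^2 s^-1.
#' @export
o2_diffusivity <- function(temperature_C, salinity = 35, D_ref = 1.1e-9,
                           T_ref = 25) {
  mu_ref <- seawater_viscosity(T_ref, salinity, kinematic = FALSE)
  mu <- seawater_viscosity(temperature_C, salinity, kinematic = FALSE)
  D_ref * ((temperature_C + 273.15) / (T_ref + 273.15)) * (mu_ref / mu)
}
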