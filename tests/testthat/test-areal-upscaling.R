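# Hydraulic closures, penetration depths and the areal flux partition.

ref_site <- function(...) {
  over <- list(...)
  base <- list(site_id = "ref", d_g_um = 290, U_bw_m_s = 0.1, T_C = 20,
               S = 35, theta = 0.4, C_O2_umol_L = 250, C_NO3_umol_L = 20,
               R_O2_umol_L_h = 26, R_den_umolN_L_h = 2)
  base[names(over)] <- over
  as.data.frame(base)
}

test_that("hydraulic closures evaluate the empirical chain", {
  h <- hydraulics(ref_site())
  expect_equal(h$lambda_m, 490 * 290e-6)          # ~0.142 m
  expect_equal(h$k_m1, 2 * pi / h$lambda_m)       # ~44.2 m^-1
  expect_equal(h$P_m2, 9.869e-13 * 735 * 290^2 * 1e-6)  # ~6.1e-11 m^2
  expect_equal(h$K_m_s, h$P_m2 * h$g / h$nu_m2_s) # K = P g / nu exactly
  expect_equal(h$K_m_s, 6.0e-4, tolerance = 0.06)
  expect_equal(h$h_m_m, 1e-4)                     # 0.01 U^2 at U = 0.1
  expect_equal(h$U_pore_m_s, h$k_m1 * h$K_m_s * h$h_m_m)
  # raising temperature lowers viscosity and raises conductivity
  h_warm <- hydraulics(ref_site(T_C = 25))
  expect_lt(h_warm$nu_m2_s, h$nu_m2_s)
  expect_gt(h_warm$K_m_s, h$K_m_s)
})

test_that("mixing depth is zero at t = 0, concave and matches the formula", {
  h <- structure(list(k_m1 = 44.2, K_m_s = 6.0e-4, h_m_m = 1e-4),
                 class = "hydraulic_state")
  expect_equal(mixing_depth(0, h, 0.4), 0)
  z <- mixing_depth(3.46e4, h, 0.4)
  expect_equal(z, log1p(0.42 * 44.2^2 * 6e-4 * 1e-4 * 3.46e4 / 0.4) / 44.2)
  expect_equal(z, 0.037, tolerance = 0.02)
  # doubling t adds less than ln(2)/k
  expect_lt(mixing_depth(2 * 3.46e4, h, 0.4) - z, log(2) / 44.2)
  tt <- seq(0, 1e5, length.out = 50)
  expect_true(all(diff(mixing_depth(tt, h, 0.4), differences = 2) < 0))
})

test_that("penetration depths follow the depletion-time construction", {
  site <- ref_site()
  h <- hydraulics(site)
  pen <- penetration_depths(site, h)
  expect_equal(pen$t_O2_s, 250 / 26 * 3600)       # ~9.6 h
  expect_equal(pen$z_O2_m, mixing_depth(pen$t_O2_s, h, 0.4))
  expect_equal(pen$z_O2_m, 0.037, tolerance = 0.05)
  expect_equal(pen$z_NO3_m, mixing_depth(20 / 2 * 3600, h, 0.4))
  expect_error(penetration_depths(ref_site(R_den_umolN_L_h = 0), h),
               "positive")
})

test_that("bulk rates scale to colony rates by either exposed route", {
  # pore-volume fraction route: 46 umol/L/h -> 46 mmol/L/h at 1/1000
  expect_equal(scale_bulk_to_colony_rate(46, "pore_fraction"), 46e3)
  expect_equal(scale_bulk_to_colony_rate(46, "pore_fraction",
                                         colony_pore_fraction = 1), 46)
  expect_equal(scale_bulk_to_colony_rate(46, "pore_fraction",
                                         colony_pore_fraction = 1 / 500),
               scale_bulk_to_colony_rate(46, "pore_fraction") / 2)
  expect_error(scale_bulk_to_colony_rate(46, "pore_fraction",
                                         colony_pore_fraction = 0),
               "colony_pore_fraction")
  # biovolume route reproduces the cell-specific chain: -46 umol/L/h over
  # 1.3e8 cells/cm3 and 0.4 um3 biovolume -> ~-885 mmol/L/h
  expect_equal(scale_bulk_to_colony_rate(-46), -884615.4, tolerance = 1e-6)
})

test_that("site records are validated against their physical bounds", {
  expect_silent(validate_site_record(ref_site()))
  expect_error(validate_site_record(ref_site(d_g_um = 10)), "sanity")
  expect_error(validate_site_record(ref_site(theta = 1.2)), "porosity")
  bad <- ref_site(); bad$R_den_umolN_L_h <- NULL
  expect_error(validate_site_record(bad), "missing")
})

test_that("the flux partition is bounded, ordered and linear in the rate", {
  ens <- rbind(cached_ensemble(TRUE), cached_ensemble(FALSE))
  fit <- fit_anoxic_powerlaw(ens[is.finite(ens$sanddbl) & ens$converged, ])
  # sites where nitrate runs out above the oxic-anoxic interface warn and
  # zero the anoxic-zone flux
  expect_warning(
    shallow <- microenv_flux(ref_site(C_NO3_umol_L = 2,
                                      R_den_umolN_L_h = 10), fit),
    "nitrate penetration")
  expect_equal(shallow$flux_anoxic_zone_umolN_m2_h, 0)
  res <- suppressWarnings(
    upscale_sites(make_site_table(seed = 9, n_sites = 8), fit))
  expect_true(all(res$fraction_microenv >= 0 & res$fraction_microenv <= 1))
  expect_true(all(res$uncertainty_low <= res$fraction_microenv + 1e-12))
  expect_true(all(res$uncertainty_high >= res$fraction_microenv - 1e-12))
  expect_true(all(res$z_O2_m >= 0 & res$z_NO3_m >= 0))
  # a powerlaw predicting zero everywhere gives no microenvironment flux
  zero_fit <- structure(list(prefactor = 0, exponent = 1,
                             lower_threshold = 10, upper_threshold = Inf),
                        class = "powerlaw_fit")
  r0 <- microenv_flux(ref_site(), zero_fit)
  expect_equal(r0$flux_microenv_umolN_m2_h, 0)
  expect_equal(r0$fraction_microenv, 0)
  # fluxes scale linearly with the denitrification rate
  r1 <- microenv_flux(ref_site(R_den_umolN_L_h = 1), fit)
  r2 <- microenv_flux(ref_site(R_den_umolN_L_h = 2,
                               C_NO3_umol_L = 40), fit)
  expect_equal(r2$flux_microenv_umolN_m2_h,
               2 * r1$flux_microenv_umolN_m2_h, tolerance = 1e-9)
  # the oxic-zone mean anoxic fraction (microenvironment flux normalised
  # by R_den and the oxic-zone depth) declines with better-oxygenated and
  # with faster bottom water; note the *share* of total denitrification
  # can still rise with O2 because a deeper oxic zone shrinks the anoxic
  # zone below it
  mean_frac <- function(s) {
    r <- suppressWarnings(microenv_flux(s, fit))
    r$flux_microenv_umolN_m2_h /
      (as.numeric(s$R_den_umolN_L_h) * 1e3 * r$z_O2_m)
  }
  fr_O2 <- vapply(c(150, 250, 350),
                  function(c) mean_frac(ref_site(C_O2_umol_L = c)), 0)
  expect_true(all(diff(fr_O2) <= 1e-9))
  fr_U <- vapply(c(0.1, 0.15, 0.2),
                 function(u) mean_frac(ref_site(U_bw_m_s = u)), 0)
  expect_true(all(diff(fr_U) <= 1e-9))
})

test_that("seawater property correlations give oceanographic values", {
  expect_equal(o2_saturation(10, 35), 281, tolerance = 0.01)
  expect_equal(seawater_density(10, 35), 1026.95, tolerance = 1e-4)
  expect_equal(seawater_viscosity(20, 35, kinematic = FALSE), 1.077e-3,
               tolerance = 0.01)
  expect_equal(o2_diffusivity(25), 1.1e-9)
  expect_lt(o2_diffusivity(5), 1.1e-9)
})
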