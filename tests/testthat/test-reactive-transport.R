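# Single-grain flow and reactive transport solver.

test_that("the flow field honours no-slip, conservation and the limits", {
  cfg <- fast_config(inflow_velocity_um_s = 100)
  fl <- solve_flow(cfg)
  # discrete divergence of the face fluxes vanishes cell by cell
  div <- fl$Q_r[-1, ] - fl$Q_r[-nrow(fl$Q_r), ] +
    fl$Q_t[, c(2:ncol(fl$Q_t), 1)] - fl$Q_t
  expect_lt(max(abs(div)), 1e-9 * max(abs(fl$Q_r)))
  # no-slip on the grain: vanishing velocity at the innermost cells
  expect_lt(max(abs(fl$u_r[1, ]), abs(fl$u_theta[1, ])), 0.05 * 100)
  # total inflow equals total outflow across the outer boundary (0.1%)
  Qb <- fl$Q_r[nrow(fl$Q_r), ]
  expect_lt(abs(sum(Qb)), 1e-3 * sum(pmax(Qb, 0)))
  # stagnant limit: everything at rest
  fl0 <- solve_flow(fast_config(inflow_velocity_um_s = 0))
  expect_equal(max(abs(fl0$u_r), abs(fl0$u_theta), abs(fl0$Q_r)), 0)
  # vanishing grain: plug flow away from the grain (slow logarithmic
  # convergence, hence the loose tolerance)
  tiny <- grain_model_config(grain_radius_um = 0.145,
                             rim_thickness_um = 0.01, n_radial_rim = 2,
                             consumer_arc_um = 0.05,
                             producer_arc_um = 0.025,
                             domain_radius_factor = 8000,
                             inflow_velocity_um_s = 100)
  flt <- solve_flow(tiny)
  far <- flt$grid$rc > 0.2 * max(flt$grid$rc)
  ux <- flt$u_r[far, ] * rep(cos(flt$grid$tc), each = sum(far)) -
    flt$u_theta[far, ] * rep(sin(flt$grid$tc), each = sum(far))
  expect_equal(mean(ux), 100, tolerance = 0.1)
})

test_that("the surface reaction field reproduces the colony pattern", {
  cfg <- grain_model_config()
  r_mid <- 147.5
  # colony cores: peak consumption at sin(4 theta) = -1, peak production
  # at sin(4 theta) = +1
  expect_equal(surface_reaction_field(cfg, r_mid, 3 * pi / 8), -955)
  expect_equal(surface_reaction_field(cfg, r_mid, pi / 8), 514)
  expect_equal(surface_reaction_field(cfg, 200, 3 * pi / 8), 0)
  # arc lengths: integrate the sign over a fine angular grid
  th <- 2 * pi * (seq_len(72000) - 0.5) / 72000
  v <- surface_reaction_field(cfg, r_mid, th)
  arc <- 2 * pi * 145 / length(th)
  expect_equal(sum(v < 0) * arc, 4 * 76, tolerance = 0.01)
  expect_equal(sum(v > 0) * arc, 4 * 38, tolerance = 0.01)
  # production switch removes all positive rates
  cfg_off <- grain_model_config(production_on = FALSE)
  expect_true(all(surface_reaction_field(cfg_off, r_mid, th) <= 0))
})

test_that("solute fields satisfy the trivial limits", {
  # no reaction: O2 stays at the bulk value, no N2 anywhere
  cfg0 <- fast_config(R_c_min = 0, R_c_max = 0, inflow_O2_umol_L = 80,
                      inflow_velocity_um_s = 50)
  sol0 <- solve_solutes(cfg0)
  expect_equal(range(sol0$C_O2), c(80, 80), tolerance = 1e-8)
  expect_equal(max(abs(sol0$C_N2)), 0, tolerance = 1e-12)
  # anoxic inflow with consumption only: O2 identically zero and the N2
  # source at full strength (f_N = 1) inside consuming colonies
  cfg_a <- fast_config(inflow_O2_umol_L = 0, production_on = FALSE,
                       inflow_velocity_um_s = 50)
  sol_a <- solve_solutes(cfg_a)
  expect_equal(max(sol_a$C_O2), 0, tolerance = 1e-10)
  expect_equal(sol_a$n2_source, 0.1 * sol_a$potential_o2_sink,
               tolerance = 1e-12)
  expect_equal(max(sol_a$n2_source), 0.1 * 955e3, tolerance = 0.05)
  # disabled consumption: nothing anoxic, no N2
  cfg_n <- fast_config(R_c_min = 0, inflow_O2_umol_L = 50,
                       inflow_velocity_um_s = 50)
  sm_n <- summarize_microenv(cfg_n, solve_solutes(cfg_n))
  expect_equal(sm_n$anoxic_rim_volume_fraction, 0)
  expect_equal(sm_n$n2_per_grain_nmol_d, 0)
})

test_that("O2 mass balance closes against the boundary fluxes", {
  cfg <- fast_config(inflow_velocity_um_s = 100, inflow_O2_umol_L = 25)
  sol <- solve_solutes(cfg)
  expect_lt(sol$o2_balance$rel_error, 0.01)
  expect_lt(sol$n2_balance$rel_error, 0.01)
  expect_lt(sol$residual_rel, 1e-8)
  expect_gte(min(sol$C_O2), 0)
})

test_that("the stagnant rim profile approaches the 1D analytic solution", {
  a <- 145; w <- 5; b <- 8 * a
  cfg <- grain_model_config(inflow_velocity_um_s = 0,
                            inflow_O2_umol_L = 100,
                            consumer_arc_um = 2 * pi * a / 4,
                            producer_arc_um = 0, R_c_min = -5, R_c_max = 0,
                            reaction_shape = "uniform", K_m = 1e-4,
                            outer_bc = "dirichlet")
  sol <- solve_solutes(cfg)
  D <- 1.1e-9 * 1e12 * 3600                 # um^2/h
  R0 <- 5e3                                 # umol/L/h
  rw <- a + w
  B <- R0 * (rw^2 - a^2) / (2 * D)
  Cw <- 100 + B * log(rw / b)
  rr <- sol$grid$rc
  Can <- ifelse(rr > rw, 100 + B * log(rr / b),
                Cw - (R0 / (4 * D) * (rw^2 - rr^2) -
                        R0 * a^2 / (2 * D) * log(rw / rr)))
  expect_lt(max(abs(rowMeans(sol$C_O2) - Can)) / max(100 - Can), 0.05)
})

test_that("fully anoxic colonies produce ~0.2 nmol N per colony per day", {
  cfg <- grain_model_config(inflow_velocity_um_s = 10,
                            inflow_O2_umol_L = 1)
  sol <- solve_solutes(cfg)
  sm <- summarize_microenv(cfg, sol)
  expect_equal(sm$anoxic_colony_count, 4L)
  # per-colony and per-grain N2 production at the reported order of
  # magnitude (factor-of-two band reflecting the 2D-to-3D extrusion)
  expect_gt(min(sm$n2_per_colony_nmol_d), 0.1)
  expect_lt(max(sm$n2_per_colony_nmol_d), 0.4)
  expect_equal(sm$n2_per_grain_nmol_d, sum(sm$n2_per_colony_nmol_d),
               tolerance = 1e-9)
})

test_that("halving the cell size changes the anoxic fraction by < 5%", {
  cfg1 <- grain_model_config(inflow_velocity_um_s = 100,
                             inflow_O2_umol_L = 25)
  f1 <- summarize_microenv(cfg1,
                           solve_solutes(cfg1))$anoxic_rim_volume_fraction
  cfg2 <- grain_model_config(inflow_velocity_um_s = 100,
                             inflow_O2_umol_L = 25,
                             n_radial_rim = 12, n_radial_outer = 100,
                             n_theta = 360)
  f2 <- summarize_microenv(cfg2,
                           solve_solutes(cfg2))$anoxic_rim_volume_fraction
  expect_lt(abs(f1 - f2) / f2, 0.05)
})

test_that("the ensemble covers the grid, records failures, stays monotone", {
  expect_equal(nrow(run_ensemble(grain_model_config(), numeric(0),
                                 numeric(0))), 0L)
  ens <- cached_ensemble(TRUE)
  expect_equal(nrow(ens), length(ensemble_U) * length(ensemble_C0))
  expect_true(all(ens$converged))
  # anoxic fraction decreases with bulk O2 at every velocity
  for (u in ensemble_U) {
    sub <- ens[ens$U_um_s == u, ]
    sub <- sub[order(sub$C0_umol_L), ]
    expect_true(all(diff(sub$anoxic_fraction) <= 1e-6),
                label = sprintf("monotone in C0 at U = %g", u))
  }
  # without photosynthesis the fraction is also non-increasing in U
  off <- cached_ensemble(FALSE)
  for (c0 in ensemble_C0) {
    sub <- off[off$C0_umol_L == c0, ]
    sub <- sub[order(sub$U_um_s), ]
    expect_true(all(diff(sub$anoxic_fraction) <= 0.03),
                label = sprintf("near-monotone in U at C0 = %g", c0))
  }
})

test_that("photosynthetic activity has a minor effect at interior conditions", {
  on <- cached_ensemble(TRUE)
  off <- cached_ensemble(FALSE)
  key <- function(d) paste(d$U_um_s, d$C0_umol_L)
  delta <- abs(on$anoxic_fraction - off$anoxic_fraction[
    match(key(on), key(off))])
  # representative mid-range conditions
  mid <- on$U_um_s %in% c(50, 150) & on$C0_umol_L %in% c(10, 25)
  expect_lt(max(delta[mid]), 0.15)
  expect_lt(stats::median(delta), 0.15)
})
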