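# Shared single-grain ensemble, solved once per test run and reused by the
# scaling, transport and acceptance tests.  The (U, C0) grid spans the
# study ranges: pore-water velocities 0-500 um/s, bulk O2 1-100 umol/L.

ensemble_U <- c(0, 10, 50, 150, 500)
ensemble_C0 <- c(1, 10, 25, 100)

.ensemble_cache <- new.env(parent = emptyenv())

cached_ensemble <- function(production = TRUE) {
  key <- if (production) "on" else "off"
  if (is.null(.ensemble_cache[[key]])) {
    cfg <- grain_model_config()
    .ensemble_cache[[key]] <- run_ensemble(cfg, ensemble_U, ensemble_C0,
                                           production_on = production)
  }
  .ensemble_cache[[key]]
}

# small fast config for structural solver tests
fast_config <- function(...) {
  grain_model_config(n_radial_rim = 4, n_radial_outer = 30, n_theta = 96, ...)
}

# synthetic Stern-Volmer calibration used across the imaging tests
reference_calibration <- function(R0 = 2, Ksv = 0.02) {
  o2 <- seq(0, 300, by = 25)
  fit_calibration(data.frame(o2_umol_L = o2, ratio = R0 / (1 + Ksv * o2)))
}
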