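# reduced-resolution settings for fast property tests; full resolution is
# exercised in the acceptance tests
fast_solver <- function(dt = 4) {
  solver_settings(rtol = 1e-6, atol = 1e-10, dt = dt)
}

fast_aristada <- function(dose_mg_eq = 400, icl = TRUE, n_bins = 8, dt = 4,
                          ...) {
  scenario_aristada(dose_mg_eq, icl = icl, n_bins = n_bins,
                    solver = fast_solver(dt), ...)
}

# clinical-style sampling grid for synthetic-profile fits (h)
clinical_grid <- function() {
  c(24, 48, 96, 168, 336, 504, 672, 840, 1008, 1344, 1680, 2136)
}
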