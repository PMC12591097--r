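test_that("synthetic profiles are reproducible with mean-one noise", {
  sc <- fast_aristada(400, dt = 8)
  grid <- clinical_grid()
  # cv = 0 returns exact model values
  clean <- generate_synthetic_profile(sc, grid, cv = 0, seed = 7)
  sim <- simulate_scenario(sc)
  expect_equal(clean$conc_ng_ml,
               approx(sim$time, sim$cp, xout = grid)$y, tolerance = 1e-12)
  # determinism under a fixed seed, variation across seeds
  n1 <- generate_synthetic_profile(sc, grid, cv = 0.1, seed = 42)
  n2 <- generate_synthetic_profile(sc, grid, cv = 0.1, seed = 42)
  n3 <- generate_synthetic_profile(sc, grid, cv = 0.1, seed = 43)
  expect_identical(n1$conc_ng_ml, n2$conc_ng_ml)
  expect_false(identical(n1$conc_ng_ml, n3$conc_ng_ml))
  # the global RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_synthetic_profile(sc, grid, 0.1, 5))
  expect_identical(rnorm(1), before)
  # log-normal multipliers have unit mean at the parameterized sigma
  sigma <- sqrt(log(1 + 0.1^2))
  mult <- withr::with_seed(99, exp(rnorm(1e4, -sigma^2 / 2, sigma)))
  expect_equal(mean(mult), 1, tolerance = 0.02)
})

test_that("the metric objective is zero at the truth and order-invariant", {
  sc <- fast_aristada(400, dt = 8)
  m <- pk_metrics(simulate_scenario(sc))
  target <- fit_target_metrics(m$cmax, m$auc0t, m$tmax, t_last = sc$horizon)
  r0 <- icldepot:::fit_residuals(
    log(c(sc$icl$A, sc$icl$B)), free = c("A", "B"),
    log_scale = c(TRUE, TRUE), sc = sc, target = target
  )
  expect_lt(sum(r0^2), 1e-12)
  # profile residuals are invariant to reordering of the target points
  prof <- generate_synthetic_profile(sc, clinical_grid(), cv = 0.1, seed = 3)
  perm <- rev(seq_len(nrow(prof)))
  r_fwd <- icldepot:::fit_residuals(log(c(sc$icl$A, sc$icl$B)),
                                    c("A", "B"), c(TRUE, TRUE), sc, prof)
  r_rev <- icldepot:::fit_residuals(log(c(sc$icl$A, sc$icl$B)),
                                    c("A", "B"), c(TRUE, TRUE), sc,
                                    prof[perm, ])
  expect_equal(sum(r_fwd^2), sum(r_rev^2), tolerance = 1e-12)
})

test_that("noise-free self-consistency: {A, B} are recovered", {
  sc <- fast_aristada(400, n_bins = 6, dt = 8)
  truth <- c(A = sc$icl$A, B = sc$icl$B)
  prof <- generate_synthetic_profile(sc, clinical_grid(), cv = 0, seed = 1)
  fit <- fit_icl(sc, prof, free = c("A", "B"),
                 bounds = list(A = c(2.09e-8, 2.09e-4)),
                 n_local = 3, maxiter = 40)
  expect_true(fit$converged)
  expect_equal(unname(fit$par["A"]), unname(truth["A"]), tolerance = 0.01)
  expect_equal(unname(fit$par["B"]), unname(truth["B"]), tolerance = 0.01)
  # refitting from the optimum is a fixed point
  refit <- minpack.lm::nls.lm(
    par = log(fit$par), lower = log(c(2.09e-8, 0.003)),
    upper = log(c(2.09e-4, 0.07)),
    fn = icldepot:::fit_residuals, free = c("A", "B"),
    log_scale = c(TRUE, TRUE), sc = sc, target = prof
  )
  expect_lt(fit$objective - refit$deviance, 1e-10)
})

test_that("the 3-parameter fit resolves the conductance ratio kappa/A", {
  # A and kappa only enter the dynamics through kappa/A, so the full
  # {A, B, kappa} fit is checked on that identified combination
  sc <- fast_aristada(400, n_bins = 6, dt = 8)
  m <- pk_metrics(simulate_scenario(sc))
  target <- fit_target_metrics(m$cmax, m$auc0t, m$tmax)
  fit <- fit_icl(sc, target, free = c("A", "B", "kappa"),
                 n_local = 3, maxiter = 40)
  expect_lt(fit$objective, 1e-6)
  ratio_true <- sc$icl$kappa / sc$icl$A
  ratio_fit <- fit$par[["kappa"]] / fit$par[["A"]]
  expect_equal(ratio_fit, ratio_true, tolerance = 0.05)
  expect_equal(fit$par[["B"]], sc$icl$B, tolerance = 0.05)
})

test_that("fit guards: under-determination and bounds", {
  sc <- fast_aristada(400, dt = 24)
  target <- fit_target_metrics(97.39, 138100)
  expect_error(fit_icl(sc, target, free = c("A", "B", "kappa", "h_uwl")),
               "under-determined")
  sc_off <- fast_aristada(400, icl = FALSE, dt = 24)
  expect_error(fit_icl(sc_off, target), "icl")
  prof <- fit_target_profile(c(24, 48), c(1, 2))
  f <- fit_icl(sc, prof, free = "B", n_local = 1, maxiter = 5)
  # bounds respected up to log/exp round-off
  expect_true(f$par[["B"]] >= 0.003 * (1 - 1e-12) &&
                f$par[["B"]] <= 0.07 * (1 + 1e-12))
})

test_that("dose validation tabulates fold errors against observed metrics", {
  kin <- icl_params(A = 2.09e-6, B = 0.012, kappa = 1)
  tab <- validate_doses(kin, doses = c(150, 400),
                        scenario_fun = function(d, icl_kinetics) {
                          scenario_aristada(d, icl_kinetics = icl_kinetics,
                                            n_bins = 8,
                                            solver = fast_solver(4))
                        })
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$cmax_fe, tab$cmax_sim / tab$cmax_obs, tolerance = 1e-12)
  expect_true(all(c("auc0t_pass", "cmax_pass") %in% names(tab)))
  # observed == simulated gives unit fold errors and all-pass flags
  obs_self <- data.frame(dose_mg_eq = c(150, 400),
                         cmax_ng_ml = tab$cmax_sim,
                         auc0t_ng_h_ml = tab$auc0t_sim,
                         tmax_h = tab$tmax_sim)
  tab2 <- validate_doses(kin, doses = c(150, 400), observed = obs_self,
                         scenario_fun = function(d, icl_kinetics) {
                           scenario_aristada(d, icl_kinetics = icl_kinetics,
                                             n_bins = 8,
                                             solver = fast_solver(4))
                         })
  expect_equal(tab2$cmax_fe, c(1, 1), tolerance = 1e-9)
  expect_true(all(tab2$cmax_pass) && all(tab2$auc0t_pass))
  # empty dose list -> empty table
  expect_identical(nrow(validate_doses(kin, doses = numeric(0))), 0L)
})
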