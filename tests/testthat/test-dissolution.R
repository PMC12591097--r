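test_that("bin discretization conserves dose and matches the PSD", {
  psd <- particle_size_distribution(n_bins = 20)
  bins <- build_bins(psd, 589.5)
  expect_equal(sum(bins$mass_mg), 589.5, tolerance = 1e-12)
  expect_true(all(bins$mass_mg > 0) && all(bins$count > 0))
  expect_true(!is.unsorted(bins$r0_um, strictly = TRUE))
  # counts consistent with mass, density and radius
  m_back <- bins$count * psd$density * (4 / 3) * pi * (bins$r0_um * 1e-4)^3 * 1000
  expect_equal(m_back, bins$mass_mg, tolerance = 1e-12)
  # degenerate discretization: one bin at the volume-weighted mean radius
  b1 <- build_bins(particle_size_distribution(n_bins = 1), 100)
  expect_identical(nrow(b1), 1L)
  expect_equal(b1$mass_mg, 100)
  expect_equal(b1$r0_um, 14.18, tolerance = 1e-12)
})

test_that("quantile-matched log-normal reproduces the measured Dv50", {
  psd <- particle_size_distribution(dv10 = 13.87, dv50 = 28.74, dv90 = 53.54,
                                    n_bins = 30)
  lp <- icldepot:::lognormal_radius_params(psd)
  dv50_implied <- 2 * exp(lp$mu) # median radius -> median diameter
  expect_equal(dv50_implied, 28.74, tolerance = 0.05)
  # mass-weighted median of the discretized bins agrees too
  bins <- build_bins(psd, 1000)
  cum <- cumsum(bins$mass_mg) / sum(bins$mass_mg)
  r_med <- bins$r0_um[which(cum >= 0.5)[1]]
  expect_equal(2 * r_med, 28.74, tolerance = 0.1)
})

test_that("dissolution rates: saturation, exhaustion, non-negativity", {
  psd <- particle_size_distribution(n_bins = 5)
  bins <- build_bins(psd, 100)
  set <- dissolution_settings(d_aq = 5.23e-6)
  s <- 3e-4
  r <- dissolution_rates(bins, c_unbound = 0, s_site = s, settings = set)
  expect_true(all(r > 0))
  # saturation shuts dissolution off
  expect_identical(dissolution_rates(bins, c_unbound = s, s_site = s,
                                     settings = set),
                   numeric(5))
  # supersaturation does not re-precipitate (no negative rates)
  expect_identical(dissolution_rates(bins, c_unbound = 2 * s, s_site = s,
                                     settings = set),
                   numeric(5))
  # exhausted bins are silent
  bins2 <- bins
  bins2$mass_mg[2] <- 0
  r2 <- dissolution_rates(bins2, 0, s, set)
  expect_identical(r2[2], 0)
  expect_equal(r2[-2], r[-2], tolerance = 1e-12)
  # smaller particles dissolve faster per unit mass
  per_mass <- r / bins$mass_mg
  expect_true(all(diff(per_mass) < 0))
})

test_that("single-particle dissolution matches the m^(2/3) closed form", {
  # one bin, sink conditions, constant diffusion layer
  psd <- particle_size_distribution(mean_radius = 14.18, sd_radius = 0,
                                    n_bins = 1)
  m0 <- 50
  bins <- build_bins(psd, m0)
  set <- dissolution_settings(h_uwl = 65, d_aq = 5.23e-6)
  rhs <- function(t, y, parms) {
    b <- bins
    b$mass_mg <- y
    list(-dissolution_rates(b, 0, 3e-4, set))
  }
  tt <- seq(0, 500, by = 5)
  num <- deSolve::lsoda(m0, tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)[, 2]
  ana <- single_particle_mass(tt, m0, 14.18, psd$density, 5.23e-6, 65, 3e-4)
  expect_lt(max(abs(num - ana)) / m0, 1e-3)
})

test_that("radii shrink over time and total dissolution speeds up for finer material", {
  sim <- simulate_scenario(fast_aristada(400, icl = FALSE, dt = 8))
  frac <- sweep(pmax(sim$bin_mass, 0), 2, sim$bin_mass[1, ], "/")
  radii <- frac^(1 / 3) # relative radius per bin
  expect_true(all(diff(radii) <= 1e-6)) # non-increasing columnwise
  # time to dissolve half the dose decreases with mean radius
  t50 <- vapply(c(7, 14.18, 28), function(r) {
    sc <- fast_aristada(400, icl = FALSE, dt = 8)
    sc$psd$mean_radius <- r
    sc$psd$sd_radius <- 7.4 * r / 14.18
    s <- simulate_scenario(sc)
    s$time[which(s$solid_mg <= 0.5 * s$solid_mg[1])[1]]
  }, numeric(1))
  expect_true(all(diff(t50) > 0))
})

test_that("under the min-radius rule small bins exhaust first", {
  sc <- fast_aristada(400, icl = FALSE, dt = 8)
  sc$dissolution$h_rule <- "min_radius"
  sim <- simulate_scenario(sc)
  frac_end <- pmax(sim$bin_mass[nrow(sim$bin_mass), ], 0) / sim$bin_mass[1, ]
  expect_true(all(diff(frac_end) > -1e-6)) # smallest radii most depleted
})
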