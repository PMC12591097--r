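# Independent oracles used to check the ODE implementation.

# Analytic three-compartment solution by eigen-decomposition of the rate
# matrix: bolus or zero-order infusion into the central compartment.
# Returns central-compartment amounts (mg) at `times`.
analytic_3cpt_central <- function(times, dose_mg, duration_h, dsp) {
  ke <- dsp$clh / dsp$vc
  m <- matrix(c(-(ke + dsp$k12 + dsp$k13), dsp$k21, dsp$k31,
                dsp$k12, -dsp$k21, 0,
                dsp$k13, 0, -dsp$k31),
              nrow = 3, byrow = TRUE)
  eg <- eigen(m)
  v <- eg$vectors; vi <- solve(v); lam <- eg$values
  expm_t <- function(t) v %*% diag(exp(lam * t), 3) %*% vi
  u <- c(dose_mg / duration_h, 0, 0)
  minv_u <- solve(m, u)
  x_on <- function(t) (expm_t(t) - diag(3)) %*% minv_u
  x_end <- x_on(duration_h)
  vapply(times, function(t) {
    x <- if (t <= duration_h) x_on(t) else expm_t(t - duration_h) %*% x_end
    Re(x[1])
  }, numeric(1))
}

# Closed-form shrinking-sphere dissolution under sink conditions with a
# constant diffusion layer: dm/dt = -K m^(2/3) gives
# m(t) = (m0^(1/3) - K t / 3)^3 until exhaustion.
single_particle_mass <- function(t, m0_mg, r0_um, density, d_aq, h_uwl_um,
                                 s_mg_ml) {
  r0_cm <- r0_um * 1e-4
  coef <- 3 * (m0_mg / 1000) / (density * r0_cm) # cm^2
  k <- coef * (d_aq / (h_uwl_um * 1e-4)) * s_mg_ml * 3600 / m0_mg^(2 / 3)
  core <- pmax(m0_mg^(1 / 3) - k * t / 3, 0)
  core^3
}
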