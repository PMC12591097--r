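#' Particle size distribution of a suspension
#'
#' The suspension's particle radii are described by a log-normal distribution
#' of the volume-weighted radius, either moment-matched to a reported
#' mean +/- SD or quantile-matched to measured Dv10/Dv50/Dv90 diameters. A
#' log-normal family is used because radii are positive; a normal distribution
#' with the reference values (14.18 +/- 7.4 um) would place around 3% of the
#' mass at negative radii.
#'
#' @param mean_radius Volume-weighted mean radius (um).
#' @param sd_radius Standard deviation of the radius (um); 0 gives a
#'   monodisperse suspension.
#' @param n_bins Number of discretization bins (>= 1).
#' @param density Particle density (g/cm^3), used to convert bin masses to
#'   particle counts and surface areas.
#' @param dv10,dv50,dv90 Optional measured cumulative volume-distribution
#'   diameters (um). When all three are given they take precedence over the
#'   mean/SD and the log-normal is least-squares fitted to the three
#'   quantiles.
#' @return An object of class `particle_size_distribution`.
#' @export
particle_size_distribution <- function(mean_radius = 14.18, sd_radius = 7.4,
                                       n_bins = 20, density = 1.774,
                                       dv10 = NULL, dv50 = NULL, dv90 = NULL) {
  stopifnot(
    "mean_radius must be > 0" = mean_radius > 0,
    "sd_radius must be >= 0" = sd_radius >= 0,
    "n_bins must be >= 1" = n_bins >= 1,
    "density must be > 0" = density > 0
  )
  dv <- c(dv10 = dv10, dv50 = dv50, dv90 = dv90)
  if (length(dv) > 0 && length(dv) != 3) {
    stop("supply all three of dv10/dv50/dv90 or none", call. = FALSE)
  }
  structure(
    list(mean_radius = mean_radius, sd_radius = sd_radius,
         n_bins = as.integer(n_bins), density = density,
         dv10 = dv10, dv50 = dv50, dv90 = dv90),
    class = "particle_size_distribution"
  )
}

#' Dissolution settings
#'
#' @param h_uwl Unstirred water (diffusion) layer thickness (um). The default
#'   65 um is the value calibrated for the lauroxil suspension depot.
#' @param h_rule How the diffusion layer relates to the particle radius:
#'   `"constant"` uses `h_uwl` for every bin at all times; `"min_radius"` caps
#'   the layer at the current particle radius (`h_i = min(r_i, h_uwl)`), the
#'   convention of radius-coupled Johnson-type models.
#' @param d_aq Optional aqueous diffusion coefficient (cm^2/s); defaults to
#'   the drug's [aqueous_diffusivity()].
#' @param s_site Optional solubility at the injection site (mg/mL). Default
#'   `NULL` uses the drug's reference solubility `s_ref` (the baseline of the
#'   model's sensitivity analyses); set `site_ph` in [depot_physiology()] to
#'   use an ionization-adjusted value instead.
#' @return An object of class `dissolution_settings`.
#' @export
dissolution_settings <- function(h_uwl = 65, h_rule = c("constant", "min_radius"),
                                 d_aq = NULL, s_site = NULL) {
  stopifnot("h_uwl must be > 0" = h_uwl > 0)
  h_rule <- match.arg(h_rule)
  if (!is.null(d_aq)) stopifnot(d_aq > 0)
  if (!is.null(s_site)) stopifnot(s_site > 0)
  structure(list(h_uwl = h_uwl, h_rule = h_rule, d_aq = d_aq, s_site = s_site),
            class = "dissolution_settings")
}

# log-normal parameters (of the radius, um) implied by a PSD specification
lognormal_radius_params <- function(psd) {
  if (!is.null(psd$dv10)) {
    # quantile fit on radii = diameters / 2
    q <- c(0.10, 0.50, 0.90)
    r <- c(psd$dv10, psd$dv50, psd$dv90) / 2
    fit <- stats::lm(log(r) ~ stats::qnorm(q))
    mu <- unname(stats::coef(fit)[1])
    sigma <- max(unname(stats::coef(fit)[2]), 0)
  } else if (psd$sd_radius == 0) {
    mu <- log(psd$mean_radius)
    sigma <- 0
  } else {
    cv2 <- (psd$sd_radius / psd$mean_radius)^2
    sigma <- sqrt(log(1 + cv2))
    mu <- log(psd$mean_radius) - sigma^2 / 2
  }
  list(mu = mu, sigma = sigma)
}

#' Discretize a particle size distribution into mass bins
#'
#' Splits the log-normal volume-weighted radius distribution into `n_bins`
#' bins of equal width in log-radius, truncated at +/- 3 sigma, assigns each
#' bin its mass fraction of the dose, and derives the (fixed) particle count
#' per bin from the bin mass, particle density and initial radius:
#' `N_i = m0_i / (rho * 4/3 * pi * r0_i^3)`. Bin masses sum to the dose by
#' construction. With `n_bins = 1` (or a monodisperse PSD) a single bin at the
#' volume-weighted mean radius carries the whole dose.
#'
#' @param psd A [particle_size_distribution].
#' @param dose_mg Solid dose (mg) to distribute over the bins.
#' @return An object of class `particle_bins`: a data frame with columns
#'   `r0_um` (initial radius), `mass_mg` (initial = current mass) and `count`,
#'   with the density kept as an attribute.
#' @export
build_bins <- function(psd, dose_mg) {
  stopifnot(inherits(psd, "particle_size_distribution"),
            "dose must be > 0" = dose_mg > 0)
  lp <- lognormal_radius_params(psd)
  if (psd$n_bins == 1L || lp$sigma == 0) {
    r0 <- exp(lp$mu + lp$sigma^2 / 2) # volume-weighted mean radius
    w <- 1
  } else {
    edges <- seq(lp$mu - 3 * lp$sigma, lp$mu + 3 * lp$sigma,
                 length.out = psd$n_bins + 1)
    w <- diff(stats::pnorm(edges, mean = lp$mu, sd = lp$sigma))
    w <- w / sum(w)
    r0 <- exp((edges[-1] + edges[-length(edges)]) / 2)
  }
  mass <- dose_mg * w
  r0_cm <- r0 * 1e-4
  count <- (mass / 1000) / (psd$density * (4 / 3) * pi * r0_cm^3)
  structure(
    data.frame(r0_um = r0, mass_mg = mass, count = count),
    class = c("particle_bins", "data.frame"),
    density = psd$density,
    dose_mg = dose_mg
  )
}

# Per-bin dissolution rates (mg/h); fast internal kernel shared with the ODE
# right-hand side. m and m0 in mg, r0 in cm, coef = initial surface area per
# bin (cm^2), d_aq cm^2/s, h_uwl cm, concentrations mg/mL.
bin_dissolution_rates <- function(m, m0, r0, coef, d_aq, h_uwl, h_rule_min,
                                  c_unbound, s_site) {
  frac <- pmax(m, 0) / m0
  grad <- max(s_site - c_unbound, 0)
  if (grad == 0) return(numeric(length(m)))
  h <- if (h_rule_min) pmin(r0 * frac^(1 / 3), h_uwl) else rep(h_uwl, length(m))
  rate <- ifelse(frac > 0, coef * frac^(2 / 3) * (d_aq / h) * grad * 3600, 0)
  rate
}

#' Per-bin dissolution rates
#'
#' Johnson/Nernst-Brunner film dissolution for a set of shrinking particle
#' bins: each bin dissolves at
#' `N_i * 4*pi*r_i^2 * (D_aq / h_i) * max(S_site - C_unbound, 0)` with the
#' current radius `r_i = r0_i * (m_i/m0_i)^(1/3)` and the diffusion layer
#' `h_i` set by the `h_rule`. Exhausted bins contribute zero and rates are
#' never negative (no re-precipitation).
#'
#' @param bins A [build_bins()] object; `mass_mg` holds the current masses.
#' @param c_unbound Unbound dissolved concentration in the depot fluid
#'   (mg/mL).
#' @param s_site Solubility at the injection site (mg/mL).
#' @param settings A [dissolution_settings] object; `d_aq` must be set.
#' @return Per-bin dissolution rates (mg/h).
#' @export
dissolution_rates <- function(bins, c_unbound, s_site, settings) {
  stopifnot(inherits(bins, "particle_bins"),
            inherits(settings, "dissolution_settings"),
            "c_unbound must be >= 0" = c_unbound >= 0,
            "settings$d_aq must be set" = !is.null(settings$d_aq))
  if (any(bins$mass_mg < -1e-9 * sum(attr(bins, "dose_mg")))) {
    stop("negative bin mass: the solver state is inconsistent", call. = FALSE)
  }
  dose <- attr(bins, "dose_mg")
  density <- attr(bins, "density")
  lp <- bins$mass_mg # current
  # initial masses: reconstruct from counts (counts are fixed over time)
  r0_cm <- bins$r0_um * 1e-4
  m0 <- bins$count * density * (4 / 3) * pi * r0_cm^3 * 1000
  coef <- 3 * (m0 / 1000) / (density * r0_cm)
  bin_dissolution_rates(lp, m0, r0_cm, coef,
                        d_aq = settings$d_aq, h_uwl = settings$h_uwl * 1e-4,
                        h_rule_min = settings$h_rule == "min_radius",
                        c_unbound = c_unbound, s_site = s_site)
}
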