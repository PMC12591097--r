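#' Inflammatory cell layer (ICL) parameters
#'
#' The foreign-body reaction to an injected suspension wraps the depot in a
#' layer of inflammatory cells that acts as a diffusion barrier. The layer
#' grows and then resolves; its thickness follows
#' `A * (t - t_lag) * exp(-B * (t - t_lag))` after an optional onset lag.
#'
#' @param A Thickness magnitude (cm/h). `A = 0` produces a permanently absent
#'   layer.
#' @param B Thickness decay rate (1/h). The layer peaks at `t_lag + 1/B` with
#'   peak thickness `A/(B*e)`.
#' @param t_lag Onset lag (h): thickness is identically zero before it.
#' @param surface_area Depot surface area (cm^2) the layer covers; see
#'   [depot_surface_area()].
#' @param d_icl Diffusion coefficient of the drug in the layer (cm^2/s); see
#'   [icl_diffusivity()].
#' @param fu_icl Fraction of drug unbound within the layer, in (0, 1]; see
#'   [icl_fraction_unbound()]. Only unbound drug is assumed to permeate.
#' @param kappa Dimensionless conductance scale (>= 0). The flux law that
#'   combines diffusivity, binding, area and thickness into a permeability is
#'   not published for the reference software; `kappa` absorbs that unknown
#'   proportionality and is calibrated together with `A` and `B`.
#' @param enabled Logical; `FALSE` removes the barrier entirely.
#'
#' @return An object of class `icl_params`.
#' @export
icl_params <- function(A = 2.09e-6, B = 0.012, t_lag = 0,
                       surface_area = NULL, d_icl = NULL, fu_icl = NULL,
                       kappa = 1, enabled = TRUE) {
  stopifnot(
    "A must be >= 0" = A >= 0,
    "B must be > 0" = B > 0,
    "t_lag must be >= 0" = t_lag >= 0,
    "kappa must be >= 0" = kappa >= 0
  )
  if (!is.null(surface_area)) stopifnot(surface_area > 0)
  if (!is.null(fu_icl)) stopifnot(fu_icl > 0, fu_icl <= 1)
  if (!is.null(d_icl)) stopifnot(d_icl > 0)
  structure(
    list(A = A, B = B, t_lag = t_lag, surface_area = surface_area,
         d_icl = d_icl, fu_icl = fu_icl, kappa = kappa,
         enabled = isTRUE(enabled)),
    class = "icl_params"
  )
}

#' ICL thickness over time
#'
#' `thickness(t) = A * (t - t_lag) * exp(-B * (t - t_lag))` for `t > t_lag`,
#' zero before. Continuous, non-negative, zero at the lag, single interior
#' maximum `A/(B*e)` at `t_lag + 1/B`, and decaying to zero as the
#' inflammation resolves.
#'
#' @param t Time since injection (h), vectorized.
#' @param p An [icl_params] object.
#' @return Thickness (cm).
#' @export
icl_thickness <- function(t, p) {
  stopifnot(inherits(p, "icl_params"), all(t >= 0))
  tau <- pmax(t - p$t_lag, 0)
  p$A * tau * exp(-p$B * tau)
}

#' Drug diffusivity in the ICL
#'
#' For lipophilic permeants with `logD(7.4) > 3` the layer diffusivity is the
#' constant `10^-5.9514` cm^2/s (1.118e-6, conventionally printed 1.12e-6).
#' The relation is only defined on that branch; for less lipophilic drugs a
#' user-supplied `d_icl` is required.
#'
#' @param logd74 Distribution coefficient at pH 7.4.
#' @return Diffusivity (cm^2/s).
#' @export
icl_diffusivity <- function(logd74) {
  if (any(logd74 <= 3)) {
    stop("ICL diffusivity is only defined for logD(7.4) > 3; ",
         "supply `d_icl` directly for this compound.", call. = FALSE)
  }
  rep_len(10^(-5.9514), length(logd74))
}

#' Fraction unbound in the ICL
#'
#' `fu_ICL = 1 / (2.12 * exp(0.523 * logD(7.4)))`, clamped to (0, 1]:
#' lipophilic drugs are heavily bound within the cell layer, which scales down
#' the permeating (unbound) concentration. Strictly decreasing in logD.
#'
#' @param logd74 Distribution coefficient at pH 7.4.
#' @return Fraction unbound (dimensionless), vectorized.
#' @export
icl_fraction_unbound <- function(logd74) {
  pmin(1 / (2.12 * exp(0.523 * logd74)), 1)
}

#' Depot surface area from injected dose
#'
#' Models the depot as a single sphere of volume `dose / density`, so
#' `SA = (36*pi)^(1/3) * (dose/density)^(2/3)`. Surface area scales exactly
#' as dose^(2/3).
#'
#' @param dose_mg Injected solid mass (mg of prodrug for a suspension).
#' @param density Depot density (g/cm^3). The default 1.774 reproduces the
#'   2.32 cm^2 surface area of the 400 mg-equivalent lauroxil depot; see
#'   [calibrate_depot_density()].
#' @return Surface area (cm^2), vectorized over `dose_mg`.
#' @export
depot_surface_area <- function(dose_mg, density = 1.774) {
  stopifnot(all(dose_mg > 0), density > 0)
  v <- (dose_mg / 1000) / density # cm^3
  (36 * pi)^(1 / 3) * v^(2 / 3)
}

#' Back-calculate depot density from a known surface area
#'
#' Inverts [depot_surface_area()]: given one (dose, surface area) pair the
#' spherical-depot density is `dose / volume` with
#' `volume = sqrt(SA^3 / (36*pi))`.
#'
#' @param dose_mg Injected solid mass (mg).
#' @param surface_area Surface area (cm^2).
#' @return Density (g/cm^3).
#' @export
calibrate_depot_density <- function(dose_mg, surface_area) {
  stopifnot(dose_mg > 0, surface_area > 0)
  v <- sqrt(surface_area^3 / (36 * pi))
  (dose_mg / 1000) / v
}

#' Diffusive conductance of the ICL
#'
#' Film model for permeation of the unbound drug across the layer:
#' `G_ICL(t) = kappa * SA * D_ICL * fu_ICL / thickness(t)`, converted to mL/h
#' (x3600 from per-second units). Where thickness is zero the layer poses no
#' barrier and the conductance is `Inf`. The product `conductance * thickness`
#' is constant in time, so the conductance is minimized exactly where the
#' thickness peaks (`t_lag + 1/B`).
#'
#' @param t Time since injection (h), vectorized.
#' @param p An [icl_params] object with `surface_area`, `d_icl` and `fu_icl`
#'   set.
#' @return Conductance (mL/h).
#' @export
icl_conductance <- function(t, p) {
  stopifnot(inherits(p, "icl_params"),
            !is.null(p$surface_area), !is.null(p$d_icl), !is.null(p$fu_icl))
  th <- icl_thickness(t, p)
  g0 <- p$kappa * p$surface_area * p$d_icl * p$fu_icl * 3600
  ifelse(th > 0, g0 / th, Inf)
}
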