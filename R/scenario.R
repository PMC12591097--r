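#' Three-compartment disposition parameters
#'
#' Linear mammillary three-compartment disposition with hepatic clearance from
#' the central compartment. All volumes and clearances are per kg of body
#' weight; a body weight converts them to absolute values.
#'
#' @param vc Central volume (L/kg).
#' @param clh Hepatic clearance (L/h/kg).
#' @param k12,k21,k13,k31 First-order inter-compartment rate constants (1/h).
#' @param body_weight Body weight (kg). The subject weight is not part of the
#'   published parameter set; 70 kg is the package default.
#' @return An object of class `disposition_params`.
#' @export
disposition_params <- function(vc = 1.5825, clh = 0.03028,
                               k12 = 0.22832, k21 = 0.17345,
                               k13 = 0.01108, k31 = 0.001911,
                               body_weight = 70) {
  stopifnot(vc > 0, clh > 0, k12 > 0, k21 > 0, k13 > 0, k31 > 0,
            body_weight > 0)
  structure(
    list(vc = vc, clh = clh, k12 = k12, k21 = k21, k13 = k13, k31 = k31,
         body_weight = body_weight),
    class = "disposition_params"
  )
}

#' Dose and formulation
#'
#' @param ar_equivalent_dose Dose in mg of parent drug equivalents.
#' @param route One of `"iv_infusion"`, `"im_solution"`, `"im_suspension"`.
#' @param is_prodrug Logical; `TRUE` when the administered species is a
#'   prodrug that is cleaved to the parent upon reaching the circulation.
#' @param injection_volume Injected volume (mL); required for IM routes.
#' @param infusion_duration Infusion duration (h); required for IV.
#' @return An object of class `formulation_dose`.
#' @export
formulation_dose <- function(ar_equivalent_dose,
                             route = c("im_suspension", "im_solution",
                                       "iv_infusion"),
                             is_prodrug = FALSE,
                             injection_volume = NULL,
                             infusion_duration = NULL) {
  route <- match.arg(route)
  stopifnot("dose must be > 0" = ar_equivalent_dose > 0)
  if (route %in% c("im_suspension", "im_solution")) {
    if (is.null(injection_volume) || injection_volume <= 0) {
      stop("IM routes require a positive injection_volume (mL)", call. = FALSE)
    }
  }
  if (route == "iv_infusion") {
    if (is.null(infusion_duration) || infusion_duration <= 0) {
      stop("iv_infusion requires a positive infusion_duration (h)",
           call. = FALSE)
    }
  }
  structure(
    list(ar_equivalent_dose = ar_equivalent_dose, route = route,
         is_prodrug = isTRUE(is_prodrug),
         injection_volume = injection_volume,
         infusion_duration = infusion_duration),
    class = "formulation_dose"
  )
}

#' Effective depot volume from injection volume
#'
#' The fluid volume available for dissolution at the injection site is the
#' injection volume divided by the muscle extracellular volume fraction
#' (default 0.118): the injectate spreads through the extracellular space of
#' a correspondingly larger tissue volume.
#'
#' @param injection_volume Injected volume (mL).
#' @param ecf_fraction Extracellular volume fraction of the tissue.
#' @return Effective depot volume (mL).
#' @examples
#' effective_depot_volume(1.6) # 13.6 mL for the 300 mg-equivalent dose
#' @export
effective_depot_volume <- function(injection_volume, ecf_fraction = 0.118) {
  stopifnot(injection_volume > 0, ecf_fraction > 0, ecf_fraction <= 1)
  injection_volume / ecf_fraction
}

#' Depot (injection site) physiology
#'
#' @param kp Tissue/plasma partition coefficient of the dosed species at the
#'   injection site.
#' @param fut Fraction unbound in the depot tissue, in (0, 1].
#' @param perfusion Site blood flow (mL/min/100 g tissue). Default 9.6, the
#'   geometric center of the 4.8-19.2 range swept in the sensitivity analysis.
#' @param ecf_fraction Extracellular volume fraction (default 0.118).
#' @param v_depot Effective depot volume (mL); derived from the injection
#'   volume via [effective_depot_volume()] when `NULL`.
#' @param site_ph Optional pH at the injection site. When set, the site
#'   solubility used for dissolution is [solubility_at_ph()] at this pH;
#'   when `NULL` (default) the drug's reference solubility is used directly.
#' @return An object of class `depot_physiology`.
#' @export
depot_physiology <- function(kp, fut, perfusion = 9.6, ecf_fraction = 0.118,
                             v_depot = NULL, site_ph = NULL) {
  stopifnot(
    "kp must be > 0" = kp > 0,
    "fut must be in (0, 1]" = fut > 0 && fut <= 1,
    "perfusion must be > 0" = perfusion > 0,
    "ecf_fraction must be in (0, 1)" = ecf_fraction > 0 && ecf_fraction < 1
  )
  if (!is.null(v_depot)) stopifnot(v_depot > 0)
  structure(
    list(kp = kp, fut = fut, perfusion = perfusion,
         ecf_fraction = ecf_fraction, v_depot = v_depot, site_ph = site_ph),
    class = "depot_physiology"
  )
}

#' Solver settings
#'
#' @param rtol Relative tolerance of the stiff integrator.
#' @param atol Absolute tolerance (mg).
#' @param dt Output grid spacing (h).
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-12, dt = 1) {
  stopifnot(rtol > 0, atol > 0, dt > 0)
  structure(list(rtol = rtol, atol = atol, dt = dt),
            class = "solver_settings")
}

default_horizon <- function(route) {
  switch(route,
         im_suspension = 2136,
         im_solution = 168,
         iv_infusion = 72)
}

#' Assemble a dosing scenario
#'
#' Bundles drug, dose, depot physiology, particle size distribution,
#' dissolution settings, ICL parameters and disposition into one validated
#' simulation scenario. Missing derived quantities are filled in: the
#' effective depot volume from the injection volume, the prodrug solid dose
#' from the parent-equivalent dose, the ICL surface area from the solid dose
#' ([depot_surface_area()]), and the ICL diffusivity/fraction unbound from the
#' dosed drug's logD(7.4).
#'
#' @param drug [drug_properties] of the administered species (the prodrug for
#'   a prodrug suspension).
#' @param dose A [formulation_dose].
#' @param disposition [disposition_params] of the parent drug.
#' @param parent [drug_properties] of the parent; required when
#'   `dose$is_prodrug`.
#' @param depot A [depot_physiology]; required for IM routes.
#' @param psd A [particle_size_distribution]; required for suspensions.
#' @param dissolution A [dissolution_settings]; suspensions only.
#' @param icl An [icl_params]; IM routes only. `NULL` disables the barrier.
#' @param horizon Simulation horizon (h). Defaults: 2136 (IM suspension),
#'   168 (IM solution), 72 (IV infusion).
#' @param solver A [solver_settings].
#' @return An object of class `lai_scenario`.
#' @export
lai_scenario <- function(drug, dose, disposition = disposition_params(),
                         parent = NULL, depot = NULL, psd = NULL,
                         dissolution = NULL, icl = NULL,
                         horizon = NULL, solver = solver_settings()) {
  stopifnot(inherits(drug, "drug_properties"),
            inherits(dose, "formulation_dose"),
            inherits(disposition, "disposition_params"),
            inherits(solver, "solver_settings"))
  route <- dose$route
  if (dose$is_prodrug) {
    if (is.null(parent)) {
      stop("a prodrug scenario needs `parent` drug properties", call. = FALSE)
    }
    stopifnot(inherits(parent, "drug_properties"))
  }
  if (route %in% c("im_solution", "im_suspension")) {
    if (is.null(depot)) stop("IM routes require `depot` physiology",
                             call. = FALSE)
    stopifnot(inherits(depot, "depot_physiology"))
    if (is.null(depot$v_depot)) {
      depot$v_depot <- effective_depot_volume(dose$injection_volume,
                                              depot$ecf_fraction)
    }
  }
  solid_dose <- NULL
  if (route == "im_suspension") {
    if (is.null(psd)) stop("a suspension requires `psd`", call. = FALSE)
    stopifnot(inherits(psd, "particle_size_distribution"))
    if (is.null(dissolution)) dissolution <- dissolution_settings()
    stopifnot(inherits(dissolution, "dissolution_settings"))
    if (is.null(dissolution$d_aq)) dissolution$d_aq <- aqueous_diffusivity(drug)
    if (is.null(dissolution$s_site)) {
      dissolution$s_site <- if (is.null(depot$site_ph)) drug$s_ref
                            else solubility_at_ph(drug, depot$site_ph)
    }
    solid_dose <- if (dose$is_prodrug) {
      prodrug_dose(dose$ar_equivalent_dose, drug$mw, parent$mw)
    } else {
      dose$ar_equivalent_dose
    }
  }
  if (!is.null(icl)) {
    stopifnot(inherits(icl, "icl_params"))
    if (route == "iv_infusion") {
      stop("the ICL barrier only applies to IM routes", call. = FALSE)
    }
    logd74 <- compute_logd(drug$logp, drug$pka, 7.4)
    if (is.null(icl$surface_area)) {
      ref_dose <- if (!is.null(solid_dose)) solid_dose
                  else dose$ar_equivalent_dose
      icl$surface_area <- depot_surface_area(ref_dose)
    }
    if (is.null(icl$d_icl)) icl$d_icl <- icl_diffusivity(logd74)
    if (is.null(icl$fu_icl)) icl$fu_icl <- icl_fraction_unbound(logd74)
  }
  if (is.null(horizon)) horizon <- default_horizon(route)
  stopifnot("horizon must be > 0" = horizon > 0)
  structure(
    list(drug = drug, parent = parent, disposition = disposition, dose = dose,
         depot = depot, psd = psd, dissolution = dissolution, icl = icl,
         horizon = horizon, solver = solver, solid_dose = solid_dose),
    class = "lai_scenario"
  )
}

#' @export
print.lai_scenario <- function(x, ...) {
  cat(sprintf("<lai_scenario> %s, %g mg parent-eq via %s\n",
              x$drug$name, x$dose$ar_equivalent_dose, x$dose$route))
  if (!is.null(x$depot)) {
    cat(sprintf("  depot: %.3g mL effective volume | Kp %.3g | fu,t %.3g\n",
                x$depot$v_depot, x$depot$kp, x$depot$fut))
  }
  if (!is.null(x$icl) && x$icl$enabled) {
    cat(sprintf("  ICL: A %.3g cm/h | B %.3g 1/h | lag %g h | kappa %.3g | SA %.3g cm2\n",
                x$icl$A, x$icl$B, x$icl$t_lag, x$icl$kappa,
                x$icl$surface_area))
  } else {
    cat("  ICL: disabled\n")
  }
  cat(sprintf("  horizon %g h, output every %g h\n", x$horizon, x$solver$dt))
  invisible(x)
}

# injection volumes (mL) of the marketed lauroxil strengths, by parent-eq mg
aristada_injection_volume <- function(dose_mg_eq) {
  vol <- c(`150` = 0.805, `300` = 1.6, `400` = 2.13)
  key <- as.character(dose_mg_eq)
  if (!key %in% names(vol)) {
    stop("no packaged injection volume for ", dose_mg_eq,
         " mg-eq; supply a formulation_dose directly", call. = FALSE)
  }
  unname(vol[key])
}

#' Ready-made scenario: aripiprazole lauroxil IM suspension
#'
#' Builds the gluteal IM suspension scenario for one of the marketed Aristada
#' strengths (150, 300 or 400 mg aripiprazole-equivalent), with the packaged
#' physicochemical properties, dose-specific injection volume, particle size
#' distribution, 65 um diffusion layer, depot physiology (Kp 4.28, tissue
#' fraction unbound 2.25e-8) and the ICL barrier.
#'
#' @param dose_mg_eq Parent-equivalent dose: 150, 300 or 400 mg.
#' @param icl Logical; `FALSE` simulates without the inflammatory cell layer.
#' @param icl_kinetics Optional [icl_params] overriding the defaults (used to
#'   plug calibrated kinetics back in; the surface area is re-derived for the
#'   dose).
#' @param n_bins Number of particle bins.
#' @param horizon Simulation horizon (h).
#' @param solver A [solver_settings].
#' @return A [lai_scenario].
#' @export
scenario_aristada <- function(dose_mg_eq = 400, icl = TRUE, icl_kinetics = NULL,
                              n_bins = 20, horizon = 2136,
                              solver = solver_settings()) {
  arl <- drug_aripiprazole_lauroxil()
  ar <- drug_aripiprazole()
  dose <- formulation_dose(dose_mg_eq, route = "im_suspension",
                           is_prodrug = TRUE,
                           injection_volume = aristada_injection_volume(dose_mg_eq))
  icl_block <- if (!icl) NULL
               else if (!is.null(icl_kinetics)) {
                 k <- icl_kinetics
                 icl_params(A = k$A, B = k$B, t_lag = k$t_lag,
                            kappa = k$kappa, enabled = k$enabled)
               } else icl_params()
  lai_scenario(
    drug = arl, parent = ar, dose = dose,
    disposition = disposition_params(),
    depot = depot_physiology(kp = 4.28, fut = 2.25e-8),
    psd = particle_size_distribution(n_bins = n_bins),
    dissolution = dissolution_settings(),
    icl = icl_block,
    horizon = horizon, solver = solver
  )
}

#' Ready-made scenario: aripiprazole IM solution
#'
#' 5 mg aripiprazole dosed as an IM solution (0.67 mL gluteal injection,
#' effective depot volume 5.7 mL, Kp 1.84, tissue fraction unbound 0.0012).
#' With `missed_injection = TRUE` the partitioning is blended between muscle
#' and adipose values ([blend_missed_injection()]), the adjustment used to
#' probe injections that partly miss the muscle.
#'
#' @param dose_mg Dose (mg).
#' @param missed_injection Logical.
#' @param horizon Simulation horizon (h).
#' @param solver A [solver_settings].
#' @return A [lai_scenario].
#' @export
scenario_ar_im_solution <- function(dose_mg = 5, missed_injection = FALSE,
                                    horizon = 168,
                                    solver = solver_settings()) {
  part <- if (missed_injection) {
    blend_missed_injection(1.84, 9.84, 1.20e-3, 2.24e-4)
  } else {
    list(kp = 1.84, fut = 1.20e-3)
  }
  lai_scenario(
    drug = drug_aripiprazole(),
    dose = formulation_dose(dose_mg, route = "im_solution",
                            injection_volume = 0.67),
    disposition = disposition_params(),
    depot = depot_physiology(kp = part$kp, fut = part$fut),
    horizon = horizon, solver = solver
  )
}

#' Ready-made scenario: aripiprazole IV infusion
#'
#' @param dose_mg Dose (mg), default 2 mg.
#' @param duration_h Infusion duration (h). The study duration is not
#'   published; 1 h is the package default.
#' @param horizon Simulation horizon (h).
#' @param solver A [solver_settings].
#' @return A [lai_scenario].
#' @export
scenario_ar_iv_infusion <- function(dose_mg = 2, duration_h = 1, horizon = 72,
                                    solver = solver_settings()) {
  lai_scenario(
    drug = drug_aripiprazole(),
    dose = formulation_dose(dose_mg, route = "iv_infusion",
                            infusion_duration = duration_h),
    disposition = disposition_params(),
    horizon = horizon, solver = solver
  )
}
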