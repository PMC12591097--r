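#' Observed PK metrics for the packaged scenarios
#'
#' Observed Cmax, AUC0-t and Tmax after IM administration of the aripiprazole
#' lauroxil suspension (150, 300 and 400 mg aripiprazole-equivalent), compiled
#' from published clinical study summaries and shipped as a plain-text
#' fixture.
#'
#' @return A data frame with columns `scenario`, `dose_mg_eq`, `cmax_ng_ml`,
#'   `auc0t_ng_h_ml`, `tmax_h`, `source`.
#' @export
observed_pk_metrics <- function() {
  path <- system.file("extdata", "observed_pk_metrics.csv",
                      package = "icldepot", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# scenario JSON schema: top-level blocks and their unit-suffixed keys
scenario_schema <- list(
  drug = c("name", "mw_g_mol", "logp", "pka", "rbp", "fup",
           "s_ref_mg_ml", "ph_ref", "solubility_factor", "d_aq_cm2_s"),
  parent = c("name", "mw_g_mol", "logp", "pka", "rbp", "fup",
             "s_ref_mg_ml", "ph_ref", "solubility_factor", "d_aq_cm2_s"),
  dose = c("ar_equivalent_dose_mg", "route", "is_prodrug",
           "injection_volume_ml", "infusion_duration_h"),
  disposition = c("vc_l_kg", "clh_l_h_kg", "k12_1_h", "k21_1_h",
                  "k13_1_h", "k31_1_h", "body_weight_kg"),
  depot = c("kp", "fut", "perfusion_ml_min_100g", "ecf_fraction",
            "v_depot_ml", "site_ph"),
  psd = c("mean_radius_um", "sd_radius_um", "n_bins", "density_g_cm3",
          "dv10_um", "dv50_um", "dv90_um"),
  dissolution = c("h_uwl_um", "h_rule", "d_aq_cm2_s", "s_site_mg_ml"),
  icl = c("A_cm_h", "B_1_h", "t_lag_h", "surface_area_cm2", "d_icl_cm2_s",
          "fu_icl", "kappa", "enabled"),
  horizon_h = NULL,
  solver = c("rtol", "atol", "dt_h")
)

check_keys <- function(given, allowed, where) {
  bad <- setdiff(given, allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                 paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
}

parse_drug_block <- function(d, where) {
  check_keys(names(d), scenario_schema$drug, where)
  req <- c("name", "mw_g_mol", "logp", "pka", "rbp", "fup", "s_ref_mg_ml")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required key(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  drug_properties(
    name = d$name, mw = d$mw_g_mol, logp = d$logp, pka = d$pka,
    rbp = d$rbp, fup = d$fup, s_ref = d$s_ref_mg_ml,
    ph_ref = d$ph_ref %||% 7,
    solubility_factor = d$solubility_factor %||% 1,
    d_aq_override = d$d_aq_cm2_s
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario from a JSON configuration file
#'
#' Reads a strict, unit-annotated JSON description of a dosing scenario and
#' returns a validated [lai_scenario]. Unknown keys raise an error naming the
#' offending key; unit suffixes in the key names (`_mg`, `_ml`, `_um`, `_h`,
#' `_g_mol`, ...) make silent unit mismatches hard. A bare name (no path
#' separator, no `.json` extension) is resolved against the packaged fixture
#' scenarios: `"arl_im_150"`, `"arl_im_300"`, `"arl_im_400"` (each also with
#' suffix `"_no_icl"`), `"ar_im_solution_5mg"`, `"ar_iv_2mg"`.
#'
#' @param path Path to a JSON file, or a packaged fixture name.
#' @return A [lai_scenario].
#' @export
load_scenario <- function(path) {
  if (!grepl("[/\\\\]", path) && !grepl("\\.json$", path)) {
    pkg_path <- system.file("extdata", "scenarios", paste0(path, ".json"),
                            package = "icldepot")
    if (pkg_path == "") {
      stop("no packaged scenario named '", path, "'", call. = FALSE)
    }
    path <- pkg_path
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(cfg) == 0) {
    stop("empty scenario file; required blocks: drug, dose (plus depot for ",
         "IM routes, psd for suspensions)", call. = FALSE)
  }
  check_keys(names(cfg), names(scenario_schema), "scenario")
  for (req in c("drug", "dose")) {
    if (is.null(cfg[[req]])) {
      stop("scenario is missing the required '", req, "' block",
           call. = FALSE)
    }
  }
  drug <- parse_drug_block(cfg$drug, "drug")
  parent <- if (!is.null(cfg$parent)) parse_drug_block(cfg$parent, "parent")
  d <- cfg$dose
  check_keys(names(d), scenario_schema$dose, "dose")
  dose <- formulation_dose(
    ar_equivalent_dose = d$ar_equivalent_dose_mg,
    route = d$route,
    is_prodrug = d$is_prodrug %||% FALSE,
    injection_volume = d$injection_volume_ml,
    infusion_duration = d$infusion_duration_h
  )
  disposition <- if (!is.null(cfg$disposition)) {
    p <- cfg$disposition
    check_keys(names(p), scenario_schema$disposition, "disposition")
    disposition_params(
      vc = p$vc_l_kg %||% 1.5825, clh = p$clh_l_h_kg %||% 0.03028,
      k12 = p$k12_1_h %||% 0.22832, k21 = p$k21_1_h %||% 0.17345,
      k13 = p$k13_1_h %||% 0.01108, k31 = p$k31_1_h %||% 0.001911,
      body_weight = p$body_weight_kg %||% 70
    )
  } else disposition_params()
  depot <- if (!is.null(cfg$depot)) {
    p <- cfg$depot
    check_keys(names(p), scenario_schema$depot, "depot")
    depot_physiology(
      kp = p$kp, fut = p$fut,
      perfusion = p$perfusion_ml_min_100g %||% 9.6,
      ecf_fraction = p$ecf_fraction %||% 0.118,
      v_depot = p$v_depot_ml, site_ph = p$site_ph
    )
  }
  psd <- if (!is.null(cfg$psd)) {
    p <- cfg$psd
    check_keys(names(p), scenario_schema$psd, "psd")
    particle_size_distribution(
      mean_radius = p$mean_radius_um %||% 14.18,
      sd_radius = p$sd_radius_um %||% 7.4,
      n_bins = p$n_bins %||% 20,
      density = p$density_g_cm3 %||% 1.774,
      dv10 = p$dv10_um, dv50 = p$dv50_um, dv90 = p$dv90_um
    )
  }
  dissolution <- if (!is.null(cfg$dissolution)) {
    p <- cfg$dissolution
    check_keys(names(p), scenario_schema$dissolution, "dissolution")
    dissolution_settings(
      h_uwl = p$h_uwl_um %||% 65, h_rule = p$h_rule %||% "constant",
      d_aq = p$d_aq_cm2_s, s_site = p$s_site_mg_ml
    )
  }
  icl <- if (!is.null(cfg$icl)) {
    p <- cfg$icl
    check_keys(names(p), scenario_schema$icl, "icl")
    icl_params(
      A = p$A_cm_h %||% 2.09e-6, B = p$B_1_h %||% 0.012,
      t_lag = p$t_lag_h %||% 0, surface_area = p$surface_area_cm2,
      d_icl = p$d_icl_cm2_s, fu_icl = p$fu_icl,
      kappa = p$kappa %||% 1, enabled = p$enabled %||% TRUE
    )
  }
  solver <- if (!is.null(cfg$solver)) {
    p <- cfg$solver
    check_keys(names(p), scenario_schema$solver, "solver")
    solver_settings(rtol = p$rtol %||% 1e-8, atol = p$atol %||% 1e-12,
                    dt = p$dt_h %||% 1)
  } else solver_settings()
  lai_scenario(drug = drug, dose = dose, disposition = disposition,
               parent = parent, depot = depot, psd = psd,
               dissolution = dissolution, icl = icl,
               horizon = cfg$horizon_h, solver = solver)
}

#' Write a simulated profile to CSV
#'
#' Writes the profile columns (`time_h`, `cp_ng_per_mL`, `icl_thickness_um`,
#' `solid_mg`, `dissolved_mg`, `absorbed_mg`) in full double precision so a
#' write/read round trip preserves values to better than 1e-12 relative.
#'
#' @param result A `lai_simulation` (or a profile data frame).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(result, path) {
  df <- as.data.frame(result)
  txt <- vapply(df, function(col) sprintf("%.15e", col), character(nrow(df)))
  if (nrow(df) == 1) txt <- matrix(txt, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    writeLines(apply(txt, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a profile CSV written by [write_profile()]
#'
#' @param path File path.
#' @return A profile data frame.
#' @export
read_profile <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
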