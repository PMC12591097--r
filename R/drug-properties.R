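#' Physicochemical properties of a drug
#'
#' Container for the physicochemical inputs the depot model needs. Both
#' compounds shipped with the package (aripiprazole and its lauroxil prodrug)
#' are monoprotic bases, and all ionization arithmetic in the package assumes
#' that convention.
#'
#' @param name Compound name.
#' @param mw Molecular mass (g/mol).
#' @param logp Octanol/water log partition coefficient (dimensionless).
#' @param pka Basic pKa (monoprotic base).
#' @param rbp Blood-to-plasma concentration ratio (dimensionless).
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param s_ref Aqueous solubility (mg/mL) measured at `ph_ref`.
#' @param ph_ref pH at which `s_ref` was measured.
#' @param solubility_factor Maximum fold-increase of solubility over the
#'   intrinsic (neutral-species) solubility; caps the ionization boost.
#' @param d_aq_override Optional aqueous diffusion coefficient (cm^2/s). When
#'   `NULL`, [aqueous_diffusivity()] falls back to a molecular-weight
#'   correlation.
#'
#' @return An object of class `drug_properties`.
#' @seealso [drug_aripiprazole()], [drug_aripiprazole_lauroxil()]
#' @export
drug_properties <- function(name, mw, logp, pka, rbp, fup,
                            s_ref, ph_ref = 7, solubility_factor = 1,
                            d_aq_override = NULL) {
  stopifnot(
    "mw must be > 0" = is.numeric(mw) && mw > 0,
    "fup must be in (0, 1]" = is.numeric(fup) && fup > 0 && fup <= 1,
    "rbp must be > 0" = is.numeric(rbp) && rbp > 0,
    "s_ref must be > 0" = is.numeric(s_ref) && s_ref > 0,
    "solubility_factor must be >= 1" =
      is.numeric(solubility_factor) && solubility_factor >= 1
  )
  if (!is.null(d_aq_override)) stopifnot(d_aq_override > 0)
  structure(
    list(name = name, mw = mw, logp = logp, pka = pka, rbp = rbp, fup = fup,
         s_ref = s_ref, ph_ref = ph_ref, solubility_factor = solubility_factor,
         d_aq_override = d_aq_override),
    class = "drug_properties"
  )
}

#' @export
print.drug_properties <- function(x, ...) {
  cat(sprintf("<drug_properties> %s\n", x$name))
  cat(sprintf("  MW %.2f g/mol | logP %.2f | pKa %.2f (base)\n",
              x$mw, x$logp, x$pka))
  cat(sprintf("  Rbp %.2f | fu,p %.4g | S %.3g mg/mL @ pH %.1f (factor %.4g)\n",
              x$rbp, x$fup, x$s_ref, x$ph_ref, x$solubility_factor))
  invisible(x)
}

#' Aripiprazole (parent drug)
#'
#' Physicochemical properties of aripiprazole (AR): MW 448.38 g/mol, logP 5.2,
#' basic pKa 7.6, Rbp 0.61, fu,p 3.17%, aqueous solubility 0.004 mg/mL at
#' pH 7 with a solubility factor of 660.92.
#'
#' @return A [drug_properties] object.
#' @export
drug_aripiprazole <- function() {
  drug_properties("aripiprazole", mw = 448.38, logp = 5.2, pka = 7.6,
                  rbp = 0.61, fup = 0.0317, s_ref = 0.004, ph_ref = 7,
                  solubility_factor = 660.92)
}

#' Aripiprazole lauroxil (prodrug)
#'
#' Physicochemical properties of aripiprazole lauroxil (AR-L), the
#' N-lauroyloxymethyl prodrug of aripiprazole formulated as the Aristada
#' long-acting injectable suspension: MW 660.73 g/mol, logP 9.8, basic pKa
#' 7.47, Rbp 0.64, fu,p 0.2%, aqueous solubility 3e-4 mg/mL at pH 7 with a
#' solubility factor of 10200.
#'
#' @return A [drug_properties] object.
#' @export
drug_aripiprazole_lauroxil <- function() {
  drug_properties("aripiprazole lauroxil", mw = 660.73, logp = 9.8,
                  pka = 7.47, rbp = 0.64, fup = 0.002, s_ref = 3e-4,
                  ph_ref = 7, solubility_factor = 10200)
}

#' Distribution coefficient of a monoprotic base
#'
#' `logD(pH) = logP - log10(1 + 10^(pKa - pH))` (Henderson-Hasselbalch).
#' Strictly increasing in pH and bounded above by `logp`.
#'
#' @param logp Octanol/water log partition coefficient.
#' @param pka Basic pKa.
#' @param ph pH at which to evaluate.
#' @return logD (dimensionless), vectorized over `ph`.
#' @examples
#' compute_logd(9.8, 7.47, 7.4) # 9.4626 for aripiprazole lauroxil
#' @export
compute_logd <- function(logp, pka, ph) {
  logp - log10(1 + 10^(pka - ph))
}

#' pH-dependent aqueous solubility of a monoprotic base
#'
#' Infers the intrinsic (neutral-species) solubility from the reference
#' measurement, `S_int = s_ref / (1 + 10^(pKa - ph_ref))`, then scales it with
#' ionization: `S(pH) = S_int * (1 + 10^(pKa - pH))`, capped at
#' `S_int * solubility_factor`. Monotone non-increasing in pH and never below
#' the intrinsic solubility.
#'
#' @param drug A [drug_properties] object.
#' @param ph pH at which to evaluate (vectorized).
#' @return Solubility in mg/mL.
#' @export
solubility_at_ph <- function(drug, ph) {
  stopifnot(inherits(drug, "drug_properties"))
  s_int <- drug$s_ref / (1 + 10^(drug$pka - drug$ph_ref))
  pmin(s_int * (1 + 10^(drug$pka - ph)), s_int * drug$solubility_factor)
}

#' Aqueous diffusion coefficient from molecular weight
#'
#' Power-law estimate `D_aq = 9.9e-5 * MW^(-0.453)` (cm^2/s), a standard
#' molecular-weight correlation for small organic molecules in water at 37 C.
#'
#' @param mw Molecular mass (g/mol).
#' @return Diffusion coefficient (cm^2/s).
#' @export
estimate_aqueous_diffusivity <- function(mw) {
  stopifnot(all(mw > 0))
  9.9e-5 * mw^(-0.453)
}

#' Aqueous diffusivity for a drug, honoring an override
#'
#' @param drug A [drug_properties] object.
#' @return `drug$d_aq_override` when supplied, otherwise
#'   [estimate_aqueous_diffusivity()] of the drug's molecular weight.
#' @export
aqueous_diffusivity <- function(drug) {
  stopifnot(inherits(drug, "drug_properties"))
  if (!is.null(drug$d_aq_override)) drug$d_aq_override
  else estimate_aqueous_diffusivity(drug$mw)
}

#' Blend muscle and adipose partitioning for a missed injection
#'
#' A gluteal injection may deposit part of the dose in adipose rather than
#' muscle tissue. This helper returns the arithmetic midpoints of the
#' tissue/plasma partition coefficients and tissue unbound fractions of the
#' two tissues, the adjustment used to test the missed-injection hypothesis.
#'
#' @param kp_muscle,kp_adipose Tissue/plasma partition coefficients.
#' @param fut_muscle,fut_adipose Tissue fractions unbound.
#' @return A list with elements `kp` and `fut` (midpoints).
#' @examples
#' blend_missed_injection(1.84, 9.84, 1.20e-3, 2.24e-4) # kp 5.84, fut 7.12e-4
#' @export
blend_missed_injection <- function(kp_muscle, kp_adipose,
                                   fut_muscle, fut_adipose) {
  stopifnot(kp_muscle > 0, kp_adipose > 0, fut_muscle > 0, fut_adipose > 0)
  list(kp = (kp_muscle + kp_adipose) / 2,
       fut = (fut_muscle + fut_adipose) / 2)
}

#' Convert a parent-equivalent dose to prodrug mass
#'
#' Doses of prodrug suspensions are labelled in parent ("AR-equivalent")
#' milligrams; the injected solid is the prodrug. Conversion is molar:
#' `prodrug mg = parent-equivalent mg * MW_prodrug / MW_parent`. The inverse
#' conversion swaps the two molecular weights.
#'
#' @param ar_equivalent Parent-equivalent dose (mg).
#' @param mw_prodrug,mw_parent Molecular masses (g/mol).
#' @return Prodrug dose (mg).
#' @examples
#' prodrug_dose(300, 660.73, 448.38) # 442.1 mg lauroxil in the 300 mg-eq vial
#' @export
prodrug_dose <- function(ar_equivalent, mw_prodrug, mw_parent) {
  stopifnot(all(ar_equivalent > 0), mw_prodrug > 0, mw_parent > 0)
  ar_equivalent * mw_prodrug / mw_parent
}
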