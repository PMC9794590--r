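#' Define a compound
#'
#' Physicochemical and clearance parameters of a drug. Clearances are plasma
#' clearances in L/min/kg body weight; `kidney_plasma_clearance` may be a
#' named vector with per-species values (`rat`, `human`). `fu_reference`
#' records the fraction unbound at which the clearance parameters were
#' estimated; elimination scales proportionally with the effective unbound
#' fraction relative to this reference (restrictive-clearance assumption).
#'
#' @param name Compound name.
#' @param mwt Molecular weight, g/mol.
#' @param logp Octanol:water log partition coefficient.
#' @param acidic_pka First acidic pKa (NA for neutral compounds).
#' @param solubility_ph7 Aqueous solubility at pH 7, g/L.
#' @param fu Fraction unbound in plasma, (0, 1].
#' @param intestinal_permeability Transcellular intestinal permeability,
#'   dm/min.
#' @param organ_permeability Organ permeability, cm/s (used only by the
#'   optional permeability-limited distribution mode).
#' @param kidney_plasma_clearance,biliary_plasma_clearance,
#'   residual_plasma_clearance,metabolic_clearance Plasma clearances,
#'   L/min/kg.
#' @param fu_reference Reference fraction unbound for clearance scaling;
#'   defaults to `fu`.
#' @return A `pbpk_compound` list.
#' @export
compound <- function(name, mwt, logp, acidic_pka = NA_real_,
                     solubility_ph7 = NA_real_, fu,
                     intestinal_permeability, organ_permeability = NA_real_,
                     kidney_plasma_clearance = 0,
                     biliary_plasma_clearance = 0,
                     residual_plasma_clearance = 0,
                     metabolic_clearance = 0,
                     fu_reference = fu) {
  assert_that(is_number(mwt) && mwt > 0, "`mwt` must be positive")
  assert_that(is_number(fu) && fu > 0 && fu <= 1, "`fu` must be in (0, 1]")
  cls <- c(kidney_plasma_clearance, biliary_plasma_clearance,
           residual_plasma_clearance, metabolic_clearance)
  assert_that(all(cls >= 0), "clearances must be non-negative")
  structure(
    list(name = name, mwt = mwt, logp = logp, acidic_pka = acidic_pka,
         solubility_ph7 = solubility_ph7, fu = fu,
         fu_reference = fu_reference,
         intestinal_permeability = intestinal_permeability,
         organ_permeability = organ_permeability,
         kidney_plasma_clearance = kidney_plasma_clearance,
         biliary_plasma_clearance = biliary_plasma_clearance,
         residual_plasma_clearance = residual_plasma_clearance,
         metabolic_clearance = metabolic_clearance),
    class = "pbpk_compound"
  )
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat(sprintf("<pbpk_compound> %s (Mwt %.3f, logP %.3f, fu %.4f)\n",
              x$name, x$mwt, x$logp, x$fu))
  invisible(x)
}

#' Define a formulation
#'
#' Oral formulations dissolve following a Weibull profile parameterized by
#' the 50%-dissolved time and a shape exponent; intravenous solutions ignore
#' both.
#'
#' @param kind `"solution_iv"`, `"suspension"` or `"capsule"`.
#' @param t50 Time to 50% dissolved, minutes (oral kinds).
#' @param shape Dimensionless Weibull shape (oral kinds).
#' @return A `pbpk_formulation` list.
#' @export
formulation <- function(kind = c("suspension", "capsule", "solution_iv"),
                        t50 = NA_real_, shape = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "solution_iv") {
    assert_that(is_number(t50) && t50 > 0, "`t50` must be positive (min)")
    assert_that(is_number(shape) && shape > 0, "`shape` must be positive")
  }
  structure(list(kind = kind, t50 = t50, shape = shape),
            class = "pbpk_formulation")
}

#' Schaftoside model parameters
#'
#' The packaged drug and formulation parameter set for schaftoside:
#' molecular weight 596.494 g/mol, logP -2.427, acidic pKa 6.35, solubility
#' 0.02 g/L, fraction unbound 0.2665, transcellular intestinal permeability
#' 1.08e-4 dm/min, organ permeability 2.98e-6 cm/s; kidney plasma clearance
#' 2.57e-3 (rat) and 1.24e-3 (human) L/min/kg; rat suspension (t50 0.92 min,
#' shape 1.08e-3) and human capsule (t50 8.16 min, shape 3.74e-4)
#' dissolution. Hepatic metabolic clearance is zero: schaftoside is not
#' metabolized by rat or human liver microsomes and is excreted unchanged.
#'
#' @return A list with elements `compound`, `formulation_rat` and
#'   `formulation_human`.
#' @examples
#' schaftoside_defaults()$compound$fu  # 0.2665
#' @export
schaftoside_defaults <- function() {
  list(
    compound = compound(
      name = "schaftoside",
      mwt = 596.494,
      logp = -2.427,
      acidic_pka = 6.35,
      solubility_ph7 = 0.02,
      fu = 0.2665,
      intestinal_permeability = 1.08e-4,
      organ_permeability = 2.98e-6,
      kidney_plasma_clearance = c(rat = 2.57e-3, human = 1.24e-3),
      biliary_plasma_clearance = 0,
      residual_plasma_clearance = 0,
      metabolic_clearance = 0
    ),
    formulation_rat = formulation("suspension", t50 = 0.92, shape = 1.08e-3),
    formulation_human = formulation("capsule", t50 = 8.16, shape = 3.74e-4)
  )
}

species_kidney_clearance <- function(cmp, species) {
  cl <- cmp$kidney_plasma_clearance
  if (length(cl) > 1L || !is.null(names(cl))) {
    assert_that(species %in% names(cl),
                sprintf("no kidney clearance for species '%s'", species))
    unname(cl[[species]])
  } else {
    unname(cl)
  }
}

#' Weibull dissolution fraction
#'
#' Fraction dissolved at time `t` for an oral formulation:
#' `1 - exp(-ln 2 * (t / t50)^shape)`. Non-decreasing in `t`, equal to 0 at
#' `t = 0` and exactly 0.5 at `t = t50`.
#'
#' @param f A `pbpk_formulation` (oral).
#' @param t Time since dosing, minutes (vectorised, `t >= 0`).
#' @return Fraction dissolved in \[0, 1\].
#' @examples
#' f <- formulation("capsule", t50 = 8.16, shape = 3.74e-4)
#' dissolution_fraction(f, 8.16)  # 0.5
#' @export
dissolution_fraction <- function(f, t) {
  assert_that(inherits(f, "pbpk_formulation"), "not a `pbpk_formulation`")
  assert_that(f$kind != "solution_iv",
              "intravenous solutions have no dissolution profile")
  assert_that(all(t >= 0), "`t` must be non-negative")
  1 - exp(-log(2) * (t / f$t50)^f$shape)
}

# Weibull dissolution hazard (per minute) at time t (min) since dosing.
dissolution_hazard <- function(f, t) {
  log(2) * (f$shape / f$t50) * (t / f$t50)^(f$shape - 1)
}

henderson_hasselbalch_neutral <- function(pka, ph) {
  if (is.na(pka)) return(1)
  1 / (1 + 10^(ph - pka))
}

#' Tissue:plasma partition coefficients
#'
#' Computes per-organ partition coefficients from tissue composition using a
#' documented tissue-composition method: the compound partitions into tissue
#' water, tissue lipid (scaled by the ionization-corrected octanol:water
#' partition coefficient of a monoprotic acid, Henderson-Hasselbalch at
#' plasma pH 7.4 and tissue pH 7.0) and, weakly, tissue protein; the plasma
#' reference phase is plasma water, with plasma protein binding carried by
#' the fraction unbound. A single global `calibration_scalar` rescales all
#' Kp values (fitted to the rat intravenous profile by the calibration step).
#'
#' The blood:plasma concentration ratio is computed from haematocrit and an
#' analogous erythrocyte partition.
#'
#' @param cmp A `pbpk_compound`.
#' @param ind A `pbpk_individual` supplying tissue composition; the
#'   individual's `fu_multiplier` scales the effective unbound fraction.
#' @param calibration_scalar Positive global Kp multiplier.
#' @return A tibble (`name`, `kp`) for the non-blood organs, with the
#'   blood:plasma ratio in attribute `"blood_plasma_ratio"`.
#' @export
partition_coefficients <- function(cmp, ind, calibration_scalar = 1) {
  assert_that(inherits(cmp, "pbpk_compound"), "not a `pbpk_compound`")
  validate_individual(ind)
  assert_that(is_number(calibration_scalar) && calibration_scalar > 0,
              "`calibration_scalar` must be > 0")
  o <- ind$organs[!ind$organs$name %in% c("arterial_blood", "venous_blood"), ]
  missing_comp <- o$name[is.na(o$water_fraction) | is.na(o$lipid_fraction) |
                           is.na(o$protein_fraction)]
  assert_that(length(missing_comp) == 0L,
              paste0("missing tissue composition for organ(s): ",
                     paste(missing_comp, collapse = ", ")))
  p <- 10^cmp$logp
  fu_eff <- min(cmp$fu * ind$fu_multiplier, 1)
  d_tissue <- p * henderson_hasselbalch_neutral(cmp$acidic_pka, 7.0)
  kp <- calibration_scalar * fu_eff *
    (o$water_fraction + d_tissue * o$lipid_fraction +
       0.5 * o$protein_fraction) / .plasma_water_fraction
  k_ery <- fu_eff *
    (.rbc_water + p * henderson_hasselbalch_neutral(cmp$acidic_pka, 7.2) *
       .rbc_lipid) / .plasma_water_fraction
  bp <- (1 - .haematocrit) + .haematocrit * k_ery
  out <- tibble(name = o$name, kp = kp)
  attr(out, "blood_plasma_ratio") <- bp
  out
}
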