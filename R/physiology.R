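#' Build a reference individual
#'
#' Constructs a rat or human individual whose organ volumes and blood flows
#' are the packaged reference tables rescaled linearly to the requested body
#' weight. For humans the documented ageing adjustments (cardiac output,
#' GFR, muscle/adipose shift) and sex adjustments are applied on top.
#'
#' @param species `"rat"` or `"human"`.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param weight Body weight in kg; must be positive.
#' @param height Height in cm (human only, informational).
#'
#' @return An object of class `pbpk_individual`: a list with demographic
#'   fields, the organ tibble (`name`, `volume` L, `blood_flow` L/h,
#'   composition fractions), GFR (mL/min/1.73 m^2 for human, mL/min for
#'   rat), gastrointestinal transit times (h) and the multipliers used by
#'   disease scaling and population sampling.
#' @examples
#' ind <- build_reference_individual("human", 28, "male", 56.35, 162.1)
#' ind$gfr
#' @export
build_reference_individual <- function(species = c("human", "rat"),
                                       age,
                                       sex = c("male", "female"),
                                       weight,
                                       height = NA_real_) {
  species <- match.arg(species)
  sex <- match.arg(sex)
  assert_that(is_number(weight) && weight > 0,
              "`weight` must be a positive number (kg)")
  assert_that(is_number(age) && age >= 0, "`age` must be non-negative (years)")

  scale <- weight / .ref_body_weight[[species]]
  organs <- .organ_reference(species)
  co <- .ref_cardiac_output[[species]] * scale
  organs$volume <- organs$volume * scale

  gfr <- .gfr_reference[[species]]
  if (species == "rat") gfr <- gfr * scale

  if (species == "human") {
    co <- co * (1 - .age_co_decline_per_year * max(0, age - 30))
    gfr <- max(gfr - .age_gfr_decline_per_year * max(0, age - 40), 5)
    muscle_f <- 1 - .age_muscle_decline_per_year * max(0, age - 30)
    if (sex == "female") muscle_f <- muscle_f * .female_muscle_factor
    adipose_f <- if (sex == "female") .female_adipose_factor else 1
    i_mus <- organs$name == "muscle"
    i_adi <- organs$name == "adipose"
    lost <- organs$volume[i_mus] * (1 - muscle_f)
    organs$volume[i_mus] <- organs$volume[i_mus] * muscle_f
    organs$volume[i_adi] <- organs$volume[i_adi] * adipose_f + lost
  }

  organs$blood_flow <- ifelse(is.na(organs$flow_fraction), 0,
                              organs$flow_fraction * co)
  organs$blood_flow[organs$name == "lung"] <- co
  organs$flow_fraction <- NULL
  organs <- left_join(organs, .organ_composition, by = "name")

  gi <- .gi_reference[[species]]
  ind <- structure(
    list(
      species = species,
      age = age,
      sex = sex,
      weight = weight,
      height = height,
      organs = as_tibble(organs),
      cardiac_output = co,
      gfr = gfr,
      fu_multiplier = 1,
      clearance_multiplier = 1,
      gastric_emptying_time = gi$gastric_emptying_time,
      small_intestinal_transit_time = gi$small_intestinal_transit_time,
      large_intestinal_transit_time = gi$large_intestinal_transit_time,
      si_lumen_volume = gi$si_lumen_volume * scale,
      absorption_area_m2 = gi$absorption_area_m2 * scale,
      ckd_stage = "healthy"
    ),
    class = "pbpk_individual"
  )
  validate_individual(ind)
  ind
}

#' Validate an individual's physiological invariants
#'
#' Checks positivity of volumes and multipliers, composition fraction sums,
#' and that the non-lung organ blood flows sum to cardiac output.
#'
#' @param ind A `pbpk_individual`.
#' @return The individual, invisibly; errors describe the violated invariant.
#' @export
validate_individual <- function(ind) {
  assert_that(inherits(ind, "pbpk_individual"), "not a `pbpk_individual`")
  o <- ind$organs
  assert_that(all(o$volume > 0), "organ volumes must be positive")
  assert_that(all(o$blood_flow >= 0), "organ blood flows must be non-negative")
  comp <- o$water_fraction + o$lipid_fraction + o$protein_fraction
  assert_that(all(o$water_fraction >= 0 & o$water_fraction <= 1) &&
                all(o$lipid_fraction >= 0 & o$lipid_fraction <= 1) &&
                all(o$protein_fraction >= 0 & o$protein_fraction <= 1) &&
                all(comp <= 1 + 1e-12),
              "tissue composition fractions must lie in [0,1] and sum to <= 1")
  perf <- o$name != "lung" & !o$name %in% c("arterial_blood", "venous_blood")
  qsum <- sum(o$blood_flow[perf])
  assert_that(abs(qsum - ind$cardiac_output) <= 1e-6 * ind$cardiac_output,
              "non-lung organ blood flows must sum to cardiac output")
  assert_that(ind$weight > 0 && ind$fu_multiplier > 0 &&
                ind$clearance_multiplier > 0 && ind$gfr >= 0,
              "weight and multipliers must be positive; GFR non-negative")
  invisible(ind)
}

#' @export
print.pbpk_individual <- function(x, ...) {
  cat(sprintf("<pbpk_individual> %s, %s, %.3g kg, age %.3g y, %s\n",
              x$species, x$sex, x$weight, x$age, x$ckd_stage))
  cat(sprintf("  cardiac output %.3g L/h, GFR %.4g %s\n", x$cardiac_output,
              x$gfr,
              if (x$species == "human") "mL/min/1.73m2" else "mL/min"))
  invisible(x)
}

#' Chronic kidney disease stage scaling factors
#'
#' The packaged disease table: per CKD stage, the target GFR and the
#' fraction-of-healthy multipliers for kidney volume, renal perfusion,
#' fraction unbound in plasma, gastric emptying time and intestinal transit
#' times.
#'
#' @param stage `"CKD3"`, `"CKD4"` or `"CKD5"`; omit for the full table.
#' @return A tibble (one row per stage), or a one-row tibble when `stage`
#'   is given.
#' @examples
#' ckd_scaling("CKD5")$fu_fraction  # 1.55
#' @export
ckd_scaling <- function(stage = NULL) {
  tbl <- tribble(
    ~stage, ~gfr_target, ~kidney_volume_fraction, ~renal_perfusion_fraction,
    ~fu_fraction, ~gastric_emptying_fraction, ~small_intestinal_transit_fraction,
    ~large_intestinal_transit_fraction,
    "CKD3", 60, 0.81, 0.55, 1.07, 1.00, 1.00, 1.00,
    "CKD4", 30, 0.61, 0.36, 1.16, 1.60, 1.40, 1.00,
    "CKD5", 15, 0.51, 0.29, 1.55, 1.60, 1.40, 1.00
  )
  if (is.null(stage)) return(tbl)
  stage <- match.arg(stage, tbl$stage)
  tbl[tbl$stage == stage, ]
}

#' Apply renal-impairment scaling to a healthy human individual
#'
#' Sets GFR to the stage target and multiplies kidney volume, kidney blood
#' flow, fraction-unbound multiplier, gastric emptying time and intestinal
#' transit times by the stage fractions. Cardiac output is recomputed from
#' the adjusted organ flows. Drug parameters are untouched; disease enters
#' the model only through physiology.
#'
#' @param ind A healthy `pbpk_individual` (human).
#' @param scaling A one-row scaling tibble from [ckd_scaling()] (or a
#'   compatible list with the same fields).
#' @return A new `pbpk_individual` with `ckd_stage` set.
#' @examples
#' h <- build_reference_individual("human", 28, "male", 56.35, 162.1)
#' apply_ckd_stage(h, ckd_scaling("CKD5"))$fu_multiplier  # 1.55
#' @export
apply_ckd_stage <- function(ind, scaling) {
  validate_individual(ind)
  assert_that(ind$species == "human",
              "CKD scaling applies to human individuals only")
  assert_that(identical(ind$ckd_stage, "healthy"),
              "individual already carries a CKD stage; scaling cannot be applied twice")
  s <- as.list(scaling)
  out <- ind
  out$gfr <- s$gfr_target
  i_k <- out$organs$name == "kidney"
  out$organs$volume[i_k] <- out$organs$volume[i_k] * s$kidney_volume_fraction
  out$organs$blood_flow[i_k] <-
    out$organs$blood_flow[i_k] * s$renal_perfusion_fraction
  out$fu_multiplier <- out$fu_multiplier * s$fu_fraction
  out$gastric_emptying_time <-
    out$gastric_emptying_time * s$gastric_emptying_fraction
  out$small_intestinal_transit_time <-
    out$small_intestinal_transit_time * s$small_intestinal_transit_fraction
  out$large_intestinal_transit_time <-
    out$large_intestinal_transit_time * s$large_intestinal_transit_fraction
  perf <- out$organs$name != "lung" &
    !out$organs$name %in% c("arterial_blood", "venous_blood")
  out$cardiac_output <- sum(out$organs$blood_flow[perf])
  out$organs$blood_flow[out$organs$name == "lung"] <- out$cardiac_output
  out$ckd_stage <- if (!is.null(s$stage)) s$stage else "scaled"
  validate_individual(out)
  out
}

#' Describe a virtual population
#'
#' @param n Number of subjects (>= 1).
#' @param fraction_male Expected male fraction in \[0,1\].
#' @param age_range Length-2 numeric, min and max age (years); ages are drawn
#'   uniformly.
#' @param ckd_stage `"healthy"`, `"CKD3"`, `"CKD4"` or `"CKD5"`.
#' @param variability Named list of log-normal coefficients of variation for
#'   `volume`, `flow`, `clearance` and `fu`. Defaults are the package's
#'   declared population variability (see the methods vignette).
#' @param seed Integer seed; the same spec and seed reproduce the population.
#' @return A `pbpk_popspec` list.
#' @export
population_spec <- function(n = 100,
                            fraction_male = 0.5,
                            age_range = c(18, 40),
                            ckd_stage = c("healthy", "CKD3", "CKD4", "CKD5"),
                            variability = list(volume = 0.15, flow = 0.15,
                                               clearance = 0.25, fu = 0.15),
                            seed = 1L) {
  ckd_stage <- match.arg(ckd_stage)
  assert_that(is_number(n) && n >= 1, "`n` must be >= 1")
  assert_that(is_number(fraction_male) && fraction_male >= 0 &&
                fraction_male <= 1, "`fraction_male` must be in [0,1]")
  assert_that(length(age_range) == 2L && age_range[1] <= age_range[2],
              "`age_range` must be (min, max)")
  cv <- utils::modifyList(list(volume = 0.15, flow = 0.15,
                               clearance = 0.25, fu = 0.15),
                          as.list(variability))
  assert_that(all(unlist(cv) >= 0), "variability CVs must be non-negative")
  structure(list(n = as.integer(n), fraction_male = fraction_male,
                 age_range = age_range, ckd_stage = ckd_stage,
                 variability = cv, seed = as.integer(seed)),
            class = "pbpk_popspec")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Sample a virtual population
#'
#' Draws `n` individuals from a base individual: sex Bernoulli
#' (`fraction_male`), age uniform on `age_range`, then multiplicative
#' log-normal perturbations (median-preserving, i.e. meanlog 0) on each organ
#' volume, each organ blood flow, the clearance multiplier and the
#' fraction-unbound multiplier. Cardiac output is recomputed from the
#' perturbed flows so the flow-sum invariant always holds. CKD scaling, when
#' requested, is applied to the demographic individual before perturbation.
#'
#' A single integer seed controls the whole draw; individual i consumes a
#' fixed-length block of the random stream, so populations are reproducible
#' element-wise.
#'
#' @param spec A [population_spec()].
#' @param base A `pbpk_individual` providing species, weight and height.
#' @return A list of `n` `pbpk_individual` objects.
#' @export
sample_population <- function(spec, base) {
  assert_that(inherits(spec, "pbpk_popspec"), "not a `pbpk_popspec`")
  validate_individual(base)
  cv <- spec$variability
  set.seed(spec$seed)
  n_org <- nrow(base$organs)
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    sex <- if (stats::rbinom(1, 1, spec$fraction_male) == 1) "male" else "female"
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    z_vol <- stats::rnorm(n_org)
    z_flow <- stats::rnorm(n_org)
    z_cl <- stats::rnorm(1)
    z_fu <- stats::rnorm(1)
    ind <- build_reference_individual(base$species, age, sex,
                                      base$weight, base$height)
    # model parameters carried on the base individual (e.g. the calibrated
    # absorption surface area) are inherited, not reset to packaged defaults
    ind$absorption_area_m2 <- base$absorption_area_m2
    ind$si_lumen_volume <- base$si_lumen_volume
    if (spec$ckd_stage != "healthy") {
      ind <- apply_ckd_stage(ind, ckd_scaling(spec$ckd_stage))
    }
    ind$organs$volume <- ind$organs$volume *
      exp(z_vol * cv_to_sdlog(cv$volume))
    ind$organs$blood_flow <- ind$organs$blood_flow *
      exp(z_flow * cv_to_sdlog(cv$flow))
    ind$clearance_multiplier <- ind$clearance_multiplier *
      exp(z_cl * cv_to_sdlog(cv$clearance))
    ind$fu_multiplier <- ind$fu_multiplier * exp(z_fu * cv_to_sdlog(cv$fu))
    perf <- ind$organs$name != "lung" &
      !ind$organs$name %in% c("arterial_blood", "venous_blood")
    ind$cardiac_output <- sum(ind$organs$blood_flow[perf])
    ind$organs$blood_flow[ind$organs$name == "lung"] <- ind$cardiac_output
    validate_individual(ind)
    out[[i]] <- ind
  }
  out
}

#' Summarise a population as one row per individual
#'
#' @param pop A list of individuals from [sample_population()].
#' @return A tibble of covariates and scaled parameters, CSV-ready.
#' @export
population_table <- function(pop) {
  list_rbind(imap(pop, function(ind, i) {
    tibble(
      id = i, species = ind$species, sex = ind$sex, age = ind$age,
      weight = ind$weight, ckd_stage = ind$ckd_stage, gfr = ind$gfr,
      fu_multiplier = ind$fu_multiplier,
      clearance_multiplier = ind$clearance_multiplier,
      cardiac_output = ind$cardiac_output,
      kidney_volume = ind$organs$volume[ind$organs$name == "kidney"],
      liver_volume = ind$organs$volume[ind$organs$name == "liver"]
    )
  }))
}
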