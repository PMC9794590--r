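# Packaged reference anatomies and physiologies.
#
# Organ volumes, blood flows and tissue composition are package constants
# compiled from standard physiology reference tables for a ~0.25 kg adult
# male rat and a ~70 kg adult male human, linearly rescaled to the requested
# body weight by `build_reference_individual()`. Flows are expressed as
# fractions of cardiac output and sum to 1 over the non-lung organs by
# construction; the lung receives total cardiac output.

.ref_body_weight <- c(rat = 0.25, human = 70)

# cardiac output at reference weight, L/h
.ref_cardiac_output <- c(rat = 4.98, human = 390)

# volumes in L at the reference body weight; flow as fraction of CO
.organ_reference <- function(species) {
  if (species == "human") {
    tibble::tribble(
      ~name,            ~volume, ~flow_fraction,
      "lung",              0.50,            NA,
      "heart",             0.33,         0.040,
      "brain",             1.45,         0.120,
      "muscle",           29.00,         0.200,
      "adipose",          13.50,         0.085,
      "skin",              3.40,         0.050,
      "bone",             10.00,         0.080,
      "kidney",            0.31,         0.190,
      "liver",             1.80,         0.065,
      "spleen",            0.19,         0.030,
      "gut_wall",          1.20,         0.140,
      "arterial_blood",    1.70,            NA,
      "venous_blood",      3.90,            NA
    )
  } else {
    tibble::tribble(
      ~name,            ~volume, ~flow_fraction,
      "lung",           0.00125,            NA,
      "heart",          0.000825,        0.049,
      "brain",          0.001425,        0.020,
      "muscle",         0.10100,         0.338,
      "adipose",        0.01750,         0.070,
      "skin",           0.04760,         0.078,
      "bone",           0.01825,         0.142,
      "kidney",         0.001825,        0.141,
      "liver",          0.00915,         0.021,
      "spleen",         0.00050,         0.010,
      "gut_wall",       0.00675,         0.131,
      "arterial_blood", 0.00550,            NA,
      "venous_blood",   0.01300,            NA
    )
  }
}

# tissue composition (mass fractions) for the partition-coefficient method;
# shared between species.
.organ_composition <- tibble::tribble(
  ~name,            ~water_fraction, ~lipid_fraction, ~protein_fraction,
  "lung",                      0.79,            0.030,             0.130,
  "heart",                     0.73,            0.100,             0.150,
  "brain",                     0.77,            0.110,             0.080,
  "muscle",                    0.76,            0.022,             0.190,
  "adipose",                   0.18,            0.790,             0.030,
  "skin",                      0.65,            0.130,             0.200,
  "bone",                      0.40,            0.070,             0.200,
  "kidney",                    0.78,            0.050,             0.150,
  "liver",                     0.75,            0.070,             0.160,
  "spleen",                    0.78,            0.030,             0.170,
  "gut_wall",                  0.75,            0.065,             0.150,
  "arterial_blood",            0.81,            0.006,             0.170,
  "venous_blood",              0.81,            0.006,             0.170
)

# plasma water fraction used as the partition reference phase
.plasma_water_fraction <- 0.96
# haematocrit used for the blood:plasma ratio
.haematocrit <- 0.45
# erythrocyte composition (water, lipid)
.rbc_water <- 0.63
.rbc_lipid <- 0.005

# gastrointestinal physiology at the reference body weight:
# gastric emptying time (h), small/large intestinal transit time (h),
# small-intestinal luminal fluid volume (L), effective absorption surface
# area (m^2). The area is a lumped absorption constant; the packaged default
# is a starting value that `calibrate_rat_model()`/`calibrate_human_model()`
# refine against the observed oral exposures.
.gi_reference <- list(
  rat = list(
    gastric_emptying_time = 0.25,
    small_intestinal_transit_time = 1.5,
    large_intestinal_transit_time = 14,
    si_lumen_volume = 0.002,
    absorption_area_m2 = 8e-5
  ),
  human = list(
    gastric_emptying_time = 0.5,
    small_intestinal_transit_time = 1.6,
    large_intestinal_transit_time = 20,
    si_lumen_volume = 0.105,
    absorption_area_m2 = 5e-4
  )
)

# healthy reference glomerular filtration rate:
# human in mL/min/1.73 m^2, rat in mL/min
.gfr_reference <- c(rat = 1.3, human = 110.57)

# Documented ageing adjustments (human): cardiac output declines ~1% per
# decade after age 30; GFR declines ~8 mL/min/1.73 m^2 per decade after 40;
# muscle mass declines ~3% per decade after 30 with the lost volume shifted
# to adipose. Constants, not fits.
.age_co_decline_per_year <- 0.001
.age_gfr_decline_per_year <- 0.8
.age_muscle_decline_per_year <- 0.003

# Documented sex adjustments (human, relative to the male reference)
.female_muscle_factor <- 0.85
.female_adipose_factor <- 1.30
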