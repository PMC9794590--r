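# shared fixtures, built in code

# one-compartment intravenous bolus closed form, concentration in ng/mL
one_compartment_iv <- function(t, dose_mg, v_L, ke) {
  dose_mg / v_L * 1000 * exp(-ke * t)
}

# calibrations are deterministic and reused across test files; compute once
.cal_cache <- new.env(parent = emptyenv())

cal_rat <- function() {
  if (is.null(.cal_cache$rat)) .cal_cache$rat <- calibrate_rat_model()
  .cal_cache$rat
}

cal_human <- function() {
  if (is.null(.cal_cache$human)) .cal_cache$human <- calibrate_human_model()
  .cal_cache$human
}

default_rat <- function(weight = 0.21) {
  build_reference_individual("rat", 0.12, "male", weight)
}

default_human <- function() {
  build_reference_individual("human", 28, "male", 56.35, 162.1)
}

# uniform-Kp partition set (all Kp = kp, blood:plasma = bp) for limit checks
uniform_partition <- function(ind, kp = 1, bp = 1) {
  organs <- ind$organs$name[!ind$organs$name %in%
                              c("arterial_blood", "venous_blood")]
  out <- tibble::tibble(name = organs, kp = kp)
  attr(out, "blood_plasma_ratio") <- bp
  out
}

# compound with a single renal clearance route and nothing else
single_clearance_compound <- function(cl_renal_L_min_kg) {
  compound(name = "probe", mwt = 500, logp = 0, fu = 1,
           intestinal_permeability = 1e-4,
           kidney_plasma_clearance = cl_renal_L_min_kg)
}
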