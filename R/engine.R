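# Whole-body PBPK ODE engine.
#
# State vector (amounts, mg):
#   1 venous blood, 2 arterial blood, 3 lung,
#   4-13 heart, brain, muscle, adipose, skin, bone, kidney, liver, spleen,
#        gut_wall,
#   14-19 gut lumen: stomach undissolved/dissolved, small intestine
#        undissolved/dissolved, large intestine undissolved/dissolved,
#   20 cumulative urine, 21 cumulative bile, 22 cumulative residual
#      ("other"), 23 cumulative feces.
#
# Distribution is perfusion-limited: organ outflow blood concentration is
# C_T / (Kp_T / BP). Gut wall and spleen drain into the liver (portal vein);
# the liver also receives the hepatic artery and the absorption flux.
# Renal elimination removes drug at the kidney plasma concentration,
# biliary elimination at the liver plasma concentration; the residual
# clearance acts on venous plasma. Oral input: Weibull dissolution in the
# stomach, first-order gastric emptying and intestinal transit, absorption
# from dissolved small-intestinal lumen into the liver.

.state_names <- c("venous_blood", "arterial_blood", "lung", "heart", "brain",
                  "muscle", "adipose", "skin", "bone", "kidney", "liver",
                  "spleen", "gut_wall", "stomach_undissolved",
                  "stomach_dissolved", "si_undissolved", "si_dissolved",
                  "li_undissolved", "li_dissolved", "urine", "bile", "other",
                  "feces")

.direct_organs <- c("heart", "brain", "muscle", "adipose", "skin", "bone",
                    "kidney")
.portal_organs <- c("gut_wall", "spleen")

# dissolution event split window, minutes (0.36 s)
.dissolution_event_window_min <- 6e-3

# capillary surface area density for the optional permeability-limited
# distribution mode, m^2 per L tissue
.capillary_area_density <- 5

#' Assemble the PBPK model
#'
#' Builds the state-derivative function and parameter set for an
#' individual/compound/formulation triple. Exposed mainly for testing;
#' [simulate_pbpk()] is the user-facing entry point.
#'
#' @param ind A `pbpk_individual`.
#' @param cmp A `pbpk_compound`.
#' @param form A `pbpk_formulation`.
#' @param partition Optional partition tibble from
#'   [partition_coefficients()]; computed with `kp_scale` if omitted.
#' @param kp_scale Global Kp calibration scalar.
#' @param permeability_limited If `TRUE`, organ exchange flows are capped by
#'   the permeability-surface-area product
#'   `PS_T = organ_permeability * area_density * V_T` (harmonic combination
#'   with perfusion).
#' @return A list with `rhs(t, y, parms)`, the parameter list `params`, the
#'   initial state `state0` and `state_names`.
#' @export
assemble_model <- function(ind, cmp, form, partition = NULL, kp_scale = 1,
                           permeability_limited = FALSE) {
  validate_individual(ind)
  if (is.null(partition)) {
    partition <- partition_coefficients(cmp, ind, calibration_scalar = kp_scale)
  }
  bp <- attr(partition, "blood_plasma_ratio")
  organs <- ind$organs
  get_organ <- function(nm, col) {
    i <- match(nm, organs$name)
    assert_that(all(!is.na(i)), paste("unknown organ(s):",
                                      paste(nm[is.na(i)], collapse = ", ")))
    organs[[col]][i]
  }
  tissue_names <- c("lung", .direct_organs, "liver", .portal_organs)
  kp <- setNames(partition$kp[match(tissue_names, partition$name)],
                 tissue_names)
  assert_that(all(!is.na(kp)),
              paste("missing Kp for organ(s):",
                    paste(tissue_names[is.na(kp)], collapse = ", ")))

  w <- ind$weight
  fu_scale <- min(cmp$fu * ind$fu_multiplier, 1) / cmp$fu_reference
  cl_kid_perkg <- species_kidney_clearance(cmp, ind$species)
  gfr_scale <- if (ind$species == "human") ind$gfr / .gfr_reference[["human"]] else 1
  cl_mult <- ind$clearance_multiplier
  cl_renal <- cl_kid_perkg * 60 * w * gfr_scale * fu_scale * cl_mult
  cl_bile <- cmp$biliary_plasma_clearance * 60 * w * fu_scale * cl_mult
  cl_resid <- (cmp$residual_plasma_clearance + cmp$metabolic_clearance) *
    60 * w * fu_scale * cl_mult

  q <- setNames(get_organ(tissue_names, "blood_flow"), tissue_names)
  v <- setNames(get_organ(tissue_names, "volume"), tissue_names)
  if (permeability_limited) {
    ps <- cmp$organ_permeability * 36 * .capillary_area_density * v * 1000
    qx <- 1 / (1 / q + 1 / ps) # harmonic: flux capped by PS
    qx["lung"] <- q[["lung"]]
  } else {
    qx <- q
  }
  co <- ind$cardiac_output
  v_ven <- get_organ("venous_blood", "volume")
  v_art <- get_organ("arterial_blood", "volume")
  q_liver_total <- sum(q[c("liver", .portal_organs)])

  # absorption clearance, L/h: permeability dm/min -> m/h (x6), times area
  # m^2, times 1000 L/m^3
  cl_abs <- cmp$intestinal_permeability * 6 * ind$absorption_area_m2 * 1000

  params <- list(
    bp = bp, kp = kp, q = q, qx = qx, v = v, co = co, v_ven = v_ven,
    v_art = v_art, q_liver_total = q_liver_total, cl_renal = cl_renal,
    cl_bile = cl_bile, cl_resid = cl_resid, cl_abs = cl_abs,
    v_si_lumen = ind$si_lumen_volume,
    k_ge = 1 / ind$gastric_emptying_time,
    k_si = 1 / ind$small_intestinal_transit_time,
    k_li = 1 / ind$large_intestinal_transit_time,
    formulation = form,
    last_oral_time = -Inf
  )

  i <- setNames(seq_along(.state_names), .state_names)
  rhs <- function(t, y, p) {
    kpbp <- p$kp / p$bp
    c_ven <- y[i["venous_blood"]] / p$v_ven
    c_art <- y[i["arterial_blood"]] / p$v_art
    c_out <- y[i[names(p$kp)]] / p$v / kpbp  # blood conc leaving each tissue

    d <- numeric(length(.state_names))

    # lung and arterial pool
    d[i["lung"]] <- p$co * (c_ven - c_out[["lung"]])
    d[i["arterial_blood"]] <- p$co * c_out[["lung"]] - p$co * c_art

    # perfusion-limited organs draining to the vein
    for (org in .direct_organs) {
      d[i[org]] <- p$qx[[org]] * (c_art - c_out[[org]])
    }
    # renal elimination at kidney plasma concentration
    e_renal <- p$cl_renal * y[i["kidney"]] / (p$v[["kidney"]] * p$kp[["kidney"]])
    d[i["kidney"]] <- d[i["kidney"]] - e_renal

    # splanchnic organs draining into the portal vein
    for (org in .portal_organs) {
      d[i[org]] <- p$qx[[org]] * (c_art - c_out[[org]])
    }

    # gut lumen
    f <- p$formulation
    if (is.finite(p$last_oral_time)) {
      tau_min <- max((t - p$last_oral_time) * 60, .dissolution_event_window_min)
      k_dis <- dissolution_hazard(f, tau_min) * 60 # per hour
    } else {
      k_dis <- 0
    }
    st_u <- y[i["stomach_undissolved"]]; st_d <- y[i["stomach_dissolved"]]
    si_u <- y[i["si_undissolved"]]; si_d <- y[i["si_dissolved"]]
    li_u <- y[i["li_undissolved"]]; li_d <- y[i["li_dissolved"]]
    r_abs <- p$cl_abs * si_d / p$v_si_lumen
    d[i["stomach_undissolved"]] <- -(k_dis + p$k_ge) * st_u
    d[i["stomach_dissolved"]] <- k_dis * st_u - p$k_ge * st_d
    d[i["si_undissolved"]] <- p$k_ge * st_u - p$k_si * si_u
    d[i["si_dissolved"]] <- p$k_ge * st_d - p$k_si * si_d - r_abs
    d[i["li_undissolved"]] <- p$k_si * si_u - p$k_li * li_u
    d[i["li_dissolved"]] <- p$k_si * si_d - p$k_li * li_d
    d[i["feces"]] <- p$k_li * (li_u + li_d)

    # liver: hepatic artery + portal inflow + absorption - outflow - bile
    c_liv_plasma <- y[i["liver"]] / (p$v[["liver"]] * p$kp[["liver"]])
    e_bile <- p$cl_bile * c_liv_plasma
    d[i["liver"]] <- p$q[["liver"]] * c_art +
      sum(p$q[.portal_organs] * c_out[.portal_organs]) + r_abs -
      p$q_liver_total * c_out[["liver"]] - e_bile

    # residual systemic clearance on venous plasma
    e_resid <- p$cl_resid * c_ven / p$bp

    d[i["venous_blood"]] <- sum(p$q[.direct_organs] * c_out[.direct_organs]) +
      p$q_liver_total * c_out[["liver"]] - p$co * c_ven - e_resid

    d[i["urine"]] <- e_renal
    d[i["bile"]] <- e_bile
    d[i["other"]] <- e_resid

    list(d)
  }

  state0 <- setNames(numeric(length(.state_names)), .state_names)
  list(rhs = rhs, params = params, state0 = state0,
       state_names = .state_names)
}

apply_dose_event <- function(state, params, route, amount_mg, time_h) {
  if (route == "iv_bolus") {
    state[["venous_blood"]] <- state[["venous_blood"]] + amount_mg
  } else {
    f <- params$formulation
    assert_that(f$kind != "solution_iv",
                "oral dose events require an oral formulation")
    f0 <- dissolution_fraction(f, .dissolution_event_window_min)
    state[["stomach_dissolved"]] <- state[["stomach_dissolved"]] + amount_mg * f0
    state[["stomach_undissolved"]] <- state[["stomach_undissolved"]] +
      amount_mg * (1 - f0)
    params$last_oral_time <- time_h
  }
  list(state = state, params = params)
}

#' Simulate a PBPK model over a dosing regimen
#'
#' Integrates the whole-body system with `deSolve::lsoda`, restarting the
#' integration at each dose event (doses are instantaneous state jumps:
#' intravenous boluses into venous blood, oral doses into the gastric
#' depots after the analytic dissolution split over the first 0.36 s).
#'
#' @param ind A `pbpk_individual`.
#' @param cmp A `pbpk_compound`.
#' @param form A `pbpk_formulation`.
#' @param reg A `pbpk_regimen`.
#' @param output_times Output grid in hours (defaults to a 0.02 h grid over
#'   the regimen duration, refined near t = 0).
#' @param partition Optional partition-coefficient override (as returned by
#'   [partition_coefficients()], including the `blood_plasma_ratio`
#'   attribute); `kp_scale` is ignored when given.
#' @param kp_scale Global partition calibration scalar.
#' @param rtol,atol Solver tolerances (relative; absolute in mg).
#' @param permeability_limited Enable the optional permeability-limited
#'   distribution mode.
#' @return A `pbpk_sim` object: list with `timecourse` (tibble: `time` h,
#'   `conc` ng/mL venous plasma, cumulative `urine_mg`, `bile_mg`,
#'   `other_mg`, `feces_mg`, `gut_lumen_mg`, `body_mg`, `dose_mg`,
#'   `balance_error` relative), `organ_amounts` (wide tibble of compartment
#'   amounts), `dose_mg` (total administered) and the model inputs.
#' @export
simulate_pbpk <- function(ind, cmp, form, reg, output_times = NULL,
                          kp_scale = 1, rtol = 1e-8, atol = 1e-10,
                          permeability_limited = FALSE, partition = NULL) {
  assert_that(inherits(reg, "pbpk_regimen"), "not a `pbpk_regimen`")
  duration <- attr(reg, "duration")
  if (is.null(output_times)) {
    output_times <- sort(unique(c(seq(0, min(2, duration), by = 0.005),
                                  seq(0, duration, by = 0.02))))
  }
  assert_that(all(diff(output_times) > 0) && output_times[1] >= 0,
              "`output_times` must be strictly increasing and start >= 0")
  assert_that(max(output_times) <= duration,
              "`output_times` must not exceed the regimen duration")

  model <- assemble_model(ind, cmp, form, partition = partition,
                          kp_scale = kp_scale,
                          permeability_limited = permeability_limited)
  events <- resolve_doses(reg, ind$weight)
  state <- model$state0
  params <- model$params

  seg_bounds <- sort(unique(c(0, events$time, max(output_times))))
  seg_bounds <- seg_bounds[seg_bounds <= max(output_times)]
  administered <- 0
  record <- list() # accumulated deSolve output rows
  for (s in seq_along(seg_bounds)) {
    t0 <- seg_bounds[s]
    ev_here <- events[events$time == t0, ]
    for (k in seq_len(nrow(ev_here))) {
      upd <- apply_dose_event(state, params, ev_here$route[k],
                              ev_here$amount_mg[k], t0)
      state <- upd$state
      params <- upd$params
      administered <- administered + ev_here$amount_mg[k]
    }
    t1 <- if (s < length(seg_bounds)) seg_bounds[s + 1] else max(output_times)
    times <- output_times[output_times >= t0 & output_times <= t1]
    times <- sort(unique(c(t0, times, t1)))
    if (length(times) < 2L) times <- c(t0, t1)
    if (t1 > t0) {
      sol <- deSolve::lsoda(y = state, times = times, func = model$rhs,
                            parms = params, rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0) {
        abort(sprintf("ODE solver failed near t = %.4g h", max(sol[, 1])))
      }
      keep <- sol[, 1] %in% output_times & sol[, 1] < t1
      if (s == length(seg_bounds)) keep <- sol[, 1] %in% output_times
      rec <- sol[keep, , drop = FALSE]
      record[[s]] <- cbind(rec, dose_mg = administered)
      state <- sol[nrow(sol), -1]
      names(state) <- model$state_names
    } else if (s == length(seg_bounds) && t0 %in% output_times) {
      record[[s]] <- matrix(c(t0, state, administered), nrow = 1,
                            dimnames = list(NULL, c("time", model$state_names,
                                                    "dose_mg")))
    }
  }
  raw <- do.call(rbind, record)
  raw <- raw[!duplicated(raw[, "time"]), , drop = FALSE]

  bp <- model$params$bp
  v_ven <- model$params$v_ven
  amounts <- raw[, model$state_names, drop = FALSE]
  neg <- amounts < 0
  if (any(neg & abs(amounts) > 1e3 * atol)) {
    warn("negative amounts beyond solver tolerance; check tolerances")
  }
  amounts[neg] <- 0
  gut_cols <- c("stomach_undissolved", "stomach_dissolved", "si_undissolved",
                "si_dissolved", "li_undissolved", "li_dissolved")
  body_cols <- setdiff(model$state_names,
                       c(gut_cols, "urine", "bile", "other", "feces"))
  total <- rowSums(amounts)
  dose_vec <- raw[, "dose_mg"]
  balance_error <- ifelse(dose_vec > 0, (total - dose_vec) / dose_vec, 0)

  timecourse <- tibble(
    time = raw[, "time"],
    conc = amounts[, "venous_blood"] / v_ven / bp * 1000, # mg/L -> ng/mL
    urine_mg = amounts[, "urine"],
    bile_mg = amounts[, "bile"],
    other_mg = amounts[, "other"],
    feces_mg = amounts[, "feces"],
    gut_lumen_mg = rowSums(amounts[, gut_cols, drop = FALSE]),
    body_mg = rowSums(amounts[, body_cols, drop = FALSE]),
    dose_mg = dose_vec,
    balance_error = balance_error
  )
  structure(
    list(timecourse = timecourse,
         organ_amounts = as_tibble(cbind(time = raw[, "time"],
                                         as.data.frame(amounts))),
         dose_mg = administered,
         individual = ind, compound = cmp, formulation = form, regimen = reg,
         kp_scale = kp_scale, blood_plasma_ratio = bp),
    class = "pbpk_sim"
  )
}

#' @export
print.pbpk_sim <- function(x, ...) {
  tc <- x$timecourse
  cat(sprintf(
    "<pbpk_sim> %s, %.4g mg administered, %d time points to %.4g h\n",
    x$individual$species, x$dose_mg, nrow(tc), max(tc$time)))
  cat(sprintf("  Cmax %.4g ng/mL, urine %.1f%%, bile %.1f%% of dose\n",
              max(tc$conc), 100 * tc$urine_mg[nrow(tc)] / x$dose_mg,
              100 * tc$bile_mg[nrow(tc)] / x$dose_mg))
  invisible(x)
}

#' Cumulative excretion fractions
#'
#' Terminal cumulative urinary and biliary amounts as fractions of the
#' administered dose.
#'
#' @param sim A `pbpk_sim`.
#' @return A tibble with `urine_fraction` and `bile_fraction` in \[0, 1\].
#' @export
cumulative_excretion_fractions <- function(sim) {
  assert_that(inherits(sim, "pbpk_sim"), "not a `pbpk_sim`")
  tc <- sim$timecourse
  n <- nrow(tc)
  tibble(urine_fraction = tc$urine_mg[n] / sim$dose_mg,
         bile_fraction = tc$bile_mg[n] / sim$dose_mg)
}

# Window summaries used by sensitivity and population layers.
window_metrics <- function(sim, window) {
  tc <- sim$timecourse
  sel <- tc$time >= window[1] & tc$time <= window[2]
  assert_that(sum(sel) >= 3, "too few simulated points in the requested window")
  tibble(cmax = max(tc$conc[sel]),
         tmax = tc$time[sel][which.max(tc$conc[sel])],
         auc = trapz(tc$time[sel], tc$conc[sel]))
}
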