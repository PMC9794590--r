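# Local sensitivity analysis: S = (dPK / dp) * (p / PK), evaluated by
# central difference at +/- a relative perturbation (two simulations per
# parameter). Parameters are addressed by dotted paths into the model
# inputs.

.sensitivity_paths <- c(
  "compound.fu", "compound.logp", "compound.acidic_pka",
  "compound.solubility_ph7", "compound.intestinal_permeability",
  "compound.kidney_plasma_clearance", "compound.biliary_plasma_clearance",
  "compound.residual_plasma_clearance",
  "formulation.t50", "formulation.shape",
  "individual.kidney_volume", "individual.kidney_flow",
  "individual.gastric_emptying_time",
  "individual.small_intestinal_transit_time",
  "individual.large_intestinal_transit_time",
  "individual.gfr", "individual.fu_multiplier", "dose"
)

#' Addressable sensitivity parameter paths
#' @return Character vector of the dotted parameter paths understood by
#'   [local_sensitivity()].
#' @export
sensitivity_paths <- function() .sensitivity_paths

perturb_inputs <- function(ind, cmp, form, reg, path, factor) {
  if (!path %in% .sensitivity_paths) {
    abort(paste0("unknown parameter path '", path, "'; valid paths: ",
                 paste(.sensitivity_paths, collapse = ", ")))
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "compound") {
    cmp[[parts[2]]] <- cmp[[parts[2]]] * factor
  } else if (parts[1] == "formulation") {
    form[[parts[2]]] <- form[[parts[2]]] * factor
  } else if (parts[1] == "individual") {
    if (parts[2] == "kidney_volume") {
      i <- ind$organs$name == "kidney"
      ind$organs$volume[i] <- ind$organs$volume[i] * factor
    } else if (parts[2] == "kidney_flow") {
      i <- ind$organs$name == "kidney"
      ind$organs$blood_flow[i] <- ind$organs$blood_flow[i] * factor
      perf <- ind$organs$name != "lung" &
        !ind$organs$name %in% c("arterial_blood", "venous_blood")
      ind$cardiac_output <- sum(ind$organs$blood_flow[perf])
      ind$organs$blood_flow[ind$organs$name == "lung"] <- ind$cardiac_output
    } else {
      ind[[parts[2]]] <- ind[[parts[2]]] * factor
    }
  } else if (parts[1] == "dose") {
    reg$amount <- reg$amount * factor
  }
  list(ind = ind, cmp = cmp, form = form, reg = reg)
}

metric_windows <- function(duration) {
  w <- list(cmax_day1 = c("cmax", 0, min(24, duration)),
            auc_day1 = c("auc", 0, min(24, duration)))
  if (duration >= 144) {
    w$cmax_day6 <- c("cmax", 120, 144)
    w$auc_day6 <- c("auc", 120, 144)
  }
  w
}

eval_metrics <- function(sim, metrics) {
  w <- metric_windows(attr(sim$regimen, "duration"))
  map_dbl(metrics, function(m) {
    assert_that(m %in% names(w),
                paste0("metric '", m, "' not available for this regimen"))
    spec <- w[[m]]
    wm <- window_metrics(sim, as.numeric(spec[2:3]))
    wm[[spec[1]]]
  })
}

#' Local parameter sensitivity of simulated exposure metrics
#'
#' For each parameter path, the model is re-simulated at `p * (1 + delta)`
#' and `p * (1 - delta)` and the normalized sensitivity coefficient
#' `S = (PK+ - PK-) / (2 * delta * PK0)` is reported per metric. `S = 1`
#' means a 10% parameter increase raises the metric by 10%.
#'
#' @param ind,cmp,form,reg Model inputs as for [simulate_pbpk()].
#' @param parameters Character vector of dotted paths, see
#'   [sensitivity_paths()].
#' @param perturbation Relative perturbation (default 0.1 = 10%).
#' @param metrics Metrics to report: subset of `cmax_day1`, `auc_day1`,
#'   `cmax_day6`, `auc_day6` (day 6 requires a >= 144 h regimen).
#' @param kp_scale,output_times Passed to [simulate_pbpk()].
#' @return A tibble: `parameter`, `metric`, `s`, `perturbation`, `baseline`.
#' @export
local_sensitivity <- function(ind, cmp, form, reg,
                              parameters = sensitivity_paths(),
                              perturbation = 0.1,
                              metrics = c("cmax_day1", "auc_day1"),
                              kp_scale = 1, output_times = NULL) {
  assert_that(is_number(perturbation) && perturbation > 0,
              "`perturbation` must be positive")
  base_sim <- simulate_pbpk(ind, cmp, form, reg, output_times = output_times,
                            kp_scale = kp_scale)
  pk0 <- eval_metrics(base_sim, metrics)
  rows <- list()
  for (path in parameters) {
    pk_pm <- map(c(1 + perturbation, 1 - perturbation), function(f) {
      p <- perturb_inputs(ind, cmp, form, reg, path, f)
      sim <- simulate_pbpk(p$ind, p$cmp, p$form, p$reg,
                           output_times = output_times, kp_scale = kp_scale)
      eval_metrics(sim, metrics)
    })
    s <- (pk_pm[[1]] - pk_pm[[2]]) / (2 * perturbation * pk0)
    rows[[path]] <- tibble(parameter = path, metric = metrics, s = s,
                           perturbation = perturbation, baseline = pk0)
  }
  list_rbind(rows)
}

#' Rank parameters by sensitivity magnitude
#'
#' @param results Output of [local_sensitivity()].
#' @return The tibble sorted by `|S|` descending within each metric, with a
#'   `rank` column; tornado-plot ready.
#' @export
rank_parameters <- function(results) {
  assert_that(nrow(results) > 0, "no sensitivity results to rank")
  results |>
    group_by(.data$metric) |>
    arrange(desc(abs(.data$s)), .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
}
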