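#' Build a dosing regimen
#'
#' @param events A data frame with columns `time` (h), `route`
#'   (`"iv_bolus"` or `"oral"`), `amount` (positive) and `basis`
#'   (`"mg"` for absolute amounts or `"mg_per_kg"` for weight-based).
#' @param duration Simulation horizon in hours; must cover the last event.
#' @return A `pbpk_regimen`: the sorted event tibble with a `duration`
#'   attribute.
#' @export
regimen <- function(events, duration) {
  ev <- as_tibble(events)
  assert_that(all(c("time", "route", "amount", "basis") %in% names(ev)),
              "events need columns time, route, amount, basis")
  assert_that(all(ev$time >= 0), "event times must be non-negative")
  assert_that(all(ev$amount > 0), "dose amounts must be positive")
  assert_that(all(ev$route %in% c("iv_bolus", "oral")),
              "route must be 'iv_bolus' or 'oral'")
  assert_that(all(ev$basis %in% c("mg", "mg_per_kg")),
              "basis must be 'mg' or 'mg_per_kg'")
  ev <- arrange(ev, .data$time)
  assert_that(is_number(duration) && duration >= max(ev$time),
              "`duration` must cover the last dose event")
  structure(ev, duration = duration, class = c("pbpk_regimen", class(ev)))
}

#' @export
print.pbpk_regimen <- function(x, ...) {
  cat(sprintf("<pbpk_regimen> %d event(s) over %.4g h\n", nrow(x),
              attr(x, "duration")))
  NextMethod()
}

#' Single-dose regimen shorthand
#'
#' @param amount Dose amount.
#' @param route `"oral"` or `"iv_bolus"`.
#' @param basis `"mg"` or `"mg_per_kg"`.
#' @param duration Simulation horizon, h.
#' @return A `pbpk_regimen` with one dose at t = 0.
#' @export
single_dose_regimen <- function(amount, route = "oral", basis = "mg",
                                duration = 24) {
  regimen(tibble(time = 0, route = route, amount = amount, basis = basis),
          duration = duration)
}

#' Study dosing regimens
#'
#' The dosing schedules of the rat and clinical studies:
#' * `rat_iv`: 1.2 mg/kg schaftoside intravenous bolus, 48 h horizon.
#' * `rat_po_50`, `rat_po_100`, `rat_po_200`: oral TFDS suspension at 50,
#'   100, 200 mg/kg, equivalent to 3.03, 6.06, 12.12 mg/kg schaftoside,
#'   24 h horizon.
#' * `human_0p6`: TFDS capsules, 0.6 g (3 capsules of 8.5 mg schaftoside =
#'   25.5 mg) once on day 1 (08:00) and day 6, three times daily (q8h:
#'   08:00, 16:00, 00:00) on days 2-5; 14 oral events, 144 h horizon.
#' * `human_1p0`: the 1 g variant (42.5 mg schaftoside per dose).
#' * `human_0p6_single`, `human_1p0_single`: single oral doses, 24 h.
#'
#' @return A named list of `pbpk_regimen` objects.
#' @export
build_study_regimens <- function() {
  q8h_times <- c(0, 24 + rep(c(0, 8, 16), 4) + rep(c(0, 24, 48, 72),
                                                   each = 3), 120)
  human_reg <- function(dose_mg) {
    regimen(tibble(time = q8h_times, route = "oral", amount = dose_mg,
                   basis = "mg"), duration = 144)
  }
  list(
    rat_iv = single_dose_regimen(1.2, route = "iv_bolus",
                                 basis = "mg_per_kg", duration = 48),
    rat_po_50 = single_dose_regimen(3.03, basis = "mg_per_kg"),
    rat_po_100 = single_dose_regimen(6.06, basis = "mg_per_kg"),
    rat_po_200 = single_dose_regimen(12.12, basis = "mg_per_kg"),
    human_0p6 = human_reg(25.5),
    human_1p0 = human_reg(42.5),
    human_0p6_single = single_dose_regimen(25.5),
    human_1p0_single = single_dose_regimen(42.5)
  )
}

resolve_doses <- function(reg, weight) {
  ev <- as_tibble(reg)
  ev$amount_mg <- ifelse(ev$basis == "mg_per_kg", ev$amount * weight,
                         ev$amount)
  ev
}
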