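#' Residual error model for synthetic concentration data
#'
#' Combined proportional-plus-additive assay error with lower-limit
#' censoring: reported concentration is
#' `c * (1 + eps_prop) + eps_add`, negative values truncated to zero and
#' values below `lloq` censored.
#'
#' @param proportional_cv Proportional error CV (fraction).
#' @param additive_sd Additive error SD, ng/mL.
#' @param lloq Lower limit of quantification, ng/mL (0.5 for the rat assay,
#'   0.05 for the human assay).
#' @param seed Integer seed making generated datasets reproducible.
#' @return A `pbpk_error_model` list.
#' @export
error_model <- function(proportional_cv = 0.1, additive_sd = NULL,
                        lloq = 0.5, seed = 1L) {
  if (is.null(additive_sd)) additive_sd <- lloq / 2
  assert_that(proportional_cv >= 0 && additive_sd >= 0 && lloq >= 0,
              "error-model components must be non-negative")
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd, lloq = lloq,
                 seed = as.integer(seed)),
            class = "pbpk_error_model")
}

#' Study sampling schedules
#'
#' The blood sampling times (hours post dose, including predose 0 h) of the
#' preclinical and clinical studies: rat intravenous (14 times to 12 h), rat
#' oral (14 times to 24 h), human oral (15 times to 24 h).
#'
#' @return A named list of numeric vectors (`rat_iv`, `rat_oral`, `human`).
#' @export
study_schedules <- function() {
  list(
    rat_iv = c(0, 0.033, 0.083, 0.167, 0.333, 0.50, 0.75, 1, 2, 3, 4, 6, 8,
               12),
    rat_oral = c(0, 0.083, 0.25, 0.50, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24),
    human = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7, 8, 12, 24)
  )
}

#' Generate observed-like concentration profiles with known truth
#'
#' Evaluates a true concentration model on a sampling schedule, applies the
#' residual error model per subject and censors below the LLOQ. The
#' generating truth travels with the dataset (attribute `"truth"`).
#'
#' @param true_model Either a function `f(times)` returning concentrations
#'   (ng/mL) or a `pbpk_sim` whose time course is interpolated.
#' @param schedule Sampling times, h (non-empty, strictly increasing).
#' @param error A [error_model()].
#' @param n_subjects Number of subjects.
#' @param truth Optional named list of generating parameters stored with
#'   the data.
#' @return A tibble `subject`, `time`, `conc`, `censored`; censored records
#'   keep `conc = 0`.
#' @export
generate_profile <- function(true_model, schedule, error = error_model(),
                             n_subjects = 1, truth = NULL) {
  assert_that(length(schedule) > 0 && all(diff(schedule) > 0),
              "`schedule` must be non-empty and strictly increasing")
  f <- if (inherits(true_model, "pbpk_sim")) {
    function(t) interp_at(true_model$timecourse$time,
                          true_model$timecourse$conc, t)
  } else {
    assert_that(is.function(true_model),
                "`true_model` must be a function or a `pbpk_sim`")
    true_model
  }
  mu <- f(schedule)
  assert_that(all(is.finite(mu) & mu >= 0),
              "true model must return finite non-negative concentrations")
  set.seed(error$seed)
  out <- list_rbind(map(seq_len(n_subjects), function(s) {
    eps_p <- stats::rnorm(length(mu), 0, error$proportional_cv)
    eps_a <- stats::rnorm(length(mu), 0, error$additive_sd)
    c_obs <- pmax(mu * (1 + eps_p) + eps_a, 0)
    censored <- c_obs < error$lloq
    c_obs[censored] <- 0
    tibble(subject = s, time = schedule, conc = c_obs, censored = censored)
  }))
  attr(out, "truth") <- truth
  out
}

#' Generate predicted/observed pairs with a target average fold error
#'
#' Observed values are drawn log-normally; predictions are
#' `observed * target_afe * lognormal(0, dispersion)`, so the realized AFE
#' converges to `target_afe` as `n` grows and equals it exactly at zero
#' dispersion.
#'
#' @param n_points Number of pairs.
#' @param target_afe Target average fold error (> 0).
#' @param dispersion SD of the log10 prediction scatter.
#' @param seed Integer seed.
#' @return A tibble `predicted`, `observed`.
#' @export
generate_predobs <- function(n_points, target_afe = 1, dispersion = 0.1,
                             seed = 1L) {
  assert_that(target_afe > 0, "`target_afe` must be positive")
  assert_that(dispersion >= 0, "`dispersion` must be non-negative")
  set.seed(seed)
  observed <- 10^stats::rnorm(n_points, mean = 1, sd = 0.5)
  predicted <- observed * target_afe * 10^stats::rnorm(n_points, 0, dispersion)
  tibble(predicted = predicted, observed = observed)
}
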