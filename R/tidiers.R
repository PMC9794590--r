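#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PBPK simulation
#'
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @return The time-course tibble (`time` h, `conc` ng/mL, cumulative
#'   excretion columns, mass-balance error).
#' @method tidy pbpk_sim
#' @export
tidy.pbpk_sim <- function(x, ...) x$timecourse

#' One-row summary of a PBPK simulation
#'
#' @param x A `pbpk_sim`.
#' @param ... Unused.
#' @return A one-row tibble: dose, Cmax, Tmax, AUC to the simulation end,
#'   terminal urinary/biliary dose fractions and the worst mass-balance
#'   error.
#' @method glance pbpk_sim
#' @export
glance.pbpk_sim <- function(x, ...) {
  tc <- x$timecourse
  exc <- cumulative_excretion_fractions(x)
  tibble(
    species = x$individual$species,
    dose_mg = x$dose_mg,
    cmax = max(tc$conc),
    tmax = tc$time[which.max(tc$conc)],
    auc = trapz(tc$time, tc$conc),
    urine_fraction = exc$urine_fraction,
    bile_fraction = exc$bile_fraction,
    max_balance_error = max(abs(tc$balance_error))
  )
}

#' @rdname tidy.pbpk_sim
#' @method tidy pbpk_evaluation
#' @export
tidy.pbpk_evaluation <- function(x, ...) x$points

#' @rdname glance.pbpk_sim
#' @method glance pbpk_evaluation
#' @export
glance.pbpk_evaluation <- function(x, ...) x$summary

#' @rdname tidy.pbpk_sim
#' @method tidy pbpk_popresult
#' @export
tidy.pbpk_popresult <- function(x, ...) x$parameters

#' @rdname glance.pbpk_sim
#' @method glance pbpk_popresult
#' @export
glance.pbpk_popresult <- function(x, ...) {
  p <- x$parameters
  m <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_
  tibble(
    n = x$spec$n, failures = length(x$failures),
    cmax_day1 = m(p$cmax_day1), auc_day1 = m(p$auc_day1),
    cmax_day6 = m(p$cmax_day6), auc_day6 = m(p$auc_day6),
    r_cmax = m(p$cmax_day6) / m(p$cmax_day1),
    r_auc = m(p$auc_day6) / m(p$auc_day1)
  )
}
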