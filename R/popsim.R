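#' Simulate a virtual population
#'
#' Samples a population with [sample_population()], simulates each
#' individual over the regimen, computes day-1 and (for >= 144 h regimens)
#' day-6 window exposure metrics per individual, and aggregates the mean and
#' empirical 2.5th/97.5th percentile concentration bands. Individual solver
#' failures are recorded and excluded; a failure rate above 5% aborts.
#'
#' @param spec A [population_spec()].
#' @param base Base `pbpk_individual` (species, weight); CKD scaling from
#'   `spec$ckd_stage` is applied inside the sampler.
#' @param cmp,form,reg As for [simulate_pbpk()].
#' @param output_times Simulation grid (defaults to 0.1 h steps).
#' @param kp_scale Partition calibration scalar.
#' @return A `pbpk_popresult`: `band` (time, mean, p2.5, p97.5),
#'   `parameters` (per-individual day-1/day-6 cmax and auc plus per-subject
#'   day6:day1 ratios), `failures`, and the population spec.
#' @export
simulate_population <- function(spec, base, cmp, form, reg,
                                output_times = NULL, kp_scale = 1) {
  duration <- attr(reg, "duration")
  if (is.null(output_times)) output_times <- seq(0, duration, by = 0.1)
  pop <- sample_population(spec, base)
  conc <- matrix(NA_real_, nrow = length(output_times), ncol = spec$n)
  pars <- vector("list", spec$n)
  failures <- integer(0)
  for (j in seq_along(pop)) {
    sim <- tryCatch(
      simulate_pbpk(pop[[j]], cmp, form, reg, output_times = output_times,
                    kp_scale = kp_scale),
      error = function(e) e
    )
    if (inherits(sim, "error")) {
      failures <- c(failures, j)
      next
    }
    conc[, j] <- sim$timecourse$conc
    d1 <- window_metrics(sim, c(0, min(24, duration)))
    row <- tibble(id = j, cmax_day1 = d1$cmax, auc_day1 = d1$auc,
                  cmax_day6 = NA_real_, auc_day6 = NA_real_)
    if (duration >= 144) {
      d6 <- window_metrics(sim, c(120, 144))
      row$cmax_day6 <- d6$cmax
      row$auc_day6 <- d6$auc
    }
    pars[[j]] <- row
  }
  if (length(failures) / spec$n > 0.05) {
    abort(sprintf("solver failed for %d of %d individuals (> 5%%)",
                  length(failures), spec$n))
  }
  ok <- setdiff(seq_len(spec$n), failures)
  band <- tibble(
    time = output_times,
    mean = rowMeans(conc[, ok, drop = FALSE]),
    p2.5 = apply(conc[, ok, drop = FALSE], 1, quantile, probs = 0.025),
    p97.5 = apply(conc[, ok, drop = FALSE], 1, quantile, probs = 0.975)
  )
  parameters <- list_rbind(pars)
  parameters$r_cmax <- parameters$cmax_day6 / parameters$cmax_day1
  parameters$r_auc <- parameters$auc_day6 / parameters$auc_day1
  structure(list(band = band, parameters = parameters, failures = failures,
                 spec = spec),
            class = "pbpk_popresult")
}

#' @export
print.pbpk_popresult <- function(x, ...) {
  cat(sprintf("<pbpk_popresult> n = %d (%d failures), %s\n",
              x$spec$n, length(x$failures), x$spec$ckd_stage))
  print(population_summary(x))
  invisible(x)
}

#' Summarise population exposure metrics
#'
#' Mean and empirical percentiles of the per-individual exposure metrics,
#' with the day6:day1 accumulation ratios computed as ratios of means
#' (the layout of the population summary tables this mirrors).
#'
#' @param pop A `pbpk_popresult`.
#' @return A tibble: `parameter`, `day`, `mean`, `p2.5`, `p97.5`.
#' @export
population_summary <- function(pop) {
  p <- pop$parameters
  stat_row <- function(x, parameter, day) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(NULL)
    tibble(parameter = parameter, day = day, mean = mean(x),
           p2.5 = unname(quantile(x, 0.025)),
           p97.5 = unname(quantile(x, 0.975)))
  }
  out <- bind_rows(
    stat_row(p$cmax_day1, "cmax", 1L), stat_row(p$cmax_day6, "cmax", 6L),
    stat_row(p$auc_day1, "auc", 1L), stat_row(p$auc_day6, "auc", 6L)
  )
  if (any(is.finite(p$cmax_day6))) {
    ratios <- tibble(
      parameter = c("r_cmax", "r_auc"), day = NA_integer_,
      mean = c(mean(p$cmax_day6) / mean(p$cmax_day1),
               mean(p$auc_day6) / mean(p$auc_day1)),
      p2.5 = c(unname(quantile(p$cmax_day6, 0.025)) /
                 unname(quantile(p$cmax_day1, 0.025)),
               unname(quantile(p$auc_day6, 0.025)) /
                 unname(quantile(p$auc_day1, 0.025))),
      p97.5 = c(unname(quantile(p$cmax_day6, 0.975)) /
                  unname(quantile(p$cmax_day1, 0.975)),
                unname(quantile(p$auc_day6, 0.975)) /
                  unname(quantile(p$auc_day1, 0.975)))
    )
    out <- bind_rows(out, ratios)
  }
  out
}

#' Compare two simulated populations
#'
#' Ratio-of-means comparison of the exposure metrics of a test population
#' against a reference (same regimen timescale), with fold increases
#' (`ratio - 1`) and the within-population day6:day1 ratios.
#'
#' @param ref,test `pbpk_popresult` objects.
#' @return A tibble: `parameter`, `day`, `ref_mean`, `test_mean`, `ratio`,
#'   `fold_increase`.
#' @export
compare_populations <- function(ref, test) {
  sr <- population_summary(ref)
  st <- population_summary(test)
  assert_that(identical(sr$parameter, st$parameter) &&
                identical(sr$day, st$day),
              "populations carry different day/parameter definitions")
  tibble(parameter = sr$parameter, day = sr$day,
         ref_mean = sr$mean, test_mean = st$mean,
         ratio = st$mean / sr$mean,
         fold_increase = st$mean / sr$mean - 1)
}

#' Day 6 : day 1 ratio of means
#'
#' The published population tables report, per population, the ratio of the
#' day-6 mean to the day-1 mean of a PK parameter; this helper applies the
#' same arithmetic to any pair of summary values.
#'
#' @param day6,day1 Positive summary values (means or matching percentiles).
#' @return `day6 / day1`.
#' @examples
#' pk_day_ratio(20.64, 2.52) # 8.19 at 2 d.p.
#' @export
pk_day_ratio <- function(day6, day1) {
  assert_that(all(day6 > 0) && all(day1 > 0), "values must be positive")
  day6 / day1
}

#' Fold increase of a test mean over a reference mean
#'
#' `test / ref - 1`, the "increased by x-fold" statistic used when
#' comparing renally impaired to healthy populations.
#'
#' @param test,ref Positive summary values.
#' @return The fold increase.
#' @examples
#' pk_fold_increase(433.77, 18.25) # 22.77 at 2 d.p.
#' @export
pk_fold_increase <- function(test, ref) {
  assert_that(all(test > 0) && all(ref > 0), "values must be positive")
  test / ref - 1
}
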