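as_predobs <- function(data) {
  df <- as_tibble(data)
  assert_that(all(c("predicted", "observed") %in% names(df)),
              "need columns `predicted` and `observed`")
  bad <- which(!(df$predicted > 0) | !(df$observed > 0))
  assert_that(length(bad) == 0L,
              paste0("non-positive predicted/observed value(s) at row(s): ",
                     paste(bad, collapse = ", ")))
  df
}

#' Per-point fold errors
#'
#' `FE_i = predicted_i / observed_i` for each paired concentration point. A
#' point is conventionally acceptable when its fold error lies in
#' \[0.3, 3\].
#'
#' @param data A data frame with positive columns `predicted` and
#'   `observed` (a `time` column, if present, is carried through).
#' @return The input tibble with columns `fe`, `within_2fold`,
#'   `within_3fold` added.
#' @export
fold_error_points <- function(data) {
  df <- as_predobs(data)
  mutate(df, fe = .data$predicted / .data$observed,
         within_2fold = .data$fe >= 0.5 & .data$fe <= 2,
         within_3fold = .data$fe >= 0.3 & .data$fe <= 3)
}

#' Average fold error
#'
#' Geometric-mean prediction bias:
#' `AFE = 10^(mean(log10(predicted / observed)))`. Values below/above 1
#' indicate net under-/over-prediction; \[0.5, 2\] is the conventional
#' acceptance band.
#'
#' @inheritParams fold_error_points
#' @return A single number.
#' @export
afe <- function(data) {
  df <- as_predobs(data)
  10^mean(log10_ratio(df$predicted, df$observed))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10(predicted / observed)|))`: the geometric mean of
#' absolute fold deviations, always >= 1 and >= AFE.
#'
#' @inheritParams fold_error_points
#' @return A single number.
#' @export
aafe <- function(data) {
  df <- as_predobs(data)
  10^mean(abs(log10_ratio(df$predicted, df$observed)))
}

#' Fold error of a PK parameter
#'
#' `FE = predicted / observed`, with the conventional \[0.5, 2\] acceptance
#' flag.
#'
#' @param predicted,observed Positive parameter values.
#' @return A one-row tibble with `fe` and `pass`.
#' @examples
#' fold_error_param(5230.70, 5567.22)$fe  # 0.94 at 2 d.p.
#' @export
fold_error_param <- function(predicted, observed) {
  assert_that(is_number(predicted) && predicted > 0,
              "`predicted` must be positive")
  assert_that(is_number(observed) && observed > 0,
              "`observed` must be positive")
  fe <- predicted / observed
  tibble(fe = fe, pass = fe >= 0.5 & fe <= 2)
}

#' Qualify a model prediction against observations
#'
#' Interpolates the predicted profile onto the observed sampling times,
#' computes the per-point fold errors, AFE and AAFE with their acceptance
#' flags (FE_i in \[0.3, 3\]; AFE and AAFE in \[0.5, 2\]), and, when
#' predicted/observed PK parameter pairs are supplied, their fold errors
#' against the \[0.5, 2\] band. Observed points below `lloq` are excluded
#' from the statistics.
#'
#' @param predicted A data frame `time`, `conc` of model predictions.
#' @param observed A data frame `time`, `conc` of observations.
#' @param pk_pred,pk_obs Optional named numeric vectors of PK parameters
#'   (matching names, e.g. `c(cmax = ..., auc_last = ...)`).
#' @param lloq Observed values below this limit are excluded.
#' @param label Series label carried into the output.
#' @return A `pbpk_evaluation` list: `points` (time, observed, predicted,
#'   fe, band flags), `summary` (one row: n, afe, aafe, pass flags),
#'   `parameters` (fe per parameter). Use [tidy()]/[glance()] to extract.
#' @export
evaluate_model <- function(predicted, observed, pk_pred = NULL,
                           pk_obs = NULL, lloq = 0, label = "series") {
  pr <- as_tibble(predicted)
  ob <- as_tibble(observed)
  assert_that(all(c("time", "conc") %in% names(pr)) &&
                all(c("time", "conc") %in% names(ob)),
              "`predicted` and `observed` need columns `time` and `conc`")
  ob <- ob[ob$conc >= lloq & ob$conc > 0, ]
  pred_at <- interp_at(pr$time, pr$conc, ob$time)
  pts <- fold_error_points(tibble(time = ob$time, observed = ob$conc,
                                  predicted = pred_at))
  sm <- tibble(
    label = label, n = nrow(pts),
    afe = afe(pts), aafe = aafe(pts),
    pass_fe_points = all(pts$within_3fold),
    pass_afe = afe(pts) >= 0.5 & afe(pts) <= 2,
    pass_aafe = aafe(pts) >= 0.5 & aafe(pts) <= 2
  )
  pars <- NULL
  if (!is.null(pk_pred)) {
    assert_that(!is.null(pk_obs) && all(names(pk_pred) %in% names(pk_obs)),
                "`pk_obs` must carry the same parameter names as `pk_pred`")
    pars <- list_rbind(imap(as.list(pk_pred), function(v, nm) {
      mutate(fold_error_param(v, pk_obs[[nm]]), parameter = nm,
             predicted = v, observed = pk_obs[[nm]], .before = 1)
    }))
  }
  structure(list(points = pts, summary = sm, parameters = pars),
            class = "pbpk_evaluation")
}

#' @export
print.pbpk_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pbpk_evaluation> %s: n = %d, AFE %.2f, AAFE %.2f\n",
              s$label, s$n, s$afe, s$aafe))
  if (!is.null(x$parameters)) {
    for (k in seq_len(nrow(x$parameters))) {
      cat(sprintf("  FE(%s) = %.2f [%s]\n", x$parameters$parameter[k],
                  x$parameters$fe[k],
                  if (x$parameters$pass[k]) "pass" else "fail"))
    }
  }
  invisible(x)
}
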