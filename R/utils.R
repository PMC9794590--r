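#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble tribble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by
#'   summarise ungroup across desc pull rename n
#' @importFrom purrr map map_dbl map2 imap list_rbind
#' @importFrom stats approx lm coef quantile rnorm rlnorm runif rbinom aov
#'   setNames
NULL

# Trapezoidal AUC; x strictly increasing.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Linear interpolation that tolerates exact grid hits; rule = 1 outside.
interp_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, ties = "ordered")$y
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# geometric helpers for fold-error statistics
log10_ratio <- function(pred, obs) log10(pred / obs)
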