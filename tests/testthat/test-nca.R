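test_that("NCA recovers one-compartment analytic parameters within 1%", {
  # C(t) = 10 * exp(-0.1 t) mg/L for a 100 mg dose in 10 L, ke = 0.1 /h
  t <- seq(0, 72, by = 0.05)
  prof <- tibble::tibble(time = t, conc = one_compartment_iv(t, 100, 10, 0.1))
  res <- compute_nca(prof, dose = 100)
  expect_equal(res$t_half, log(2) / 0.1, tolerance = 0.01)
  expect_equal(res$auc_inf, 100 / 10 / 0.1 * 1000, tolerance = 0.01)
  expect_equal(res$cl_f, 1, tolerance = 0.01)     # ke * V = 1 L/h
  expect_equal(res$vz_f, 10, tolerance = 0.01)
  # iv one-compartment: MRT = 1/ke, Vss = CL * MRT = V
  expect_equal(res$mrt, 10, tolerance = 0.01)
  expect_equal(res$vss, 10, tolerance = 0.01)
  expect_equal(res$cmax, prof$conc[1])
})

test_that("Cmax and Tmax are the observed maximum", {
  prof <- tibble::tibble(time = c(0.25, 0.5, 1.0, 2, 4),
                         conc = c(20.1, 35.0, 46.25, 30.2, 12.4))
  res <- compute_nca(prof)
  expect_equal(res$cmax, 46.25)
  expect_equal(res$tmax, 1.0)
})

test_that("degenerate profiles are handled explicitly", {
  flat <- tibble::tibble(time = 1:5, conc = rep(3, 5))
  res <- compute_nca(flat)
  expect_true(is.na(res$lambda_z))
  expect_true(is.na(res$t_half))
  expect_equal(res$auc_last, 3 * 4) # c * (t_last - t_0)
  expect_error(compute_nca(tibble::tibble(time = 1:2, conc = c(1, 2))),
               "3 quantifiable")
})

test_that("linear trapezoid is exact on piecewise-linear profiles", {
  set.seed(3)
  for (k in 1:10) {
    tt <- sort(runif(8, 0, 10))
    a <- runif(1, 1, 5); b <- runif(1, 0.1, 2)
    prof <- tibble::tibble(time = tt, conc = a + b * tt)
    res <- compute_nca(prof)
    exact <- a * (max(tt) - min(tt)) + b / 2 * (max(tt)^2 - min(tt)^2)
    expect_equal(res$auc_last, exact, tolerance = 1e-12)
  }
})

test_that("post-Tmax censored points do not change the result", {
  t <- c(0.25, 0.5, 1, 2, 4, 8, 12)
  prof <- tibble::tibble(time = t, conc = one_compartment_iv(t, 1, 5, 0.5))
  base <- compute_nca(prof, dose = 1, lloq = 0.01)
  padded <- rbind(prof, tibble::tibble(time = c(18, 24), conc = c(0.004, 0)))
  res <- compute_nca(padded, dose = 1, lloq = 0.01)
  expect_equal(res, base)
})

test_that("renal clearance reconciles units and scales proportionally", {
  expect_equal(renal_clearance(1, 1000), 1000) # 1 L/h = 1000 mL/h
  expect_equal(renal_clearance(0.252, 2599), 2 * renal_clearance(0.126, 2599))
  expect_error(renal_clearance(0, 100), "positive")
  expect_error(renal_clearance(1, -5), "positive")
})

test_that("accumulation index matches the closed-form accumulation factor", {
  # one compartment, q8h, t1/2 = 2 h: R = 1 / (1 - 2^(-8/2))
  ke <- log(2) / 2
  tau <- 8
  t <- seq(0.01, tau, by = 0.01)
  day1 <- tibble::tibble(time = t, conc = 100 * exp(-ke * t))
  ss <- tibble::tibble(time = t,
                       conc = 100 * exp(-ke * t) / (1 - exp(-ke * tau)))
  n1 <- compute_nca(day1, tau = tau)
  nss <- compute_nca(ss, tau = tau)
  r <- accumulation_index(n1, nss)
  expect_equal(r, 1 / (1 - 2^(-4)), tolerance = 0.01)

  # identical profiles give exactly 1; linearity makes R >= 1
  expect_equal(accumulation_index(n1, n1), 1)
  expect_gte(r, 1)
  expect_error(accumulation_index(compute_nca(day1), nss), "auc_tau")
})

test_that("trough stationarity ANOVA matches the textbook formula", {
  # hand-computable 2 groups x 3 values
  troughs <- tibble::tibble(day = rep(c(3, 4), each = 3),
                            conc = c(0.70, 0.75, 0.65, 0.60, 0.66, 0.72))
  res <- trough_stationarity(troughs)
  g <- split(troughs$conc, troughs$day)
  means <- vapply(g, mean, numeric(1))
  grand <- mean(troughs$conc)
  ss_b <- sum(3 * (means - grand)^2)
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_hand <- (ss_b / 1) / (ss_w / 4)
  expect_equal(res$f_statistic, f_hand, tolerance = 1e-12)

  # all equal -> F = 0 and stationary
  same <- tibble::tibble(day = rep(1:3, each = 2), conc = 0.7)
  expect_equal(trough_stationarity(same)$f_statistic, 0)
  expect_true(trough_stationarity(same)$stationary)

  # identical means, within-day noise -> comfortably stationary
  eq <- tibble::tibble(day = rep(1:2, each = 3),
                       conc = c(0.6, 0.7, 0.8, 0.8, 0.7, 0.6))
  res_eq <- trough_stationarity(eq)
  expect_gt(res_eq$p_value, 0.9)
  expect_true(res_eq$stationary)
})
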