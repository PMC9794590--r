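test_that("study regimens encode the published dosing schedules", {
  regs <- build_study_regimens()
  expect_equal(nrow(regs$human_0p6), 14) # 1 + 3 x 4 + 1 doses
  expect_equal(unique(regs$human_0p6$amount), 25.5)
  expect_equal(unique(regs$human_1p0$amount), 42.5)
  expect_equal(regs$rat_po_100$amount, 6.06)
  expect_equal(regs$rat_iv$route, "iv_bolus")
  for (r in regs) {
    expect_true(all(r$time >= 0))
    expect_true(!is.unsorted(r$time))
    expect_gte(attr(r, "duration"), max(r$time))
  }
})

test_that("the assembled system conserves mass by construction", {
  d <- schaftoside_defaults()
  ind <- default_rat()
  m <- assemble_model(ind, d$compound, d$formulation_rat)

  # zero state -> zero derivative
  expect_equal(m$rhs(0, m$state0, m$params)[[1]],
               rep(0, length(m$state_names)))

  # any state: body losses appear in the cumulative sinks (row sums zero)
  set.seed(1)
  y <- stats::setNames(runif(length(m$state_names)), m$state_names)
  p <- m$params
  p$last_oral_time <- -0.5
  expect_equal(sum(m$rhs(1, y, p)[[1]]), 0, tolerance = 1e-12)
})

test_that("organs equilibrate to their partition coefficients", {
  ind <- default_rat()
  cmp <- single_clearance_compound(0) # no elimination at all
  form <- formulation("solution_iv")
  s <- schaftoside_defaults()$compound
  part <- partition_coefficients(s, ind) # non-trivial Kp set
  reg <- regimen(tibble::tibble(time = 0, route = "iv_bolus", amount = 1,
                                basis = "mg"), duration = 300)
  sim <- simulate_pbpk(ind, cmp, form, reg,
                       output_times = c(seq(0, 10, 1), seq(50, 300, 50)),
                       partition = part)
  oa <- sim$organ_amounts
  n <- nrow(oa)
  c_plasma <- sim$timecourse$conc[n] / 1000 # mg/L
  for (org in c("muscle", "adipose", "liver", "kidney", "brain")) {
    v <- ind$organs$volume[ind$organs$name == org]
    c_org <- oa[[org]][n] / v
    expect_equal(c_org / c_plasma, part$kp[part$name == org],
                 tolerance = 1e-3)
  }
  # nothing eliminated
  expect_equal(sim$timecourse$urine_mg[n], 0)
  expect_equal(sim$timecourse$bile_mg[n], 0)
})

test_that("mass balance holds at every output time for every regimen", {
  d <- schaftoside_defaults()
  rat <- default_rat()
  hum <- default_human()
  regs <- build_study_regimens()
  for (nm in c("rat_iv", "rat_po_100")) {
    sim <- simulate_pbpk(rat, d$compound, d$formulation_rat, regs[[nm]],
                         output_times = seq(0, attr(regs[[nm]], "duration"),
                                            by = 0.25))
    expect_lt(max(abs(sim$timecourse$balance_error)), 1e-6)
  }
  for (nm in c("human_0p6", "human_1p0_single")) {
    sim <- simulate_pbpk(hum, d$compound, d$formulation_human, regs[[nm]],
                         output_times = seq(0, attr(regs[[nm]], "duration"),
                                            by = 0.5))
    expect_lt(max(abs(sim$timecourse$balance_error)), 1e-6)
  }
})

test_that("the linear model is dose-proportional and superposable", {
  d <- schaftoside_defaults()
  hum <- default_human()
  times <- seq(0, 48, by = 0.1)
  reg1 <- regimen(tibble::tibble(time = c(0, 8, 16), route = "oral",
                                 amount = 25.5, basis = "mg"), duration = 48)
  reg2 <- regimen(tibble::tibble(time = c(0, 8, 16), route = "oral",
                                 amount = 51.0, basis = "mg"), duration = 48)
  s1 <- simulate_pbpk(hum, d$compound, d$formulation_human, reg1,
                      output_times = times)
  s2 <- simulate_pbpk(hum, d$compound, d$formulation_human, reg2,
                      output_times = times)
  expect_equal(s2$timecourse$conc, 2 * s1$timecourse$conc,
               tolerance = 1e-6)

  # superposition: multiple-dose curve = sum of time-shifted single doses
  single <- simulate_pbpk(hum, d$compound, d$formulation_human,
                          regimen(tibble::tibble(time = 0, route = "oral",
                                                 amount = 25.5,
                                                 basis = "mg"),
                                  duration = 48),
                          output_times = times)
  f <- stats::approxfun(single$timecourse$time, single$timecourse$conc,
                        yleft = 0, rule = 2)
  super <- f(times) + ifelse(times >= 8, f(pmax(times - 8, 0)), 0) +
    ifelse(times >= 16, f(pmax(times - 16, 0)), 0)
  keep <- times > 16.5 # past the last dose discontinuity
  expect_equal(s1$timecourse$conc[keep][super[keep] > 1e-6],
               super[keep][super[keep] > 1e-6], tolerance = 1e-3)
})

test_that("uniform-Kp reduction matches the one-compartment closed form", {
  ind <- default_rat()
  cl <- 0.005 / 60 / ind$weight # 0.005 L/h total, as L/min/kg
  cmp <- single_clearance_compound(cl)
  part <- uniform_partition(ind, kp = 1, bp = 1)
  reg <- regimen(tibble::tibble(time = 0, route = "iv_bolus", amount = 1,
                                basis = "mg"), duration = 30)
  sim <- simulate_pbpk(ind, cmp, formulation("solution_iv"), reg,
                       output_times = seq(0, 30, 0.25), partition = part)
  v_tot <- sum(ind$organs$volume)
  tc <- sim$timecourse
  keep <- tc$time >= 1 # past the initial mixing transient
  expected <- 1 / v_tot * 1000 * exp(-0.005 * tc$time[keep] / v_tot)
  expect_equal(tc$conc[keep], expected, tolerance = 0.01)
})

test_that("excretion fractions report terminal cumulative amounts", {
  ind <- default_rat()
  # single renal route run long enough for complete elimination
  cmp <- single_clearance_compound(0.01)
  part <- uniform_partition(ind, kp = 1, bp = 1)
  reg <- regimen(tibble::tibble(time = 0, route = "iv_bolus", amount = 1,
                                basis = "mg"), duration = 48)
  sim <- simulate_pbpk(ind, cmp, formulation("solution_iv"), reg,
                       output_times = seq(0, 48, 0.25), partition = part)
  exc <- cumulative_excretion_fractions(sim)
  expect_gte(exc$urine_fraction, 0.99)
  expect_equal(exc$bile_fraction, 0)

  # zero clearance -> nothing excreted
  sim0 <- simulate_pbpk(ind, single_clearance_compound(0),
                        formulation("solution_iv"), reg,
                        output_times = seq(0, 48, 1), partition = part)
  exc0 <- cumulative_excretion_fractions(sim0)
  expect_equal(exc0$urine_fraction, 0)
  expect_equal(exc0$bile_fraction, 0)
})

test_that("simulated renal clearance is self-consistent with its input", {
  # low-extraction probe: Ae/AUC recovers the renal plasma clearance input
  ind <- default_rat()
  d <- schaftoside_defaults()
  cmp <- d$compound
  cmp$kidney_plasma_clearance <- 2.57e-4 # small: negligible renal extraction
  cmp$biliary_plasma_clearance <- 0
  cmp$residual_plasma_clearance <- 0
  reg <- regimen(tibble::tibble(time = 0, route = "iv_bolus", amount = 1.2,
                                basis = "mg_per_kg"), duration = 48)
  sim <- simulate_pbpk(ind, cmp, d$formulation_rat, reg,
                       output_times = seq(0, 48, 0.05))
  tc <- sim$timecourse
  ae <- tc$urine_mg[nrow(tc)]
  auc <- sum(diff(tc$time) * (head(tc$conc, -1) + tail(tc$conc, -1)) / 2)
  clr_mlh <- renal_clearance(ae, auc)
  cl_input_mlh <- 2.57e-4 * 60 * ind$weight * 1000
  expect_equal(clr_mlh, cl_input_mlh, tolerance = 0.02)
})
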