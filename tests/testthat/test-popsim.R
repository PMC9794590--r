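test_that("zero-variability populations collapse onto the individual", {
  cal <- cal_human()
  spec <- population_spec(n = 3, fraction_male = 1, age_range = c(28, 28),
                          variability = list(volume = 0, flow = 0,
                                             clearance = 0, fu = 0),
                          seed = 5)
  reg <- single_dose_regimen(25.5, duration = 24)
  pop <- simulate_population(spec, cal$individual, cal$compound,
                             cal$formulation, reg,
                             output_times = seq(0, 24, 0.1),
                             kp_scale = cal$kp_scale)
  expect_equal(pop$band$p2.5, pop$band$p97.5)
  expect_equal(pop$band$p2.5, pop$band$mean)
  # equal to the single-individual simulation (same demographics)
  base <- build_reference_individual("human", 28, "male",
                                     cal$individual$weight,
                                     cal$individual$height)
  base$absorption_area_m2 <- cal$individual$absorption_area_m2
  sim <- simulate_pbpk(base, cal$compound, cal$formulation, reg,
                       output_times = seq(0, 24, 0.1),
                       kp_scale = cal$kp_scale)
  expect_equal(pop$band$mean, sim$timecourse$conc, tolerance = 1e-10)
  expect_equal(unique(pop$parameters$cmax_day1), max(sim$timecourse$conc))
})

test_that("population mean exposure is dose-linear across regimens", {
  cal <- cal_human()
  spec <- population_spec(n = 5, seed = 9)
  r06 <- single_dose_regimen(25.5, duration = 24)
  r10 <- single_dose_regimen(42.5, duration = 24)
  p06 <- simulate_population(spec, cal$individual, cal$compound,
                             cal$formulation, r06,
                             output_times = seq(0, 24, 0.2),
                             kp_scale = cal$kp_scale)
  p10 <- simulate_population(spec, cal$individual, cal$compound,
                             cal$formulation, r10,
                             output_times = seq(0, 24, 0.2),
                             kp_scale = cal$kp_scale)
  ratio <- mean(p10$parameters$cmax_day1) / mean(p06$parameters$cmax_day1)
  expect_equal(round(ratio, 2), 1.67)
  cmp <- compare_populations(p06, p10)
  expect_equal(cmp$ratio[cmp$parameter == "auc" & cmp$day == 1], 42.5 / 25.5,
               tolerance = 1e-6)
})

test_that("renal impairment raises day-6 exposure more than 5-fold", {
  cal <- cal_human()
  reg <- build_study_regimens()$human_0p6
  times <- seq(0, 144, 0.25)
  spec_h <- population_spec(n = 6, seed = 21, ckd_stage = "healthy")
  spec_5 <- population_spec(n = 6, seed = 21, ckd_stage = "CKD5")
  pop_h <- simulate_population(spec_h, cal$individual, cal$compound,
                               cal$formulation, reg, output_times = times,
                               kp_scale = cal$kp_scale)
  pop_5 <- simulate_population(spec_5, cal$individual, cal$compound,
                               cal$formulation, reg, output_times = times,
                               kp_scale = cal$kp_scale)
  cmp <- compare_populations(pop_h, pop_5)
  auc6_ratio <- cmp$ratio[cmp$parameter == "auc" & cmp$day == 6]
  expect_gt(auc6_ratio, 5)
  # identical populations compare as unity
  self <- compare_populations(pop_h, pop_h)
  expect_true(all(abs(self$ratio - 1) < 1e-12))
  expect_true(all(abs(self$fold_increase) < 1e-12))

  s <- population_summary(pop_5)
  expect_true(all(s$p2.5 <= s$p97.5 + 1e-12, na.rm = TRUE))
  g <- glance(pop_5)
  expect_equal(g$r_auc, s$mean[s$parameter == "r_auc"])
})

test_that("published-table ratio arithmetic helpers", {
  expect_equal(round(pk_day_ratio(20.64, 2.52), 2), 8.19)
  expect_equal(round(pk_fold_increase(433.77, 18.25), 2), 22.77)
  expect_error(pk_day_ratio(-1, 2), "positive")
})
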