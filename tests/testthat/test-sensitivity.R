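hum_inputs <- function() {
  cal <- cal_human()
  list(ind = cal$individual, cmp = cal$compound, form = cal$formulation,
       reg = single_dose_regimen(25.5, duration = 24),
       kp = cal$kp_scale, times = seq(0, 24, by = 0.05))
}

test_that("sensitivity coefficients behave on known limits", {
  m <- hum_inputs()
  res <- local_sensitivity(
    m$ind, m$cmp, m$form, m$reg,
    parameters = c("dose", "individual.large_intestinal_transit_time",
                   "compound.kidney_plasma_clearance"),
    perturbation = 0.05, metrics = c("cmax_day1", "auc_day1"),
    kp_scale = m$kp, output_times = m$times)

  # dose scales the linear model exactly: S = +1
  s_dose <- res$s[res$parameter == "dose"]
  expect_equal(s_dose, c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)

  # large-intestinal transit does not feed absorption: S = 0
  s_li <- res$s[res$parameter == "individual.large_intestinal_transit_time"]
  expect_equal(s_li, c(0, 0), tolerance = 1e-3, ignore_attr = TRUE)

  # AUC = Dose / CL when elimination acts on the sampled plasma pool:
  # S of AUC w.r.t. that clearance = -1 (analytic oracle)
  rat <- default_rat()
  probe <- compound(name = "probe", mwt = 400, logp = 0, fu = 1,
                    intestinal_permeability = 1e-4,
                    residual_plasma_clearance = 0.2 / 60 / rat$weight)
  poreg <- regimen(tibble::tibble(time = 0, route = "oral", amount = 1,
                                  basis = "mg"), duration = 24)
  s_probe <- local_sensitivity(rat, probe,
                               formulation("suspension", t50 = 1, shape = 1),
                               poreg,
                               parameters = "compound.residual_plasma_clearance",
                               perturbation = 0.05, metrics = "auc_day1",
                               output_times = seq(0, 24, 0.05))
  expect_equal(s_probe$s, -1, tolerance = 0.01)

  # renal clearance on the whole-body model: -1 up to renal extraction
  s_cl <- res$s[res$parameter == "compound.kidney_plasma_clearance" &
                  res$metric == "auc_day1"]
  expect_lt(s_cl, -0.85)
  expect_gt(s_cl, -1.01)

  expect_error(local_sensitivity(m$ind, m$cmp, m$form, m$reg,
                                 parameters = "compound.bogus",
                                 output_times = m$times),
               "valid paths")
})

test_that("central differences converge as the perturbation shrinks", {
  m <- hum_inputs()
  s_at <- function(delta) {
    local_sensitivity(m$ind, m$cmp, m$form, m$reg,
                      parameters = "compound.kidney_plasma_clearance",
                      perturbation = delta, metrics = "auc_day1",
                      kp_scale = m$kp, output_times = m$times)$s
  }
  s10 <- s_at(0.10)
  s01 <- s_at(0.01)
  expect_lt(abs(s10 - s01) / abs(s01), 0.05)
})

test_that("clearance and protein binding rank among the key parameters", {
  m <- hum_inputs()
  panel <- c("compound.fu", "compound.kidney_plasma_clearance",
             "compound.intestinal_permeability", "compound.logp",
             "compound.acidic_pka", "compound.solubility_ph7",
             "formulation.t50", "formulation.shape",
             "individual.kidney_volume", "individual.gastric_emptying_time",
             "individual.small_intestinal_transit_time",
             "individual.large_intestinal_transit_time")
  res <- local_sensitivity(m$ind, m$cmp, m$form, m$reg, parameters = panel,
                           perturbation = 0.1, metrics = "auc_day1",
                           kp_scale = m$kp, output_times = m$times)
  ranked <- rank_parameters(res)
  top4 <- ranked$parameter[ranked$rank <= 4]
  expect_true("compound.kidney_plasma_clearance" %in% top4)
  expect_true("compound.fu" %in% top4)
})

test_that("ranking orders by absolute sensitivity", {
  res <- tibble::tibble(parameter = c("a", "b", "c"),
                        metric = "auc_day1", s = c(0.5, -1.0, 0.1),
                        perturbation = 0.1, baseline = 1)
  ranked <- rank_parameters(res)
  expect_equal(ranked$parameter[ranked$rank == 1], "b")
  single <- rank_parameters(res[1, ])
  expect_equal(single$parameter, "a")
  expect_equal(single$rank, 1L)
})
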