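test_that("reference individuals satisfy anatomical and flow invariants", {
  h <- default_human()
  expect_s3_class(h, "pbpk_individual")
  expect_identical(h$ckd_stage, "healthy")
  expect_equal(h$gfr, 110.57)
  expect_equal(h$fu_multiplier, 1)
  perf <- h$organs$name != "lung" &
    !h$organs$name %in% c("arterial_blood", "venous_blood")
  expect_equal(sum(h$organs$blood_flow[perf]), h$cardiac_output,
               tolerance = 1e-9)

  # anatomical closure: total organ volume ~ body weight / tissue density
  r <- default_rat(0.21)
  expect_equal(sum(r$organs$volume), r$weight / 1.05, tolerance = 0.15)

  # linear rescaling: doubling body weight doubles every organ volume
  h2 <- build_reference_individual("human", 28, "male", 112.70, 162.1)
  expect_equal(h2$organs$volume, 2 * h$organs$volume, tolerance = 1e-12)

  expect_error(build_reference_individual("human", 28, "male", -1),
               "positive")
  expect_error(build_reference_individual("dog", 5, "male", 10))
})

test_that("ageing adjustments reduce cardiac output, GFR and muscle", {
  young <- build_reference_individual("human", 28, "male", 70)
  old <- build_reference_individual("human", 75, "male", 70)
  expect_lt(old$cardiac_output, young$cardiac_output)
  expect_equal(old$gfr, 110.57 - 0.8 * 35)
  v <- function(ind, org) ind$organs$volume[ind$organs$name == org]
  expect_lt(v(old, "muscle"), v(young, "muscle"))
  expect_gt(v(old, "adipose"), v(young, "adipose"))
  # volume shifted, not lost
  expect_equal(sum(old$organs$volume), sum(young$organs$volume),
               tolerance = 1e-12)
})

test_that("CKD scaling applies the packaged stage fractions", {
  tbl <- ckd_scaling()
  expect_identical(tbl$stage, c("CKD3", "CKD4", "CKD5"))
  s5 <- ckd_scaling("CKD5")
  expect_equal(s5$kidney_volume_fraction, 0.51)
  expect_equal(s5$renal_perfusion_fraction, 0.29)
  expect_equal(s5$fu_fraction, 1.55)
  expect_equal(s5$gastric_emptying_fraction, 1.60)
  expect_equal(s5$small_intestinal_transit_fraction, 1.40)
  expect_equal(s5$large_intestinal_transit_fraction, 1.00)

  h <- default_human()
  kv <- function(ind) ind$organs$volume[ind$organs$name == "kidney"]
  sick <- apply_ckd_stage(h, s5)
  expect_equal(sick$gfr, 15)
  expect_equal(kv(sick), kv(h) * 0.51)
  expect_equal(sick$fu_multiplier, 1.55)

  s3 <- ckd_scaling("CKD3")
  mild <- apply_ckd_stage(h, s3)
  expect_equal(mild$gastric_emptying_time, h$gastric_emptying_time)

  # identity scaling returns the input field-by-field
  ident <- list(stage = "healthy", gfr_target = h$gfr,
                kidney_volume_fraction = 1, renal_perfusion_fraction = 1,
                fu_fraction = 1, gastric_emptying_fraction = 1,
                small_intestinal_transit_fraction = 1,
                large_intestinal_transit_fraction = 1)
  same <- apply_ckd_stage(h, ident)
  same$ckd_stage <- "healthy"
  expect_equal(same, h, tolerance = 1e-15)

  # inverse multipliers restore the baseline
  inv <- list(stage = "healthy", gfr_target = h$gfr,
              kidney_volume_fraction = 1 / 0.51,
              renal_perfusion_fraction = 1 / 0.29,
              fu_fraction = 1 / 1.55, gastric_emptying_fraction = 1 / 1.60,
              small_intestinal_transit_fraction = 1 / 1.40,
              large_intestinal_transit_fraction = 1)
  sick$ckd_stage <- "healthy" # permit re-scaling for the inverse round trip
  back <- apply_ckd_stage(sick, inv)
  expect_equal(kv(back), kv(h), tolerance = 1e-12)
  expect_equal(back$fu_multiplier, 1, tolerance = 1e-12)
  expect_equal(back$gastric_emptying_time, h$gastric_emptying_time,
               tolerance = 1e-12)

  expect_error(apply_ckd_stage(default_rat(), s5), "human")
  expect_error(apply_ckd_stage(apply_ckd_stage(h, s3), s5), "twice")
})

test_that("population sampling is seeded, positive and has the requested CV", {
  base <- default_human()
  spec0 <- population_spec(n = 4, variability = list(volume = 0, flow = 0,
                                                     clearance = 0, fu = 0),
                           age_range = c(30, 30), fraction_male = 1,
                           seed = 7)
  pop0 <- sample_population(spec0, base)
  expect_length(pop0, 4)
  # zero CV: all individuals identical demographic-only variants
  for (ind in pop0[-1]) expect_equal(ind, pop0[[1]])
  expect_equal(pop0[[1]]$clearance_multiplier, 1)

  spec <- population_spec(n = 100, variability = list(clearance = 0.2),
                          seed = 11)
  pop_a <- sample_population(spec, base)
  pop_b <- sample_population(spec, base)
  expect_equal(pop_a, pop_b) # determinism under the seed

  cl <- vapply(pop_a, function(x) x$clearance_multiplier, numeric(1))
  expect_true(all(cl > 0))
  expect_gt(stats::sd(cl) / mean(cl), 0.14)
  expect_lt(stats::sd(cl) / mean(cl), 0.26)
  expect_true(all(vapply(pop_a, function(x) all(x$organs$volume > 0),
                         logical(1))))
  tbl <- population_table(pop_a)
  expect_equal(nrow(tbl), 100)
  expect_true(all(tbl$age >= 18 & tbl$age <= 40))
})
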