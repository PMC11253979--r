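test_that("loop-diuretic schedule follows the light/dark inhibition split", {
  ld <- intervention_spec("loop_diuretic", efficacy = 0.5)
  expect_equal(unname(loop_diuretic_modifiers(ld, 14)), 1 - 0.5 * 0.8)
  expect_equal(unname(loop_diuretic_modifiers(ld, 2)), 1 - 0.5 * 0.7)
  expect_equal(unname(loop_diuretic_modifiers(ld, 11.99)), 1 - 0.5 * 0.7)
  expect_equal(unname(loop_diuretic_modifiers(ld, 12)), 1 - 0.5 * 0.8)
  expect_named(loop_diuretic_modifiers(ld, 0), "NKCC2")
  # zero efficacy leaves the model untouched
  ld0 <- intervention_spec("loop_diuretic", efficacy = 1e-12)
  expect_error(intervention_spec("loop_diuretic", efficacy = 1.5), "efficacy")
  model <- test_model()
  s0 <- simulate_kidney(model, "male", 14)
  s1 <- simulate_kidney(model, "male", 14, ld0)
  expect_equal(s1$segments$na_active, s0$segments$na_active,
               tolerance = 1e-9)
})

test_that("full ENaC inhibition zeroes distal active transport", {
  en <- intervention_spec("enac_inhibition")
  expect_equal(unname(enac_inhibition_modifiers(en)), 0)
  model <- test_model()
  for (sex in c("male", "female")) for (zt in c(0, 12)) {
    st <- simulate_kidney(model, sex, zt, en)
    distal <- st$segments$id %in% c("CNT", "CCD", "OMCD", "IMCD")
    expect_equal(st$segments$na_active[distal], rep(0, 4))
    # urine then carries the whole CNT delivery
    expect_equal(st$urine_na, st$segments$na_in[st$segments$id == "CNT"])
  }
  half <- intervention_spec("enac_inhibition", enac_inhibition = 0.5)
  expect_equal(unname(enac_inhibition_modifiers(half)), 0.5)
})

test_that("null intervention comparisons report zero fractional change", {
  model <- test_model()
  cmp <- compare_scenarios(model, "male", 14, intervention_spec("none"))
  expect_equal(cmp$fractional_change, rep(0, nrow(cmp)))
  expect_error(compare_scenarios(model, "male", 14,
                                 intervention_spec("loop_diuretic"),
                                 metrics = "unknown_metric"))
})

test_that("loop diuretics lower medullary QO2, raise pO2 and urine output", {
  model <- test_model()
  ld <- intervention_spec("loop_diuretic")
  for (sex in c("male", "female")) for (zt in c(2, 6, 14, 20)) {
    cmp <- compare_scenarios(model, sex, zt, ld)
    fc <- setNames(cmp$fractional_change, cmp$metric)
    expect_lt(fc["medullary_qo2"], 0)
    expect_gt(fc["medullary_po2"], 0)
    expect_gt(fc["urine_na"], 0)
    expect_gt(fc["urine_v"], 0)
  }
})

test_that("stronger inhibition monotonically deepens the diuretic response", {
  model <- test_model()
  effs <- c(0.2, 0.4, 0.6, 0.8)
  qo2 <- po2v <- numeric(length(effs))
  for (i in seq_along(effs)) {
    ld <- intervention_spec("loop_diuretic", efficacy = effs[i])
    qo2[i] <- medullary_qo2(model, "female", 14, ld)
    po2v[i] <- po2(model, "female", 14, ld)
  }
  expect_true(all(diff(qo2) < 0))
  expect_true(all(diff(po2v) > 0))
})

test_that("alpha stays at its control calibration under intervention", {
  model <- test_model()
  ld <- intervention_spec("loop_diuretic")
  a_before <- model$alpha$male
  invisible(compare_scenarios(model, "male", 14, ld))
  expect_identical(model$alpha$male, a_before)
  # treated pO2 uses the control alpha: difference equals dQ/alpha
  dq <- medullary_qo2(model, "male", 14) -
    medullary_qo2(model, "male", 14, ld)
  expect_equal(po2(model, "male", 14, ld) - po2(model, "male", 14),
               dq / a_before, tolerance = 1e-12)
})

test_that("males show the larger fractional ENaC response at ZT0 and ZT12", {
  model <- test_model()
  en <- intervention_spec("enac_inhibition")
  resp <- function(sex, zt) {
    cmp <- compare_scenarios(model, sex, zt, en,
                             metrics = c("urine_na", "urine_v"))
    setNames(cmp$fractional_change, cmp$metric)
  }
  for (zt in c(0, 12)) {
    expect_gt(resp("male", zt)["urine_na"], resp("female", zt)["urine_na"])
    expect_gt(resp("male", zt)["urine_v"], resp("female", zt)["urine_v"])
  }
})

test_that("comparison CSV export is tidy and deterministic", {
  model <- test_model()
  ld <- intervention_spec("loop_diuretic")
  cmp <- compare_scenarios(model, "female", 2, ld)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, f1)
  write_comparison_csv(compare_scenarios(model, "female", 2, ld), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read.csv(f1, comment.char = "#")
  expect_equal(names(back),
               c("sex", "zt", "intervention", "metric", "control", "treated",
                 "fractional_change"))
})
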