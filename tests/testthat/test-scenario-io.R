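test_that("an empty configuration yields the full default scenario", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_setequal(cfg$sexes, c("male", "female"))
  expect_equal(cfg$zt, c(2, 6, 14, 18))
  expect_null(cfg$intervention)
  expect_identical(load_config(NULL)$zt, cfg$zt)
})

test_that("unknown keys and invalid overrides are hard errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", f)
  expect_error(load_config(f), "unknown config key")
  writeLines("drivers:\n  NKCC2:\n    wrong_field: 2", f)
  expect_error(load_config(f), "unknown driver override")
  writeLines("oxygenation:\n  bogus: 1", f)
  expect_error(load_config(f), "unknown oxygenation override")
  writeLines("zt: [25]", f)
  expect_error(load_config(f), "zt")
  # an amplitude >= 1 passes parsing but is rejected by the constructor
  writeLines("drivers:\n  NKCC2:\n    amplitude_frac: 1.2", f)
  expect_error(model_from_config(load_config(f)), "amplitude")
})

test_that("oxygenation overrides propagate into the alpha calibration", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("oxygenation:\n  mean_po2_ref: 25", f)
  model <- model_from_config(load_config(f))
  for (sex in c("male", "female")) {
    expect_equal(mean(po2(model, sex, hourly_grid())), 25, tolerance = 1e-9)
  }
})

test_that("fixtures are reproducible and valid", {
  a <- generate_fixtures(11, n_params = 5, n_registries = 1)
  b <- generate_fixtures(11, n_params = 5, n_registries = 1)
  c <- generate_fixtures(12, n_params = 5, n_registries = 1)
  expect_identical(a$vectors, b$vectors)
  expect_false(identical(a$vectors, c$vectors))
  bounds <- param_bounds()
  for (v in a$vectors) {
    expect_true(all(v >= bounds$lower & v <= bounds$upper))
    expect_silent(vector_to_params(v))
  }
  expect_identical(a$registries[[1]]$target, b$registries[[1]]$target)
})

test_that("the CLI simulate subcommand writes deterministic artifacts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  code <- run_cli(c("simulate", "--sex", "male", "--zt", "14",
                    "--out-dir", d1))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(d1, "kidney_state.csv")))
  expect_true(file.exists(file.path(d1, "oxygen_budget.csv")))
  expect_true(file.exists(file.path(d1, "run_log.txt")))
  run_cli(c("simulate", "--sex", "male", "--zt", "14", "--out-dir", d2))
  expect_identical(readLines(file.path(d1, "kidney_state.csv")),
                   readLines(file.path(d2, "kidney_state.csv")))
  expect_identical(readLines(file.path(d1, "oxygen_budget.csv")),
                   readLines(file.path(d2, "oxygen_budget.csv")))
})

test_that("the CLI compare subcommand writes the comparison schema", {
  d <- withr::local_tempdir()
  code <- run_cli(c("compare", "--intervention", "loop-diuretic",
                    "--zt", "2", "--zt", "14", "--out-dir", d))
  expect_equal(code, 0L)
  cmp <- read.csv(file.path(d, "comparison.csv"), comment.char = "#")
  expect_setequal(unique(cmp$sex), c("male", "female"))
  expect_setequal(unique(cmp$zt), c(2, 14))
  expect_true(all(c("metric", "control", "treated", "fractional_change")
                  %in% names(cmp)))
})

test_that("CLI errors exit non-zero with a message", {
  expect_message(code <- run_cli(c("frobnicate")), "unknown subcommand")
  expect_equal(code, 1L)
  expect_message(code <- run_cli(character(0)), "usage")
  expect_equal(code, 1L)
  expect_message(code <- run_cli(c("compare", "--zt", "2")), "intervention")
  expect_equal(code, 1L)
})
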