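test_that("active oxygen consumption is tna/15 and basal is a third of it", {
  expect_equal(qo2_active(15), 1)
  expect_equal(qo2_active(0), 0)
  expect_equal(qo2_active(c(30, 45)), c(2, 3))
  expect_error(qo2_active(-1), "non-negative")
  expect_equal(basal_allocation(3), 1)
  expect_error(basal_allocation(NULL), "baseline")
  # basal share override: 30% basal means basal = (0.3/0.7) active*
  expect_equal(basal_allocation(7, basal_frac = 0.3), 3)
})

test_that("whole-kidney basal share is exactly 25% under baseline drivers", {
  for (model in list(init_model(), test_model())) {
    for (sex in c("male", "female")) {
      base <- baseline_reference(model, sex)
      tot <- sum(base$qo2_active_star + base$qo2_basal)
      expect_equal(sum(base$qo2_basal) / tot, 0.25, tolerance = 1e-12)
    }
  }
})

test_that("basal allocation is time-invariant off baseline", {
  model <- test_model()
  b2 <- kidney_oxygen(model, simulate_kidney(model, "male", 2))
  b14 <- kidney_oxygen(model, simulate_kidney(model, "male", 14))
  expect_equal(b2$segments$qo2_basal, b14$segments$qo2_basal)
  expect_false(isTRUE(all.equal(b2$segments$qo2_active,
                                b14$segments$qo2_active)))
})

test_that("efficiency follows its defining ratio and known limits", {
  expect_equal(efficiency(15, 1), 15)
  # at baseline with the 25% basal share: 15 * 0.75 = 11.25
  expect_equal(efficiency(15, 1 + 1 / 3), 11.25)
  expect_error(efficiency(10, 0), "positive")
  # passive transport raises efficiency at fixed oxygen cost
  expect_gt(efficiency(20, 1.2), efficiency(15, 1.2))
  model <- test_model()
  ox <- kidney_oxygen(model, simulate_kidney(model, "male", 2))
  reg <- ox$regions
  expect_equal(reg$efficiency, reg$na_total / reg$qo2_total)
})

test_that("oxygen budget aggregates exactly and matches Eq-level recompute", {
  model <- test_model()
  for (sex in c("male", "female")) {
    st <- simulate_kidney(model, sex, 14)
    ox <- kidney_oxygen(model, st)
    segs <- ox$segments
    expect_equal(segs$qo2_total, segs$qo2_active + segs$qo2_basal)
    # independent recompute from the state and the baseline reference
    base <- baseline_reference(model, sex)
    expect_equal(segs$qo2_active, st$segments$na_active / 15)
    expect_equal(segs$qo2_basal, (0.25 / 0.75) * base$na_active / 15)
    reg <- ox$regions
    expect_equal(reg$qo2_total[reg$region == "whole"],
                 reg$qo2_total[reg$region == "cortex"] +
                   reg$qo2_total[reg$region == "medulla"])
  }
})

test_that("proximal tubule transports Na+ more efficiently than TAL and DT", {
  model <- test_model()
  for (sex in c("male", "female")) for (zt in c(2, 14)) {
    ox <- kidney_oxygen(model, simulate_kidney(model, sex, zt))
    segs <- ox$segments
    eff_grp <- function(ids) {
      idx <- segs$id %in% ids
      sum(segs$na_total[idx]) / sum(segs$qo2_total[idx])
    }
    pt <- eff_grp(c("PCT", "PST"))
    expect_gt(pt, eff_grp(c("mTAL", "cTAL")))
    expect_gt(pt, eff_grp(c("DCT", "CNT", "CCD", "OMCD", "IMCD")))
  }
})

test_that("whole-kidney efficiency is nearly flat across the day", {
  model <- test_model()
  for (sex in c("male", "female")) {
    eff <- vapply(c(2, 14), function(zt) {
      ox <- kidney_oxygen(model, simulate_kidney(model, sex, zt))
      ox$regions$efficiency[ox$regions$region == "whole"]
    }, 0)
    expect_lt(abs(eff[2] / eff[1] - 1), 0.05)
  }
})

test_that("oxygen budget CSV export carries units and all levels", {
  model <- test_model()
  f <- withr::local_tempfile(fileext = ".csv")
  ox <- kidney_oxygen(model, simulate_kidney(model, "female", 6))
  write_oxygen_csv(ox, f)
  expect_match(readLines(f, n = 1), "umol O2/min")
  back <- read.csv(f, comment.char = "#")
  expect_setequal(unique(back$level), c("segment", "region"))
})
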