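test_that("single-segment arithmetic follows the fraction/clip rules", {
  pp <- default_segment_params("male")
  row <- pp[pp$id == "PCT", ]
  row$f_active <- 0.5
  row$f_passive <- 0.2
  st <- step_segment(row, na_in = 100, v_in = 700, m = 1)
  expect_equal(st$na_active, 50)
  expect_equal(st$na_passive, 20)
  expect_equal(st$na_out, 30)
  # clipping: passive takes precedence, active truncated
  row$f_active <- 0.9
  row$f_passive <- 0.09
  row$beta <- 1
  st <- step_segment(row, na_in = 100, v_in = 700, m = 1.4)
  expect_equal(st$na_active + st$na_passive, 99.5)
  expect_equal(st$na_passive, 9)
  # zero activity kills active transport when beta > 0
  row$beta <- 0.5
  st <- step_segment(row, na_in = 100, v_in = 700, m = 0)
  expect_equal(st$na_active, 0)
  expect_error(step_segment(row, na_in = -1, v_in = 0, m = 1), "negative")
})

test_that("chain solver agrees with segment-by-segment application", {
  fx <- test_fixtures()
  for (vec in fx$vectors[1:6]) {
    model <- kidney_model(vector_to_params(vec), alpha = FALSE)
    for (sex in c("male", "female")) {
      st <- simulate_kidney(model, sex, 14.5)
      oracle <- oracle_resum(model, sex, 14.5)
      expect_equal(st$urine_na, unname(oracle$urine["na"]), tolerance = 1e-12)
      expect_equal(sum(st$segments$na_active + st$segments$na_passive),
                   unname(oracle$reabsorbed["na"]), tolerance = 1e-12)
    }
  }
})

test_that("sodium and volume are conserved on random parameter sets", {
  fx <- test_fixtures(seed = 99, n_params = 200, n_registries = 0)
  zts <- rep(c(1.5, 6, 14, 22), length.out = length(fx$vectors))
  sexes <- rep(c("male", "female"), length.out = length(fx$vectors))
  ld <- intervention_spec("loop_diuretic", efficacy = 0.5)
  for (i in seq_along(fx$vectors)) {
    model <- kidney_model(vector_to_params(fx$vectors[[i]]), alpha = FALSE)
    interv <- if (i %% 3 == 0) ld else NULL
    st <- simulate_kidney(model, sexes[i], zts[i], interv)
    segs <- st$segments
    expect_lt(abs(sum(segs$na_active + segs$na_passive) + st$urine_na -
                    st$filtered_na) / st$filtered_na, 1e-9)
    expect_lt(abs(sum(segs$v_reab) + st$urine_v - st$filtered_v) /
                st$filtered_v, 1e-9)
    expect_true(all(segs$na_out >= 0))
    expect_true(all(segs$v_out >= 0))
    expect_true(all(segs$na_active >= 0))
  }
})

test_that("transport is flow-proportional at mean drivers (pre-clipping)", {
  model <- init_model()
  sc2 <- kidney_scale(nephrons_per_kidney = 36000 * 1.7)
  model2 <- kidney_model(
    list(male = default_segment_params("male"),
         female = default_segment_params("female"), eps = 0.3),
    scale = sc2, alpha = FALSE)
  flat_model <- function(m) {
    m$drivers <- lapply(m$drivers, renalclock:::flat_drivers)
    m
  }
  s1 <- simulate_kidney(flat_model(model), "male", 8)
  s2 <- simulate_kidney(flat_model(model2), "male", 8)
  expect_equal(s2$segments$na_active, s1$segments$na_active * 1.7,
               tolerance = 1e-12)
  expect_equal(s2$segments$na_passive, s1$segments$na_passive * 1.7,
               tolerance = 1e-12)
  expect_equal(s2$urine_na, s1$urine_na * 1.7, tolerance = 1e-12)
})

test_that("raising a driver raises its segments' transport, lowers delivery", {
  base <- test_model()
  up <- base
  for (sex in c("male", "female")) {
    d <- up$drivers[[sex]]$NKCC2
    up$drivers[[sex]]$NKCC2 <- driver_spec("NKCC2", d$mean * 1.2,
                                           d$amplitude_frac, d$peak_zt)
  }
  for (zt in c(2, 14)) {
    s0 <- simulate_kidney(base, "male", zt)$segments
    s1 <- simulate_kidney(up, "male", zt)$segments
    # the first NKCC2-linked segment sees the same delivery and must gain
    expect_gte(s1$na_active[s0$id == "mTAL"], s0$na_active[s0$id == "mTAL"])
    # all downstream deliveries weakly decrease
    for (id in c("cTAL", "DCT", "CNT", "IMCD")) {
      expect_lte(s1$na_in[s0$id == id], s0$na_in[s0$id == id])
    }
  }
  # at fixed delivery the per-segment response is monotone in activity
  row <- base$params$male[base$params$male$id == "mTAL", ]
  acts <- vapply(c(0.5, 0.8, 1, 1.3, 1.6),
                 function(m) step_segment(row, 50, 300, m)$na_active, 0)
  expect_true(all(diff(acts) > 0))
})

test_that("region map and aggregation form an exact partition", {
  st <- simulate_kidney(test_model(), "female", 14)
  agg <- regional_aggregate(st)
  expect_equal(agg$na_total[3], agg$na_total[1] + agg$na_total[2])
  expect_equal(sort(st$segments$id[st$segments$region == "cortex"]),
               sort(c("PCT", "cTAL", "DCT", "CNT", "CCD")))
  expect_equal(sort(st$segments$id[st$segments$region == "medulla"]),
               sort(c("PST", "ThinLimbs", "mTAL", "OMCD", "IMCD")))
  # invalid region remap is rejected
  bad <- default_segment_params("male")
  bad$region[1] <- "medulla"
  expect_error(validate_segment_params(bad), "region")
})

test_that("passive transport is confined to the proximal tubule", {
  for (sex in c("male", "female")) {
    p <- test_model()$params[[sex]]
    expect_true(all(p$f_passive[!p$id %in% c("PCT", "PST")] == 0))
    expect_true(all(p$f_passive[p$id %in% c("PCT", "PST")] > 0))
  }
})

test_that("filtered load (proximal delivery) peaks in the dark phase", {
  grid <- hourly_grid()
  for (sex in c("male", "female")) {
    load <- filtered_na(sex, grid)
    expect_true(grid[which.max(load)] >= 12)
  }
})

test_that("kidney state CSV round-trips with units header", {
  model <- test_model()
  f <- withr::local_tempfile(fileext = ".csv")
  st <- simulate_kidney(model, "male", 14)
  df <- write_kidney_csv(st, f)
  expect_match(readLines(f, n = 1), "umol/min")
  back <- read.csv(f, comment.char = "#")
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$na_total[back$level == "urine"], st$urine_na)
})
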