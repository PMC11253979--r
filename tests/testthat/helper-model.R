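# shared fixtures: the packaged calibrated model (built once per test run)
# and a small cache environment for expensive objects
.test_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.test_cache$model)) {
    .test_cache$model <- kidney_model()
  }
  .test_cache$model
}

# model built from the documented initial (uncalibrated) point
init_model <- function(alpha = FALSE) {
  key <- paste0("init_model_", alpha)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- kidney_model(
      list(male = default_segment_params("male"),
           female = default_segment_params("female"),
           eps = 0.3),
      alpha = alpha)
  }
  .test_cache[[key]]
}

test_fixtures <- function(seed = 421, n_params = 20, n_registries = 1) {
  key <- paste("fx", seed, n_params, n_registries, sep = "_")
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- generate_fixtures(seed, n_params, n_registries)
  }
  .test_cache[[key]]
}

# independent brute-force re-summation oracle for mass balance: recompute
# per-segment outputs one segment at a time through the exported
# step_segment(), then compare totals against the chain solution
oracle_resum <- function(model, sex, zt, intervention = NULL) {
  params <- model$params[[sex]]
  drivers <- model$drivers[[sex]]
  mods <- renalclock:::intervention_modifiers(intervention, zt, model$eps)
  na_in <- filtered_na(sex, zt, model$scale, drivers)
  v_in <- whole_kidney_gfr(sex, zt, model$scale, drivers) * 1000
  filtered <- c(na = na_in, v = v_in)
  reab_na <- 0
  reab_v <- 0
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    m <- segment_multiplier(row, drivers, zt, mods$driver)
    amod <- 1
    if (!is.null(mods$active) && !is.na(row$driver1) &&
        row$driver1 %in% names(mods$active)) {
      amod <- mods$active[[row$driver1]]
    }
    nfb <- model$na_frac_baseline[[sex]][[row$id]]
    st <- step_segment(row, na_in, v_in, m, amod, nfb)
    reab_na <- reab_na + st$na_active + st$na_passive
    reab_v <- reab_v + st$v_reab
    na_in <- st$na_out
    v_in <- st$v_out
  }
  list(filtered = filtered, reabsorbed = c(na = reab_na, v = reab_v),
       urine = c(na = na_in, v = v_in))
}
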