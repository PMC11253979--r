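#' Specify an intervention protocol
#'
#' Two protocols are supported. Loop diuretics (e.g. furosemide) inhibit
#' NKCC2 in both thick ascending limbs; reflecting the circadian rhythm
#' of the organic anion transporter that secretes the drug, 80% of NKCC2
#' activity is inhibited in the dark (active) phase, ZT 12-24, and 70% in
#' the light (inactive) phase, ZT 0-12, scaled by a calibrated efficacy
#' `efficacy` shared across sexes and phases; SNGFR stays at control
#' values. ENaC inhibition (e.g. amiloride) removes the stated fraction
#' (default 100%) of ENaC-mediated active transport in CNT, CCD, OMCD and
#' IMCD.
#'
#' @param kind `"none"`, `"loop_diuretic"` or `"enac_inhibition"`.
#' @param inhibition_dark,inhibition_light NKCC2 inhibition fractions for
#'   the dark and light phase schedules.
#' @param enac_inhibition Inhibited fraction of ENaC activity.
#' @param efficacy Loop-diuretic efficacy in (0, 1]; `NULL` uses the
#'   calibrated value stored in the model.
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(kind = c("none", "loop_diuretic",
                                       "enac_inhibition"),
                              inhibition_dark = 0.8, inhibition_light = 0.7,
                              enac_inhibition = 1.0, efficacy = NULL) {
  kind <- match.arg(kind)
  for (f in c(inhibition_dark, inhibition_light, enac_inhibition)) {
    if (f < 0 || f > 1) stop("inhibition fractions must lie in [0, 1]",
                             call. = FALSE)
  }
  if (!is.null(efficacy) && (efficacy <= 0 || efficacy > 1)) {
    stop("efficacy must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, inhibition_dark = inhibition_dark,
                 inhibition_light = inhibition_light,
                 enac_inhibition = enac_inhibition, efficacy = efficacy),
            class = "intervention_spec")
}

#' Loop-diuretic driver modifiers
#'
#' Returns the multiplicative factor applied to the NKCC2 driver at time
#' `t`: `1 - efficacy * i(t)` with `i(t) = 0.8` for ZT in \[12, 24) and
#' `0.7` for ZT in \[0, 12).
#'
#' @param spec An [intervention_spec()] with `kind = "loop_diuretic"`.
#' @param t Zeitgeber time, hours.
#' @param eps Calibrated efficacy used when `spec$efficacy` is `NULL`.
#' @return Named numeric vector of driver multipliers (`NKCC2`).
#' @export
loop_diuretic_modifiers <- function(spec, t, eps = NULL) {
  stopifnot(inherits(spec, "intervention_spec"),
            spec$kind == "loop_diuretic")
  eff <- if (!is.null(spec$efficacy)) spec$efficacy else eps
  if (is.null(eff) || is.na(eff)) {
    stop("loop-diuretic efficacy is not calibrated and no override given",
         call. = FALSE)
  }
  i_t <- if (clock_time(t) >= 12) spec$inhibition_dark else spec$inhibition_light
  c(NKCC2 = 1 - eff * i_t)
}

#' ENaC-inhibition active-transport modifiers
#'
#' Returns the multiplier applied directly to ENaC-linked active
#' transport: `1 - enac_inhibition` (0 at 100% inhibition, which zeroes
#' active reabsorption in CNT, CCD, OMCD and IMCD).
#'
#' @param spec An [intervention_spec()] with `kind = "enac_inhibition"`.
#' @return Named numeric vector of active-transport multipliers (`ENaC`).
#' @export
enac_inhibition_modifiers <- function(spec) {
  stopifnot(inherits(spec, "intervention_spec"),
            spec$kind == "enac_inhibition")
  c(ENaC = 1 - spec$enac_inhibition)
}

# dispatch an intervention into driver-level and active-level modifiers
intervention_modifiers <- function(intervention, zt, eps) {
  if (is.null(intervention) || intervention$kind == "none") {
    return(list(driver = NULL, active = NULL))
  }
  switch(intervention$kind,
    loop_diuretic = list(
      driver = loop_diuretic_modifiers(intervention, zt, eps),
      active = NULL),
    enac_inhibition = list(
      driver = NULL,
      active = enac_inhibition_modifiers(intervention)),
    stop("unknown intervention kind ", intervention$kind, call. = FALSE)
  )
}

#' Compare treated and control scenarios
#'
#' Runs the control and treated simulations at one zeitgeber time and
#' reports fractional changes (`treated/control - 1`) of the requested
#' metrics. The pO2 conversion factor alpha is held at its control
#' calibration.
#'
#' @param model A [kidney_model()].
#' @param sex `"male"` or `"female"`.
#' @param zt Zeitgeber time, hours.
#' @param intervention An [intervention_spec()].
#' @param metrics Any of `"medullary_qo2"`, `"medullary_po2"`,
#'   `"urine_na"`, `"urine_v"`.
#' @return Data frame: `sex`, `zt`, `intervention`, `metric`, `control`,
#'   `treated`, `fractional_change`.
#' @export
compare_scenarios <- function(model, sex = c("male", "female"), zt,
                              intervention,
                              metrics = c("medullary_qo2", "medullary_po2",
                                          "urine_na", "urine_v")) {
  sex <- match.arg(sex)
  metrics <- match.arg(metrics, several.ok = TRUE)
  known <- c("medullary_qo2", "medullary_po2", "urine_na", "urine_v")
  if (!all(metrics %in% known)) {
    stop("unknown metric(s): ", paste(setdiff(metrics, known), collapse = ", "),
         call. = FALSE)
  }
  one <- function(interv) {
    st <- simulate_kidney(model, sex, zt, interv)
    vals <- c(
      medullary_qo2 = medullary_qo2(model, sex, zt, interv),
      medullary_po2 = if (!is.na(model$alpha[[sex]]))
        po2(model, sex, zt, interv) else NA_real_,
      urine_na = st$urine_na,
      urine_v = st$urine_v
    )
    vals[metrics]
  }
  ctrl <- one(NULL)
  trt <- one(intervention)
  data.frame(
    sex = sex, zt = clock_time(zt), intervention = intervention$kind,
    metric = metrics, control = unname(ctrl), treated = unname(trt),
    fractional_change = unname(trt / ctrl - 1),
    row.names = NULL
  )
}

#' Tidy CSV export of scenario comparisons
#'
#' @param comparisons Data frame(s) from [compare_scenarios()].
#' @param file Path of the CSV to write.
#' @return The combined data frame, invisibly.
#' @export
write_comparison_csv <- function(comparisons, file) {
  if (is.data.frame(comparisons)) comparisons <- list(comparisons)
  df <- do.call(rbind, comparisons)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# renalclock scenario comparison: Q_O2 in umol O2/min,",
                   "pO2 in mmHg, urine Na+ in umol/min, urine volume in",
                   "uL/min. The values are given per kidney."), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}
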