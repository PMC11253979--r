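SEGMENT_IDS <- c("PCT", "PST", "ThinLimbs", "mTAL", "cTAL",
                 "DCT", "CNT", "CCD", "OMCD", "IMCD")

CORTICAL_SEGMENTS  <- c("PCT", "cTAL", "DCT", "CNT", "CCD")
MEDULLARY_SEGMENTS <- c("PST", "ThinLimbs", "mTAL", "OMCD", "IMCD")

#' Segment identifiers and fixed region map
#'
#' The chain runs PCT -> PST -> thin limbs -> mTAL -> cTAL -> DCT -> CNT ->
#' CCD -> OMCD -> IMCD. Cortical segments are PCT, cTAL, DCT, CNT, CCD;
#' medullary segments are PST, thin limbs, mTAL, OMCD, IMCD.
#'
#' @return Character vector of the ten segment ids in chain order.
#' @export
segment_ids <- function() SEGMENT_IDS

#' @rdname segment_ids
#' @export
segment_regions <- function() {
  ifelse(SEGMENT_IDS %in% CORTICAL_SEGMENTS, "cortex", "medulla")
}

#' Reduced-order segment parameter table
#'
#' One row per nephron segment with the transport parameters of the
#' reduced chain:
#' \describe{
#'   \item{f_active}{baseline active reabsorbed fraction of delivered Na+}
#'   \item{f_passive}{baseline passive (paracellular) fraction; non-zero
#'     only in the proximal segments}
#'   \item{beta}{activity-sensitivity exponent: active transport scales as
#'     (driver multiplier)^beta. Shared within the PT, TAL, DCT and ENaC
#'     driver groups.}
#'   \item{driver1/w1, driver2/w2}{convex mix of circadian drivers feeding
#'     the segment (PCT/PST: 0.9 NHE3 + 0.1 SGLT1; TALs: NKCC2; DCT: NCC;
#'     CNT/CCD/OMCD/IMCD: ENaC; thin limbs: none)}
#'   \item{water_mode}{`"iso"` (proximal, volume follows total Na+
#'     fraction), `"fixed"` (constant fraction), `"coupled"` (fraction
#'     modulated by local Na+ handling through `lambda`) or `"none"`
#'     (water-impermeable thick ascending limbs)}
#'   \item{water_frac, lambda}{baseline reabsorbed volume fraction and the
#'     Na+-water coupling strength of the distal segments}
#'   \item{clip_frac}{maximum reabsorbable fraction of delivery (0.995);
#'     when active + passive would exceed it, passive takes precedence and
#'     active is truncated}
#' }
#'
#' The numbers returned here are the documented initial point of the
#' calibration, not a calibrated set; see [calibrated_params()] for the
#' shipped fit.
#'
#' @param sex `"male"` or `"female"`.
#' @return Data frame with one row per segment, class `segment_params`.
#' @export
default_segment_params <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  df <- data.frame(
    id = SEGMENT_IDS,
    region = segment_regions(),
    driver1 = c("NHE3", "NHE3", NA, "NKCC2", "NKCC2",
                "NCC", "ENaC", "ENaC", "ENaC", "ENaC"),
    w1 = c(0.9, 0.9, 0, 1, 1, 1, 1, 1, 1, 1),
    driver2 = c("SGLT1", "SGLT1", NA, NA, NA, NA, NA, NA, NA, NA),
    w2 = c(0.1, 0.1, 0, 0, 0, 0, 0, 0, 0, 0),
    beta_group = c("PT", "PT", NA, "TAL", "TAL",
                   "DCT", "ENaC", "ENaC", "ENaC", "ENaC"),
    water_mode = c("iso", "iso", "fixed", "none", "none",
                   "fixed", "coupled", "coupled", "coupled", "coupled"),
    water_frac = c(NA, NA, 0.30, 0, 0, 0.10, 0.55, 0.55, 0.55, 0.55),
    lambda = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
    clip_frac = 0.995
  )
  # male/female asymmetry encodes the stated transporter dimorphism:
  # males carry more proximal (NHE3) transport, females roughly double
  # NKCC2/NCC activity in TAL and DCT. The numbers reproduce, at mean
  # drivers, segmental shares near PT 0.65/0.53, TAL 0.25/0.33 and
  # DT 0.09/0.13 of the filtered load (male/female) with ~1% excretion.
  if (sex == "male") {
    df$f_active  <- c(0.40, 0.16, 0, 0.47, 0.50, 0.33,
                      0.45, 0.45, 0.10, 0.10)
    df$f_passive <- c(0.15, 0.06, 0, 0, 0, 0, 0, 0, 0, 0)
  } else {
    df$f_active  <- c(0.40, 0.08, 0, 0.64, 0.18, 0.67,
                      0.50, 0.35, 0.15, 0.10)
    df$f_passive <- c(0.07, 0.03, 0, 0, 0, 0, 0, 0, 0, 0)
  }
  df$beta <- ifelse(is.na(df$beta_group), 0, 0.5)
  class(df) <- c("segment_params", "data.frame")
  validate_segment_params(df)
  df
}

#' Validate a segment parameter table
#'
#' Checks the chain order, region assignment, fraction bounds
#' (`0 <= f_active + f_passive <= clip_frac <= 0.999`) and `beta >= 0`.
#'
#' @param params A `segment_params` data frame.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_segment_params <- function(params) {
  if (!is.data.frame(params) || !identical(params$id, SEGMENT_IDS)) {
    stop("segment parameter table must contain the ten chain segments in order",
         call. = FALSE)
  }
  if (!identical(params$region, segment_regions())) {
    stop("region assignment is fixed: cortex = {PCT, cTAL, DCT, CNT, CCD}, ",
         "medulla = {PST, ThinLimbs, mTAL, OMCD, IMCD}", call. = FALSE)
  }
  if (any(params$f_active < 0 | params$f_passive < 0)) {
    stop("reabsorbed fractions must be non-negative", call. = FALSE)
  }
  if (any(params$f_active + params$f_passive > params$clip_frac + 1e-12)) {
    stop("f_active + f_passive must not exceed clip_frac", call. = FALSE)
  }
  if (any(params$clip_frac > 0.999)) {
    stop("clip_frac must not exceed 0.999", call. = FALSE)
  }
  if (any(params$beta < 0)) stop("beta must be >= 0", call. = FALSE)
  invisible(params)
}

# single-segment transport arithmetic shared by step_segment() and the
# chain solver; returns c(na_active, na_passive, v_reab)
seg_step_core <- function(f_active, f_passive, beta, clip_frac,
                          water_mode, water_frac, lambda,
                          na_in, v_in, m, active_mod, nfb) {
  na_active <- if (f_active > 0) f_active * na_in * m^beta * active_mod else 0
  na_passive <- f_passive * na_in
  cap <- clip_frac * na_in
  if (na_active + na_passive > cap) {
    na_passive <- min(na_passive, cap)
    na_active <- cap - na_passive
  }
  na_frac <- if (na_in > 0) (na_active + na_passive) / na_in else 0
  v_reab <- switch(water_mode,
    iso = na_frac * v_in,
    fixed = water_frac * v_in,
    none = 0,
    coupled = water_frac * v_in *
      (1 + lambda * (if (nfb > 0) na_frac - nfb else 0)),
    stop("unknown water_mode ", water_mode, call. = FALSE)
  )
  v_reab <- min(max(v_reab, 0), clip_frac * v_in)
  c(na_active, na_passive, v_reab)
}

#' Steady-state transport across one nephron segment
#'
#' Active reabsorption is a fraction of delivered Na+ scaled sublinearly
#' by transporter activity, `f_active * na_in * m^beta * active_mod`;
#' passive reabsorption is `f_passive * na_in`. The total is clipped at
#' `clip_frac * na_in` with passive taking precedence. Volume follows the
#' segment's `water_mode` (see [default_segment_params()]); in coupled
#' segments `v_reab = water_frac * v_in * (1 + lambda * (na_frac -
#' na_frac_baseline))`, clipped to `[0, clip_frac * v_in]`, where
#' `na_frac` is the fraction of delivered Na+ reabsorbed locally.
#'
#' @param row One row of a segment parameter table.
#' @param na_in Delivered Na+, umol/min (>= 0).
#' @param v_in Delivered volume, uL/min (>= 0).
#' @param m Driver activity multiplier (see [segment_multiplier()]).
#' @param active_mod Direct multiplier on active transport (the
#'   ENaC-inhibition route), default 1.
#' @param na_frac_baseline Baseline local reabsorbed Na+ fraction used by
#'   the water coupling (0 disables the coupling term).
#' @return One-row data frame: `id`, `na_in`, `na_active`, `na_passive`,
#'   `na_out`, `v_in`, `v_reab`, `v_out`.
#' @export
#' @examples
#' pp <- default_segment_params("male")
#' step_segment(pp[pp$id == "PCT", ], na_in = 100, v_in = 700, m = 1)
step_segment <- function(row, na_in, v_in, m, active_mod = 1,
                         na_frac_baseline = 0) {
  if (na_in < 0 || v_in < 0) {
    stop("negative inflow to segment ", row$id, call. = FALSE)
  }
  if (m < 0) stop("negative driver multiplier", call. = FALSE)
  res <- seg_step_core(row$f_active, row$f_passive, row$beta, row$clip_frac,
                       row$water_mode, row$water_frac, row$lambda,
                       na_in, v_in, m, active_mod, na_frac_baseline)
  data.frame(
    id = row$id, na_in = na_in, na_active = res[1], na_passive = res[2],
    na_out = na_in - res[1] - res[2],
    v_in = v_in, v_reab = res[3], v_out = v_in - res[3]
  )
}

#' Driver activity multiplier seen by one segment
#'
#' Convex mix of the linked drivers at time `t`, after applying any
#' driver-level modifiers (e.g. the loop-diuretic NKCC2 inhibition).
#' Segments with no driver link (thin limbs) get multiplier 1.
#'
#' @param row One row of a segment parameter table.
#' @param drivers Named list of [driver_spec()] objects.
#' @param t Zeitgeber time, hours.
#' @param driver_mods Named numeric vector of multiplicative factors on
#'   driver activity (default none).
#' @return Scalar multiplier, >= 0.
#' @export
segment_multiplier <- function(row, drivers, t, driver_mods = NULL) {
  dv <- vapply(drivers, driver_value, 0, t = t)
  mix_multiplier(row$driver1, row$w1, row$driver2, row$w2, dv, driver_mods)
}

mix_multiplier <- function(d1, w1, d2, w2, driver_vals, driver_mods) {
  mod_of <- function(name) {
    if (!is.null(driver_mods) && name %in% names(driver_mods)) {
      driver_mods[[name]]
    } else 1
  }
  m <- 0
  used <- 0
  if (!is.na(d1) && w1 > 0) {
    m <- m + w1 * driver_vals[[d1]] * mod_of(d1)
    used <- used + w1
  }
  if (!is.na(d2) && w2 > 0) {
    m <- m + w2 * driver_vals[[d2]] * mod_of(d2)
    used <- used + w2
  }
  if (used == 0) 1 else m / used
}

# fast sequential solve of the whole chain on plain vectors.
# pp: list-of-columns view of a segment_params table; driver_vals: named
# numeric vector of driver multipliers at the evaluation time.
run_chain <- function(pp, L, V, driver_vals, driver_mods = NULL,
                      active_mods = NULL, nfb = NULL) {
  n <- length(pp$id)
  na_active <- na_passive <- na_in_v <- numeric(n)
  v_reab <- v_in_v <- numeric(n)
  na_in <- L
  v_in <- V
  for (i in seq_len(n)) {
    if (na_in < 0 || v_in < 0) {
      stop("negative inflow to segment ", pp$id[i], call. = FALSE)
    }
    m <- mix_multiplier(pp$driver1[i], pp$w1[i], pp$driver2[i], pp$w2[i],
                        driver_vals, driver_mods)
    amod <- 1
    if (!is.null(active_mods) && !is.na(pp$driver1[i]) &&
        pp$driver1[i] %in% names(active_mods)) {
      amod <- active_mods[[pp$driver1[i]]]
    }
    nfb_i <- if (is.null(nfb)) 0 else nfb[[i]]
    res <- seg_step_core(pp$f_active[i], pp$f_passive[i], pp$beta[i],
                         pp$clip_frac[i], pp$water_mode[i], pp$water_frac[i],
                         pp$lambda[i], na_in, v_in, m, amod, nfb_i)
    na_in_v[i] <- na_in
    v_in_v[i] <- v_in
    na_active[i] <- res[1]
    na_passive[i] <- res[2]
    v_reab[i] <- res[3]
    na_in <- na_in - res[1] - res[2]
    v_in <- v_in - res[3]
  }
  list(id = pp$id, region = pp$region,
       na_in = na_in_v, na_active = na_active, na_passive = na_passive,
       na_out = na_in_v - na_active - na_passive,
       v_in = v_in_v, v_reab = v_reab, v_out = v_in_v - v_reab,
       urine_na = na_in, urine_v = v_in)
}

as_column_list <- function(params) {
  validate_segment_params(params)
  lapply(params, identity)
}

# core steady-state solve used by simulate_kidney() and the calibration;
# returns the run_chain() list plus urine after the concentrating limit
sim_core <- function(model, sex, zt, intervention = NULL) {
  pp <- model$pp[[sex]]
  drivers <- model$drivers[[sex]]
  mods <- intervention_modifiers(intervention, zt, model$eps)
  dv <- vapply(drivers, driver_value, 0, t = zt)
  L <- filtered_na(sex, zt, model$scale, drivers)
  V <- whole_kidney_gfr(sex, zt, model$scale, drivers) * 1000 # mL -> uL
  ch <- run_chain(pp, L, V, dv, mods$driver, mods$active,
                  model$na_frac_baseline[[sex]])
  ch <- close_urine_volume(ch, model$urine_na_conc)
  ch$filtered_na <- L
  ch$filtered_v <- V
  ch
}

#' Simulate the kidney at one zeitgeber time
#'
#' Applies the segment chain sequentially to the filtered Na+ and volume
#' loads and returns the per-segment flows, regional aggregates and urine.
#' Mass is conserved exactly: filtered load equals total reabsorption plus
#' urinary excretion, for both Na+ and volume.
#'
#' Final urine volume is closed by a fixed urinary Na+ concentration
#' (`urine_na_conc` of the model, default 0.18 umol/uL): terminal
#' (inner-medullary) water reabsorption is adjusted so urine leaves at
#' that concentration, bounded by the delivered volume and the maximum
#' reabsorbable fraction. This reduced free-water handling carries the
#' osmotic component of diuresis (solute that escapes reabsorption takes
#' water with it) that a purely fraction-based water chain lacks.
#'
#' @param model A [kidney_model()].
#' @param sex `"male"` or `"female"`.
#' @param zt Zeitgeber time, hours.
#' @param intervention An [intervention_spec()] or `NULL` for control.
#' @return Object of class `kidney_state`: list with `segments` (data
#'   frame), `urine_na` (umol/min), `urine_v` (uL/min), `filtered_na`,
#'   `filtered_v`, `sex`, `zt`, `intervention`.
#' @export
simulate_kidney <- function(model, sex = c("male", "female"), zt,
                            intervention = NULL) {
  stopifnot(inherits(model, "kidney_model"))
  sex <- match.arg(sex)
  zt <- clock_time(zt)
  ch <- sim_core(model, sex, zt, intervention)
  segs <- data.frame(
    id = ch$id, region = ch$region, na_in = ch$na_in,
    na_active = ch$na_active, na_passive = ch$na_passive,
    na_out = ch$na_out, v_in = ch$v_in, v_reab = ch$v_reab, v_out = ch$v_out
  )
  structure(
    list(segments = segs, urine_na = ch$urine_na, urine_v = ch$urine_v,
         filtered_na = ch$filtered_na, filtered_v = ch$filtered_v,
         sex = sex, zt = zt,
         intervention = if (is.null(intervention)) "none" else intervention$kind),
    class = "kidney_state"
  )
}

#' @export
print.kidney_state <- function(x, ...) {
  cat(sprintf("<kidney_state> %s rat, ZT%g, intervention: %s\n",
              x$sex, x$zt, x$intervention))
  cat(sprintf(
    "  filtered Na+ %.2f umol/min; urine Na+ %.3f umol/min (%.2f%% of filtered)\n",
    x$filtered_na, x$urine_na, 100 * x$urine_na / x$filtered_na))
  cat(sprintf("  filtered volume %.1f uL/min; urine volume %.2f uL/min\n",
              x$filtered_v, x$urine_v))
  agg <- regional_aggregate(x)
  cat(sprintf(
    "  total T_Na (umol/min): cortex %.1f, medulla %.1f, whole kidney %.1f\n",
    agg$na_total[agg$region == "cortex"],
    agg$na_total[agg$region == "medulla"],
    agg$na_total[agg$region == "whole"]))
  invisible(x)
}

#' Regional transport aggregates of a kidney state
#'
#' Sums active, passive and total Na+ reabsorption over the fixed
#' cortical/medullary region map; the whole kidney is the exact sum of
#' the two regions.
#'
#' @param state A `kidney_state` from [simulate_kidney()].
#' @return Data frame with rows `cortex`, `medulla`, `whole` and columns
#'   `na_active`, `na_passive`, `na_total` (umol/min).
#' @export
regional_aggregate <- function(state) {
  stopifnot(inherits(state, "kidney_state"))
  segs <- state$segments
  one <- function(idx) {
    data.frame(na_active = sum(segs$na_active[idx]),
               na_passive = sum(segs$na_passive[idx]),
               na_total = sum(segs$na_active[idx] + segs$na_passive[idx]))
  }
  ctx <- one(segs$region == "cortex")
  med <- one(segs$region == "medulla")
  out <- rbind(ctx, med, ctx + med)
  out$region <- c("cortex", "medulla", "whole")
  out[, c("region", "na_active", "na_passive", "na_total")]
}

#' Tidy CSV export of kidney states
#'
#' @param states List of `kidney_state` objects (or a single one).
#' @param file Path of the CSV to write. A header comment records units
#'   and the per-kidney convention.
#' @return The tidy data frame, invisibly.
#' @export
write_kidney_csv <- function(states, file) {
  if (inherits(states, "kidney_state")) states <- list(states)
  rows <- lapply(states, function(st) {
    segs <- st$segments
    seg_df <- data.frame(
      sex = st$sex, zt = st$zt, intervention = st$intervention,
      unit = segs$id, level = "segment",
      na_active = segs$na_active, na_passive = segs$na_passive,
      na_total = segs$na_active + segs$na_passive,
      v_in = segs$v_in, v_out = segs$v_out
    )
    agg <- regional_aggregate(st)
    agg_df <- data.frame(
      sex = st$sex, zt = st$zt, intervention = st$intervention,
      unit = agg$region, level = "region",
      na_active = agg$na_active, na_passive = agg$na_passive,
      na_total = agg$na_total, v_in = NA, v_out = NA
    )
    urine <- data.frame(
      sex = st$sex, zt = st$zt, intervention = st$intervention,
      unit = "urine", level = "urine",
      na_active = NA, na_passive = NA, na_total = st$urine_na,
      v_in = NA, v_out = st$urine_v
    )
    rbind(seg_df, agg_df, urine)
  })
  df <- do.call(rbind, rows)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# renalclock kidney state: Na+ in umol/min, volume in",
                   "uL/min. The values are given per kidney."), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

# fixed-urinary-concentration closure: adjust terminal water reabsorption
# so urine leaves at na concentration `conc` (umol/uL), within physical
# bounds (cannot reabsorb more than the clip fraction, nor add water)
close_urine_volume <- function(ch, conc) {
  n <- length(ch$id)
  if (ch$urine_na <= 0 || is.null(conc) || is.na(conc)) return(ch)
  v_target <- ch$urine_na / conc
  v_min <- (1 - 0.995) * ch$v_in[n]
  v_out <- min(max(v_target, v_min), ch$v_in[n])
  ch$v_reab[n] <- ch$v_in[n] - v_out
  ch$v_out[n] <- v_out
  ch$urine_v <- v_out
  ch
}
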