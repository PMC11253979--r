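#' Oxygen consumption of active sodium transport
#'
#' Na-K-ATPase moves 3 Na+ per ATP and oxidative metabolism yields 5 ATP
#' per O2, so active transport consumes one O2 per 15 Na+:
#' `qo2_active = tna_active / 15`.
#'
#' @param tna_active Active Na+ reabsorption, umol/min (non-negative).
#' @return Oxygen consumption, umol O2/min.
#' @export
#' @examples
#' qo2_active(15) # 1
qo2_active <- function(tna_active) {
  if (any(tna_active < 0)) {
    stop("active transport must be non-negative", call. = FALSE)
  }
  tna_active / 15
}

#' Fixed basal oxygen consumption allocated per segment
#'
#' Basal consumption is 25% of total consumption under baseline
#' conditions, i.e. one third of baseline active consumption, and stays
#' fixed when the drivers move off baseline. The whole-kidney 25% split is
#' applied segmentwise in proportion to each segment's baseline active
#' consumption, which preserves the global ratio and keeps regional
#' aggregation well defined. The basal share is exposed as `basal_frac`
#' (reported range in rats is about 25-30%).
#'
#' @param qo2_active_star Baseline active oxygen consumption per segment,
#'   umol O2/min (the starred reference values).
#' @param basal_frac Basal share of total consumption at baseline.
#' @return Per-segment basal consumption, umol O2/min.
#' @export
#' @examples
#' basal_allocation(3) # 1
basal_allocation <- function(qo2_active_star, basal_frac = 0.25) {
  if (is.null(qo2_active_star)) {
    stop("baseline reference not computed", call. = FALSE)
  }
  (basal_frac / (1 - basal_frac)) * qo2_active_star
}

#' Sodium transport efficiency
#'
#' Moles of Na+ reabsorbed per mole of O2 consumed:
#' `(tna_active + tna_passive) / (qo2_active + qo2_basal)`.
#'
#' @param tna_total Total Na+ reabsorption, umol/min.
#' @param qo2_total Total oxygen consumption, umol O2/min (> 0).
#' @return Dimensionless mol Na+ / mol O2 ratio.
#' @export
#' @examples
#' efficiency(15, 1)          # 15: purely active, no basal
#' efficiency(15, 1 + 1 / 3)  # 11.25: active plus baseline basal
efficiency <- function(tna_total, qo2_total) {
  if (any(qo2_total <= 0)) {
    stop("total oxygen consumption must be positive", call. = FALSE)
  }
  tna_total / qo2_total
}

#' Baseline reference of a calibrated model
#'
#' Per-segment active transport and oxygen consumption with all drivers
#' at their daily mean, per sex; these starred values fix the basal
#' allocation. Recomputed whenever the model is rebuilt with new
#' parameters.
#'
#' @param model A [kidney_model()].
#' @param sex `"male"` or `"female"`.
#' @return Data frame: `id`, `region`, `na_active`, `na_passive`,
#'   `qo2_active_star`, `qo2_basal`.
#' @export
baseline_reference <- function(model, sex = c("male", "female")) {
  stopifnot(inherits(model, "kidney_model"))
  sex <- match.arg(sex)
  model$baseline[[sex]]
}

#' Oxygen budget of a kidney state
#'
#' Converts the per-segment active transport of a simulated state into
#' oxygen consumption (Na-K-ATPase stoichiometry), adds the fixed basal
#' allocation, aggregates over the cortical/medullary region map and
#' computes transport efficiencies.
#'
#' @param model The [kidney_model()] that produced the state (supplies the
#'   baseline basal allocation).
#' @param state A `kidney_state` from [simulate_kidney()].
#' @return Object of class `oxygen_budget`: list with `segments` and
#'   `regions` data frames (columns `qo2_active`, `qo2_basal`,
#'   `qo2_total`, `efficiency`).
#' @export
kidney_oxygen <- function(model, state) {
  stopifnot(inherits(model, "kidney_model"), inherits(state, "kidney_state"))
  base <- model$baseline[[state$sex]]
  segs <- state$segments
  if (!identical(segs$id, base$id)) {
    stop("segment/region map mismatch between state and baseline",
         call. = FALSE)
  }
  qa <- qo2_active(segs$na_active)
  qb <- base$qo2_basal
  qt <- qa + qb
  na_tot <- segs$na_active + segs$na_passive
  seg_df <- data.frame(
    id = segs$id, region = segs$region,
    na_total = na_tot, qo2_active = qa, qo2_basal = qb, qo2_total = qt,
    efficiency = ifelse(qt > 0, na_tot / qt, NA_real_)
  )
  agg <- function(idx) {
    c(na_total = sum(na_tot[idx]), qo2_active = sum(qa[idx]),
      qo2_basal = sum(qb[idx]), qo2_total = sum(qt[idx]))
  }
  ctx <- agg(segs$region == "cortex")
  med <- agg(segs$region == "medulla")
  reg <- as.data.frame(rbind(ctx, med, ctx + med))
  reg$region <- c("cortex", "medulla", "whole")
  reg$efficiency <- efficiency(reg$na_total, reg$qo2_total)
  structure(
    list(segments = seg_df,
         regions = reg[, c("region", "na_total", "qo2_active", "qo2_basal",
                           "qo2_total", "efficiency")],
         sex = state$sex, zt = state$zt, intervention = state$intervention),
    class = "oxygen_budget"
  )
}

#' @export
print.oxygen_budget <- function(x, ...) {
  cat(sprintf("<oxygen_budget> %s rat, ZT%g, intervention: %s\n",
              x$sex, x$zt, x$intervention))
  print(x$regions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Grouped segmental totals (proximal tubule, TAL, distal tubule)
#'
#' Reporting convenience mirroring the usual segmental grouping: PT =
#' PCT + PST, TAL = mTAL + cTAL, DT = DCT + CNT + CCD + OMCD + IMCD.
#'
#' @param state A `kidney_state`.
#' @return Data frame with rows `PT`, `TAL`, `DT` and columns
#'   `na_active`, `na_passive`, `na_total`.
#' @export
segment_groups <- function(state) {
  segs <- state$segments
  grp <- list(PT = c("PCT", "PST"), TAL = c("mTAL", "cTAL"),
              DT = c("DCT", "CNT", "CCD", "OMCD", "IMCD"))
  out <- do.call(rbind, lapply(names(grp), function(g) {
    idx <- segs$id %in% grp[[g]]
    data.frame(group = g,
               na_active = sum(segs$na_active[idx]),
               na_passive = sum(segs$na_passive[idx]),
               na_total = sum(segs$na_active[idx] + segs$na_passive[idx]))
  }))
  out
}

#' Tidy CSV export of oxygen budgets
#'
#' @param budgets List of `oxygen_budget` objects (or a single one).
#' @param file Path of the CSV to write.
#' @return The tidy data frame, invisibly.
#' @export
write_oxygen_csv <- function(budgets, file) {
  if (inherits(budgets, "oxygen_budget")) budgets <- list(budgets)
  rows <- lapply(budgets, function(b) {
    seg <- cbind(data.frame(sex = b$sex, zt = b$zt,
                            intervention = b$intervention,
                            unit = b$segments$id, level = "segment"),
                 b$segments[, c("qo2_active", "qo2_basal", "qo2_total",
                                "efficiency")])
    reg <- cbind(data.frame(sex = b$sex, zt = b$zt,
                            intervention = b$intervention,
                            unit = b$regions$region, level = "region"),
                 b$regions[, c("qo2_active", "qo2_basal", "qo2_total",
                               "efficiency")])
    rbind(seg, reg)
  })
  df <- do.call(rbind, rows)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# renalclock oxygen budget: Q_O2 in umol O2/min,",
                   "efficiency in mol Na+ per mol O2.",
                   "The values are given per kidney."), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}
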