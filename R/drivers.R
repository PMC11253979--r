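#' Reduce a zeitgeber time to the canonical [0, 24) interval
#'
#' Zeitgeber time (ZT) is measured in hours since lights-on. For nocturnal
#' rodents ZT0 starts the light (rest) phase and ZT12 the dark (active)
#' phase. All clock arithmetic in the package is modulo 24 h.
#'
#' @param zt Numeric vector of times in hours (any real values).
#' @return Numeric vector in `[0, 24)`.
#' @export
#' @examples
#' clock_time(c(-2, 26, 14))
clock_time <- function(zt) {
  if (!is.numeric(zt) || anyNA(zt)) {
    stop("`zt` must be numeric without missing values", call. = FALSE)
  }
  zt %% 24
}

#' Construct a circadian driver specification
#'
#' A driver is a sinusoidally clock-modulated quantity
#' \deqn{X_p(t) = X_{p,0}\,\bigl(1 + \gamma_p \sin(2\pi (t + 6 - \theta_p)/24)\bigr),}
#' where \eqn{X_{p,0}} is the daily mean, \eqn{\gamma_p} the fractional
#' oscillation amplitude and \eqn{\theta_p} the peak time (ZT hours). The
#' maximum \eqn{X_{p,0}(1+\gamma_p)} is attained exactly at
#' \eqn{t = \theta_p} and the minimum at \eqn{\theta_p \pm 12}.
#'
#' Drivers are stored as dimensionless multipliers (`mean = 1`); physical
#' means such as SNGFR live in the modules that consume them.
#'
#' @param name Identifier, one of `"GFR"`, `"NHE3"`, `"SGLT1"`, `"NKCC2"`,
#'   `"NCC"`, `"ENaC"`, `"RBF"` (other names are allowed for user-defined
#'   drivers).
#' @param mean Daily mean \eqn{X_{p,0}} in the native units of the quantity
#'   (default 1, a pure multiplier).
#' @param amplitude_frac Fractional amplitude \eqn{\gamma_p} in `[0, 1)`.
#' @param peak_zt Peak time \eqn{\theta_p} in hours; reduced modulo 24.
#' @return An object of class `driver_spec`.
#' @export
#' @examples
#' gfr <- driver_spec("GFR", amplitude_frac = 0.14, peak_zt = 18)
#' driver_value(gfr, 18) # 1.14
driver_spec <- function(name, mean = 1, amplitude_frac = 0, peak_zt = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0) {
    stop("`mean` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(amplitude_frac) || length(amplitude_frac) != 1L ||
      amplitude_frac < 0 || amplitude_frac >= 1) {
    stop("`amplitude_frac` must lie in [0, 1): the driver must stay positive",
         call. = FALSE)
  }
  structure(
    list(name = name, mean = mean, amplitude_frac = amplitude_frac,
         peak_zt = clock_time(peak_zt)),
    class = "driver_spec"
  )
}

#' @export
print.driver_spec <- function(x, ...) {
  cat(sprintf("<driver_spec> %s: mean %.4g, amplitude %.0f%%, peak ZT%g\n",
              x$name, x$mean, 100 * x$amplitude_frac, x$peak_zt))
  invisible(x)
}

#' Evaluate a circadian driver at given zeitgeber times
#'
#' @param spec A [driver_spec()].
#' @param t Zeitgeber time(s) in hours; reduced modulo 24.
#' @return Numeric vector of driver values (same units as `spec$mean`),
#'   strictly positive and bounded by `mean * (1 +/- amplitude_frac)`.
#' @export
driver_value <- function(spec, t) {
  stopifnot(inherits(spec, "driver_spec"))
  t <- clock_time(t)
  spec$mean * (1 + spec$amplitude_frac *
                 sin(2 * pi * (t + 6 - spec$peak_zt) / 24))
}

#' Circadian parameter table for the rat kidney model
#'
#' Returns the seven clock-regulated quantities of the model: GFR, the five
#' apical sodium transporters and renal blood flow. Oscillation amplitudes
#' and peak times are shared between the sexes (the sex differences live in
#' the mean transport parameters, not in the clock). All drivers are
#' dimensionless multipliers with mean 1.
#'
#' @param sex `"male"` or `"female"`.
#' @param rbf_amplitude Fractional amplitude of the renal blood flow driver.
#'   The default 0.20 is the tabulated value; it is exposed as an override
#'   because estimates up to ~0.4 exist in the literature.
#' @return Named list of [driver_spec()] objects.
#' @export
#' @examples
#' default_driver_table("male")$ENaC
default_driver_table <- function(sex = c("male", "female"),
                                 rbf_amplitude = 0.20) {
  sex <- match.arg(sex)
  list(
    GFR   = driver_spec("GFR",   amplitude_frac = 0.14, peak_zt = 18),
    NHE3  = driver_spec("NHE3",  amplitude_frac = 0.40, peak_zt = 14),
    SGLT1 = driver_spec("SGLT1", amplitude_frac = 0.20, peak_zt = 14),
    NKCC2 = driver_spec("NKCC2", amplitude_frac = 0.20, peak_zt = 14),
    NCC   = driver_spec("NCC",   amplitude_frac = 0.20, peak_zt = 14),
    ENaC  = driver_spec("ENaC",  amplitude_frac = 0.56, peak_zt = 14),
    RBF   = driver_spec("RBF",   amplitude_frac = rbf_amplitude, peak_zt = 10)
  )
}

#' Hourly evaluation grid over one circadian period
#'
#' The canonical grid for daily means and reported profiles: 24 hourly
#' points `0, 1, ..., 23`. Any uniform grid with at least two points per
#' period averages a sinusoid exactly to its mean; hourly is cheap and is
#' used consistently for baseline references and the oxygen-tension
#' calibration.
#'
#' @return Numeric vector of 24 hours.
#' @export
hourly_grid <- function() seq(0, 23, by = 1)

#' Daily mean of a driver over a time grid
#'
#' @param spec A [driver_spec()].
#' @param grid Times in hours; for an exact daily mean use a uniform grid
#'   over `[0, 24)` such as [hourly_grid()].
#' @return Arithmetic mean of [driver_value()] over the grid.
#' @export
daily_mean <- function(spec, grid = hourly_grid()) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  mean(driver_value(spec, grid))
}

#' Export a driver table as a tidy data frame / CSV
#'
#' @param sex `"male"` or `"female"`.
#' @param file Optional path; when given, the table is written as CSV.
#' @param ... Passed to [default_driver_table()].
#' @return Data frame with columns `name`, `sex`, `mean`, `amplitude_frac`,
#'   `peak_zt` (invisibly when writing to file).
#' @export
driver_table_df <- function(sex = c("male", "female"), file = NULL, ...) {
  sex <- match.arg(sex)
  tab <- default_driver_table(sex, ...)
  df <- data.frame(
    name = vapply(tab, `[[`, "", "name"),
    sex = sex,
    mean = vapply(tab, `[[`, 0, "mean"),
    amplitude_frac = vapply(tab, `[[`, 0, "amplitude_frac"),
    peak_zt = vapply(tab, `[[`, 0, "peak_zt"),
    row.names = NULL
  )
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
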