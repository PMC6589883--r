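#' Voltage trace of one reactor
#'
#' Container for the logged cell voltage of a single MFC reactor under a
#' fixed external resistance. Internally everything is in SI units (s, V,
#' ohm, m^2); densities are converted to mA m^-2 / mW m^-2 at the reporting
#' boundary.
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param voltage_V cell voltage at each time, volts.
#' @param resistance_ohm external resistance, ohm (> 0).
#' @param cathode_area_m2 projected air-cathode area, m^2 (> 0).
#' @param reactor,treatment identifying labels.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(time_s, voltage_V, resistance_ohm,
                          cathode_area_m2 = 0.0036,
                          reactor = "r1", treatment = "NA") {
  time_s <- as.numeric(time_s)
  voltage_V <- as.numeric(voltage_V)
  if (length(time_s) != length(voltage_V))
    stop("time and voltage must have equal length")
  if (length(time_s) == 0L) stop("empty trace")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (!is.numeric(resistance_ohm) || resistance_ohm <= 0)
    stop("resistance must be > 0")
  if (!is.numeric(cathode_area_m2) || cathode_area_m2 <= 0)
    stop("cathode area must be > 0")
  structure(list(reactor = reactor, treatment = treatment,
                 time_s = time_s, voltage_V = voltage_V,
                 resistance_ohm = resistance_ohm,
                 cathode_area_m2 = cathode_area_m2),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace>", x$reactor, "/", x$treatment, ":",
      length(x$time_s), "samples over",
      round(diff(range(x$time_s)) / 86400, 2), "days, R =",
      x$resistance_ohm, "ohm\n")
  invisible(x)
}

#' Polarization sweep
#'
#' (external resistance, voltage) pairs recorded while stepping the load,
#' typically from 10000 down to 100 ohm.
#'
#' @param resistance_ohm positive load resistances, ohm.
#' @param voltage_V measured cell voltages, V.
#' @param treatment label.
#' @return An object of class `polarization_sweep`.
#' @export
polarization_sweep <- function(resistance_ohm, voltage_V, treatment = "NA") {
  if (length(resistance_ohm) != length(voltage_V))
    stop("resistance and voltage must have equal length")
  if (length(resistance_ohm) == 0L) stop("empty resistance ladder")
  if (any(resistance_ohm <= 0)) stop("resistances must be > 0")
  structure(list(resistance_ohm = as.numeric(resistance_ohm),
                 voltage_V = as.numeric(voltage_V),
                 treatment = treatment),
            class = "polarization_sweep")
}

#' Current density
#'
#' I' = U / (R * A), reported in mA m^-2 and normalized to the projected
#' cathode area.
#'
#' @param voltage_V cell voltage(s), V.
#' @param resistance_ohm external resistance, ohm (> 0).
#' @param area_m2 cathode area, m^2 (> 0).
#' @return Current density in mA m^-2 (vectorized over `voltage_V`).
#' @export
current_density <- function(voltage_V, resistance_ohm, area_m2 = 0.0036) {
  if (any(resistance_ohm <= 0)) stop("resistance must be > 0")
  if (any(area_m2 <= 0)) stop("area must be > 0")
  1000 * voltage_V / (resistance_ohm * area_m2)
}

#' Power density
#'
#' P' = U^2 / (R * A), reported in mW m^-2.
#'
#' @inheritParams current_density
#' @return Power density in mW m^-2.
#' @export
power_density <- function(voltage_V, resistance_ohm, area_m2 = 0.0036) {
  if (any(resistance_ohm <= 0)) stop("resistance must be > 0")
  if (any(area_m2 <= 0)) stop("area must be > 0")
  1000 * voltage_V^2 / (resistance_ohm * area_m2)
}

#' Accumulated charge
#'
#' Q = integral of U/R dt over the trace. The default mirrors the logger's
#' per-cycle bookkeeping: a rectangle rule at the recorded cadence, each
#' sample standing for the interval up to the next one (the 1800 s logging
#' cycle when times are absent). A trapezoid rule is available.
#'
#' @param trace a [voltage_trace()], or a numeric voltage vector.
#' @param method `"rectangle"` (default, left endpoints) or `"trapezoid"`.
#' @param dt_s sampling interval used when `trace` is a bare voltage vector,
#'   seconds.
#' @param resistance_ohm external resistance when `trace` is a bare vector.
#' @return Accumulated charge in coulombs.
#' @export
accumulate_charge <- function(trace, method = c("rectangle", "trapezoid"),
                              dt_s = 1800, resistance_ohm = NULL) {
  method <- match.arg(method)
  if (inherits(trace, "voltage_trace")) {
    u <- trace$voltage_V
    r <- trace$resistance_ohm
    t <- trace$time_s
  } else {
    u <- as.numeric(trace)
    if (is.null(resistance_ohm)) stop("resistance_ohm required for bare voltages")
    r <- resistance_ohm
    if (is.null(dt_s)) stop("missing timestamps and no default interval")
    t <- seq_along(u) * dt_s  # uniform cadence
  }
  if (length(u) == 0L) stop("empty trace")
  if (length(u) == 1L) return(0)
  dt <- diff(t)
  i <- u / r
  switch(method,
         rectangle = sum(i[-length(i)] * dt),
         trapezoid = sum((i[-length(i)] + i[-1]) / 2 * dt))
}

#' Start-up time
#'
#' Time for the voltage output to first exceed a threshold (1 mV by
#' convention), in hours. Returns `NA` when the threshold is never crossed.
#'
#' @param trace a [voltage_trace()].
#' @param threshold_V crossing threshold, volts.
#' @return Hours to first crossing, or `NA_real_`.
#' @export
startup_time <- function(trace, threshold_V = 0.001) {
  stopifnot(inherits(trace, "voltage_trace"))
  hit <- which(trace$voltage_V > threshold_V)
  if (length(hit) == 0L) return(NA_real_)
  trace$time_s[hit[1L]] / 3600
}

#' Fit a polarization curve
#'
#' Converts each sweep point to current I = U/R, then fits the ohmic region
#' of U = OCV - Rint * I by least squares. The highest-current fraction of
#' points (activation / mass-transport tails) is excluded from the fit;
#' the power-density curve is returned for every point.
#'
#' @param sweep a [polarization_sweep()].
#' @param area_m2 cathode area used for the density conversions.
#' @param ohmic_frac fraction of points, ranked by current, kept in the fit
#'   (default 0.9: the highest-current 10 percent is excluded).
#' @return A list with `ocv_V`, `internal_resistance_ohm`, and a data frame
#'   `power_curve` (resistance_ohm, voltage_V, current_density_mA_m2,
#'   power_density_mW_m2).
#' @export
fit_polarization <- function(sweep, area_m2 = 0.0036, ohmic_frac = 0.9) {
  stopifnot(inherits(sweep, "polarization_sweep"))
  u <- sweep$voltage_V
  r <- sweep$resistance_ohm
  if (length(u) < 3L) stop("need >= 3 sweep points")
  i <- u / r
  if (diff(range(i)) == 0) stop("degenerate sweep: all currents identical")
  keep <- i <= quantile(i, ohmic_frac, names = FALSE)
  if (sum(keep) < 2L) keep <- rep(TRUE, length(i))
  fit <- lm(u[keep] ~ i[keep])
  ocv <- unname(coef(fit)[1L])
  rint <- -unname(coef(fit)[2L])
  curve <- data.frame(
    resistance_ohm = r,
    voltage_V = u,
    current_density_mA_m2 = current_density(u, r, area_m2),
    power_density_mW_m2 = power_density(u, r, area_m2)
  )
  curve <- curve[order(curve$current_density_mA_m2), , drop = FALSE]
  rownames(curve) <- NULL
  list(ocv_V = ocv, internal_resistance_ohm = rint, power_curve = curve)
}

#' Percent increase of a over b
#'
#' (a - b) / b * 100. Used throughout reporting, e.g. "23 percent higher".
#'
#' @param a,b numeric values; `b` must be nonzero.
#' @param digits rounding applied to the result; `NULL` keeps full precision.
#' @return Percent increase (negative when `a < b`).
#' @export
percent_increase <- function(a, b, digits = NULL) {
  if (any(b == 0)) stop("reference value must be nonzero")
  out <- (a - b) / b * 100
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Summary metrics of one voltage trace
#'
#' Start-up time, first current-density peak (maximum within an early
#' window), overall maximum current density, and accumulated charge.
#'
#' @param trace a [voltage_trace()].
#' @param first_peak_window_days window, in days, scanned for the first peak.
#' @param threshold_V start-up threshold.
#' @return A one-row data frame of metrics.
#' @export
trace_summary <- function(trace, first_peak_window_days = c(1, 3),
                          threshold_V = 0.001) {
  stopifnot(inherits(trace, "voltage_trace"))
  cd <- current_density(trace$voltage_V, trace$resistance_ohm,
                        trace$cathode_area_m2)
  t_d <- trace$time_s / 86400
  win <- t_d >= first_peak_window_days[1] & t_d <= first_peak_window_days[2]
  data.frame(
    reactor = trace$reactor,
    treatment = trace$treatment,
    startup_time_h = startup_time(trace, threshold_V),
    first_peak_mA_m2 = if (any(win)) max(cd[win]) else NA_real_,
    max_current_density_mA_m2 = max(cd),
    charge_C = accumulate_charge(trace),
    stringsAsFactors = FALSE
  )
}
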