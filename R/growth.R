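# Growth-curve kinetics: exponential rates, yields, diauxie detection and
# shift duration from calibrated OD600 time series.

validate_curve <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time_h", "od") %in% names(curve))) {
    stop_diauxr("a growth curve needs columns `time_h` and `od`",
                "diauxr_parameter_error")
  }
  keep <- complete.cases(curve[c("time_h", "od")])
  curve <- curve[keep, , drop = FALSE]
  if (nrow(curve) < 2L) {
    stop_diauxr("a growth curve needs at least 2 points",
                "diauxr_parameter_error")
  }
  if (any(curve$od <= 0)) {
    stop_diauxr("all OD values must be positive", "diauxr_parameter_error")
  }
  if (any(diff(curve$time_h) <= 0)) {
    stop_diauxr("`time_h` must be strictly increasing",
                "diauxr_parameter_error")
  }
  curve
}

#' Calibrate raw plate-reader OD readouts
#'
#' Plate-reader OD600 readouts are multiplied by a path-length calibration
#' factor (default 2.2) to make them comparable to a 1-cm-cuvette
#' spectrophotometer. All OD window bounds in this package refer to
#' calibrated OD.
#'
#' @param x numeric OD readouts, or a data frame with an `od` column.
#' @param factor positive calibration scalar.
#' @return same shape as `x`, with OD multiplied by `factor`; data frames
#'   record the factor in attribute `calibration`.
#' @examples
#' calibrate_od(0.10)            # 0.22
#' @export
calibrate_od <- function(x, factor = 2.2) {
  check_number(factor, "factor", lower = 0, allow_zero = FALSE)
  if (factor <= 0) {
    stop_diauxr("calibration `factor` must be positive",
                "diauxr_parameter_error")
  }
  if (is.data.frame(x)) {
    if (!"od" %in% names(x)) {
      stop_diauxr("data frame has no `od` column", "diauxr_parameter_error")
    }
    x$od <- x$od * factor
    attr(x, "calibration") <- factor * (attr(x, "calibration") %||% 1)
    return(x)
  }
  x * factor
}

# indices of the first contiguous run of points with od inside [lo, hi]
window_indices <- function(od, lo, hi) {
  first_run(od >= lo & od <= hi)
}

#' Fit the exponential growth rate from an OD window
#'
#' Ordinary least squares of ln(OD) on time over the first contiguous run of
#' readouts whose calibrated OD lies inside `[od_lo, od_hi]` (inclusive; no
#' interpolation to the exact bounds). The slope is the specific growth rate
#' mu in 1/h.
#'
#' @param curve data frame with columns `time_h` (hours, strictly
#'   increasing) and `od` (calibrated, positive).
#' @param od_lo,od_hi OD bounds of the regression window (defaults
#'   0.05-0.35, the exponential-phase window).
#' @param min_points minimum readouts required inside the window.
#' @return an object of class `growth_fit`: fields `mu`, `intercept`
#'   (ln-OD), `se_mu`, `r2`, `n_points`, `df`, and `window` (index range,
#'   time range and OD bounds used). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' curve <- data.frame(time_h = 0:2, od = 0.06 * 2^(0:2))
#' fit_growth_rate(curve)$mu   # ln(2)
#' @export
fit_growth_rate <- function(curve, od_lo = 0.05, od_hi = 0.35,
                            min_points = 5L) {
  curve <- validate_curve(curve)
  idx <- window_indices(curve$od, od_lo, od_hi)
  if (length(idx) < max(2L, min_points)) {
    stop_diauxr(sprintf(
      "window underpopulated: %d point(s) with OD in [%g, %g], need %d",
      length(idx), od_lo, od_hi, min_points), "diauxr_window_error")
  }
  f <- ols_fit(curve$time_h[idx], log(curve$od[idx]))
  structure(
    list(mu = f$slope, intercept = f$intercept, se_mu = f$se, r2 = f$r2,
         n_points = f$n, df = f$df,
         window = list(idx = range(idx),
                       time_h = range(curve$time_h[idx]),
                       od_lo = od_lo, od_hi = od_hi)),
    class = "growth_fit")
}

#' Growth yield as the maximum of the smoothed OD trace
#'
#' The yield of a batch culture is its maximum OD. A centered local-linear
#' smoother (5 readouts, i.e. 50 min at 10-min sampling) suppresses
#' single-readout spikes before taking the maximum.
#'
#' @inheritParams fit_growth_rate
#' @param smooth_window odd readout count for the smoother; 1 disables
#'   smoothing.
#' @return maximum smoothed OD, a single number.
#' @export
yield_max_od <- function(curve, smooth_window = 5L) {
  curve <- validate_curve(curve)
  od <- if (smooth_window > 1L && nrow(curve) >= smooth_window) {
    local_linear(curve$time_h, curve$od, window = smooth_window)
  } else {
    curve$od
  }
  max(od)
}

#' Detect diauxic growth by the two-slope regression test
#'
#' Two independent ln-linear fits are compared: the primary exponential
#' window (OD `od_lo`-`od_hi`) and an extended window from `od_lo` up to 90%
#' of the maximum (smoothed) OD, which includes any later growth phase. A
#' second, slower phase lowers the extended slope; slope equality is tested
#' with a two-sample Welch t statistic, one-sided in the direction extended
#' < primary. Curves whose two slopes are statistically indistinguishable
#' (p > alpha) are classified single-phase.
#'
#' @inheritParams fit_growth_rate
#' @param alpha significance threshold for the slope-equality test.
#' @param max_frac upper OD bound of the extended window as a fraction of
#'   maximum OD.
#' @return an object of class `diauxic_call`: `slope_primary`,
#'   `slope_extended`, `p_value`, `is_diauxic`, `alpha`, `flag` (set when
#'   the extended slope significantly exceeds the primary one, a data
#'   quality warning), and the two component fits.
#' @export
detect_diauxie <- function(curve, alpha = 0.05, od_lo = 0.05, od_hi = 0.35,
                           max_frac = 0.9, min_points = 5L) {
  curve <- validate_curve(curve)
  primary <- fit_growth_rate(curve, od_lo = od_lo, od_hi = od_hi,
                             min_points = min_points)
  hi_ext <- max_frac * yield_max_od(curve)
  idx <- window_indices(curve$od, od_lo, hi_ext)
  if (length(idx) < max(2L, min_points)) {
    stop_diauxr(sprintf(
      "extended window underpopulated: %d point(s) with OD in [%g, %g]",
      length(idx), od_lo, hi_ext), "diauxr_window_error")
  }
  f <- ols_fit(curve$time_h[idx], log(curve$od[idx]))
  extended <- list(mu = f$slope, se_mu = f$se, df = f$df, n_points = f$n,
                   window = list(idx = range(idx), od_lo = od_lo,
                                 od_hi = hi_ext))
  denom <- sqrt(primary$se_mu^2 + extended$se_mu^2)
  diff_mu <- primary$mu - extended$mu
  if (!is.finite(denom) || denom < 1e-12) {
    # exact fits (noiseless data): slopes either agree or differ outright
    p_lower <- if (diff_mu > 1e-9) 0 else 1
    p_greater <- if (diff_mu < -1e-9) 0 else 1
  } else {
    tstat <- diff_mu / denom
    df_w <- denom^4 / (primary$se_mu^4 / primary$df +
                       extended$se_mu^4 / extended$df)
    p_lower <- pt(tstat, df_w, lower.tail = FALSE)   # extended < primary
    p_greater <- pt(tstat, df_w, lower.tail = TRUE)
  }
  flag <- p_greater <= alpha
  is_diauxic <- (p_lower <= alpha) && (extended$mu < primary$mu) && !flag
  structure(
    list(slope_primary = primary$mu, slope_extended = extended$mu,
         p_value = p_lower, is_diauxic = is_diauxic, alpha = alpha,
         flag = flag, primary = primary, extended = extended),
    class = "diauxic_call")
}

#' Estimate the diauxic-shift duration
#'
#' The shift is the growth-arrest interval between the glucose and acetate
#' phases. The smoothed specific growth rate d(ln OD)/dt (centered
#' local-linear slope) is scanned after the primary exponential window: the
#' shift starts when it first falls below `mu_threshold` and ends when it
#' next rises back above it. The raw threshold crossings locate the
#' transitions; each boundary is then refined at the half-height crossing
#' of the adjacent growth plateau (glucose-phase slope before the arrest,
#' post-shift plateau after it). Because the smoothing kernel is symmetric,
#' its step response passes 50% exactly at the true transition time, so the
#' half-height crossing is unbiased on noiseless curves and sits on the
#' steepest part of the smoothed ramp, where readout noise displaces it
#' least. Crossing times are interpolated linearly between readouts. Only
#' defined for curves classified diauxic.
#'
#' @inheritParams fit_growth_rate
#' @param call the [detect_diauxie()] result for the same curve.
#' @param mu_threshold specific-growth-rate cutoff in 1/h separating arrest
#'   from growth.
#' @param smooth_window odd readout count for the derivative smoother.
#' @return an object of class `shift_estimate`: `duration_h`, `t_start`,
#'   `t_end`, `threshold_mu`.
#' @export
estimate_shift <- function(curve, call, mu_threshold = 0.1,
                           smooth_window = 5L) {
  curve <- validate_curve(curve)
  if (!inherits(call, "diauxic_call")) {
    stop_diauxr("`call` must be a detect_diauxie() result",
                "diauxr_parameter_error")
  }
  if (!call$is_diauxic) {
    stop_diauxr("shift duration is undefined for single-phase curves",
                "diauxr_shift_error")
  }
  t <- curve$time_h
  mu_t <- local_linear(t, log(curve$od), window = smooth_window,
                       what = "slope")
  t_search <- call$primary$window$time_h[2L]
  dt_med <- stats::median(diff(t))
  w_span <- (smooth_window - 1L) * dt_med  # full kernel span
  interp <- function(j, thr) {
    # crossing between readouts j-1 and j, linearly interpolated
    if (j <= 1L || is.na(mu_t[j - 1L]) || mu_t[j] == mu_t[j - 1L]) {
      return(t[j])
    }
    t[j - 1L] + (thr - mu_t[j - 1L]) * (t[j] - t[j - 1L]) /
      (mu_t[j] - mu_t[j - 1L])
  }
  below <- which(!is.na(mu_t) & mu_t < mu_threshold & t > t_search)
  if (length(below) == 0L) {
    stop_diauxr("shift unresolved: growth rate never fell below the threshold",
                "diauxr_shift_error")
  }
  j_start <- below[1L]
  # arrest onset: half-height crossing of the primary-phase growth rate
  thr_down <- max(mu_threshold, call$slope_primary / 2)
  k <- j_start
  while (k > 1L && !is.na(mu_t[k - 1L]) && mu_t[k - 1L] < thr_down) {
    k <- k - 1L
  }
  t_start <- interp(k, thr_down)
  # regrowth must be sustained over 3 consecutive readouts: a single OD
  # outlier elevates up to two consecutive smoothed-slope points and would
  # otherwise fake the end of the arrest
  up <- !is.na(mu_t) & mu_t >= mu_threshold
  sustained <- up & c(up[-1L], FALSE) & c(up[-(1:2)], FALSE, FALSE)
  above <- which(sustained & seq_along(mu_t) > j_start)
  if (length(above) == 0L) above <- which(up & seq_along(mu_t) > j_start)
  if (length(above) == 0L) {
    stop_diauxr("shift unresolved: no regrowth above the threshold (culture entered stationary phase)",
                "diauxr_shift_error")
  }
  j_end <- above[1L]
  # post-shift plateau from the rate trace just after regrowth; its
  # half-height crossing marks the end of the arrest
  sel <- which(!is.na(mu_t) & t > t[j_end] & t <= t[j_end] + 2 * w_span)
  mu_post <- if (length(sel) > 0) {
    stats::quantile(mu_t[sel], 0.9, names = FALSE)
  } else {
    mu_t[j_end]
  }
  thr_up <- max(mu_threshold / 2, mu_post / 2)
  k <- j_end
  while (k > j_start && !is.na(mu_t[k - 1L]) && mu_t[k - 1L] >= thr_up) {
    k <- k - 1L
  }
  while (k <= length(mu_t) && (is.na(mu_t[k]) || mu_t[k] < thr_up)) {
    k <- k + 1L
  }
  t_end <- if (k > length(mu_t)) t[j_end] else interp(k, thr_up)
  if (t_end < t_start) t_end <- t_start
  structure(
    list(duration_h = t_end - t_start, t_start = t_start, t_end = t_end,
         threshold_mu = mu_threshold),
    class = "shift_estimate")
}

#' Per-well growth summary of a plate
#'
#' Applies [fit_growth_rate()], [yield_max_od()], [detect_diauxie()] and
#' [estimate_shift()] to every well of a [read_plate_table()] result and
#' returns one tidy row per well. Wells whose windows cannot be populated
#' get `NA` results rather than aborting the plate.
#'
#' @param plate a `plate_data` tibble.
#' @param od_lo,od_hi primary exponential window bounds.
#' @param alpha diauxie-test significance threshold.
#' @param mu_threshold shift-duration growth-rate cutoff, 1/h.
#' @return tibble with columns `well`, `strain`, `mu`, `se_mu`, `r2`,
#'   `max_od`, `is_diauxic`, `p_value`, `shift_h`.
#' @export
summarize_growth <- function(plate, od_lo = 0.05, od_hi = 0.35,
                             alpha = 0.05, mu_threshold = 0.1) {
  stopifnot(is.data.frame(plate))
  plate |>
    dplyr::group_by(.data$well, .data$strain) |>
    dplyr::group_modify(function(df, key) {
      curve <- df[c("time_h", "od")]
      fit <- tryCatch(fit_growth_rate(curve, od_lo, od_hi),
                      diauxr_error = function(e) NULL)
      call <- tryCatch(detect_diauxie(curve, alpha, od_lo, od_hi),
                       diauxr_error = function(e) NULL)
      shift <- if (!is.null(call) && call$is_diauxic) {
        tryCatch(estimate_shift(curve, call, mu_threshold),
                 diauxr_error = function(e) NULL)
      }
      tibble::tibble(
        mu = if (is.null(fit)) NA_real_ else fit$mu,
        se_mu = if (is.null(fit)) NA_real_ else fit$se_mu,
        r2 = if (is.null(fit)) NA_real_ else fit$r2,
        max_od = yield_max_od(curve),
        is_diauxic = if (is.null(call)) NA else call$is_diauxic,
        p_value = if (is.null(call)) NA_real_ else call$p_value,
        shift_h = if (is.null(shift)) NA_real_ else shift$duration_h)
    }) |>
    dplyr::ungroup()
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> mu = %.4f /h (se %.2g), r2 = %.4f, %d points, OD %.3g-%.3g\n",
    x$mu, x$se_mu, x$r2, x$n_points, x$window$od_lo, x$window$od_hi))
  invisible(x)
}

#' @export
print.diauxic_call <- function(x, ...) {
  cat(sprintf(
    "<diauxic_call> %s (primary %.3f, extended %.3f /h, one-sided p = %.3g)\n",
    if (x$is_diauxic) "diauxic" else "single-phase",
    x$slope_primary, x$slope_extended, x$p_value))
  invisible(x)
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %.2f h (%.2f to %.2f h at mu < %.2g /h)\n",
              x$duration_h, x$t_start, x$t_end, x$threshold_mu))
  invisible(x)
}
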