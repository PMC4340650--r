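# Substrate uptake/secretion physiology: yields by regression of
# extracellular concentration against biomass, specific rates as
# yield x growth rate, and co-utilization classification.

#' Substrate or product yield by regression against biomass
#'
#' Ordinary least squares of extracellular concentration on OD over an
#' exponential-phase window. The signed slope is the yield in g/l per OD
#' unit: negative for a consumed substrate (concentration falls as biomass
#' rises), positive for a secreted product. At least five points in the
#' window are required.
#'
#' @param series data frame with columns `time_h`, `od` and one
#'   concentration column per compound (g/l), e.g. `glucose_gl`.
#' @param compound name of the concentration column to regress.
#' @param window optional numeric length-2 time range (hours) delimiting the
#'   exponential phase; default uses all rows.
#' @param min_points minimum points required for the regression.
#' @return a tibble with one row: `compound`, `yield`, `se`, `n_points`,
#'   `r2`.
#' @export
substrate_yield <- function(series, compound, window = NULL,
                            min_points = 5L) {
  if (!is.data.frame(series) ||
      !all(c("time_h", "od", compound) %in% names(series))) {
    stop_diauxr(sprintf("`series` needs columns time_h, od and `%s`",
                        compound), "diauxr_parameter_error")
  }
  df <- series[complete.cases(series[c("time_h", "od", compound)]), ]
  if (!is.null(window)) {
    df <- df[df$time_h >= window[1L] & df$time_h <= window[2L], ]
  }
  if (nrow(df) < min_points) {
    stop_diauxr(sprintf(
      "only %d point(s) in the regression window; at least %d required",
      nrow(df), min_points), "diauxr_window_error")
  }
  f <- ols_fit(df$od, df[[compound]])
  tibble::tibble(compound = compound, yield = f$slope, se = f$se,
                 n_points = f$n, r2 = f$r2)
}

#' Specific uptake or secretion rate
#'
#' The specific rate is the yield multiplied by the growth rate. The sign of
#' the yield determines the role: uptake when concentration falls with
#' biomass (yield < 0), secretion otherwise; reported magnitudes are
#' positive with the role in a separate column. Standard errors are
#' propagated to first order from both inputs.
#'
#' @param yield signed yield in g/l per OD (a number or one-row tibble from
#'   [substrate_yield()]).
#' @param mu growth rate in 1/h (a number or a [fit_growth_rate()] result).
#' @param yield_se,mu_se standard errors; taken from the inputs when those
#'   are fitted objects.
#' @param min_rate threshold below which the rate is flagged indeterminate.
#' @return a tibble of class `rate_estimate` with columns `compound`,
#'   `yield`, `specific_rate` (g/l per OD per h, magnitude), `role`
#'   (`"uptake"`/`"secretion"`), `se`, `indeterminate`.
#' @examples
#' specific_rate(-2, 0.5)   # uptake at 1.0 g/l/OD/h
#' @export
specific_rate <- function(yield, mu, yield_se = NULL, mu_se = NULL,
                          min_rate = 0.05) {
  compound <- NA_character_
  if (is.data.frame(yield)) {
    compound <- yield$compound[1L]
    yield_se <- yield_se %||% yield$se[1L]
    yield <- yield$yield[1L]
  }
  if (inherits(mu, "growth_fit")) {
    mu_se <- mu_se %||% mu$se_mu
    mu <- mu$mu
  }
  if (!is.finite(mu) || mu < 0) {
    stop_diauxr("`mu` must be a nonnegative growth rate",
                "diauxr_parameter_error")
  }
  rate <- abs(yield) * mu
  se <- sqrt((mu * (yield_se %||% 0))^2 + (yield * (mu_se %||% 0))^2)
  out <- tibble::tibble(
    compound = compound,
    yield = yield,
    specific_rate = rate,
    role = if (yield < 0) "uptake" else "secretion",
    se = se,
    indeterminate = rate < min_rate)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Classify glucose/acetate co-utilization
#'
#' A culture co-utilizes when, over the same glucose-present window, both
#' compounds are taken up at rates at or above `min_rate`. The canonical
#' single-substrate pattern is glucose uptake with acetate secretion; when
#' both rates fall below `min_rate` the call is indeterminate.
#'
#' @param glc,ace [specific_rate()] rows for glucose and acetate estimated
#'   on the same window.
#' @param min_rate minimum rate magnitude (g/l per OD per h) to count a
#'   compound as actively used.
#' @return one of `"coutilizer"`, `"single_substrate"`, `"indeterminate"`.
#' @export
classify_cometabolism <- function(glc, ace, min_rate = 0.05) {
  stopifnot(is.data.frame(glc), is.data.frame(ace))
  g_up <- glc$role[1L] == "uptake" && glc$specific_rate[1L] >= min_rate
  a_up <- ace$role[1L] == "uptake" && ace$specific_rate[1L] >= min_rate
  if (glc$specific_rate[1L] < min_rate && ace$specific_rate[1L] < min_rate) {
    return("indeterminate")
  }
  if (g_up && a_up) "coutilizer" else "single_substrate"
}

#' All-in-one rate table for a concentration series
#'
#' Fits the growth rate on the OD trace, regresses every concentration
#' column against biomass over the exponential-phase window mapped to time,
#' and returns one tidy row per compound plus the co-utilization call as an
#' attribute (when glucose and acetate are both present).
#'
#' @inheritParams substrate_yield
#' @param compounds concentration columns to fit; defaults to every column
#'   ending in `_gl`.
#' @param od_lo,od_hi OD bounds defining the exponential window.
#' @param min_rate threshold for [classify_cometabolism()].
#' @return tibble: `compound`, `yield`, `se`, `mu`, `specific_rate`, `role`,
#'   `indeterminate`; attribute `cometabolism` holds the classification.
#' @export
summarize_rates <- function(series, compounds = NULL, od_lo = 0.05,
                            od_hi = 0.35, min_rate = 0.05,
                            min_points = 5L) {
  compounds <- compounds %||% grep("_gl$", names(series), value = TRUE)
  if (length(compounds) == 0L) {
    stop_diauxr("no concentration columns found", "diauxr_parameter_error")
  }
  fit <- fit_growth_rate(series[c("time_h", "od")], od_lo = od_lo,
                         od_hi = od_hi, min_points = min_points)
  window <- fit$window$time_h
  rows <- purrr::map(compounds, function(cmp) {
    y <- substrate_yield(series, cmp, window = window,
                         min_points = min_points)
    r <- specific_rate(y, fit, min_rate = min_rate)
    r$mu <- fit$mu
    r
  })
  out <- dplyr::bind_rows(rows)
  if (all(c("glucose_gl", "acetate_gl") %in% out$compound)) {
    attr(out, "cometabolism") <- classify_cometabolism(
      out[out$compound == "glucose_gl", ],
      out[out$compound == "acetate_gl", ], min_rate = min_rate)
  }
  out
}
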