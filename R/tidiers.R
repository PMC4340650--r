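#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_growth_rate one-row tibble of the fitted slope term.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = "mu", estimate = x$mu, std.error = x$se_mu,
                 statistic = x$mu / x$se_mu,
                 p.value = 2 * pt(abs(x$mu / x$se_mu), x$df,
                                  lower.tail = FALSE))
}

#' @describeIn fit_growth_rate one-row model summary.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n_points, df.residual = x$df,
                 od_lo = x$window$od_lo, od_hi = x$window$od_hi)
}

#' @describeIn detect_diauxie one-row tibble of the two slopes and the call.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.diauxic_call <- function(x, ...) {
  tibble::tibble(slope_primary = x$slope_primary,
                 slope_extended = x$slope_extended,
                 p_value = x$p_value, is_diauxic = x$is_diauxic,
                 flag = x$flag)
}

#' @describeIn estimate_shift one-row tibble of the shift interval.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.shift_estimate <- function(x, ...) {
  tibble::tibble(duration_h = x$duration_h, t_start = x$t_start,
                 t_end = x$t_end, threshold_mu = x$threshold_mu)
}

#' @describeIn summarize_window one-row tibble of the summary.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.expression_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, ci95 = x$ci95, n_runs = x$n_runs)
}

#' @describeIn crp_activity one-row tibble of the ratio.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.crp_activity <- function(x, ...) {
  tibble::tibble(value = x$value, ci95 = x$ci95,
                 numerator = x$numerator$mean,
                 denominator = x$denominator$mean)
}

#' @describeIn delta_delta_ct one-row tibble of the fold change.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.fold_change <- function(x, ...) {
  tibble::tibble(fold = x$value, delta_delta_ct = x$delta_delta_ct,
                 ci95 = x$ci95)
}

#' @describeIn fit_allele_standard_curve mixture points of the fitted curve.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.allele_curve <- function(x, ...) x$points

#' @describeIn fit_allele_standard_curve one-row curve summary.
#' @export
glance.allele_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r2,
                 form = x$form, n_mixtures = nrow(x$points))
}

#' @describeIn estimate_allele_frequency one-row tibble of the estimate.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.frequency_estimate <- function(x, ...) {
  tibble::tibble(fraction = x$fraction, ci95 = x$ci95,
                 clamped = x$clamped, censored = x$censored)
}
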