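# Promoter-reporter dynamics: transcriptional activity (GFP/OD), promoter
# activity (dGFP/dt/OD), exponential-phase expression summaries, the
# CRP-activity ratio and between-strain percent changes.

validate_reporter_curve <- function(rc) {
  if (!is.data.frame(rc) ||
      !all(c("time_h", "od", "gfp") %in% names(rc))) {
    stop_diauxr("a reporter curve needs columns `time_h`, `od` and `gfp`",
                "diauxr_parameter_error")
  }
  keep <- complete.cases(rc[c("time_h", "od", "gfp")])
  rc <- rc[keep, , drop = FALSE]
  if (any(diff(rc$time_h) <= 0)) {
    stop_diauxr("`time_h` must be strictly increasing",
                "diauxr_parameter_error")
  }
  rc
}

#' Transcriptional activity: GFP per OD
#'
#' Pointwise reporter fluorescence divided by biomass, a per-cell expression
#' proxy. Points with OD below `od_floor` are dropped (the quotient is
#' noise-dominated there) and counted in attribute `n_dropped`.
#'
#' @param rc data frame with columns `time_h`, `od`, `gfp`.
#' @param od_floor minimum calibrated OD for a retained point.
#' @return tibble `time_h`, `od`, `transcriptional` (GFP/OD units).
#' @export
transcriptional_activity <- function(rc, od_floor = 0.02) {
  rc <- validate_reporter_curve(rc)
  keep <- rc$od >= od_floor
  if (!any(keep)) {
    stop_diauxr("all points fall below the OD floor; empty trajectory",
                "diauxr_window_error")
  }
  out <- tibble::tibble(time_h = rc$time_h[keep], od = rc$od[keep],
                        transcriptional = rc$gfp[keep] / rc$od[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Promoter activity: dGFP/dt per OD
#'
#' The GFP synthesis-rate proxy: the time derivative of fluorescence,
#' estimated by a centered local-linear regression over `smooth_window`
#' readouts, divided by the OD at the window center. Defined on interior
#' points only (where the full window fits); edge points are dropped.
#'
#' @inheritParams transcriptional_activity
#' @param smooth_window odd readout count for the derivative estimator.
#' @return tibble `time_h`, `od`, `promoter` (GFP/OD/h units).
#' @export
promoter_activity <- function(rc, smooth_window = 5L, od_floor = 0.02) {
  rc <- validate_reporter_curve(rc)
  if (nrow(rc) < smooth_window) {
    stop_diauxr("smoothing window is larger than the series",
                "diauxr_parameter_error")
  }
  dgfp <- local_linear(rc$time_h, rc$gfp, window = smooth_window,
                       what = "slope")
  keep <- !is.na(dgfp) & rc$od >= od_floor
  if (!any(keep)) {
    stop_diauxr("no interior points above the OD floor; empty trajectory",
                "diauxr_window_error")
  }
  out <- tibble::tibble(time_h = rc$time_h[keep], od = rc$od[keep],
                        promoter = dgfp[keep] / rc$od[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Exponential-phase expression summary across replicates
#'
#' Averages an activity trajectory over the growth period where OD lies in
#' `[od_lo, od_hi]` (the first contiguous run; default 0.1-0.3, the
#' operational exponential phase), per replicate, then reports the
#' across-replicate mean with a t-based 95% confidence half-width.
#'
#' @param replicates a list of trajectory tibbles (one per replicate
#'   experiment), each with an `od` column and the activity column `value`.
#' @param value name of the activity column to average (e.g.
#'   `"transcriptional"` or `"promoter"`).
#' @param od_lo,od_hi OD bounds of the averaging window.
#' @return an object of class `expression_summary`: `mean`, `ci95`
#'   (half-width; 0 when fewer than 2 replicates vary), `n_runs`,
#'   `replicate_means`, `window`.
#' @export
summarize_window <- function(replicates, value = "transcriptional",
                             od_lo = 0.1, od_hi = 0.3) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  means <- purrr::imap_dbl(replicates, function(df, i) {
    if (!all(c("od", value) %in% names(df))) {
      stop_diauxr(sprintf("replicate %s lacks `od` or `%s` column", i, value),
                  "diauxr_parameter_error")
    }
    idx <- window_indices(df$od, od_lo, od_hi)
    if (length(idx) == 0L) {
      stop_diauxr(sprintf("replicate %s has no points with OD in [%g, %g]",
                          i, od_lo, od_hi), "diauxr_window_error")
    }
    mean(df[[value]][idx])
  })
  n <- length(means)
  ci95 <- if (n >= 2L && sd(means) > 0) {
    qt(0.975, n - 1L) * sd(means) / sqrt(n)
  } else {
    0
  }
  structure(list(mean = mean(means), ci95 = ci95, n_runs = n,
                 replicate_means = means,
                 window = c(od_lo = od_lo, od_hi = od_hi)),
            class = "expression_summary")
}

#' CRP activity: hybrid-promoter over constitutive-promoter transcription
#'
#' The cAMP-CRP regulatory activity statistic: transcription driven by a
#' CRP-binding-site hybrid promoter (epd-CBS) divided by that of the
#' constitutive epd promoter measured in the same condition. The confidence
#' half-width is propagated to first order from the two summaries.
#'
#' @param num [summarize_window()] result for the epd-CBS hybrid promoter.
#' @param den [summarize_window()] result for the constitutive epd promoter.
#' @return an object of class `crp_activity`: `value`, `ci95`, and the two
#'   component summaries.
#' @examples
#' crp_activity(expression_summary(9555, 51), expression_summary(1479, 43))
#' @export
crp_activity <- function(num, den) {
  num <- as_expression_summary(num)
  den <- as_expression_summary(den)
  if (!is.finite(den$mean) || den$mean <= 0) {
    stop_diauxr("denominator (constitutive promoter) mean must be positive",
                "diauxr_parameter_error")
  }
  value <- num$mean / den$mean
  ci95 <- value * sqrt((num$ci95 / num$mean)^2 + (den$ci95 / den$mean)^2)
  structure(list(value = value, ci95 = ci95, numerator = num,
                 denominator = den),
            class = "crp_activity")
}

#' Construct an expression summary from printed values
#'
#' Wraps a reported mean and 95% confidence half-width (as printed in a
#' results table) so it can feed [crp_activity()] and [percent_change()].
#'
#' @param mean reported mean activity.
#' @param ci95 reported 95% confidence half-width.
#' @param n_runs replicate count behind the summary, if known.
#' @return an `expression_summary` object.
#' @export
expression_summary <- function(mean, ci95 = 0, n_runs = NA_integer_) {
  structure(list(mean = mean, ci95 = ci95, n_runs = n_runs,
                 replicate_means = NULL, window = NULL),
            class = "expression_summary")
}

as_expression_summary <- function(x) {
  if (inherits(x, "expression_summary")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(expression_summary(x))
  stop_diauxr("expected an expression summary or a single number",
              "diauxr_parameter_error")
}

#' Percent change between two expression summaries
#'
#' Signed percent difference of a test mean relative to a reference mean,
#' `100 * (test - reference) / reference`. For comparison with printed
#' tables use `round = TRUE`, which rounds half away from zero to the
#' nearest integer.
#'
#' @param test,reference [summarize_window()] results (or single numbers,
#'   e.g. printed means).
#' @param round logical; round to the nearest integer percent.
#' @return signed percent, a single number.
#' @examples
#' percent_change(3802, 3284, round = TRUE)   # +16
#' @export
percent_change <- function(test, reference, round = FALSE) {
  test <- as_expression_summary(test)
  reference <- as_expression_summary(reference)
  if (!is.finite(reference$mean) || reference$mean <= 0) {
    stop_diauxr("reference mean must be positive", "diauxr_parameter_error")
  }
  pc <- 100 * (test$mean - reference$mean) / reference$mean
  if (round) round_half_away(pc) else pc
}

#' @export
print.expression_summary <- function(x, ...) {
  cat(sprintf("<expression_summary> %.4g +/- %.2g (95%% CI, n = %s)\n",
              x$mean, x$ci95, x$n_runs))
  invisible(x)
}

#' @export
print.crp_activity <- function(x, ...) {
  cat(sprintf("<crp_activity> %.3g +/- %.2g (95%% CI)\n", x$value, x$ci95))
  invisible(x)
}
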