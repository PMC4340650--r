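# qPCR quantification: relative expression by 2^ddCt against a reference
# gene, and allele-frequency estimation from a mixture standard curve.

#' Construct a qPCR sample
#'
#' @param sample sample (condition) label.
#' @param gene gene label (target, or the reference such as rpoD).
#' @param ct numeric replicate cycle-threshold values; `NA` marks a
#'   censored ("no amplification") replicate.
#' @return an object of class `qpcr_sample`.
#' @export
qpcr_sample <- function(sample, gene, ct) {
  if (length(ct) < 1L) {
    stop_diauxr("at least one Ct replicate is required",
                "diauxr_parameter_error")
  }
  if (any(!is.na(ct) & (ct <= 0 | !is.finite(ct)))) {
    stop_diauxr("Ct values must be positive and finite (or NA if censored)",
                "diauxr_parameter_error")
  }
  structure(list(sample = sample, gene = gene, ct = ct),
            class = "qpcr_sample")
}

#' Relative expression by the 2^ddCt method
#'
#' dCt is the mean Ct of the target gene minus that of the reference gene
#' within a condition; ddCt is dCt(control) - dCt(test); the expression
#' fold change of test relative to control is `2^ddCt` (100% amplification
#' efficiency assumed). When all four samples carry equal replicate counts
#' (>= 2) the confidence half-width comes from recomputing ddCt per
#' replicate.
#'
#' @param target_test,ref_test target- and reference-gene samples of the
#'   test condition ([qpcr_sample()] objects).
#' @param target_ctrl,ref_ctrl the same for the control condition.
#' @return an object of class `fold_change`: `value` (= 2^ddCt exactly),
#'   `delta_delta_ct`, `ci95` (NA when replicate structure does not permit
#'   it).
#' @examples
#' fc <- delta_delta_ct(
#'   target_test = qpcr_sample("ZED", "pntAB", c(20, 20.1, 19.9)),
#'   ref_test    = qpcr_sample("ZED", "rpoD",  c(18, 18.0, 18.0)),
#'   target_ctrl = qpcr_sample("WT",  "pntAB", c(22, 22.1, 21.9)),
#'   ref_ctrl    = qpcr_sample("WT",  "rpoD",  c(18, 18.0, 18.0)))
#' fc$value   # about 4
#' @export
delta_delta_ct <- function(target_test, ref_test, target_ctrl, ref_ctrl) {
  samples <- list(target_test = target_test, ref_test = ref_test,
                  target_ctrl = target_ctrl, ref_ctrl = ref_ctrl)
  for (nm in names(samples)) {
    s <- samples[[nm]]
    if (!inherits(s, "qpcr_sample")) {
      stop_diauxr(sprintf("`%s` must be a qpcr_sample", nm),
                  "diauxr_parameter_error")
    }
    if (any(is.na(s$ct))) {
      stop_diauxr(sprintf("censored Ct among `%s` replicates", nm),
                  "diauxr_censored_error")
    }
  }
  if (target_test$gene != target_ctrl$gene ||
      ref_test$gene != ref_ctrl$gene) {
    stop_diauxr("gene labels of test and control samples do not match",
                "diauxr_parameter_error")
  }
  dct_test <- mean(target_test$ct) - mean(ref_test$ct)
  dct_ctrl <- mean(target_ctrl$ct) - mean(ref_ctrl$ct)
  ddct <- dct_ctrl - dct_test
  value <- 2^ddct

  ns <- vapply(samples, function(s) length(s$ct), integer(1))
  ci95 <- NA_real_
  if (length(unique(ns)) == 1L && ns[1L] >= 2L) {
    per_rep <- (target_ctrl$ct - ref_ctrl$ct) -
      (target_test$ct - ref_test$ct)
    n <- length(per_rep)
    ddct_ci <- qt(0.975, n - 1L) * sd(per_rep) / sqrt(n)
    ci95 <- log(2) * value * ddct_ci  # delta method on 2^x
  }
  structure(list(value = value, delta_delta_ct = ddct, ci95 = ci95),
            class = "fold_change")
}

#' Fit an allele-frequency standard curve from defined mixtures
#'
#' Genomic DNA of two genotypes mixed at known ratios is amplified with an
#' allele-specific primer; allele frequency is inversely related to the
#' logarithm of the observed Ct. Two functional forms are offered:
#' `"fraction_on_logct"` (the default) regresses fraction directly on
#' log10(mean Ct); `"ct_on_logfraction"` is the conventional standard-curve
#' form, Ct regressed on log10(fraction), inverted at estimation time. The
#' 0% mixture carries no template for the allele-specific primer, so
#' censored points are excluded from the fit.
#'
#' @param mixtures data frame with columns `fraction` (percent) and `ct`
#'   (replicates as multiple rows; `NA` = censored), e.g. from
#'   [simulate_qpcr()].
#' @param form functional form of the curve (see Details).
#' @return an object of class `allele_curve`: `points` (fraction, mean Ct),
#'   `slope`, `intercept`, `r2`, `form`.
#' @export
fit_allele_standard_curve <- function(mixtures,
                                      form = c("fraction_on_logct",
                                               "ct_on_logfraction")) {
  form <- match.arg(form)
  if (!is.data.frame(mixtures) ||
      !all(c("fraction", "ct") %in% names(mixtures))) {
    stop_diauxr("`mixtures` needs columns `fraction` and `ct`",
                "diauxr_parameter_error")
  }
  pts <- mixtures |>
    dplyr::filter(!is.na(.data$ct), .data$fraction > 0) |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  if (nrow(pts) < 3L) {
    stop_diauxr("fewer than 3 usable (non-censored) mixture points",
                "diauxr_parameter_error")
  }
  if (length(unique(pts$ct)) < 2L) {
    stop_diauxr("mixture Cts are degenerate; slope is undefined",
                "diauxr_degenerate_error")
  }
  f <- if (form == "fraction_on_logct") {
    ols_fit(log10(pts$ct), pts$fraction)
  } else {
    ols_fit(log10(pts$fraction), pts$ct)
  }
  if (f$slope >= 0) {
    stop_diauxr("fitted slope is nonnegative: frequency must fall as Ct rises",
                "diauxr_degenerate_error")
  }
  structure(list(points = pts, slope = f$slope, intercept = f$intercept,
                 r2 = f$r2, form = form),
            class = "allele_curve")
}

#' Estimate an allele frequency from observed Ct values
#'
#' Inverts a fitted [fit_allele_standard_curve()] at the mean of the
#' replicate Cts and clamps the estimate to \[0, 100\]%. The confidence
#' half-width is obtained by pushing each replicate Ct through the curve. A
#' censored input (no amplification) returns 0% with the `censored` flag.
#'
#' @param curve an `allele_curve`.
#' @param ct numeric replicate cycle thresholds (NA = censored).
#' @return an object of class `frequency_estimate`: `fraction` (percent),
#'   `ci95`, `clamped`, `censored`.
#' @export
estimate_allele_frequency <- function(curve, ct) {
  if (!inherits(curve, "allele_curve")) {
    stop_diauxr("`curve` must come from fit_allele_standard_curve()",
                "diauxr_parameter_error")
  }
  if (all(is.na(ct))) {
    return(structure(list(fraction = 0, ci95 = 0, clamped = FALSE,
                          censored = TRUE),
                     class = "frequency_estimate"))
  }
  ct <- ct[!is.na(ct)]
  if (any(ct <= 0)) {
    stop_diauxr("Ct values must be positive", "diauxr_parameter_error")
  }
  invert <- function(c0) {
    if (curve$form == "fraction_on_logct") {
      curve$intercept + curve$slope * log10(c0)
    } else {
      10^((c0 - curve$intercept) / curve$slope)
    }
  }
  raw <- invert(mean(ct))
  fraction <- min(100, max(0, raw))
  per_rep <- vapply(ct, invert, numeric(1))
  n <- length(per_rep)
  ci95 <- if (n >= 2L && sd(per_rep) > 0) {
    qt(0.975, n - 1L) * sd(per_rep) / sqrt(n)
  } else {
    0
  }
  structure(list(fraction = fraction, ci95 = ci95,
                 clamped = !identical(raw, fraction), censored = FALSE),
            class = "frequency_estimate")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change> %.3g-fold (ddCt = %.3g, 95%% CI +/- %.2g)\n",
              x$value, x$delta_delta_ct, x$ci95))
  invisible(x)
}

#' @export
print.allele_curve <- function(x, ...) {
  cat(sprintf(
    "<allele_curve> %s: slope %.3g, intercept %.3g, r2 = %.4f (%d mixtures)\n",
    x$form, x$slope, x$intercept, x$r2, nrow(x$points)))
  invisible(x)
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("<frequency_estimate> %.1f%% +/- %.1f%s%s\n",
              x$fraction, x$ci95,
              if (x$clamped) " [clamped]" else "",
              if (x$censored) " [censored]" else ""))
  invisible(x)
}
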