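#' @importFrom stats lm coef pf pt qt sd var cor.test anova rnorm rlnorm rbinom
#'   setNames complete.cases approx
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# internal: stop with a classed condition so tests can match on class
stop_diauxr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "diauxr_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_diauxr(sprintf("`%s` must be a single finite number", name),
                "diauxr_parameter_error")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_diauxr(sprintf("`%s` = %g is outside the allowed range [%g, %g]",
                        name, x, lower, upper),
                "diauxr_parameter_error")
  }
  invisible(x)
}

#' Centered local-linear smoothing of a time series
#'
#' Runs a moving ordinary-least-squares regression of `y` on `x` over a
#' centered window and returns the fitted value (or slope) at each window
#' center. At the edges the window is truncated (fitted value) or the result
#' is `NA` (slope), so derivative traces are defined on interior points only.
#'
#' @param x numeric, strictly increasing (typically time in hours).
#' @param y numeric, same length as `x`.
#' @param window odd integer number of readouts in the moving window.
#' @param what `"fit"` for the smoothed value, `"slope"` for the local slope.
#' @return numeric vector of `length(y)`.
#' @keywords internal
local_linear <- function(x, y, window = 5L, what = c("fit", "slope")) {
  what <- match.arg(what)
  n <- length(y)
  if (length(x) != n) stop_diauxr("`x` and `y` lengths differ",
                                  "diauxr_parameter_error")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop_diauxr("`window` must be an odd integer >= 3", "diauxr_parameter_error")
  }
  if (what == "slope" && window > n) {
    stop_diauxr("smoothing window is larger than the series",
                "diauxr_parameter_error")
  }
  half <- window %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (what == "slope" && (hi - lo + 1L) < window) next
    xi <- x[lo:hi]
    yi <- y[lo:hi]
    xc <- xi - mean(xi)
    sxx <- sum(xc^2)
    slope <- if (sxx > 0) sum(xc * (yi - mean(yi))) / sxx else 0
    out[i] <- if (what == "slope") slope else mean(yi) + slope * (x[i] - mean(xi))
  }
  out
}

# half-away-from-zero rounding, used when comparing against printed tables
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# simple OLS of y on x returning slope, intercept, se of slope, r2, df
ols_fit <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) {
    stop_diauxr("zero variance in the regressor; regression is degenerate",
                "diauxr_degenerate_error")
  }
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  df <- n - 2L
  s2 <- if (df > 0) sum(resid^2) / df else NA_real_
  se <- if (df > 0) sqrt(s2 / sxx) else NA_real_
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1
  list(slope = slope, intercept = intercept, se = se, r2 = r2,
       df = df, n = n)
}

# first contiguous run of TRUE values; returns integer indices (or empty)
first_run <- function(flag) {
  if (!any(flag)) return(integer(0))
  start <- which(flag)[1L]
  end <- start
  while (end < length(flag) && flag[end + 1L]) end <- end + 1L
  start:end
}

# restore the RNG state on exit so seeded simulators do not disturb callers
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
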