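# Serial-passage accounting, competition-frequency trajectories and the
# cohort statistics used for evolved-isolate phenotypes.

#' Cell generations per serial passage
#'
#' At steady state a culture diluted `dilution`-fold regrows by exactly that
#' factor before the next transfer, so doublings per passage equal
#' `log2(dilution)`: 512-fold dilution gives 9 generations.
#'
#' @param dilution fold-dilution at transfer, >= 1.
#' @return doublings per passage.
#' @examples
#' generations_per_passage(512)   # 9
#' @export
generations_per_passage <- function(dilution) {
  check_number(dilution, "dilution", lower = 1)
  log2(dilution)
}

#' Total generations over an evolution experiment
#'
#' @param n_passages number of serial passages, >= 0.
#' @inheritParams generations_per_passage
#' @return `n_passages * log2(dilution)` doublings.
#' @examples
#' total_generations(113, 512)    # 1017
#' @export
total_generations <- function(n_passages, dilution) {
  check_number(n_passages, "n_passages", lower = 0)
  n_passages * generations_per_passage(dilution)
}

#' Genotype frequency from flow-cytometry counts
#'
#' The focal-genotype frequency with a 95% Wilson binomial interval, which
#' keeps good coverage at the boundary fractions seen late in competitions.
#' Samples with fewer than `min_total` counted cells are flagged.
#'
#' @param focal focal-genotype cell count.
#' @param total total cells counted.
#' @param min_total quality threshold on the total count (default 45000).
#' @param conf confidence level.
#' @return tibble: `fraction`, `lower`, `upper`, `low_count` flag.
#' @export
frequency_from_counts <- function(focal, total, min_total = 45000,
                                  conf = 0.95) {
  if (any(focal < 0) || any(total <= 0) || any(focal > total)) {
    stop_diauxr("need 0 <= focal <= total with total > 0",
                "diauxr_parameter_error")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- focal / total
  denom <- 1 + z^2 / total
  center <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  tibble::tibble(fraction = p,
                 lower = pmax(0, center - half),
                 upper = pmin(1, center + half),
                 low_count = total < min_total)
}

#' Call coexistence or exclusion on a competition trajectory
#'
#' Looks at the last `tail_passages` frequencies: coexistence when they all
#' lie inside `[floor, 1 - floor]` and span at most `band`; exclusion when
#' the final frequency has fallen below `floor` (or above `1 - floor`, the
#' mirrored call for the competitor); otherwise undecided. The verdict is
#' invariant to relabeling focal and competitor.
#'
#' @param traj a `competition_trajectory` (or any data frame with columns
#'   `passage` and `focal_fraction`).
#' @param tail_passages passages at the end of the trajectory to inspect.
#' @param band maximum frequency range of a settled tail.
#' @param floor frequency below which a genotype counts as excluded.
#' @return tibble: `verdict` (`"coexistence"`, `"exclusion"`,
#'   `"undecided"`), `level` (tail mean frequency, NA unless coexistence),
#'   `excluded_passage` (first passage at/below the floor, NA otherwise).
#' @export
coexistence_call <- function(traj, tail_passages = 3L, band = 0.05,
                             floor = 0.01) {
  stopifnot(is.data.frame(traj), "focal_fraction" %in% names(traj))
  f <- traj$focal_fraction
  n <- length(f)
  if (n < tail_passages) {
    return(tibble::tibble(verdict = "undecided", level = NA_real_,
                          excluded_passage = NA_integer_))
  }
  pass <- if ("passage" %in% names(traj)) traj$passage else seq_len(n) - 1L
  final <- f[n]
  if (final < floor || final > 1 - floor) {
    lost_low <- final < floor
    hit <- if (lost_low) which(f <= floor) else which(f >= 1 - floor)
    return(tibble::tibble(verdict = "exclusion", level = NA_real_,
                          excluded_passage = as.integer(pass[hit[1L]])))
  }
  tail_f <- f[(n - tail_passages + 1L):n]
  settled <- all(tail_f >= floor & tail_f <= 1 - floor) &&
    (max(tail_f) - min(tail_f)) <= band
  if (settled) {
    tibble::tibble(verdict = "coexistence", level = mean(tail_f),
                   excluded_passage = NA_integer_)
  } else {
    tibble::tibble(verdict = "undecided", level = NA_real_,
                   excluded_passage = NA_integer_)
  }
}

#' One-sided Fisher exact test on a 2x2 contingency table
#'
#' Computes the exact hypergeometric tail probability of tables as or more
#' extreme than observed, in the stated direction, from log-factorials. The
#' table rows are the two groups, the columns the with/without counts of the
#' trait (e.g. presence of diauxic growth among evolved isolates).
#'
#' @param with_trait length-2 integer counts of trait carriers per group.
#' @param without_trait length-2 integer counts of non-carriers per group.
#' @param alternative direction: `"less"` tests whether group 1 has fewer
#'   non-carriers than expected... concretely, the tail is taken over group
#'   1's `without_trait` count: `"less"` sums tables with a count at or
#'   below the observed one, `"greater"` at or above, `"two.sided"` doubles
#'   the smaller tail (capped at 1).
#' @return tibble: `p_value`, `alternative`, `degenerate` (TRUE with a zero
#'   margin, where the probability is 1 by convention).
#' @examples
#' fisher_exact_one_sided(c(48, 36), c(0, 12), alternative = "less")
#' @export
fisher_exact_one_sided <- function(with_trait, without_trait,
                                   alternative = c("less", "greater",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(with_trait, without_trait)
  if (length(with_trait) != 2L || length(without_trait) != 2L ||
      any(counts < 0) || any(counts != round(counts))) {
    stop_diauxr("need nonnegative integer counts for two groups",
                "diauxr_parameter_error")
  }
  a <- without_trait[1L]                 # group 1 without the trait
  n1 <- with_trait[1L] + without_trait[1L]
  n2 <- with_trait[2L] + without_trait[2L]
  k <- sum(without_trait)                # column margin
  if (n1 == 0L || n2 == 0L || k == 0L || sum(with_trait) == 0L) {
    return(tibble::tibble(p_value = 1, alternative = alternative,
                          degenerate = TRUE))
  }
  # log P(X = x) for X ~ Hypergeometric(n1, n2, k)
  lchoose2 <- function(n, x) lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1)
  support <- max(0L, k - n2):min(n1, k)
  logp <- lchoose2(n1, support) + lchoose2(n2, k - support) -
    lchoose2(n1 + n2, k)
  tail_p <- function(side) {
    sel <- if (side == "less") support <= a else support >= a
    min(1, sum(exp(logp[sel])))
  }
  p <- switch(alternative,
              less = tail_p("less"),
              greater = tail_p("greater"),
              two.sided = min(1, 2 * min(tail_p("less"), tail_p("greater"))))
  tibble::tibble(p_value = p, alternative = alternative, degenerate = FALSE)
}

#' One-way ANOVA on a group/value table
#'
#' Standard between/within variance decomposition via [stats::lm()].
#'
#' @param data data frame with a grouping column and a numeric value column.
#' @param group,value column names.
#' @return tibble: `f_statistic`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(data, group = "group", value = "value") {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop_diauxr("need >= 2 groups with >= 2 values each",
                "diauxr_parameter_error")
  }
  tab <- suppressWarnings(anova(lm(y ~ g)))
  ms_within <- tab$`Mean Sq`[2L]
  if (!is.finite(ms_within) || ms_within <= 0) {
    if (tab$`Mean Sq`[1L] <= .Machine$double.eps) {
      # all values identical: no evidence against the null
      return(tibble::tibble(f_statistic = 0, df_between = tab$Df[1L],
                            df_within = tab$Df[2L], p_value = 1))
    }
    stop_diauxr("within-group variance is degenerate",
                "diauxr_degenerate_error")
  }
  tibble::tibble(f_statistic = tab$`F value`[1L],
                 df_between = tab$Df[1L], df_within = tab$Df[2L],
                 p_value = tab$`Pr(>F)`[1L])
}

#' Nested ANOVA: groups with isolates nested within them
#'
#' Tests the group effect against the isolate-within-group mean square (the
#' correct error stratum when replicate measurements are pseudo-replicates
#' of isolates). Sums of squares are Type I with group entered before
#' isolate-within-group, the natural ordering for this design.
#'
#' @param data data frame with group, isolate and value columns; >= 2
#'   isolates per group and >= 2 replicates per isolate.
#' @param group,isolate,value column names.
#' @return tibble: `f_statistic`, `df_group`, `df_isolate`, `p_value`,
#'   `degenerate` flag (all-identical values return p = 1 with the flag).
#' @export
nested_anova <- function(data, group = "group", isolate = "isolate",
                         value = "value") {
  g <- factor(data[[group]])
  iso <- factor(paste(data[[group]], data[[isolate]], sep = "/"))
  y <- data[[value]]
  if (nlevels(g) < 2L) {
    stop_diauxr("need >= 2 groups", "diauxr_parameter_error")
  }
  per_group <- tapply(as.character(iso), g, function(z) length(unique(z)))
  if (any(per_group < 2L)) {
    stop_diauxr("need >= 2 isolates per group", "diauxr_parameter_error")
  }
  if (any(table(iso) < 2L)) {
    stop_diauxr("need >= 2 replicates per isolate", "diauxr_parameter_error")
  }
  tab <- suppressWarnings(anova(lm(y ~ g + iso)))
  ms_g <- tab["g", "Mean Sq"]
  ms_iso <- tab["iso", "Mean Sq"]
  if (!is.finite(ms_iso) || ms_iso <= .Machine$double.eps) {
    if (ms_g <= .Machine$double.eps) {
      return(tibble::tibble(f_statistic = NA_real_,
                            df_group = tab["g", "Df"],
                            df_isolate = tab["iso", "Df"],
                            p_value = 1, degenerate = TRUE))
    }
    stop_diauxr("isolate-within-group stratum is degenerate",
                "diauxr_degenerate_error")
  }
  f_stat <- ms_g / ms_iso
  tibble::tibble(f_statistic = f_stat,
                 df_group = tab["g", "Df"],
                 df_isolate = tab["iso", "Df"],
                 p_value = pf(f_stat, tab["g", "Df"], tab["iso", "Df"],
                              lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Coefficient of variation in percent
#'
#' @param values numeric vector, n >= 2, positive mean.
#' @return `100 * sd / mean`.
#' @examples
#' coefficient_of_variation(c(0.5, 1.0, 1.5))   # 50
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop_diauxr("need at least 2 values", "diauxr_parameter_error")
  }
  m <- mean(values)
  if (m <= 0) {
    stop_diauxr("mean must be positive for a coefficient of variation",
                "diauxr_parameter_error")
  }
  100 * sd(values) / m
}

#' Pearson or Spearman correlation with a two-sided p-value
#'
#' Thin tidy wrapper over [stats::cor.test()] (t approximation for Pearson;
#' exact small-n or approximate p for Spearman, as cor.test chooses).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble: `estimate`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_diauxr("need at least 3 complete pairs", "diauxr_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_diauxr("zero variance in `x` or `y`", "diauxr_degenerate_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}
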