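test_that("generation accounting follows log2 of the dilution", {
  expect_equal(generations_per_passage(512), 9)
  expect_equal(generations_per_passage(1), 0)
  expect_equal(generations_per_passage(8), 3)
  expect_equal(generations_per_passage(640 / 1.25), 9)
  expect_error(generations_per_passage(0.5), class = "diauxr_error")
  expect_equal(total_generations(113, 512), 1017)
  expect_equal(total_generations(0, 512), 0)
  expect_equal(total_generations(10, 1024), 100)
  # additive over concatenated passage counts
  expect_equal(total_generations(60, 512) + total_generations(53, 512),
               total_generations(113, 512))
})

test_that("count frequencies carry Wilson intervals and count-quality flags", {
  f <- frequency_from_counts(4500, 45000)
  expect_equal(f$fraction, 0.10)
  expect_false(f$low_count)
  expect_true(f$lower < 0.1 && f$upper > 0.1)
  zero <- frequency_from_counts(0, 45000)
  expect_equal(zero$fraction, 0)
  expect_equal(zero$lower, 0)
  expect_gt(zero$upper, 0)
  expect_true(frequency_from_counts(10, 100)$low_count)
  expect_error(frequency_from_counts(10, 5), class = "diauxr_error")
})

test_that("Wilson interval covers the truth at close to nominal rate", {
  set.seed(13)
  covered <- 0L
  for (i in 1:100) {
    x <- rbinom(1, 45000, 0.12)
    ci <- frequency_from_counts(x, 45000)
    if (ci$lower <= 0.12 && ci$upper >= 0.12) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("coexistence calls fire on settled tails and exclusions at the floor", {
  flat <- data.frame(passage = 0:6, focal_fraction = rep(0.5, 7))
  cc <- coexistence_call(flat)
  expect_equal(cc$verdict, "coexistence")
  expect_equal(cc$level, 0.5)
  lost <- data.frame(passage = 0:6,
                     focal_fraction = c(0.3, 0.1, 0.03, 0.01, 0.004,
                                        0.001, 0))
  ce <- coexistence_call(lost)
  expect_equal(ce$verdict, "exclusion")
  expect_lte(ce$excluded_passage, 6L)
  short <- data.frame(passage = 0:1, focal_fraction = c(0.4, 0.3))
  expect_equal(coexistence_call(short)$verdict, "undecided")
})

test_that("coexistence verdicts are invariant under focal relabeling", {
  traj <- data.frame(passage = 0:8,
                     focal_fraction = c(0.6, 0.35, 0.2, 0.14, 0.12,
                                        0.11, 0.115, 0.112, 0.11))
  mirrored <- traj
  mirrored$focal_fraction <- 1 - traj$focal_fraction
  a <- coexistence_call(traj)
  b <- coexistence_call(mirrored)
  expect_equal(a$verdict, "coexistence")
  expect_equal(b$verdict, "coexistence")
  expect_equal(a$level, 1 - b$level)
})

test_that("one-sided Fisher tail reproduces the diauxie-table probability", {
  res <- fisher_exact_one_sided(with_trait = c(48, 36),
                                without_trait = c(0, 12),
                                alternative = "less")
  expect_equal(signif(res$p_value, 3), 1.12e-4)
  # all successes in one group of a 5/5 balanced table: single-table mass
  res2 <- fisher_exact_one_sided(c(5, 0), c(0, 5), alternative = "less")
  expect_equal(res2$p_value, 1 / choose(10, 5))
  degen <- fisher_exact_one_sided(c(0, 0), c(3, 4))
  expect_equal(degen$p_value, 1)
  expect_true(degen$degenerate)
})

test_that("Fisher tail equals exhaustive enumeration for all tables with total <= 24", {
  brute_tail <- function(w, wo) {
    n1 <- w[1] + wo[1]; n2 <- w[2] + wo[2]; k <- wo[1] + wo[2]
    supp <- max(0, k - n2):min(n1, k)
    probs <- choose(n1, supp) * choose(n2, k - supp) / choose(n1 + n2, k)
    c(less = sum(probs[supp <= wo[1]]),
      greater = sum(probs[supp >= wo[1]]))
  }
  for (total in c(4, 9, 16, 24)) {
    for (n1 in 1:(total - 1)) {
      n2 <- total - n1
      for (k in 0:total) {
        for (a in max(0, k - n2):min(n1, k)) {
          w <- c(n1 - a, n2 - (k - a)); wo <- c(a, k - a)
          if (sum(w) == 0 || sum(wo) == 0) next
          oracle <- brute_tail(w, wo)
          expect_equal(
            fisher_exact_one_sided(w, wo, "less")$p_value,
            unname(oracle["less"]), tolerance = 1e-10)
          expect_equal(
            fisher_exact_one_sided(w, wo, "greater")$p_value,
            unname(oracle["greater"]), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("one-way ANOVA matches the closed-form decomposition", {
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  value = c(1, 2, 3, 4, 3, 4, 5, 6))
  res <- one_way_anova(d)
  # hand computation: group means 2.5 and 4.5, pooled within-SS 10
  ss_b <- 4 * (2.5 - 3.5)^2 + 4 * (4.5 - 3.5)^2
  f_hand <- (ss_b / 1) / (10 / 6)
  expect_equal(res$f_statistic, f_hand)
  expect_equal(res$p_value, pf(f_hand, 1, 6, lower.tail = FALSE))
  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     value = rep(c(1, 2, 3), 2))
  expect_equal(one_way_anova(same)$f_statistic, 0)
  expect_equal(one_way_anova(same)$p_value, 1)
})

test_that("ANOVA rejection rates under the null stay within alpha +/- 2%", {
  set.seed(271)
  rej_oneway <- mean(replicate(1000, {
    d <- data.frame(group = rep(letters[1:4], each = 5),
                    value = rnorm(20))
    one_way_anova(d)$p_value <= 0.05
  }))
  expect_lt(abs(rej_oneway - 0.05), 0.02)
  rej_nested <- mean(replicate(1000, {
    d <- expand.grid(isolate = 1:4, rep = 1:3, group = c("a", "b"))
    iso_eff <- rnorm(8, sd = 2)   # strong isolate effect, zero group effect
    d$value <- rnorm(nrow(d)) +
      iso_eff[as.integer(factor(paste(d$group, d$isolate)))]
    nested_anova(d)$p_value <= 0.05
  }))
  expect_lt(abs(rej_nested - 0.05), 0.02)
})

test_that("nested ANOVA detects a group effect and absorbs isolate variance", {
  set.seed(5)
  pow <- mean(replicate(200, {
    d <- expand.grid(isolate = 1:6, rep = 1:3, group = c("a", "b"))
    iso_eff <- rnorm(12, sd = 0.5)
    d$value <- rnorm(nrow(d), sd = 0.3) +
      iso_eff[as.integer(factor(paste(d$group, d$isolate)))] +
      ifelse(d$group == "b", 1, 0)
    nested_anova(d)$p_value <= 0.05
  }))
  expect_gte(pow, 0.8)
  allsame <- expand.grid(isolate = 1:2, rep = 1:2, group = c("a", "b"))
  allsame$value <- 1
  res <- nested_anova(allsame)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("coefficient of variation and correlations behave as textbook", {
  expect_equal(coefficient_of_variation(c(0.5, 1.0, 1.5)), 50)
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_error(coefficient_of_variation(c(-2, 0)), class = "diauxr_error")
  # recovery of a configured cohort CV
  set.seed(21)
  cvs <- replicate(200, coefficient_of_variation(rnorm(48, 1, 0.234)))
  expect_equal(mean(cvs), 23.4, tolerance = 0.05)

  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$estimate, 1)
  y_mono <- exp(x)
  expect_equal(correlate(x, y_mono, "spearman")$estimate, 1)
  expect_lt(correlate(x, y_mono, "pearson")$estimate, 1)
  expect_error(correlate(x, rep(1, 5)), class = "diauxr_degenerate_error")
})

test_that("small-n Spearman p equals the exhaustive permutation tail", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  res <- correlate(x, y, "spearman")
  # enumerate all 6! rank permutations
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(all_perm(1:6), function(p) cor(1:6, p), numeric(1))
  obs <- cor(rank(x), rank(y))
  p_perm <- mean(abs(rhos) >= abs(obs) - 1e-12)
  expect_equal(res$p_value, p_perm, tolerance = 1e-9)
})
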