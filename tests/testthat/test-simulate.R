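test_that("single-exponential limit: od trace is exactly od0 * exp(mu t)", {
  g <- single_phase(mu = 0.9)
  s <- simulate_batch(g, reporter = NULL, od0 = 0.01, glucose0 = 1,
                      horizon_h = 12)
  t_exh <- log(1 + 1 * g$y_x_glc / 0.01) / 0.9
  in_phase <- s$time_h < t_exh - 0.1
  expect_equal(s$od[in_phase], 0.01 * exp(0.9 * s$time_h[in_phase]),
               tolerance = 1e-12)
})

test_that("glucose-exhaustion time matches the closed-form mass balance", {
  for (mu in c(0.5, 0.9)) {
    g <- single_phase(mu)
    s <- simulate_batch(g, reporter = NULL, od0 = 0.02, glucose0 = 2,
                        horizon_h = 16)
    t_closed <- log(1 + 2 * g$y_x_glc / 0.02) / mu
    # integrator resolves the boundary to one internal (1-min) step
    expect_lt(abs(attr(s, "events")$t_glc_exhaust - t_closed), 2 / 60)
  }
})

test_that("mass monotonicity: glucose non-increasing, acetate unimodal and nonnegative", {
  s <- noiseless_zed_sim()
  expect_true(all(diff(s$glucose_gl) <= 1e-12))
  expect_true(all(s$acetate_gl >= 0))
  d <- diff(s$acetate_gl)
  peak <- which.max(s$acetate_gl)
  expect_true(all(d[seq_len(peak - 1L)] >= -1e-12))
  expect_true(all(d[peak:length(d)] <= 1e-12))
  expect_true(all(s$od > 0))
})

test_that("identical seeds reproduce bit-identical noisy output; zero noise ignores the seed", {
  g <- zed_like()
  n <- noise_model(od_cv = 0.03, gfp_sd = 5)
  s1 <- simulate_batch(g, noise = n, seed = 11)
  s2 <- simulate_batch(g, noise = n, seed = 11)
  s3 <- simulate_batch(g, noise = n, seed = 12)
  expect_identical(s1$od, s2$od)
  expect_identical(s1$gfp, s2$gfp)
  expect_false(identical(s1$od, s3$od))
  z1 <- simulate_batch(g, noise = noise_model(), seed = 11)
  z2 <- simulate_batch(g, noise = noise_model(), seed = 99)
  expect_identical(z1$od, z2$od)
})

test_that("lag -> 0 and mu_ace -> mu_glc collapses the diauxic curve to one exponential", {
  g <- genotype_params(mu_glc = 0.6, mu_ace = 0.6, lag_h = 0,
                       q_ace_sec = 0.8)
  s <- simulate_batch(g, reporter = NULL, od0 = 0.01, glucose0 = 1,
                      horizon_h = 24)
  grow <- s$od < 0.95 * max(s$od)
  expect_equal(log(s$od[grow]), log(0.01) + 0.6 * s$time_h[grow],
               tolerance = 1e-3)
})

test_that("co-utilizer mode consumes both substrates with no secretion and forces lag 0", {
  g <- genotype_params(coutilizer = TRUE, mu_co = 0.6, lag_h = 5,
                       q_ace_sec = 0.9)
  expect_equal(g$lag_h, 0)
  expect_equal(g$q_ace_sec, 0)
  s <- simulate_batch(g, reporter = NULL, od0 = 0.01, glucose0 = 2,
                      acetate0 = 2, horizon_h = 24)
  expect_true(all(diff(s$glucose_gl) <= 1e-12))
  expect_true(all(diff(s$acetate_gl) <= 1e-12))
  grow <- s$od < 0.9 * max(s$od)
  expect_equal(log(s$od[grow]), log(0.01) + 0.6 * s$time_h[grow],
               tolerance = 1e-3)
})

test_that("simulator rejects invalid parameters", {
  expect_error(simulate_batch(zed_like(), od0 = 0), class = "diauxr_error")
  expect_error(simulate_batch(zed_like(), glucose0 = -1),
               class = "diauxr_error")
  expect_error(simulate_batch(zed_like(), horizon_h = 24, readout_min = 7),
               class = "diauxr_error")
  expect_error(genotype_params(mu_glc = -0.5), class = "diauxr_error")
  expect_error(noise_model(od_cv = -0.1), class = "diauxr_error")
})

test_that("identical genotypes at 50/50 stay at 0.5 every passage", {
  g <- zed_like()
  tr <- simulate_serial_passages(list(g, g), c(0.5, 0.5), n_passages = 5,
                                 sample_counts = FALSE)
  expect_equal(tr$focal_fraction, rep(0.5, 6), tolerance = 1e-12)
})

test_that("a single genotype regrows by the dilution factor: 9 doublings at 512-fold", {
  g <- genotype_params(mu_glc = 0.9, mu_ace = 0.3, lag_h = 0.5,
                       q_ace_sec = 0.8)
  # steady state after a couple of passages; regrowth factor equals dilution
  x0 <- 0.001
  s1 <- diauxr:::sim_culture(list(g), x0, glucose0 = 1, acetate0 = 0,
                             horizon_h = 24)
  x_end <- s1$X[nrow(s1$X), 1]
  s2 <- diauxr:::sim_culture(list(g), x_end / 512, glucose0 = 1,
                             acetate0 = 0, horizon_h = 24)
  fold <- s2$X[nrow(s2$X), 1] / (x_end / 512)
  expect_equal(log2(fold), 9, tolerance = 0.05)
})

test_that("passage horizon too short for regrowth raises the warning flag", {
  g <- genotype_params(mu_glc = 0.3, mu_ace = 0.1, lag_h = 2)
  expect_warning(
    tr <- simulate_serial_passages(list(g, g), c(0.5, 0.5), dilution = 512,
                                   n_passages = 2, passage_h = 6,
                                   sample_counts = FALSE),
    "regrowth")
  expect_true(attr(tr, "incomplete_regrowth"))
})

test_that("simulated Ct values sit exactly on the log-linear line at zero noise", {
  q <- simulate_qpcr(c(5, 10, 100), slope = -3.32, intercept = 26,
                     ct_sd = 0, reps = 2)
  expect_equal(unique(q$ct[q$fraction == 10]), 26 - 3.32)
  # one decade of template spacing changes Ct by exactly the slope
  ct100 <- unique(q$ct[q$fraction == 100])
  ct10 <- unique(q$ct[q$fraction == 10])
  expect_equal(ct100 - ct10, -3.32)
})

test_that("the 0% mixture is censored, not extrapolated", {
  q <- simulate_qpcr(paper_mixtures, ct_sd = 0.2, reps = 3, seed = 4)
  zero <- q[q$fraction == 0, ]
  expect_true(all(zero$censored))
  expect_true(all(is.na(zero$ct)))
  expect_true(all(!q$censored[q$fraction > 0]))
  expect_error(simulate_qpcr(50, ct_sd = -1), class = "diauxr_error")
  expect_error(simulate_qpcr(150), class = "diauxr_error")
})
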