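test_that("OD calibration is elementwise multiplication by the factor", {
  expect_equal(calibrate_od(0.10), 0.22)
  expect_equal(calibrate_od(c(0.05, 0.10)), c(0.11, 0.22))
  expect_equal(calibrate_od(0.3, factor = 1), 0.3)
  expect_error(calibrate_od(0.1, factor = 0), class = "diauxr_error")
  df <- data.frame(time_h = 0:1, od = c(0.1, 0.2))
  expect_equal(calibrate_od(df)$od, c(0.22, 0.44))
})

test_that("fit_growth_rate recovers exact rates on noiseless exponentials", {
  # exact doubling: three points spanning one doubling per hour
  curve <- data.frame(time_h = 0:2, od = c(0.06, 0.12, 0.24))
  f <- fit_growth_rate(curve, min_points = 3)
  expect_equal(f$mu, log(2), tolerance = 1e-12)
  # regression on exact data recovers the generating rate to 1e-9
  for (mu in c(0.3, 0.56, 1.1)) {
    f <- fit_growth_rate(exp_curve(mu))
    expect_equal(f$mu, mu, tolerance = 1e-9)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("window extraction takes the first contiguous in-range run and errors when underpopulated", {
  curve <- exp_curve(0.5, od0 = 0.01)
  f <- fit_growth_rate(curve)
  ods <- curve$od[f$window$idx[1]:f$window$idx[2]]
  expect_true(all(ods >= 0.05 & ods <= 0.35))
  expect_error(fit_growth_rate(exp_curve(0.5, od0 = 0.001,
                                         t = seq(0, 2, by = 1 / 6))),
               "underpopulated", class = "diauxr_window_error")
  low <- data.frame(time_h = 0:5, od = rep(0.01, 6) * exp(0.01 * 0:5))
  expect_error(fit_growth_rate(low), class = "diauxr_window_error")
})

test_that("calibration commutes with fitting: mu unchanged, intercept shifts by ln f", {
  curve <- exp_curve(0.6, od0 = 0.02)
  f1 <- fit_growth_rate(curve, od_lo = 0.05, od_hi = 0.35)
  f2 <- fit_growth_rate(calibrate_od(curve, 2.2),
                        od_lo = 0.05 * 2.2, od_hi = 0.35 * 2.2)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log(2.2), tolerance = 1e-12)
})

test_that("growth-rate recovery within 5% at 2% OD noise across 100 seeds", {
  ok <- 0L
  for (seed in 1:100) {
    s <- simulate_batch(zed_like(), noise = noise_model(od_cv = 0.02),
                        od0 = 0.01, glucose0 = 1, horizon_h = 24,
                        seed = seed)
    f <- fit_growth_rate(s)
    if (abs(f$mu - 0.56) / 0.56 < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("yield is the smoothed maximum OD", {
  mono <- data.frame(time_h = seq(0, 4, by = 0.25),
                     od = 0.05 * exp(0.5 * seq(0, 4, by = 0.25)))
  mono$od[mono$od > 0.3] <- 0.3   # plateaued monotone curve
  expect_equal(yield_max_od(mono), 0.3, tolerance = 0.01)
  spiked <- mono
  spiked$od[8] <- spiked$od[8] * 10
  expect_lt(yield_max_od(spiked), max(spiked$od) / 2)
  # noiseless simulation: final biomass follows the mass balance
  s <- noiseless_zed_sim()
  g <- zed_like()
  ace_total <- g$q_ace_sec * (g$y_x_glc * 1)     # secreted during phase 1
  closed <- 0.01 + g$y_x_glc * 1 + g$y_x_ace * ace_total
  expect_equal(yield_max_od(s), closed, tolerance = 0.02)
})

test_that("noiseless single exponential is called single-phase with p near 1", {
  curve <- exp_curve(0.7, od0 = 0.01, t = seq(0, 8, by = 1 / 6))
  # truncate before stationary so both windows see pure exponential
  call <- detect_diauxie(curve)
  expect_false(call$is_diauxic)
  expect_equal(call$p_value, 1)
  expect_equal(call$slope_primary, call$slope_extended, tolerance = 1e-9)
})

test_that("noiseless diauxic simulation is detected with a lower extended slope", {
  s <- noiseless_zed_sim()
  call <- detect_diauxie(s)
  expect_true(call$is_diauxic)
  expect_lt(call$slope_extended, call$slope_primary)
  expect_lt(call$p_value, 1e-6)
})

test_that("diauxie classifier sensitivity and specificity are at least 95%", {
  sens <- 0L
  spec <- 0L
  for (seed in 1:100) {
    di <- simulate_batch(genotype_params(mu_glc = 0.7, mu_ace = 0.3,
                                         lag_h = 1.5),
                         noise = noise_model(od_cv = 0.02), od0 = 0.01,
                         glucose0 = 1, horizon_h = 24, seed = seed)
    cd <- tryCatch(detect_diauxie(di), diauxr_error = function(e) NULL)
    if (!is.null(cd) && cd$is_diauxic) sens <- sens + 1L
    si <- simulate_batch(single_phase(0.8),
                         noise = noise_model(od_cv = 0.02), od0 = 0.01,
                         glucose0 = 1, horizon_h = 24, seed = seed + 500)
    cs <- tryCatch(detect_diauxie(si), diauxr_error = function(e) NULL)
    if (!is.null(cs) && !cs$is_diauxic) spec <- spec + 1L
  }
  expect_gte(sens, 95L)
  expect_gte(spec, 95L)
})

test_that("shift duration is within one readout of truth across lag values", {
  for (lag in c(0.5, 1, 2, 3.47, 5)) {
    g <- genotype_params(mu_glc = 0.56, mu_ace = 0.25, lag_h = lag)
    s <- simulate_batch(g, noise = noise_model(), od0 = 0.01,
                        glucose0 = 1, horizon_h = 30)
    call <- detect_diauxie(s)
    expect_true(call$is_diauxic)
    sh <- estimate_shift(s, call)
    expect_lt(abs(sh$duration_h - lag), 10 / 60 + 1e-9)
  }
})

test_that("shift estimates preserve the ordering of true lags", {
  s_wt <- simulate_batch(wt_like(), noise = noise_model(), od0 = 0.01,
                         glucose0 = 1, horizon_h = 24)
  s_zed <- noiseless_zed_sim()
  d_wt <- estimate_shift(s_wt, detect_diauxie(s_wt))$duration_h
  d_zed <- estimate_shift(s_zed, detect_diauxie(s_zed))$duration_h
  expect_lt(d_wt, d_zed)
  expect_equal(d_wt, 2.10, tolerance = 0.1)
  expect_equal(d_zed, 3.47, tolerance = 0.1)
})

test_that("shift estimation refuses single-phase calls and unresolved shifts", {
  s <- simulate_batch(single_phase(0.8), noise = noise_model(),
                      od0 = 0.01, glucose0 = 1, horizon_h = 24)
  call <- detect_diauxie(s)
  expect_false(call$is_diauxic)
  expect_error(estimate_shift(s, call), class = "diauxr_shift_error")
  # diauxic culture truncated inside the lag: no regrowth to detect
  g <- genotype_params(mu_glc = 0.56, mu_ace = 0.25, lag_h = 10)
  s2 <- simulate_batch(g, noise = noise_model(), od0 = 0.01, glucose0 = 1,
                       horizon_h = 12)
  call2 <- detect_diauxie(s2)
  if (call2$is_diauxic) {
    expect_error(estimate_shift(s2, call2), "unresolved",
                 class = "diauxr_shift_error")
  }
})

test_that("summarize_growth returns one tidy row per well", {
  sims <- list(A1 = noiseless_zed_sim(),
               A2 = simulate_batch(single_phase(), noise = noise_model()))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "p.csv")
  write_plate_csv(sims, csv)
  plate <- read_plate_table(csv)
  out <- summarize_growth(plate)
  expect_equal(nrow(out), 2L)
  expect_equal(out$is_diauxic, c(TRUE, FALSE))
  expect_equal(out$mu, c(0.56, 0.8), tolerance = 1e-6)
  expect_false(is.na(out$shift_h[1]))
  expect_true(is.na(out$shift_h[2]))
})
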