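# Mechanistic batch-culture simulator.
#
# Dynamics are a piecewise-exponential mass balance integrated by a
# fixed-step forward update at 1-min internal resolution and down-sampled to
# the readout grid (10 min by default, the plate-reader sampling interval).
# Within each internal step a growing genotype multiplies its biomass by
# exp(mu * dt), so with zero noise each phase's OD trace is exactly
# exponential at the readouts; substrate consumption follows from the yield
# coefficients, capped so concentrations never go negative. Glucose is
# declared exhausted at <= 1e-6 g/l to avoid floating-point chatter at the
# phase boundary.

GLC_EPS <- 1e-6

# one culture shared by >=1 genotypes (shared glucose/acetate pools).
# Returns biomass matrix at readout times plus pool traces and phase events.
sim_culture <- function(genotypes, x0, glucose0, acetate0, horizon_h,
                        step_min = 1, readout_min = 10,
                        reporter = NULL, gfp0 = 0) {
  n_g <- length(genotypes)
  dt <- step_min / 60
  n_steps <- round(horizon_h * 60 / step_min)
  rec_every <- round(readout_min / step_min)

  X <- x0
  glc <- glucose0
  ace <- acetate0
  G <- gfp0
  phase <- vapply(genotypes, function(g) {
    if (g$coutilizer) "co" else "glc"
  }, character(1))
  lag_rem <- rep(0, n_g)
  events <- list(t_glc_exhaust = NA_real_, t_lag_end = rep(NA_real_, n_g),
                 t_ace_exhaust = NA_real_)

  n_rec <- n_steps %/% rec_every + 1L
  rec_X <- matrix(NA_real_, n_rec, n_g)
  rec <- matrix(NA_real_, n_rec, 4L)  # time, glc, ace, gfp
  rec_X[1L, ] <- X
  rec[1L, ] <- c(0, glc, ace, G)
  ri <- 1L

  for (s in seq_len(n_steps)) {
    t_now <- (s - 1L) * dt
    # lag countdown happens before growth within the step
    for (i in seq_len(n_g)) {
      if (phase[i] == "lag") {
        lag_rem[i] <- lag_rem[i] - dt
        if (lag_rem[i] <= 1e-12) {
          phase[i] <- "ace"
          events$t_lag_end[i] <- t_now
        }
      }
    }

    glc_avail <- glc > GLC_EPS
    ace_avail <- ace > GLC_EPS
    d_glc_dem <- numeric(n_g)   # glucose demand per genotype
    d_ace_dem <- numeric(n_g)
    dX_g <- numeric(n_g)        # glucose-funded growth
    dX_a <- numeric(n_g)        # acetate-funded growth
    for (i in seq_len(n_g)) {
      g <- genotypes[[i]]
      if (phase[i] == "glc" && glc_avail) {
        dX_g[i] <- X[i] * expm1(g$mu_glc * dt)
        d_glc_dem[i] <- dX_g[i] / g$y_x_glc
      } else if (phase[i] == "ace" && ace_avail) {
        dX_a[i] <- X[i] * expm1(g$mu_ace * dt)
        d_ace_dem[i] <- dX_a[i] / g$y_x_ace
      } else if (phase[i] == "co" && (glc_avail || ace_avail)) {
        dX <- X[i] * expm1(g$mu_co * dt)
        fg <- if (glc_avail && ace_avail) glc / (glc + ace) else
          as.numeric(glc_avail)
        dX_g[i] <- fg * dX
        dX_a[i] <- (1 - fg) * dX
        d_glc_dem[i] <- dX_g[i] / g$y_x_glc
        d_ace_dem[i] <- dX_a[i] / g$y_x_ace
      }
    }
    # scale demands if a pool cannot cover them (shared-pool competition)
    tot_g <- sum(d_glc_dem)
    s_g <- if (tot_g > glc && tot_g > 0) glc / tot_g else 1
    tot_a <- sum(d_ace_dem)
    s_a <- if (tot_a > ace && tot_a > 0) ace / tot_a else 1

    sec <- 0
    alpha_eff <- 0
    for (i in seq_len(n_g)) {
      g <- genotypes[[i]]
      dX <- dX_g[i] * s_g + dX_a[i] * s_a
      if (phase[i] == "glc") sec <- sec + g$q_ace_sec * dX_g[i] * s_g
      if (!is.null(reporter) && n_g == 1L) {
        alpha_eff <- switch(phase[i],
          glc = reporter$alpha_exp,
          co  = if (glc_avail || ace_avail) reporter$alpha_exp else 0,
          lag = reporter$alpha_shift,
          ace = if (ace_avail) reporter$alpha_shift else 0,
          0)
        G <- G + alpha_eff * (X[i] + dX / 2) * dt
      }
      X[i] <- X[i] + dX
    }
    glc <- max(0, glc - sum(d_glc_dem) * s_g)
    ace <- max(0, ace - sum(d_ace_dem) * s_a + sec)

    # phase transitions on substrate exhaustion
    if (glc <= GLC_EPS) {
      if (is.na(events$t_glc_exhaust) && any(phase %in% c("glc", "co"))) {
        events$t_glc_exhaust <- s * dt
      }
      for (i in seq_len(n_g)) {
        if (phase[i] == "glc") {
          g <- genotypes[[i]]
          if (g$lag_h > 1e-12) {
            phase[i] <- "lag"
            lag_rem[i] <- g$lag_h
          } else {
            phase[i] <- "ace"
            events$t_lag_end[i] <- s * dt
          }
        }
      }
    }
    if (ace <= GLC_EPS && is.na(events$t_ace_exhaust) &&
        any(phase == "ace")) {
      events$t_ace_exhaust <- s * dt
    }

    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      rec_X[ri, ] <- X
      rec[ri, ] <- c(s * dt, glc, ace, G)
    }
  }

  list(time_h = rec[, 1L], X = rec_X, glucose_gl = rec[, 2L],
       acetate_gl = rec[, 3L], gfp = rec[, 4L], events = events)
}

#' Simulate a diauxic (or co-utilizing) glucose batch culture
#'
#' Generates OD, GFP and extracellular glucose/acetate time courses for one
#' well with known ground truth. The diauxic mode reproduces the three
#' sequential stages of a glucose-fed batch culture: exponential growth on
#' glucose with acetate overflow secretion, a growth-arrest lag (the diauxic
#' shift), and exponential growth on the accumulated acetate. The
#' co-utilizing mode consumes glucose and acetate simultaneously in a single
#' phase with no secretion.
#'
#' @param genotype a [genotype_params()] object.
#' @param reporter a [reporter_params()] object, or `NULL` for no GFP channel.
#' @param noise a [noise_model()] object.
#' @param od0 inoculation OD (calibrated units), > 0.
#' @param glucose0,acetate0 initial substrate concentrations, g/l.
#' @param horizon_h simulated duration in hours; the readout interval must
#'   divide it.
#' @param readout_min readout spacing in minutes (default 10, the
#'   plate-reader sampling interval).
#' @param step_min internal integrator step in minutes.
#' @param seed integer seed for the readout noise; ignored when the noise
#'   model is all-zero, so noiseless output is seed-independent.
#' @return a tibble of class `batch_sim` with columns `time_h`, `od`, `gfp`,
#'   `glucose_gl`, `acetate_gl`. The generating parameters are attached as
#'   attribute `truth` and the phase-boundary times (glucose exhaustion, lag
#'   end, acetate exhaustion) as attribute `events`.
#' @examples
#' sim <- simulate_batch(genotype_params(mu_glc = 0.56, lag_h = 3.47),
#'                       noise = noise_model(od_cv = 0.02), seed = 1)
#' head(sim)
#' @export
simulate_batch <- function(genotype, reporter = reporter_params(),
                           noise = noise_model(), od0 = 0.01,
                           glucose0 = 1, acetate0 = 0, horizon_h = 24,
                           readout_min = 10, step_min = 1, seed = NULL) {
  stopifnot(inherits(genotype, "genotype_params"),
            is.null(reporter) || inherits(reporter, "reporter_params"),
            inherits(noise, "noise_model"))
  check_number(od0, "od0", lower = 0, allow_zero = FALSE)
  if (od0 <= 0) stop_diauxr("`od0` must be positive", "diauxr_parameter_error")
  check_number(glucose0, "glucose0", lower = 0)
  check_number(acetate0, "acetate0", lower = 0)
  check_number(horizon_h, "horizon_h", lower = 0, allow_zero = FALSE)
  check_number(step_min, "step_min", lower = 0, allow_zero = FALSE)
  if (step_min <= 0 || horizon_h <= 0) {
    stop_diauxr("`step_min` and `horizon_h` must be positive",
                "diauxr_parameter_error")
  }
  if (abs(horizon_h * 60 / readout_min -
          round(horizon_h * 60 / readout_min)) > 1e-8) {
    stop_diauxr("the readout interval must divide the horizon",
                "diauxr_parameter_error")
  }

  gfp0 <- if (is.null(reporter)) 0 else reporter$gfp0
  sim <- sim_culture(list(genotype), x0 = od0, glucose0 = glucose0,
                     acetate0 = acetate0, horizon_h = horizon_h,
                     step_min = step_min, readout_min = readout_min,
                     reporter = reporter, gfp0 = gfp0)
  od <- sim$X[, 1L]
  gfp <- sim$gfp
  n <- length(od)
  if (noise$od_cv > 0 || noise$gfp_sd > 0) {
    with_seed(seed, {
      if (noise$od_cv > 0) {
        sdlog <- sqrt(log1p(noise$od_cv^2))
        od <- od * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      if (noise$gfp_sd > 0) gfp <- gfp + rnorm(n, 0, noise$gfp_sd)
    })
  }
  out <- tibble::tibble(time_h = sim$time_h, od = od, gfp = gfp,
                        glucose_gl = sim$glucose_gl,
                        acetate_gl = sim$acetate_gl)
  attr(out, "truth") <- list(genotype = genotype, reporter = reporter,
                             noise = noise, od0 = od0, glucose0 = glucose0,
                             acetate0 = acetate0)
  attr(out, "events") <- sim$events
  class(out) <- c("batch_sim", class(out))
  out
}

#' Simulate serial-passage competition between genotypes
#'
#' Grows two or more genotypes in a well-mixed shared culture (secreted
#' acetate is available to every genotype, the cross-feeding scenario),
#' records end-of-passage biomass fractions, and dilutes into fresh medium
#' by `1/dilution` each passage. Flow-cytometry-style counts of the focal
#' (first) genotype are drawn binomially from the biomass fraction.
#'
#' @param genotypes list of [genotype_params()]; the first is the focal one.
#' @param fractions starting biomass fractions, summing to 1.
#' @param dilution fold-dilution between passages (> 1); doublings per
#'   passage at steady state equal `log2(dilution)`.
#' @param n_passages number of passages to simulate.
#' @param passage_h hours of growth per passage.
#' @param od0_total total inoculation OD at passage 1.
#' @param glucose0,acetate0 fresh-medium composition, g/l.
#' @param count_total cells counted per sample (default 45000, the assay's
#'   minimum count).
#' @param sample_counts logical; draw counts binomially (seeded) instead of
#'   rounding the exact fraction.
#' @param step_min internal integrator step in minutes.
#' @param seed integer seed for count sampling.
#' @return a tibble of class `competition_trajectory` with columns
#'   `passage`, `focal_fraction`, `focal_count`, `total_count`; attributes
#'   `dilution`, `gens_per_passage` and `incomplete_regrowth` (TRUE when a
#'   passage's fold-growth fell short of the dilution factor).
#' @export
simulate_serial_passages <- function(genotypes, fractions, dilution = 512,
                                     n_passages = 7, passage_h = 24,
                                     od0_total = 0.001, glucose0 = 1,
                                     acetate0 = 0, count_total = 45000,
                                     sample_counts = TRUE, step_min = 1,
                                     seed = NULL) {
  stopifnot(is.list(genotypes),
            all(vapply(genotypes, inherits, logical(1), "genotype_params")))
  if (length(fractions) != length(genotypes)) {
    stop_diauxr("`fractions` must match `genotypes` in length",
                "diauxr_parameter_error")
  }
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    stop_diauxr("`fractions` must be nonnegative and sum to 1",
                "diauxr_parameter_error")
  }
  check_number(dilution, "dilution", lower = 1, allow_zero = FALSE)
  if (dilution <= 1) {
    stop_diauxr("`dilution` must exceed 1", "diauxr_parameter_error")
  }

  X <- od0_total * fractions
  frac <- numeric(n_passages + 1L)
  frac[1L] <- fractions[1L]
  incomplete <- FALSE
  for (p in seq_len(n_passages)) {
    sim <- sim_culture(genotypes, x0 = X, glucose0 = glucose0,
                       acetate0 = acetate0, horizon_h = passage_h,
                       step_min = step_min, readout_min = 60)
    X_end <- sim$X[nrow(sim$X), ]
    if (sum(X_end) / sum(X) < dilution * 0.9) incomplete <- TRUE
    frac[p + 1L] <- X_end[1L] / sum(X_end)
    X <- X_end / dilution
  }
  focal_count <- if (sample_counts) {
    with_seed(seed, rbinom(n_passages + 1L, count_total, frac))
  } else {
    round(frac * count_total)
  }
  out <- tibble::tibble(passage = 0:n_passages, focal_fraction = frac,
                        focal_count = focal_count,
                        total_count = count_total)
  attr(out, "dilution") <- dilution
  attr(out, "gens_per_passage") <- log2(dilution)
  attr(out, "incomplete_regrowth") <- incomplete
  if (incomplete) {
    rlang::warn("passage horizon too short: regrowth did not reach the dilution factor")
  }
  class(out) <- c("competition_trajectory", class(out))
  out
}

#' Simulate qPCR cycle thresholds for allele-mixture standards
#'
#' Ct values are linear in the log10 of template quantity (the mixture
#' fraction of the allele-specific template): `Ct = intercept + slope *
#' log10(fraction)`, plus Gaussian noise. The 0% mixture carries no template
#' for the allele-specific primer and emits a censored ("no amplification")
#' Ct rather than an extrapolated value.
#'
#' @param fractions mixture fractions in percent, within \[0, 100\].
#' @param slope Ct change per log10 unit of template (negative: more
#'   template, earlier amplification). The default -3.32 corresponds to
#'   100% amplification efficiency.
#' @param intercept Ct at a 1% mixture.
#' @param ct_sd Gaussian Ct noise, cycles.
#' @param reps technical replicates per mixture.
#' @param seed integer seed; noiseless output is seed-independent.
#' @return tibble with columns `fraction`, `replicate`, `ct`, `censored`.
#' @export
simulate_qpcr <- function(fractions, slope = -3.32, intercept = 26,
                          ct_sd = 0, reps = 3, seed = NULL) {
  if (any(fractions < 0 | fractions > 100)) {
    stop_diauxr("`fractions` must lie in [0, 100] percent",
                "diauxr_parameter_error")
  }
  check_number(ct_sd, "ct_sd", lower = 0)
  if (reps < 1) stop_diauxr("`reps` must be >= 1", "diauxr_parameter_error")
  grid <- tidyr::expand_grid(fraction = fractions,
                             replicate = seq_len(reps))
  ct_true <- ifelse(grid$fraction > 0,
                    intercept + slope * log10(grid$fraction), NA_real_)
  ct <- ct_true
  if (ct_sd > 0) {
    with_seed(seed, {
      noise <- rnorm(nrow(grid), 0, ct_sd)
      ct <- ct_true + ifelse(is.na(ct_true), 0, noise)
    })
  }
  tibble::tibble(fraction = grid$fraction, replicate = grid$replicate,
                 ct = ct, censored = is.na(ct))
}
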