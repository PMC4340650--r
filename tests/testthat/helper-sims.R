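# shared fixtures, generated in code

# ZED-like diauxic genotype: Table-style glucose rate 0.56/h, shift 3.47 h
zed_like <- function() {
  genotype_params(mu_glc = 0.56, mu_ace = 0.25, lag_h = 3.47)
}

wt_like <- function() {
  genotype_params(mu_glc = 0.66, mu_ace = 0.25, lag_h = 2.10)
}

# single-phase pure-glucose exponential (no secretion, no acetate phase)
single_phase <- function(mu = 0.8) {
  genotype_params(mu_glc = mu, lag_h = 0, q_ace_sec = 0)
}

noiseless_zed_sim <- function(...) {
  simulate_batch(zed_like(), noise = noise_model(), od0 = 0.01,
                 glucose0 = 1, horizon_h = 24, ...)
}

# exact exponential curve as a plain data frame
exp_curve <- function(mu, od0 = 0.05, t = seq(0, 5, by = 1 / 6)) {
  data.frame(time_h = t, od = od0 * exp(mu * t))
}

paper_mixtures <- c(0, 5, 10, 20, 40, 60, 100)
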