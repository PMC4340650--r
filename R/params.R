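#' Genotype parameters for the batch-culture simulator
#'
#' Describes one genotype's growth physiology on glucose and acetate. Two
#' modes are supported: the canonical diauxic mode (exponential growth on
#' glucose with acetate overflow secretion, a growth-arrest lag of `lag_h`
#' hours at glucose exhaustion, then exponential growth on acetate) and a
#' co-utilizing mode (`coutilizer = TRUE`) in which glucose and acetate are
#' consumed simultaneously at a single rate `mu_co` with no secretion, the
#' phenotype of PTS-attenuated mutants.
#'
#' @param mu_glc per-hour exponential growth rate on glucose.
#' @param mu_ace per-hour growth rate on acetate (post-shift phase).
#' @param lag_h duration of the diauxic shift (growth arrest), hours.
#' @param y_x_glc biomass yield, OD units produced per g/l glucose consumed.
#' @param q_ace_sec g/l acetate secreted per OD unit produced on glucose.
#' @param y_x_ace biomass yield, OD units per g/l acetate consumed.
#' @param coutilizer logical; single-phase simultaneous-consumption mode.
#'   Forces `lag_h = 0` and `q_ace_sec = 0`.
#' @param mu_co per-hour growth rate in co-utilization mode.
#' @param label optional genotype label carried into simulator output.
#' @return an object of class `genotype_params`.
#' @examples
#' genotype_params(mu_glc = 0.66, lag_h = 2.10)           # wild-type-like
#' genotype_params(coutilizer = TRUE, mu_co = 0.6)        # ptsG-mutant-like
#' @export
genotype_params <- function(mu_glc = 0.66, mu_ace = 0.25, lag_h = 2.1,
                            y_x_glc = 0.5, q_ace_sec = 0.8, y_x_ace = 0.25,
                            coutilizer = FALSE, mu_co = 0.6,
                            label = NULL) {
  for (nm in c("mu_glc", "mu_ace", "lag_h", "y_x_glc", "q_ace_sec",
               "y_x_ace", "mu_co")) {
    check_number(get(nm), nm, lower = 0)
  }
  if (y_x_glc <= 0 || y_x_ace <= 0) {
    stop_diauxr("biomass yields must be positive", "diauxr_parameter_error")
  }
  if (isTRUE(coutilizer)) {
    lag_h <- 0
    q_ace_sec <- 0
  }
  structure(
    list(mu_glc = mu_glc, mu_ace = mu_ace, lag_h = lag_h,
         y_x_glc = y_x_glc, q_ace_sec = q_ace_sec, y_x_ace = y_x_ace,
         coutilizer = isTRUE(coutilizer), mu_co = mu_co, label = label),
    class = "genotype_params"
  )
}

#' Reporter parameters for the batch-culture simulator
#'
#' Phenomenological state-dependent GFP synthesis: a low constant rate per
#' unit biomass during glucose exponential growth and a higher rate from the
#' onset of the diauxic shift onward, reproducing the surge of cAMP-CRP
#' driven promoters at the shift. Synthesis stops in stationary phase.
#'
#' @param alpha_exp GFP units synthesized per OD per hour during the glucose
#'   exponential phase.
#' @param alpha_shift GFP synthesis rate per OD per hour during the shift and
#'   acetate phase; must be `>= alpha_exp` for a surge.
#' @param gfp0 initial GFP signal (background units).
#' @return an object of class `reporter_params`.
#' @export
reporter_params <- function(alpha_exp = 1500, alpha_shift = 9000,
                            gfp0 = 50) {
  check_number(alpha_exp, "alpha_exp", lower = 0)
  check_number(alpha_shift, "alpha_shift", lower = 0)
  check_number(gfp0, "gfp0", lower = 0)
  structure(list(alpha_exp = alpha_exp, alpha_shift = alpha_shift,
                 gfp0 = gfp0),
            class = "reporter_params")
}

#' Measurement-noise model for simulated readouts
#'
#' Noise is applied per readout after the deterministic dynamics:
#' multiplicative lognormal noise with coefficient of variation `od_cv` on
#' OD (mean-unbiased), additive Gaussian noise with sd `gfp_sd` on GFP, and
#' Gaussian noise with sd `ct_sd` on simulated qPCR cycle thresholds. All
#' zero gives bit-deterministic trajectories.
#'
#' @param od_cv coefficient of variation of the OD readout noise.
#' @param gfp_sd standard deviation of additive GFP noise, fluorescence units.
#' @param ct_sd standard deviation of Ct noise, cycles.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(od_cv = 0, gfp_sd = 0, ct_sd = 0) {
  check_number(od_cv, "od_cv", lower = 0)
  check_number(gfp_sd, "gfp_sd", lower = 0)
  check_number(ct_sd, "ct_sd", lower = 0)
  structure(list(od_cv = od_cv, gfp_sd = gfp_sd, ct_sd = ct_sd),
            class = "noise_model")
}

#' @export
print.genotype_params <- function(x, ...) {
  mode <- if (x$coutilizer) {
    sprintf("co-utilizer (mu_co = %.3g /h, no secretion)", x$mu_co)
  } else {
    sprintf("diauxic (mu_glc = %.3g, mu_ace = %.3g /h, lag = %.3g h)",
            x$mu_glc, x$mu_ace, x$lag_h)
  }
  cat("<genotype_params> ", if (!is.null(x$label)) paste0(x$label, ": "),
      mode, "\n", sep = "")
  invisible(x)
}
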