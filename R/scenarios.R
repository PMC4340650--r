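# Stylized genotype parameter sets for the cross-feeding competition
# scenario: a fast-growing diauxic secretor (FG), a slow-growing
# glucose/acetate co-utilizer (SG, the PTS-attenuated phenotype), and the
# SG allelic revertant which regains fast diauxic growth but loses
# co-utilization. Values were frozen after one calibration pass that ran
# the serial-passage simulator to its fixed point (see the methods
# vignette).

#' Fast-growing diauxic secretor genotype
#'
#' Evolved FG phenotype: fast glucose growth, substantial acetate overflow,
#' a short diauxic shift, then growth on acetate.
#'
#' @return a [genotype_params()] object.
#' @export
fg_genotype <- function() {
  genotype_params(mu_glc = 0.9, mu_ace = 0.3, lag_h = 1.5,
                  y_x_glc = 0.5, q_ace_sec = 0.8, y_x_ace = 0.25,
                  label = "FG")
}

#' Slow-growing glucose/acetate co-utilizer genotype
#'
#' Evolved SG phenotype: a single growth phase consuming glucose and
#' acetate simultaneously with minimal secretion, at a rate below the FG
#' glucose rate. Cross-feeds on FG-secreted acetate in competition.
#'
#' @return a [genotype_params()] object.
#' @export
sg_genotype <- function() {
  genotype_params(coutilizer = TRUE, mu_co = 0.72,
                  y_x_glc = 0.5, y_x_ace = 0.25, label = "SG")
}

#' SG revertant genotype (co-utilization advantage removed)
#'
#' The SG isolate with its PTS allele reverted: glucose growth is faster
#' than the co-utilizer's but still below the FG rate, the diauxic shift is
#' long, and acetate is only used after the shift - the phenotype that is
#' competitively excluded.
#'
#' @return a [genotype_params()] object.
#' @export
sg_revertant_genotype <- function() {
  genotype_params(mu_glc = 0.7, mu_ace = 0.3, lag_h = 3.5,
                  y_x_glc = 0.5, q_ace_sec = 0.5, y_x_ace = 0.25,
                  label = "SG-revertant")
}
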