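# diauxr

Quantitative analysis of glucose batch-culture experiments built around the
glucose–acetate diauxie of *Escherichia coli*, the setting of
experimental-evolution studies in which populations are serially passaged in
M9 glucose and evolved isolates are characterized by growth profiling,
promoter reporters, physiology and competition assays.

The package turns each raw data type into the statistics such studies
report, and ships a ground-truth synthetic batch-culture generator so every
estimator can be validated end to end without wet-lab data.

## What it computes

**Growth-curve kinetics** (`fit_growth_rate`, `yield_max_od`,
`detect_diauxie`, `estimate_shift`, `summarize_growth`). The specific growth
rate is the OLS slope of ln OD against time over the exponential window
(calibrated OD 0.05–0.35; raw plate-reader readouts are scaled by 2.2 to a
1-cm path length); yield is the smoothed maximum OD. Diauxic growth is
detected by the two-slope rule — an independent fit over the extended window
(OD 0.05 to 90% of max) must be significantly *shallower* (one-sided Welch
t, p ≤ 0.05) than the primary slope:

  μ = d ln OD / dt,  t = (μ₁ − μ₂)/√(se₁² + se₂²)

The diauxic-shift duration is the growth-arrest interval where the smoothed
d(ln OD)/dt falls below 0.1 h⁻¹, with kernel-unbiased half-height boundary
refinement.

**Reporter dynamics** (`transcriptional_activity`, `promoter_activity`,
`summarize_window`, `crp_activity`, `percent_change`). Transcriptional
activity GFP/OD and promoter activity dGFP/dt/OD, averaged over the
exponential phase (OD 0.1–0.3) with t-based 95% CIs across replicates; CRP
activity as the epd-CBS hybrid-promoter transcription divided by the
constitutive epd promoter's.

**Physiology** (`substrate_yield`, `specific_rate`,
`classify_cometabolism`, `summarize_rates`). Substrate/product yields as the
regression slope of extracellular concentration on biomass (≥5
exponential-phase points); specific rates as yield × μ, with uptake vs
secretion from the slope sign and a glucose/acetate co-utilization call.

**qPCR** (`delta_delta_ct`, `fit_allele_standard_curve`,
`estimate_allele_frequency`). Relative expression by 2^ΔΔCt against a
reference gene; allele frequencies by inverting a standard curve fitted to
defined genotype mixtures, with censoring of no-amplification samples.

**Competition and cohort statistics** (`generations_per_passage`,
`total_generations`, `frequency_from_counts`, `coexistence_call`,
`fisher_exact_one_sided`, `one_way_anova`, `nested_anova`,
`coefficient_of_variation`, `correlate`). log2(dilution) generation
accounting, Wilson-interval frequencies from cytometry counts,
coexistence/exclusion verdicts on frequency trajectories, an exact
one-sided Fisher test from log-factorials, nested ANOVA with
isolate-within-population as the error stratum.

**Synthetic data** (`simulate_batch`, `simulate_serial_passages`,
`simulate_qpcr`, plus the `fg_genotype`/`sg_genotype`/
`sg_revertant_genotype` competition scenario). A piecewise-exponential
mass-balance simulator of diauxic and co-utilizing batch cultures with
state-dependent reporter expression, shared-pool cross-feeding serial
passages, and log-linear Ct generation — all with embedded ground truth.

## Worked example

```r
library(diauxr)

# two synthetic wells: a diauxic strain and a co-utilizing mutant
sims <- list(
  A1 = simulate_batch(genotype_params(mu_glc = 0.56, mu_ace = 0.25,
                                      lag_h = 3.47),
                      noise = noise_model(od_cv = 0.02), seed = 101),
  A2 = simulate_batch(genotype_params(coutilizer = TRUE, mu_co = 0.62),
                      noise = noise_model(od_cv = 0.02), seed = 102))
write_plate_csv(sims, "plate.csv", map_path = "map.csv",
                strains = c("ZED-like", "ptsG-like"))

read_plate_table("plate.csv", well_map = "map.csv") |>
  summarize_growth()
#> # A tibble: 2 × 9
#>   well  strain       mu   se_mu    r2 max_od is_diauxic  p_value shift_h
#>   <chr> <chr>     <dbl>   <dbl> <dbl>  <dbl> <lgl>         <dbl>   <dbl>
#> 1 A1    ZED-like  0.564 0.00458 0.999  0.622 TRUE       5.71e-18    3.41
#> 2 A2    ptsG-like 0.627 0.00546 0.999  0.521 FALSE      5.81e- 1   NA
```

The diauxic well recovers its generating parameters (μ = 0.56 h⁻¹, shift =
3.47 h) within noise; the co-utilizer is correctly called single-phase
(p = 0.58, no shift).

```r
crp_activity(expression_summary(9555, 51), expression_summary(1479, 43))
#> <crp_activity> 6.46 +/- 0.19 (95% CI)
percent_change(3802, 3284, round = TRUE)
#> [1] 16

fisher_exact_one_sided(with_trait = c(48, 36), without_trait = c(0, 12),
                       alternative = "less")
#> # A tibble: 1 × 3
#>    p_value alternative degenerate
#>      <dbl> <chr>       <lgl>
#> 1 0.000112 less        FALSE

# cross-feeding competition settles at a low co-utilizer frequency
simulate_serial_passages(list(sg_genotype(), fg_genotype()), c(0.3, 0.7),
                         n_passages = 10, seed = 7) |>
  coexistence_call()
#> # A tibble: 1 × 3
#>   verdict     level excluded_passage
#>   <chr>       <dbl>            <int>
#> 1 coexistence 0.120               NA
```

Fitted objects support `tidy()`/`glance()`, and `autoplot()`/`plot_*()`
methods draw simulations, plates, activity trajectories and competition
trajectories with ggplot2. The methods vignette
(`vignettes/diauxr-methods.Rmd`) documents every model, default and design
choice.

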