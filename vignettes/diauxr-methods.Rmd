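---
title: "Methods behind diauxr: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind diauxr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diauxr)
```

diauxr analyzes glucose batch-culture experiments of the kind used in
microbial experimental evolution: plate-reader OD600/GFP time series,
extracellular metabolite concentrations, qPCR cycle thresholds, and
flow-cytometry counts from serial-passage competitions. This vignette
records the models each estimator assumes, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## Growth-curve kinetics

**Calibration.** Raw microplate OD600 readouts are multiplied by a
path-length factor (default 2.2) so thresholds are comparable to a 1-cm
spectrophotometer. Every OD bound below refers to calibrated OD.

**Growth rate.** The specific growth rate mu (1/h) is the ordinary
least-squares slope of ln(OD) against time over the first contiguous run of
readouts with OD in [0.05, 0.35], the canonical exponential-phase window.
Points are used as observed; we never interpolate to the exact bounds,
because interpolation would fabricate data and make the window depend on
the noise realization. A regression window must hold at least 5 readouts,
mirroring the minimum used for the substrate-rate regressions.

**Yield.** The yield of a batch culture is its maximum OD. A centered
local-linear smoother over 5 readouts (50 min at the default 10-min
sampling) is applied first so a single spiked readout (bubble, condensation)
cannot masquerade as the maximum. Five points is the smallest symmetric
window that distinguishes a one-readout spike from a real plateau.

**Diauxie detection.** A culture switching from glucose to acetate shows a
second, slower growth phase. Detection follows the two-slope rule: fit the
primary window (OD 0.05–0.35) and an extended window (OD 0.05 to 90% of
maximum OD) independently, and test slope equality. A genuine second phase
lowers the extended slope; statistically indistinguishable slopes mean a
single phase. The equality test is a two-sample Welch t statistic,

$$t = \frac{\hat\mu_{primary} - \hat\mu_{extended}}
           {\sqrt{se_1^2 + se_2^2}},$$

with Welch–Satterthwaite degrees of freedom, one-sided in the direction
*extended < primary* because that is the only direction a diauxie can
produce. The choice of test is ours: the original plate-reader software
behind this procedure is not documented, and a two-sample t on two
separately reported slopes is the simplest test consistent with the
field's decision rule (call diauxic when p <= 0.05). On noiseless data
both standard errors are zero; we then return p = 1 for equal slopes and
p = 0 otherwise rather than dividing zero by zero. An extended slope that
is significantly *larger* than the primary one cannot be diauxie; such
curves are classified single-phase and flagged as a data-quality warning.

Note an intrinsic limit of the rule: the extended window tops out at 90% of
maximum OD, so the second phase is only visible when post-shift growth
contributes more than ~10% of the final OD. Cultures secreting very little
acetate are undetectable by construction, whatever the statistics.

**Shift duration.** The diauxic shift is the growth-arrest interval between
the phases. We compute the smoothed specific growth rate d(ln OD)/dt
(local-linear slope, 5 readouts) and scan it after the primary window. An
absolute threshold of 0.1/h separates arrest from growth; we preferred an
absolute cutoff over a fraction of mu because relative cutoffs misbehave
when the acetate-phase rate is small. The raw threshold crossings only
locate the transitions; each boundary is then refined at the *half-height*
crossing of the adjacent growth plateau (the primary-fit slope before the
arrest; a 90th-percentile estimate of the post-arrest rate trace after it).
The smoothing kernel is symmetric, so its step response passes 50% exactly
at the true transition time — the half-height crossing is unbiased on
noiseless curves, and it sits on the steepest part of the smoothed ramp,
where readout noise displaces it least. Regrowth must persist for three
consecutive readouts before it counts: a single outlying OD readout
contaminates up to two neighboring slope estimates and would otherwise end
the arrest prematurely. If the culture never regrows above threshold
(entered stationary phase inside the observation window) the shift is
reported as unresolved rather than guessed.

## Reporter dynamics

Transcriptional activity is GFP/OD, a per-cell expression proxy; promoter
activity is dGFP/dt/OD, a synthesis-rate proxy. The derivative uses the
same 5-readout local-linear estimator as the growth-rate trace, for
internal consistency, and is defined on interior points only. Points with
OD below 0.02 are dropped before forming either quotient — below that floor
the ratio is dominated by background noise. Blank-well background
subtraction is available but off by default.

Exponential-phase summaries average a trajectory over the growth period
with OD in [0.1, 0.3] per replicate, then report the across-replicate mean
with a t-based 95% confidence half-width. CRP activity is the transcription
driven by a CRP-binding-site hybrid promoter divided by that of the
constitutive control promoter in the same condition; its confidence width
is propagated to first order from the two summaries, and the ratio is
invariant to any common rescaling of the fluorescence units. When comparing
against printed tables we round half-away-from-zero to one decimal for
ratios and to the nearest integer for percent changes, matching the
formatting conventions of such tables.

During balanced exponential growth with synthesis rate alpha, dG/dt =
alpha X implies G/X approaches alpha/mu (up to the decaying inoculum term),
while dG/dt/X recovers alpha directly — these closed forms are the oracles
the test suite checks the estimators against.

## Substrate uptake and secretion rates

Yields are the OLS slope of extracellular concentration against biomass
(OD), restricted to the exponential-phase window mapped to time from the
growth fit, with at least five points. Because the regression is against
biomass rather than time, yields are invariant to reparameterizing the
clock. The specific rate is |yield| x mu in g/l per OD per hour; the yield
sign determines the role (uptake when concentration falls as biomass rises,
secretion otherwise), and reported tables carry positive magnitudes plus a
role column so no downstream reader has to guess a sign convention.
Conversion to molar units is left to the caller: the underlying measurements
are in g/l and OD, and we do not bake in a cell-mass coefficient.

A culture is called a glucose/acetate co-utilizer when both compounds are
taken up at or above a minimum rate (default 0.05 g/l/OD/h) over the same
glucose-present window; glucose uptake with acetate secretion is the
canonical single-substrate pattern; two sub-threshold rates are
indeterminate rather than forced into either class.

## qPCR quantification

Relative expression uses the 2^ddCt method with 100% amplification
efficiency (base-2 exponentiation fixed): dCt = mean Ct(target) − mean
Ct(reference) within a condition, ddCt = dCt(control) − dCt(test), fold =
2^ddCt. Replicates are averaged before differencing — the common
convention — and the confidence width comes from recomputing ddCt per
replicate when all four samples carry equal replicate counts.

Allele frequencies come from a standard curve built on defined genomic-DNA
mixtures. The usual verbal description of this assay - frequency inversely
related to the logarithm of Ct - is ambiguous between two functional
forms, so both are implemented:

* `fraction_on_logct` (default, the literal reading): fraction regressed
  on log10(mean Ct), inverted directly;
* `ct_on_logfraction` (the conventional standard-curve form): Ct regressed
  on log10(fraction), inverted through the exponential.

The two are different curves. Only the conventional form is the exact
inverse of a log-linear amplification process, so round-trip validation
(simulate, fit, invert) uses it; the default follows that literal wording for
users matching an existing protocol. The 0% mixture carries no template
for the allele-specific primer and is censored ("no amplification") rather
than extrapolated; censored points are excluded from fits, and a censored
unknown returns 0% with a flag. Estimates are clamped to [0, 100]% with a
flag when the raw inversion falls outside.

One quantitative caveat worth stating: near the 100% mixture, a Ct error of
e cycles corresponds to a relative template error of about 2^e, so with
0.2-cycle replicate noise a *single* estimate at the top of the curve is
uncertain by several percentage points no matter how the curve is fit.
Recovery checks therefore assert unbiasedness (mean recovery across many
simulated runs within 3 points everywhere) rather than per-run sharpness,
which only holds at low fractions — the regime of the end-point
allele-frequency measurements this method serves.

## Serial-passage competition and cohort statistics

At steady state a culture diluted D-fold regrows D-fold, so generations
per passage equal log2(D) — 9 at the 512-fold transfer regime — and an
experiment of P passages spans P log2(D) generations. Frequencies from
flow-cytometry counts carry 95% Wilson intervals (good coverage at the
boundary fractions seen late in competitions) and a quality flag below
45000 counted cells.

The coexistence verdict inspects the last `tail_passages` (default 3)
frequencies: coexistence when all lie inside [floor, 1 − floor] (floor
0.01) and span at most `band` (default 0.05); exclusion when the final
frequency crosses the floor (mirrored at 1 − floor so the verdict is
invariant to relabeling focal and competitor); otherwise undecided. The
thresholds are operational definitions of "settled" and "lost", not
estimates of anything; they are exposed as arguments.

The one-sided Fisher exact test is computed from log-factorials over the
full hypergeometric support, the tail taken in the stated direction; the
two-sided doubled-tail variant is exposed as an option. One-sided is the
default because a directional hypothesis (loss of diauxie enriched in one
group) is what this contingency encodes; the doubled two-sided value is
exactly twice the one-sided tail here.
One-way ANOVA is the standard between/within decomposition. The nested
ANOVA tests the group (population) effect against the isolate-within-group
mean square, since replicate measurements of one isolate are
pseudo-replicates; sums of squares are Type I with the group entered first,
the natural ordering for a nested design. Both are calibrated under their
null simulations in the test suite (rejection within 2 points of the
nominal 5%).

## The synthetic batch-culture generator

The generator exists so every estimator can be validated against known
ground truth. It is a piecewise-exponential mass balance, not a mechanistic
flux model:

* **Diauxic mode** — three stages: exponential growth on glucose at
  `mu_glc` with acetate overflow (`q_ace_sec` g/l per OD produced), a
  growth arrest of `lag_h` hours at glucose exhaustion, then exponential
  growth on the accumulated acetate at `mu_ace` until it is gone.
* **Co-utilizing mode** — one phase at `mu_co` consuming glucose and
  acetate in proportion to their concentrations, with no secretion and no
  lag: the phenotype of PTS-attenuated mutants.

Integration is a fixed-step forward update at 1-min resolution,
down-sampled to the 10-min readout grid; within each step biomass is
multiplied by exp(mu dt), so with zero noise each phase is *exactly*
exponential at the readouts and regression oracles are exact. Glucose is
declared exhausted at 1e-6 g/l to avoid floating-point chatter at the phase
boundary. GFP integrates alpha(state) x biomass with a low exponential-phase
rate and a higher rate from the shift onward — a phenomenological surge,
not a cAMP-CRP transcription model. Measurement noise is applied per
readout after the dynamics: mean-unbiased multiplicative lognormal noise on
OD (coefficient of variation `od_cv`), additive Gaussian noise on GFP, and
Gaussian noise on simulated Ct values; all-zero noise gives bit-identical,
seed-independent output.

Default parameters are chosen as typical for *E. coli* in M9 glucose batch
culture: glucose rates 0.56–0.9/h (spanning an OPP-pathway-deficient strain
and evolved isolates), acetate-phase rate 0.25/h, biomass yield 0.5 OD per
g/l glucose, and overflow secretion 0.8 g/l acetate per OD — about 0.4 g
acetate per g glucose, a typical aerobic overflow figure. The secretion
default also matters methodologically: below roughly half this value the
acetate phase contributes less than 10% of final OD and the 90%-of-max
two-slope rule cannot see it, which is a property of the two-slope decision
rule itself rather than of this implementation.

The serial-passage simulator grows all genotypes in one well-mixed culture:
secreted acetate enters a shared pool available to every genotype (the
cross-feeding scenario), growth demands are capped jointly when a substrate
cannot cover them, and each passage ends with a 1/D dilution into fresh
medium. Within-passage spatial structure is not modeled, and the only
stochasticity is binomial sampling of the cytometry counts — there is no
demographic drift, so deterministic coexistence levels are exact fixed
points. The shipped scenario parameters (`fg_genotype()`, `sg_genotype()`,
`sg_revertant_genotype()`) were frozen after one calibration pass that ran
the simulator to its fixed point: a fast secretor (0.9/h, 1.5 h shift)
against a 0.72/h co-utilizer settles near 10% co-utilizer frequency from
any starting ratio, while replacing the co-utilizer with a 0.7/h diauxic
revertant produces exclusion within six passages. The stabilizing mechanism
is frequency dependence through the shared acetate pool: when the
co-utilizer is rare, the secretor's post-exhaustion lag leaves it abundant
acetate; when common, its own consumption (and the smaller secretor
population) removes that advantage.

**What passing tests do and do not show.** The generator reproduces the
statistical structure the estimators assume — piecewise exponentials,
log-linear Ct, shared-pool competition — so recovery tests validate the
estimators, not the biology. Real plate-reader data additionally contain
inoculation lags, stationary-phase OD drift, GFP maturation delays,
non-lognormal artifacts (condensation spikes), and Monod-type rate
saturation near substrate exhaustion, none of which are emulated. Results
on real data therefore depend on those effects being small within the
regression windows, which is the reason the windows exclude the culture's
first readouts and its stationary phase.

## Problem sizes and runtime

Monte-Carlo validations use 100 seeded cultures per condition (24-h
horizons at 10-min readouts), 1000 null replicates per ANOVA calibration,
and exhaustive Fisher enumeration over all 2x2 tables with total up to 24 —
sizes at which every check runs in seconds to a couple of minutes on one
core while leaving the binomial uncertainty of the pass counts well inside
the asserted margins.

## Known limitations

* The two-slope diauxie rule is blind to second phases contributing <10%
  of final OD (see above) and to shifts shorter than the smoothing window.
* The shift-duration estimator needs the post-shift rate to exceed the
  0.1/h threshold; very slow acetate growth is reported unresolved.
* The ddCt method assumes equal amplification efficiency across genes; no
  efficiency calibration is performed.
* Nested ANOVA handles unbalanced designs through Type-I sums with group
  first; strongly unbalanced cohorts deserve a mixed model instead.
* The competition simulator's deterministic pools cannot show stochastic
  loss of a rare genotype; its coexistence levels are idealizations.
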