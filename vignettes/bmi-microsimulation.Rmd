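---
title: "Methods: simulating childhood BMI trajectories and evaluating interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating childhood BMI trajectories and evaluating interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmisim)
```

## The problem and the model

Childhood obesity interventions deliver most of their benefit years after
they end, so their evaluation needs a model that can carry a cohort of
children forward in time. `bmisim` implements an individual-level
(micro-simulation) model of BMI progression from early childhood (ages 4/5)
to adolescence (ages 14/15), in discrete time with annual cycles. Each
simulated child carries sex, age, BMI, survival status and survey-design
information (weight, stratum, primary sampling unit). One cycle applies, in
order:

1. **Mortality** — a Bernoulli draw with the life-table probability
   $q(\text{age}, \text{sex})$. Child mortality at these ages is of order
   $10^{-4}$ per year, so the population is nearly conserved.
2. **Expected BMI change** — from a sex-stratified, age-piecewise linear
   equation $\Delta = \beta_0 + \beta_{age}\,a + \beta_{bmi}\,b$, fitted to
   longitudinal data by survey-weighted least squares. Two segments cover
   boys and three cover girls, tiling ages $[4, 16)$ with half-open
   boundaries.
3. **Intervention overlay** — active interventions subtract their
   decay-adjusted effect (kg/m² per year) from the expected gain; effects
   of overlapping interventions add, and persist only for the stated
   duration.
4. **Residual draw** — a mean-zero normal innovation, truncated at ±4 SD,
   whose scale grows linearly with current BMI. This is what lets a cohort
   that starts with a tight, nearly symmetric BMI distribution develop the
   increasing right skew observed in adolescence.
5. **Clamp and age** — BMI is floored at 10 kg/m² and age advances a year.

Weight status uses BMI-for-age z-scores computed by the LMS method,
$z = ((b/M)^L - 1)/(LS)$, with strict cut-point exceedance: underweight
$z < -2$, overweight $z > +1$, obese $z > +2$, and severe obesity $z > +3$
as a reported subcategory of obesity. A child exactly at a cut point stays
in the lower category; the same strictness governs the data-cleaning rule
that drops records with $|z| > 5$.

Population-level outputs (mean BMI, category prevalences, totals) are
survey-weighted with Taylor-linearized variance from between-PSU,
within-stratum variation, so estimates generalize to the weighted
population rather than the sample.

## The synthetic cohort generator: a stated world

The longitudinal study the model family is built on is access-restricted,
and the fitted equation coefficients are unpublished. The package therefore
ships a generator that emulates the published summary series of the child
cohort: six biennial waves at ages 4/5 through 14/15, wave mean BMI 16.3,
16.6, 17.7, 19.2, 20.6, 22.2 kg/m²; overweight (excluding obesity) 23.8 →
20.9 %; obesity 9.1 → 11.7 %; 4,983 children representing a population of
more than 250,000. Those numbers are the generator's defaults
(`calibration_targets()`, `generator_config()`), not tuning dials.

**Cross-sections.** Each wave's BMI distribution (per sex and single year
of age) is a shifted log-normal — the minimal right-skewed family with
three parameters to meet three constraints: the wave's mean and the
exceedance probabilities over the overweight and obesity BMI thresholds at
that age. The two tail constraints determine `meanlog` and `sdlog` exactly
as functions of the shift; the shift is then solved by `uniroot` on the
mean constraint (tolerance 1e-10). Infeasible triples (a mean too low for
the requested tails) raise a calibration error naming the wave. Overweight
and obese prevalences are treated as *disjoint* reported categories, so
the calibrated tails are $P(B > b_{+1}) = (\text{ow}+\text{ob})/100$ and
$P(B > b_{+2}) = \text{ob}/100$.

**Dynamics.** A child's rank in the distribution evolves as a Gaussian
copula: the latent score follows an AR(1) with per-wave (2-year)
correlation $\rho = 0.9$, a value chosen once as realistic for BMI
tracking in childhood, where 2-year rank correlations are typically
0.8–0.95. Each wave's observed BMI is the inverse CDF of that wave's
calibrated marginal, so every cross-section reproduces its targets *by
construction* while children track over time. Because the marginals grow
increasingly skewed, so does the cohort — the generator's analogue of the
real distributional change.

**Survey structure.** Weights are gamma-distributed (CV 0.3) and rescaled
to sum exactly to the population total; the design is a synthetic 8
strata × 4 PSUs assigned round-robin, since real design identifiers are
unavailable. A socioeconomic quintile column is generated uniformly but
unused by the default equations (a placeholder for future stratification).
Sex is pooled in the published series, so the generator applies a
symmetric ±0.05 kg/m² offset (boys higher) around the pooled mean; sex
differences are deliberately not a calibrated quantity. Attrition is
monotone Bernoulli dropout at 7 %/wave by default (≈30 % loss by wave 6),
and an optional contamination rate injects records with $|z| > 5$ — and
*only* those records — for testing the cleaning rule. At ages where strong
reference skew makes $z > +5$ unrepresentable (the LMS transform has
supremum $-1/(LS)$ for $L<0$), contamination goes to the low side instead;
clean draws are clamped inside $|z| < 4.9$ so the generator itself never
produces implausible records.

**What the generator does not emulate.** Real two-stage geographic
sampling; informative (non-random) dropout; measurement error; seasonal
and within-year age structure (ages are exactly the two integer years of
each wave pair); secular cohort effects. A green calibration test
establishes that the pipeline is self-consistent — that equations fitted
on generator output drive the simulator back to the generator's targets —
not that the model would validate on the restricted real data.

## The bundled reference tables are synthetic

Official growth-reference LMS coefficients could not be redistributed
offline, so `inst/extdata/who_lms_synthetic.tsv` contains *synthetic*
curves: smooth splines through realistic knots for the median (adiposity
rebound near ages 5–6, rising to ≈19–20 kg/m² at 16), the coefficient of
variation (0.08 → 0.12), and the Box–Cox power (−0.7 → about −2),
monthly from 48 to 191 months, both sexes. All calibration and
classification use the same reference, so results are internally
consistent; absolute cut-point values differ slightly from the official
tables, and users with access to them can pass their own file to
`lms_reference(path)`. The bundled life table is likewise a labelled
synthetic stand-in with realistic magnitudes.

## Annualizing biennial fits

The fitting data are biennial, while the engine steps annually. Regressing
the annualized change $(b_1 - b_0)/2$ on $(1, a_0, b_0)$ gives the correct
*2-year* map $b \mapsto (1 + 2\beta_{bmi})b + 2(\beta_0 + \beta_{age}a)$,
but applying the annual-rate coefficients twice is not the same thing:
compounding adds $\beta_{age} + \beta_{bmi}\Delta$ per wave, which we
measured as a systematic +0.35 kg/m² drift in endpoint mean BMI over ten
cycles. The engine therefore uses the exact affine square root of the
fitted biennial map when `delta_t = 2`:
$$\phi = (1 + 2\beta_{bmi})^{1/2},\qquad
c_a = \frac{2\beta_{age}}{1+\phi},\qquad
c_0 = \frac{2\beta_0 - c_a}{1+\phi},$$
so that two annual steps compose exactly to the fitted biennial step. The
per-cycle innovation SD is scaled by $2/\sqrt{1+\phi^2}$ so the dispersion
accumulated over two cycles equals the residual dispersion observed
between waves. For equation sets with `delta_t = 1` (hand-built
coefficients, or `annualize = FALSE`) the engine is the literal affine
recursion $b \leftarrow b + \beta_0 + \beta_{age}a + \beta_{bmi}b$, which
is also the closed-form oracle the test suite checks to 1e-10.

The residual scale is fitted as a linear function of current BMI from a
weighted regression of absolute residuals (scaled by $\sqrt{\pi/2}$ under
normality), floored at 0.01 kg/m²; this BMI-dependent scale is on by
default and is required for the skew emergence property.

## The validation pipeline

`run_validation()` wires the stages together with a holdout design:
generate baseline and follow-up; drop implausible records; fit the
equations on *all* waves' change pairs; then initialize the simulator with
the wave-1 cross-section only and run ten annual cycles with zero
mortality. Even cycles align with the biennial target waves. The simulated
means and prevalences at later waves are genuine model output — waves ≥ 2
never reach the simulator's state — and are compared with the targets at
±3 design-based standard errors per wave.

Measured behaviour over seeds 1–10 (n = 4,983): endpoint weighted mean BMI
22.18 (target 22.2), obesity 11.9 % (target 11.7), severe obesity 2.0 %
(consistent with "around 2 %"), endpoint skewness ≈ 2.5 vs ≈ 1.2 at
baseline. **Known limitation:** the overweight (non-obese) band runs
1.5–2 pp high (≈22.5 % vs 20.9 %). The engine's normal innovations give the
simulated cross-section a near-Gaussian core, which overfills the
$1 < z \le 2$ band relative to the log-normal target shape even when mean,
SD and the obese/severe tails match. Reproducing the core shape exactly
would need non-Gaussian innovations, which we kept out of scope
deliberately: the residual model stays the simplest one consistent with
skew emergence.

## Health economics

QALYs accrue as $\sum_t \mathbb{1}[\text{alive}_t]\,u(\text{age}_t,
\text{status}_t)\,d(t)$ over lived cycles $t = 0..H{-}1$ (the final
snapshot is a time point, not a lived year), with $d(t) = 1$ for $t<1$ and
$(1+r)^{-t}$ beyond one year — first year undiscounted, end-of-cycle
accrual, no half-cycle correction (annual cycles, short horizon). The
default rate is 5 %/year, a common national reference-case convention, and
configurable. Costs work the same way, plus a one-off per-participant
delivery cost at each enrollee's start cycle; indirect costs enter only
under the societal perspective. The shipped utility and cost tables are
**placeholders** (e.g. healthy 0.95, obese 0.88; costs zero) because no
authoritative values could be bundled; substantive analyses must supply
their own tables.

ICERs compare arms simulated from the same baseline and seed (common
random numbers), so a zero-effect intervention yields exactly zero deltas.
Effects are oriented so health gains are positive (QALYs gained; BMI or
z-score units avoided); cheaper-and-better is *dominant*,
costlier-and-worse *dominated*, and a zero effect delta reports no ratio.
`sensitivity_scan()` re-runs the paired simulation seed-matched for each
bound of effect size, duration and discount rate.

## Numerical choices and conventions, collected

- Calibration root-finding: `uniroot` tolerance 1e-10 on the shift; tails
  are exact in the two threshold constraints by construction.
- Whole-year ages map to mid-year (years×12+6 months) for reference
  lookup; fractional ages convert exactly. Reference interpolation is
  linear in months, with no extrapolation outside 48–191 months.
- Segment boundaries, age bands and status cut points are half-open /
  strict as described; boundary ages use the older segment.
- Engine draws are truncated at ±4 SD; BMI is floored at 10 kg/m²;
  innovation SD floored at 0.01.
- Eligibility is evaluated once at enrollment, not re-evaluated.
- Determinism: every stochastic stage is a pure function of its integer
  seed; the pipeline seed derives the engine seed by a fixed offset.
- Variance estimation uses first-order Taylor linearization with the
  with-replacement approximation and normal-quantile (1.96) intervals;
  single-PSU strata are rejected rather than silently collapsed.

## Known limitations

Beyond the overweight-band bias discussed above: equations are linear in
age and BMI within segments (no splines, interactions off by default, no
mixed effects); socioeconomic position is carried but unused; the model
stops at age 15 with no adult linkage; chronic-disease events are not
simulated; the synthetic reference tables approximate, but are not, the
official growth references.
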