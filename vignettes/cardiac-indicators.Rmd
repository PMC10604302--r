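---
title: "Methods: cuff-vitals indicators and their evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuff-vitals indicators and their evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioCS)
```

## The pressure-decay model and the seven indicators

All seven indicators are deterministic transforms of one subject's systolic
blood pressure (SBP, mmHg), diastolic blood pressure (DBP, mmHg), and heart
rate (HR, beats/min). The physical picture is a two-element windkessel:
after the systolic peak, arterial pressure decays exponentially,

$$P(t) = \mathrm{SBP}\, e^{-t/RC},$$

with time constant $RC$, the product of peripheral resistance and
compliance. Two requirements pin everything down:

* the decay must reach DBP after exactly one beat period $\tau = 1/\mathrm{HR}$,
  which forces $RC = 1/(\mathrm{HR}\,\ln(\mathrm{SBP}/\mathrm{DBP}))$;
* MAP is the time-average of $P(t)$ over the beat, which evaluates to the
  logarithmic mean $(\mathrm{SBP}-\mathrm{DBP})/(\ln \mathrm{SBP}-\ln
  \mathrm{DBP})$.

Natural logarithms are not a convention here but a consequence: the closed
form must equal the integral of the exponential model. The package tests
both identities directly (quadrature of `pressure_decay()` against
`cs_map()` to 1e-8 relative error; `pressure_decay(τ) = DBP` to 1e-10).

PBPI is pulse pressure normalised by DBP; PBPIRC divides it by RC. The
harmony measure HM relates the squared beat frequency to the cubed gap
between SBP and MAP, by analogy with the square-period/cubed-axis form of
Kepler's third law. The ejection-time fraction $\alpha$ comes from a
different, triangular approximation of the pressure wave with equal ascent
and descent slopes, yielding $\alpha(1-\alpha)\tau^2 =
(\mathrm{SBP}-\mathrm{DBP})^2$; the physiological root is the smaller one,
and $\alpha_2 = -\ln\alpha$.

### Unit conventions

The source formulas are unit-sensitive and the literature leaves the units
implicit, so `cs_conventions()` pins them explicitly and keeps them in one
place:

* RC uses HR per **minute** (typical resting values land near 0.03);
* $\alpha$ uses the beat period in **milliseconds**, $\tau =
  60000/\mathrm{HR}$ (values near 0.002–0.005);
* HM squares the scaled rate $1000\cdot\mathrm{HR}/60$ (values roughly
  30–200).

Each convention matches the magnitudes of the published per-group summary
tables for the UCI heart-disease subsets; alternates (`per_sec`, seconds)
are available for sensitivity analysis. HM uses the logarithmic-mean MAP of
the decay model, not the arithmetic mean of the triangular model: the HM
definition refers to "the MAP" as an already-defined quantity, and only the
log-mean reading reproduces the published HM magnitudes.

### Numerical and degenerate-input choices

* $\alpha$ is evaluated as $x/(2(1+\sqrt{1-x}))$ with $x =
  (2(\mathrm{SBP}-\mathrm{DBP})/\tau)^2$ — algebraically identical to the
  quadratic-root form but free of the catastrophic cancellation that the
  naive $\tfrac12 - \tfrac12\sqrt{1-x}$ suffers at the small $\alpha$
  typical of resting vitals.
* A negative discriminant (pulse pressure exceeding half the beat period)
  yields `NA` with a warning, never a clamped 0.5: silent clamping would
  bias group statistics toward the boundary.
* Invalid vitals (SBP ≤ DBP, non-positive values, missing components) raise
  errors in the strict scalar functions (`cs_map()` etc.) but become
  per-field `NA`s in the tolerant vectorised front end `cs_indicators()`,
  which never fails on a single bad record. Zeros in pressure/HR fields are
  treated as missing-value sentinels only where configured
  (`cohort_policy()`), because 0 is a legal code in other UCI fields; the
  sentinel −9 is always missing.
* Equal SBP and DBP is rejected rather than mapped to the logarithmic-mean
  limit: in cuff data an equal pair is a recording artifact, not a
  measurement.

## Group comparison

`indicator_report()` produces, per indicator and in a fixed order (α, α2,
HM, MAP, PBPI, PBPIRC, RC), group means, medians (midpoint convention for
even sizes), sample SDs (n−1), a two-sided Wilcoxon–Mann–Whitney p-value,
and the consistency measure

$$d = \frac{|\mu_0 - \mu_1|}{\sqrt{\sigma_0^2 + \sigma_1^2}}.$$

The denominator is the square root of the summed group variances. The
printed source formula is typographically ambiguous between this reading
and a variance (non-root) denominator; the root reading is adopted because
it reproduces the published consistency matrix cell-for-cell (e.g. Cleveland
MAP: $|105.1306-108.0998|/\sqrt{11.6754^2+11.6864^2} = 0.1797$), while the
non-root reading misses every robust cell by large factors. This
cross-check is part of the test suite, using the published group statistics
shipped in `reference_group_stats()`.

The WMW test uses exact enumeration when the combined sample is at most 30
and untied, and the continuity-corrected normal approximation with tie
correction otherwise. The two paths agree to about 0.01 absolute p at
n = 8 per group (measured worst case 0.011). Significance stars follow the
10%/5%/1% convention. No multiple-testing correction is applied across the
seven indicators, matching the reporting style the package reproduces.
Because $\alpha_2$ is a strictly decreasing transform of $\alpha$,
`median(ALPHA2) = -log(median(ALPHA))` holds exactly on odd-sized samples
(the even-n midpoint convention breaks exactness, which is why the
equivariance test uses an odd sample).

## Feature selection and classification

`scenario_features()` encodes two candidate sets: Scenario 1 is the
low-acquisition-cost set (age V3, gender V4, hypertension history V11, plus
the seven indicators — exactly 10 features); Scenario 2 is every registered
non-identifier, non-response variable plus the indicators.

The selection criteria are deterministic given the data:

* **InfoGain** ranks by Shannon-entropy gain in bits. Continuous features
  are discretised by equal-frequency binning with 10 bins (configurable);
  the ranking, not the absolute gain, is what downstream use consumes, and
  equal-frequency binning is robust to skewed indicator distributions.
  No retention cutoff is imposed by default; `top_k` is available.
* **VIF** iteratively removes the feature owning the highest-VIF design
  column while any VIF exceeds 10, with exact collinearity treated as
  infinite VIF (removed first). Categorical features are one-hot encoded
  and removed whole if any encoded column exceeds the threshold.
* **ANOVA** keeps features whose one-way ANOVA against the binary response
  (equivalently the two-sample equal-variance F test) has p < 0.05;
  categorical features use a chi-squared association test.
* **AIC** steps backward from the full logistic model (the direction
  matching the removal-of-variables language used for VIF; forward mode is
  available). Quasi-separation is handled by an iteration cap rather than
  penalisation so the AIC stays comparable to the unpenalised likelihood.
* The composites ANOVA+VIF and AIC+VIF chain the stages with a concatenated
  trace.

The classifiers mirror the standard R fits: `e1071::naiveBayes` (no Laplace
smoothing, NAs passed through), `randomForest` (500 trees, complete-case
training), `stats::glm` logit with a 0.5 probability threshold,
polynomial-kernel `e1071::svm` with cost 100 and unscaled inputs, and an
in-package AdaBoost.M1 (`cs_adaboost()`) boosting `rpart` classification
trees for 10 rounds.

`run_experiment()` repeats a stratified 70/30 holdout (the fraction is a
package default, exposed as `train_fraction`, since the repeated-holdout
convention reports means over splits). Feature selection runs once on the
full cohort by default, matching the presentation of fixed per-model
variable lists; `nested = TRUE` re-selects inside every iteration for
leakage-sensitivity analysis. Accuracy is averaged over iterations with the
(J−1)-denominator SD (a single iteration reports `NA`, never 0). Averaged
sensitivity, specificity, and positive predictive value skip iterations
with a zero denominator and report the skipped count — averaging zeros in
would silently bias the measures, while genuinely all-positive predictions
still produce a defined specificity of exactly zero (the behaviour seen on
severely imbalanced cohorts).

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` draw (DBP, pulse pressure, HR) per group
from truncated normals, with SBP = DBP + PP, so `SBP > DBP > 0` is
structural rather than enforced by rejection. Group separation enters only
through vitals and covariate parameter shifts; indicator-level effects are
emergent nonlinear transforms, exactly as in real cohorts. Missingness is
MCAR over covariate columns (list-wise deletion downstream is then
unbiased, the only policy the pipeline's complete-case handling can be said
to assume).

The default pulse-pressure truncation floor is 15 mmHg: HM behaves like
PP⁻³, so a lower floor gives it a tail whose sample mean converges too
slowly for stable summaries; 15 mmHg is also at the low edge of plausible
cuff measurements.

`cohort_preset()` freezes four configurations emulating the UCI subsets,
with the published sizes and prevalences (Cleveland 282/125, Hungarian
294/106, Long Beach 200/149, Switzerland 123/115). The per-group vitals
parameters were fitted once, by Nelder–Mead on log-ratios of large-sample
simulated indicator summaries against the published group means and SDs,
and then frozen. Across the 4 datasets × 2 groups × 7 indicators, means and
SDs land within ±25% of the published values, with one documented
exception: the Long Beach cardiac-group α2 SD (printed 3.07 against a mean
of 5.88) is mutually inconsistent with the same row's α statistics under
any smooth vitals distribution — it reflects a handful of extreme raw
records — and is excluded from the tuning targets and the comparison test.
What passing these checks shows is that the generator reproduces the
marginal location/scale structure of the real subsets; what it does not
show is fidelity of tails, of vitals–covariate correlation (age and gender
are independent of vitals in the presets), or of the 75 clinical
covariates, which are represented only by labelled noise columns.

`spec_implied_effects()` propagates the spec parameters through each
indicator by the delta method (first-order, truncation ignored), and
`recovery_check()` compares replicate estimates of d against those analytic
values — the package's parameter-recovery harness. For smooth, mildly
nonlinear indicators (MAP, PBPI, RC) the delta approximation is accurate to
a few percent at the default dispersions; for heavy-tailed HM it is only
indicative.

## Problem sizes and determinism

The shipped tests exercise: quadrature consistency on 1,000 random vitals;
the repeated holdout at n = 300 with 100 iterations for all five
classifiers; parameter recovery over 50 replicate cohorts of n = 2,000; and
null-cohort calibration at n = 10,000. All randomness flows from explicit
seeds — cohorts are byte-identical across runs for a fixed spec and seed,
and `run_experiment()` derives per-iteration seeds from its master seed so
the whole experiment is bit-reproducible.

## Known limitations

* The indicators assume resting cuff vitals; no waveform acquisition or
  beat-to-beat variability is modelled, and R and C are not separately
  identifiable.
* The generator's presets match published summary statistics, not record-
  level reality; conclusions about classifier rankings on real data should
  be drawn from real cohorts read via `read_uci_raw()`/`read_cohort_csv()`.
* Published headline accuracies on the real UCI subsets depend on
  undocumented curation of the raw files and are deliberately not encoded
  as package expectations; the pipeline reproduces the methodology, and its
  property-level behaviour (separable-data recovery, chance-level
  degradation, the imbalance-driven zero-specificity pathology) is what the
  tests pin down.
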