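---
title: "Methods: a patient-level cost-utility model of major trauma triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a patient-level cost-utility model of major trauma triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumatriage)
```

## Scope and perspective

`traumatriage` evaluates prehospital triage tools for suspected major
trauma from an NHS and personal social services perspective, over a
lifetime horizon, with future costs and QALYs discounted at 3.5% per
annum. The unit of analysis is the individual patient: a decision tree
routes each simulated patient through triage and (possibly) a secondary
transfer, a three-stage survival cascade determines death within 30 days,
between 30 days and one year, or during a long-term annual simulation,
and lifetime QALYs and costs are accrued along the way. Nine tools with
realistic sensitivity/specificity trade-offs (from 99.8%/2.5% to
28.4%/88.6%) are compared on one common cohort.

The analysis deliberately excludes patients injured within an MTC's own
catchment (no routing trade-off exists for them), geographic ambulance
network modelling, and productivity costs.

## The decision tree

A tool-positive patient always receives full MTC care. Secondary movement
between hospitals is governed by four probabilities conditional on the
triage category: true positives (26.6%) and false positives (7.4%) are
first stabilised at a local hospital and then moved to the MTC — they
retain the full MTC benefit but incur the £252 transfer cost — while
false negatives (32.5%) and true negatives (4.3%) are transferred from
their local hospital to the MTC after admission. This reading of the
transfer probabilities is the one that reproduces the expected per-strata
MTC flows implied by the analytic formula
`n16·(sens + (1−sens)·fn)` and `nLT16·((1−spec) + spec·tn)`, which the
package exposes as `expected_flows()` and uses as the exact oracle for
the Monte-Carlo engine.

## Survival cascade

**30 days.** `logit(Ps) = b0 + b_age·age + b_iss·ISS + b_gcs·GCS +
b_male·male`. The shipped coefficients (intercept 1.3488, age −0.045,
ISS −0.12, GCS +0.4, male −0.1) are *illustrative, TARN-like* values: the
slopes have the clinically expected signs and the intercept was calibrated
once so that cohort-level 30-day mortality is ≈ 4.2%, a plausible figure
for a suspected-major-trauma case mix in which ~9% have ISS ≥ 16. They are
not estimates from any registry; users with access to published
survival-equation coefficients should supply them through the
`survival_model` section of the parameter file. ISS ≥ 16 patients never
treated at an MTC have their death probability multiplied by RR 1.25
(capped at 1).

**30 days to 1 year.** 3.6% for ISS ≥ 16 (× RR 1.64 if never at an MTC),
1.7% for ISS < 16.

**Long term.** Survivors of the first year face annual life-table death
probabilities transformed on the survival scale, `q' = 1 − (1 − q)^HR`,
with HR 5.19 (ISS ≥ 16) or 1.38 (ISS < 16). The hazard ratio depends on
injury severity, not on where the patient was treated — the MTC benefit
operates entirely within the first year — which is why the engine can
compute each patient's death age once per parameter set and reuse it
across all nine tools.

The annual walk is implemented by inverting the patient's cumulative
survival curve with a single uniform draw (death year = first year at
which cumulative survival falls below the draw). This is distributionally
identical to year-by-year Bernoulli draws but couples the outcome
monotonically in the hazard ratio: for the same draw, a larger HR can only
bring death forward. Death is placed mid-cycle.

## Accrual conventions

Cycles are annual from the injury (t = 0 undiscounted, discount factor
`(1+r)^-t` thereafter); the year of death earns a half-year credit.
Specifically:

* death within 30 days: zero QALYs; acute costs only (treatment band +
  tariff + transfer);
* death between 30 days and 1 year: half a year of utility
  (undiscounted), acute costs plus the £1,766 post-discharge charge, no
  long-term costs;
* 1-year survivors: full utility in year 0, then annual utility and
  long-term NHS costs to the death year. Long-term costs start at year 1
  (year 0 is covered by the acute and post-discharge components).

Utility is the general-population quadratic age/sex regression
(constant 0.9508566, age −0.0002587, age² −0.0000332, male +0.0212126),
multiplied by 0.789 for survivors with ISS ≥ 9 (0.65 observed one year
post-injury ÷ 0.824 for the matched reference population, age 61, 59.1%
male). ISS < 9 injuries are assumed to have no long-term utility effect.
Long-term NHS costs are the age/sex schedule × 1.45 (ISS ≥ 16) or × 1.25
(all other suspected-trauma survivors, including ISS < 9 — the source
multipliers are grouped only as ISS ≥ 16 versus ISS < 16; the choice is
configurable). The MTC admission tariff applies only from ISS ≥ 9 (no
tariff row exists below that), which matters for the tariff threshold
grid. Treatment cost bands follow the published tariff tables literally,
with half-open `(lo, hi]` edges; the blunt table splits at ISS 16 and the
penetrating table at ISS 15 — an asymmetry in the sources that we
preserve rather than harmonise.

## Synthetic cohort

Only marginal summaries of the source registry population are published
(age 46.8 ± 21.3; 58.3% male; ISS 5.2 ± 7.2; 9.1% ISS ≥ 16;
GCS 14.4 ± 1.9; 98.2% blunt), so the generator matches those moments
*by construction* and treats everything else as explicit configuration:

* age — truncated normal on [16, 100] whose truncated moments are solved
  numerically to the targets (adult trauma population);
* ISS — integers 1–75; the severe tail (16–75) is a discretised gamma
  with mean 24 / sd 8 (a typical registry tail shape; only its total mass,
  0.091, is a published fact) and the low-severity component is a
  discretised gamma solved so the overall mean/sd hit 5.2/7.2;
* GCS — a point mass at 15 plus a geometric tail to 3, solved to
  mean 14.4 / sd 1.9;
* dependence — a Gaussian copula over (age, ISS, GCS) with rank
  correlations defaulting to ISS–GCS −0.4 (severe injuries depress
  consciousness, which the survival equation needs to see jointly),
  age–ISS +0.05 (weak), age–GCS 0. These correlations are *choices*, not
  recovered facts, and are arguments of `cohort_spec()`.

If a user-supplied moment target is infeasible (e.g. an ISS variance the
support cannot carry), the solver warns and uses the best fit. What
passing the moment-recovery tests shows is that the generator reproduces
the published *marginals*; it cannot show that the joint structure
matches the unavailable patient-level data, and any conclusions that
hinge on the ISS–GCS–age joint tail should be re-run against real
registry data via `read_cohort()`.

## Probabilistic sensitivity analysis

Uncertainty distributions are assigned by parameter type, moment-matched
so every distribution's analytic mean equals its point estimate:
probabilities and the injury utility ~ Beta; costs ~ Gamma; relative
risks, hazard ratios and cost multipliers ~ Lognormal. Where no standard
error is supplied the default is 20% of the mean (`psa$se_frac`). Tool
sensitivities and specificities are Beta with an effective sample size
(`psa$tool_ess`, default 1000, the scale of the derivation cohorts);
a proportional SE would be incoherent for probabilities near 1.
Parameters at a support boundary (RR = 1, zero costs) stay fixed.
Regression coefficients and the discount rate are not varied.

Each PSA run draws one parameter set and fresh patient-event uniforms;
the cohort itself is fixed per seed (resampling patients each run would
conflate population sampling error with parameter uncertainty, which the
analysis intends to isolate; pass a different cohort to study the
former). Within a run all nine tools share every uniform draw (common
random numbers), so tool contrasts are differenced free of shared
Monte-Carlo noise; with the severity-only hazard ratios this makes the
null-effect invariant (no MTC benefit ⇒ all tools identical) hold to
numerical identity, not merely in expectation. Run `r` reseeds with
`seed + r − 1`. Decision statistics are computed from PSA mean costs and
mean QALYs, not from averaged per-run ICERs (ratios of means, not means
of ratios). Stability is monitored with a running-mean check
(`stability_check()`: converged when the trailing 10% of the trace stays
within a configurable tolerance of the final mean).

Default analysis sizes in this package's own checks are 100 runs × 2,000
patients (and single 100,000-patient cohorts for moment and flow checks);
a full-scale analysis uses 2,000 runs × 25,000 patients via the same
functions.

## Incremental analysis

Strategies are sorted by mean QALYs; strictly dominated entries are
removed (another strategy with at least the QALYs at no more cost, one
comparison strict; exact ties keep the first-listed, lower-cost-first),
then extended dominance is eliminated iteratively until the ICER sequence
along the frontier is strictly increasing — equivalently, the frontier is
the lower convex hull of the cost–QALY cloud. `cost_effective_at()`
selects the highest-QALY frontier member whose ICER does not exceed the
MAICER (boundary inclusive), which coincides with the net-monetary-benefit
argmax; the test suite verifies both properties against brute-force
search over random strategy sets.

Two scenario levers mirror the policy questions the model exists for:

* **Partial MTC benefit for ISS 9–15** (`scenario_iss9to15_benefit()`):
  the 30-day RR (from 1.25) and the 1-year RR (from 1.64) are
  interpolated *linearly on the RR scale*, `1 + f·(RR − 1)`, giving e.g.
  1.32 and 1.48 for the 1-year RR at f = 0.5 and 0.75. Log-linear
  interpolation (`RR^f`) was considered and rejected for transparency;
  at f = 0.25 the two differ only in the third decimal (1.0625 vs
  1.057 on the 30-day RR).
* **MTC tariff threshold grid** (`tariff_threshold_grid()`): tariffs
  enter the ledger linearly and do not affect survival, so mean costs are
  re-priced exactly from the recorded proportions of patients ever at an
  MTC in each tariff stratum — an exact shortcut, not an approximation,
  verified in the tests against full re-simulation.

## Numerical and degenerate-input choices

* All probability transforms are clipped to [0, 1]; utilities to [0, 1]
  (never active for the default coefficients over ages 0–100, which the
  tests assert as a typo guard).
* The life-table walk terminates because `q = 1` at the horizon age cap
  (default 100); a zero uniform draw is nudged to machine epsilon so the
  survival-curve inversion always crosses.
* Ledger components reconcile to totals within 10⁻⁶ GBP by construction
  and by test.
* Identical cost/QALY ties in the frontier are broken deterministically
  (lower cost, then input order) so results are order-invariant.
* YAML round-trips use 15 significant digits; seeds are plain R integer
  seeds and every public entry point that consumes randomness takes one.

## Known limitations

The shipped survival coefficients, life table and NHS cost schedule are
synthetic stand-ins; absolute QALY/cost levels and hence ICER magnitudes
depend on them and should not be quoted as estimates for the English
system without calibrated inputs. Flow quantities, the utility
derivations, RR interpolation, and all orderings and frontier mechanics
are input-calibration-independent. Direct-to-MTC and transferred patients
receive the same MTC benefit (quantitative evidence separating them is
lacking); comorbidity-adjusted survival equations are out of scope beyond
the pluggable model form; and costs are used as given in 2017/18 prices
with no re-inflation machinery.
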