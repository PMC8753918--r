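# traumatriage

Patient-level probabilistic cost-utility model of prehospital major trauma
triage in an English trauma system.

## The problem

English major trauma networks route patients with suspected severe injuries
either to a major trauma centre (MTC) or to their local hospital, using a
prehospital triage tool combined with paramedic judgement. Patients with an
Injury Severity Score (ISS) ≥ 16 have better outcomes at an MTC, but MTC
care costs more and every triage tool trades sensitivity (severe cases sent
to the MTC) against specificity (non-severe cases kept local). This package
implements a microsimulation that quantifies that trade-off for nine
empirically derived tools spanning sensitivity 28.4–99.8% and specificity
2.5–88.6%, and identifies the tool a UK decision maker should consider
cost-effective at a given maximum acceptable incremental cost-effectiveness
ratio (MAICER, typically £20,000–£30,000 per QALY).

## The model

For each simulated patient (age, sex, ISS, GCS, blunt/penetrating type,
drawn from a Gaussian-copula synthetic cohort matching published registry
marginals):

1. **Triage decision tree** — the tool classifies the patient
   (P(positive | ISS ≥ 16) = sensitivity; P(positive | ISS < 16) =
   1 − specificity); tool-negative patients may still receive a secondary
   transfer to the MTC with probability 32.5% (ISS ≥ 16) or 4.3%
   (ISS < 16); tool-positives are sometimes stabilised locally first
   (26.6% / 7.4%) and incur a £252 transfer cost.
2. **Survival cascade** — 30-day survival from a TARN-style logistic
   equation `logit(Ps) = b0 + b_age·age + b_iss·ISS + b_gcs·GCS +
   b_male·male`; ISS ≥ 16 patients never seen at an MTC have their 30-day
   death probability multiplied by RR 1.25 and their 30-day-to-1-year
   probability (3.6%) by RR 1.64. Survivors of the first year face annual
   life-table hazards inflated by HR 5.19 (ISS ≥ 16) or 1.38 (ISS < 16),
   via `q' = 1 − (1 − q)^HR`.
3. **Lifetime accrual** — QALYs multiply each life year by a general-
   population utility (quadratic age/sex regression) scaled by 0.789 for
   ISS ≥ 9 survivors; costs sum the admission tariff (£2,819 ISS ≥ 16 /
   £1,466 ISS 9–15 at an MTC), ISS-band treatment costs, a £1,766
   post-discharge charge, and multiplier-inflated (1.45/1.25) annual NHS
   costs to death. Future costs and QALYs are discounted at 3.5% per
   annum.

Strategies are compared by full incremental analysis: dominated and
extendedly dominated tools are removed, ICERs (ΔCost/ΔQALY) are computed
along the efficiency frontier, and the cost-effective tool at a MAICER λ
is the frontier argmax of net monetary benefit λ·QALY − Cost. A
probabilistic sensitivity analysis redraws every uncertain parameter
(Beta for probabilities and utilities, Gamma for costs, Lognormal for
RRs/HRs, all moment-matched) each run; ICERs are computed from PSA mean
costs and QALYs.

The shipped survival-equation coefficients, life table and NHS cost
schedule are clearly-labelled illustrative/synthetic stand-ins (the
published TARN coefficients and person-level cost data are not
redistributable); all are replaceable through the YAML parameter file.

## Worked example

```r
library(traumatriage)
params <- default_parameters()
psa <- run_psa(cohort_spec(), params, n_runs = 200, n_patients = 5000, seed = 42)
frontier <- incremental_analysis(psa$means)
frontier
#>                    tool   qalys   costs               status     icer
#>  28.4% Sens, 88.6% Spec 14.1385 43547.0           comparator       NA
#>  57.0% Sens, 80.0% Spec 14.1476 43631.7 extendedly dominated       NA
#>  64.2% Sens, 76.1% Spec 14.1501 43654.3             frontier  9239.87
#>  69.8% Sens, 70.1% Spec 14.1521 43673.5 extendedly dominated       NA
#>  74.6% Sens, 65.7% Spec 14.1538 43690.6 extendedly dominated       NA
#>  87.5% Sens, 62.8% Spec 14.1584 43731.2             frontier  9340.51
#>  90.4% Sens, 58.4% Spec 14.1593 43742.1             frontier 11142.91
#>  94.8% Sens, 18.7% Spec 14.1607 43777.3 extendedly dominated       NA
#>   99.8% Sens, 2.5% Spec 14.1623 43800.7             frontier 19998.39
cost_effective_at(frontier, 20000)
#> [1] "99.8% Sens, 2.5% Spec"
```

Reading the output: the most specific tool (28.4% sensitivity) sends the
fewest patients to MTCs and is the cheapest, least effective comparator;
each frontier row's ICER is the cost per additional QALY of stepping up to
that tool from the previous frontier member. With the illustrative
survival coefficients and synthetic cost schedule the frontier ICERs are
lower than in a fully calibrated analysis, so the most sensitive tool is
selected here at £20,000/QALY; with calibrated national inputs the
selection shifts toward more specific tools. The mean discounted QALY and
cost *orderings* across tools, and all flow quantities, are calibration-
independent.

Analytic MTC flow check (no simulation):

```r
expected_flows(0.284, 0.886, 8916, 91084, params$clinical$transfer)
#>   mtc_iss16 mtc_issLT16 mtc_total
#> 1    4606.9     13853.7   18460.6
```

A command-line wrapper ships in `inst/cli/traumatriage.R`
(`cohort`, `flows`, `run`, `psa`, `scenario`, `grid`, `frontier`
subcommands), e.g.
`Rscript $(Rscript -e 'cat(system.file("cli","traumatriage.R",package="traumatriage"))') flows --sens 0.284 --spec 0.886 --out flows.csv`.

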