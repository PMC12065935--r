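# gscore

Tumor growth-rate (g-score) modeling of longitudinal tumor burden, with
cohort-level association of growth rate and survival.

## The problem

Objective response under RECIST summarizes only the best tumor shrinkage.
For serial sum-of-diameters (SOD) measurements collected on treatment, a
two-process kinetic model separates exponential regression of the
treatment-sensitive tumor (rate *d*, per day) from exponential growth or
regrowth of the resistant fraction (rate *g*, per day). With burden
normalized to baseline (f(0) = 1, t in days), each subject is fitted to
four candidate forms:

    dx:    f(t) = exp(-d t)
    gx:    f(t) = exp(g t)
    gd:    f(t) = exp(-d t) + exp(g t) - 1
    gdphi: f(t) = phi exp(-d t) + (1 - phi) exp(g t)

where `phi` is the treatment-sensitive fraction. A parameter stays in a
model when its Wald p-value is < 0.1; among admissible models the smallest
AIC wins; subjects with no admissible model are "not fit". The g-score is
the fitted *g* of the selected model — exactly 0 for regression-only (dx)
subjects — and the tumor doubling time is ln(2)/g. Cohort analyses
compare arms by median g (Mann-Whitney), stratify subjects into pooled g
quartiles (dx held out as a "no growth" stratum), summarize overall and
progression-free survival per stratum (Kaplan-Meier, Cox hazard ratios vs
the fastest quartile), compare Harrell concordance of g against
RECIST-style response, and emulate interim "early look" data cuts.

Because patient-level trial data of this kind are available only on
request, the package ships a trial-like simulator (6-weekly jittered
scans, progression-triggered assessment stop, multiplicative measurement
noise, database lock, ramped accrual, survival whose hazard increases
with the true g), so every stage is testable against known ground truth.

## Worked example

```r
library(gscore)

scenario <- sim_scenario()                 # two-arm trial-like defaults
cohort   <- simulate_cohort(scenario, seed = 1)
results  <- fit_cohort(cohort$measurements)
compare_arms_g(results)$summary
```

```
    arm   n     median_g q1_g        q3_g median_g_display
1 T-DXd 232 4.819961e-05    0 0.001081413      0.004819961
2 T-DM1 212 6.552928e-04    0 0.002290500      0.065529276
```

The experimental arm's median g-score (0.005 x 1e-2/day, i.e.
4.8e-5/day) is an order of magnitude below the control arm's
(0.066 x 1e-2/day); the Mann-Whitney p-value for the shift is 5.6e-05
(`compare_arms_g(results)$p_value`). Classification counts, quartile
survival tables and concordances come from `analyze_cohort()`:

```r
an <- analyze_cohort(results, cohort$subjects)
an$km_os_pooled      # per-stratum n, events, median, 1-year OS
an$cox_os_pooled     # HRs vs Q4, e.g. Q1 0.25 (0.10-0.63) ... Q4 ref
```

In this run the pooled 1-year OS falls monotonically across quartiles
(95.3%, 87.4%, 86.1%, 74.1% for Q1-Q4, with 95.5% in the no-growth dx
stratum), mirroring the inverse association between growth rate and
survival that motivates the g-score.

The same pipeline is packaged as numbered drivers that write CSV tables
under `results/`:

```sh
Rscript analysis/01_simulate.R 1       # cohort with ground truth
Rscript analysis/02_fit.R              # per-subject fits + Table-1-style summaries
Rscript analysis/03_survival_analysis.R
Rscript analysis/04_early_look.R       # interim cuts at k = 40, 60, 80
```

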