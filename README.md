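# survrecon

Reconstruction of individual patient data (IPD) from digitized Kaplan-Meier
curves, and indirect comparison of treatments that were never trialled
head-to-head.

## The problem

Single-arm oncology trials publish a KM overall-survival figure, the number
of enrolled patients N, and the number of deaths D — but no subject-level
data. To compare treatments across such trials (the motivating case:
pembrolizumab, nivolumab, and nivolumab+ipilimumab in dMMR/MSI-H metastatic
colorectal cancer), the published curve must first be inverted back into IPD.
`survrecon` implements that inversion and the downstream statistics:

* **Reconstruction** — given digitized (time, survival) coordinates, N and D,
  produce subject records `(time, event)` that reproduce the curve exactly in
  counts (N records, D events) and near-exactly in shape. In-follow-up
  censoring is assumed uniform in time; its total count is the one free
  integer, solved by bisection against D.
* **Estimation** — product-limit refit with Greenwood standard errors
  (`km_fit`), median OS with an explicit "not reached" convention.
* **Comparison** — Cox hazard ratio with the Efron tie correction
  (`cox_hr`), log-rank test (`log_rank`), and restricted mean survival time
  at a milestone τ (default 15 months):
  RMST = ∫₀^τ Ŝ(t) dt, with Var = Σ_{tᵢ≤τ} (∫_{tᵢ}^τ Ŝ)² dᵢ/(nᵢ(nᵢ−dᵢ)).
* **Extrapolation** — Weibull MLE and mean lifetime survival
  MLS = λ Γ(1 + 1/k) with a seeded parametric-bootstrap CI.
* **Synthesis** — a seed-deterministic generator of ground-truth arms
  (exponential / Weibull / piecewise-exponential hazards, administrative plus
  random censoring) and their exact or noise-perturbed curve coordinates, so
  the whole pipeline is testable by round trip and parameter recovery.
* **Pipeline** — a YAML-config runner (`run_study`) producing a JSON / CSV /
  markdown study report, plus a thin CLI (`inst/cli/survrecon.R`).

## Worked example

Simulate a "published figure" with known truth, invert it, and compare arms:

```r
library(survrecon)

truth <- simulate_ipd(sim_spec("exponential", n = 119, admin_censor = 16,
                               rate = 0.065, seed = 42, label = "combo"))
curve <- ipd_to_curve(truth)          # the digitized-coordinates stand-in
rec   <- reconstruct_ipd(curve, attr(truth, "meta"))
print(km_fit(rec))

ref  <- simulate_ipd(sim_spec("exponential", n = 124, admin_censor = 16,
                              rate = 0.10, seed = 43, label = "reference"))
rref <- reconstruct_ipd(ipd_to_curve(ref), attr(ref, "meta"))
cox_hr(rec, rref)
rmst_diff(rec, rref, 15)
mean_lifetime_survival(weibull_fit(rec), B = 1000, seed = 1)
```

prints

```
KM estimate for 'combo': n = 119, 75 events, median OS = 9.89 months
HR (combo vs reference) = 0.60 (95% CI 0.44 to 0.808, p = 0.000786)
RMST difference (combo - reference) at 15 months = 2.04 (95% CI 0.74 to 3.35, p = 0.00207)
MLS (combo) = 14.7 months (95% CI 11.7 to 18.6, bootstrap)
```

The true hazard ratio here is 0.065/0.10 = 0.65 and the reconstruction-based
estimate (0.60, CI 0.44-0.81) covers it; the RMST difference of 2.04 months
is the area between the two survival curves up to the 15-month milestone; the
MLS extrapolates the combo arm's fitted Weibull to its lifetime mean.

For a file-driven study (several cohorts, pooling, one reference arm), write
a YAML config and run either `run_study(read_study_config("study.yaml"))` or

```sh
Rscript inst/cli/survrecon.R compare --config study.yaml --out results/
```

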