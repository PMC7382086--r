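# rmtlcr — restricted mean time lost for competing risks data

When subjects can fail from more than one cause (relapse vs.
treatment-related death, disease-specific vs. other-cause mortality), the
usual summary of a treatment effect on one cause — the sub-distribution
hazard ratio — is only valid under proportional sub-distribution hazards and
carries no absolute baseline. This package implements inference on the
**restricted mean time lost** (RMTL),

RMTL_j = ∫₀^τ I_j(t) dt,

the area under cause *j*'s cumulative incidence function (CIF) up to a
restriction time τ: the average time lost to that cause within the window,
in plain time units, with no proportionality assumption. It is aimed at
biostatisticians analysing competing-risks trials and registries, and at
trial designers who need sample sizes for RMTL-based comparisons.

## What's inside

* **Estimation** — Aalen–Johansen CIF with pointwise counting-process
  variance (`cif()`, `cif_var_at()`), all-cause Kaplan–Meier
  (`allcause_survival()`), RMTL with exact step-function integration and
  closed-form variance (`rmtl()`), composite-endpoint restricted mean
  survival (`rmstc()`). The decomposition RMTL₁ + RMTL₂ + RMSTc = τ holds
  exactly on every sample.
* **Two-sample tests on the RMTL difference Δ** —
  `rmtl_diff_test()`: fixed-time normal test
  Z = Δ̂ / √(var₁/n₁ + var₂/n₂);
  `rmtl_sdiff_test()`: supremum of the cumulative difference process
  Q_S = sup_r |Δ̂(t_r)| / σ̂(τ), referred to the distribution of
  sup|M(t)| of standard Brownian motion (`sup_bm_tail()`, an exact series
  with a controlled truncation bound). The supremum test keeps power when
  CIFs cross and the fixed-time difference cancels.
* **Sample size** — closed form for the fixed-time test
  (`samplesize_diff()`); for the supremum test, n = ξ·ñ with the inflation
  factor ξ = η²/η̃² obtained by safeguarded Newton–Raphson on the
  drifted-Brownian-motion power equation (`samplesize_sdiff()`,
  `solve_eta()`); ξ depends only on (α, power), ≈ 1.057 at (0.05, 0.8).
  `pilot_design()` extracts the design parameters from pilot data.
* **Simulator** — six piecewise-Weibull competing-risks scenarios (null,
  ordered, non-proportional, early, late, crossing; `cr_scenarios()`),
  exact inverse-transform sampling, calibrated uniform censoring, and
  rejection-rate / observed-power studies (`rejection_study()`,
  `observed_power_at_n()`).
* **Workflow** — CSV I/O (`read_cr_sample()`: columns `time`,
  `status` 0 = censored / 1 = event of interest / 2 = competing event,
  `group`), a one-call analysis report (`analyze()`), and a command-line
  wrapper (`inst/cli/rmtlcr-cli.R`) with subcommands `estimate`, `test`,
  `samplesize`, `simulate`, `analyze`.

## Worked example

```r
library(rmtlcr)
set.seed(2026)
study <- simulate_cr_study(scenario_config("B", 120, 120, censoring = 0.15),
                           labels = c("control", "treated"))
analyze(study)
```

```
Two-group RMTL analysis at tau = 22.0406 (min_last_event_of_interest)
                   index             group estimate ci_lower ci_upper p_value statistic
                    RMTL           control    8.660  7.29500   10.020      NA        NA
                    RMTL           treated   10.640  9.22500   12.060      NA        NA
                   RMSTc           control   10.970  9.75900   12.180      NA        NA
                   RMSTc           treated    8.110  7.08700    9.134      NA        NA
        RMSTc difference treated - control   -2.861 -4.44700   -1.275      NA        NA
  RMTL difference (Diff) treated - control    1.980  0.01448    3.946 0.04834     1.974
 RMTL difference (sDiff) treated - control    1.980  0.01448    3.946 0.06158     2.160
```

Read: within the first 22.0 time units, treated subjects lose on average
10.64 units to the event of interest versus 8.66 in the control arm — the
treated arm loses 1.98 units more (95% CI 0.01 to 3.95), borderline
significant by the fixed-time test (p = 0.048) and not by the more
conservative supremum test (p = 0.062). The RMSTc rows summarise the
composite endpoint the same way, and each arm's RMTL₁ + RMTL₂ + RMSTc equals
τ. Designing a confirmatory trial from this pilot:

```r
pd <- pilot_design(study)
samplesize_sdiff(pd$delta, pd$var1, pd$var2)
```

```
Sample size (supremum difference test): n1 = 256, n2 = 256, total = 512
  delta = 1.98, var1 = 58.19, var2 = 62.55, alpha = 0.05, power = 0.8, r = 1
  xi = 1.0573 (eta = 2.8807, eta~ = 2.8016, V = 2.2414)
```

512 subjects give the supremum test 80% power at two-sided α = 0.05 for this
effect; the fixed-time test would need 512/1.0573 ≈ 486.

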