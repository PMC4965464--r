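# mycometa

Random-effects meta-analysis and meta-regression of arbuscular-mycorrhizal
(AM) effects on leaf gas exchange.

## The problem

Hundreds of paired experiments report gas-exchange means — carbon exchange
rate (CER), stomatal conductance (g_s), transpiration (E) — for AM-inoculated
plants and their non-mycorrhizal (NM) controls, usually without dispersion
measures. `mycometa` turns such a study table into a quantitative synthesis:

- **Effect size**: the log response ratio `lnR = ln(Y_AM / Y_NM)` per study,
  with zero/negative readings handled by a per-study floor at 1% of the
  study maximum.
- **Weighting**: the non-parametric variance
  `V = (n_AM + n_NM) / (n_AM × n_NM)` computed from sample sizes alone;
  studies with m repeated time-points are collapsed to one synthetic score
  with variance `V_y = V (1 + (m − 1) r) / m` (default time-point
  correlation `r = 0.1`).
- **Pooling**: random-effects model with REML between-study variance τ²,
  weights `1/(V + τ²)`, heterogeneity statistics
  `Q`, `I² = (Q − df) × 100 / Q` (truncated at 0), and categorical subgroup
  analysis with a common τ² across levels.
- **Meta-regression**: weighted least squares of lnR on study-level
  moderators (percent root colonization, shoot-DW effect size, leaf-P
  effect size, NM leaf N:P, leaf N:P effect size, publication year) with
  Knapp–Hartung-adjusted t inference, an R² analog on the τ² scale, and a
  raw average slope back-transformation
  `[exp(b·maxX + a) − exp(b·minX + a)] / (maxX − minX)`.
- **Diagnostics**: Cook's D influence screening, Begg–Mazumdar rank
  correlation and funnel data for publication bias, leave-one-out
  sensitivity on the response-ratio scale.
- **Synthetic literature**: a seeded generator emulating the table's
  statistical structure, so every stage is testable by parameter recovery.

## Worked example

```r
library(mycometa)

cfg <- simulation_config(n_studies = 583, mu = 0.399, tau2 = 0.05, seed = 2024)
lit <- generate_literature(cfg)          # synthetic AM/NM study table
es  <- effect_table(lit$studies, r = 0.1)

pool_effects(es)
#> Random-effects summary (k = 583)
#>   lnR = 0.3850  [0.3352, 0.4347],  ratio = 1.47 (+47%),  p = <2e-16
#>   tau^2 = 0.0744, se = 0.0254

subgroup_analysis(es, es$stress)
#> Subgroup analysis: Q_between = 14.24 (df = 1, p = 0.000161)
#>   common tau^2 = 0.0666, residual I^2 = 18.9% (p_hetero = 9.72e-05)
#>        level   k mu_hat      se ci_low ci_high   p_value ratio percent_change
#> 1   stressed 161 0.5370 0.04747 0.4440  0.6301 1.117e-29 1.711          71.09
#> 2 unstressed 422 0.3261 0.02950 0.2683  0.3839 2.058e-28 1.386          38.56

fit <- fit_meta_regression(es, es[, "colonization_pct", drop = FALSE])
average_raw_slope(fit$coef$estimate[1], fit$coef$estimate[2], 0, 100)
#> 0.0014  # raw ratio change per % colonization over the 0-100 range

leave_one_out(es)
#> Leave-one-out over k = 583 studies; full ratio = 1.470
#> Most influential: S0488 (max |ratio change| = 0.0061)
```

The pooled ratio 1.47 (+47%) recovers the generating mean `mu = 0.399`
(ratio 1.49) within sampling error; the stressed subgroup sits near the
configured 72%-vs-39% contrast; the generating colonization slope here is
0, and the fitted slope is correspondingly non-significant (p = 0.34).

A CLI wraps the same steps:

```sh
inst/exec/mycometa simulate --n-studies 200 --seed 7 --out out/
inst/exec/mycometa summarize --input out/synthetic_studies.csv --out out/
inst/exec/mycometa regress   --input out/synthetic_studies.csv --out out/
inst/exec/mycometa diagnose  --input out/synthetic_studies.csv --out out/
```

Real literature tables are ingested from CSV with one row per
(study × outcome × time-point); see `?read_study_table` for the column
contract.

## Documentation

`vignettes/meta-analysis-methods.Rmd` describes the model, the variance
and zero-handling rules, the estimation choices (REML, Knapp–Hartung),
what the synthetic generator does and does not emulate, and known
limitations.
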