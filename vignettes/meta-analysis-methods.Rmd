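---
title: "Methods: random-effects synthesis of AM/NM gas-exchange studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-effects synthesis of AM/NM gas-exchange studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycometa)
```

## The model

Each study contributes a paired comparison of an arbuscular-mycorrhizal
(AM) treatment against a non-mycorrhizal (NM) control for one or more leaf
gas-exchange outcomes (carbon exchange rate, stomatal conductance,
transpiration). The unit of analysis is the log response ratio

$$\mathrm{ln}R_i = \ln(\bar Y_{AM,i} / \bar Y_{NM,i}),$$

a unit-free, symmetric measure of the treatment effect. The random-effects
model assumes

$$\mathrm{ln}R_i = \theta_i + e_i,\qquad
  \theta_i \sim N(\mu, \tau^2),\qquad e_i \sim N(0, V_i),$$

with $V_i$ the within-study sampling variance and $\tau^2$ genuine
between-study variation. A fixed-effect model (one shared true effect) is
implausible across hosts, fungi, and growing conditions, so it is used
only internally, for the $Q$ statistic.

## Within-study variance without dispersion data

Most plant gas-exchange papers report means and sample sizes but no
standard deviations. Rather than discard them, studies are weighted by the
non-parametric variance

$$V = \frac{n_{AM} + n_{NM}}{n_{AM}\, n_{NM}},$$

which depends on sample sizes alone. Sample-size gaps are resolved
conservatively: a reported range resolves to its minimum; a missing sample
size resolves to $n = 2$ when an LSD or standard error was printed
(replication must have existed) and to $n = 1$ otherwise. These floors
keep poorly documented studies in the analysis while capping their weight.

When a study reports the same outcome at $m$ time-points (light-response
curves are treated identically), the per-study effect is the mean of the
per-time-point $\mathrm{ln}R$ values and its variance is

$$V_y = V\,\frac{1 + (m - 1)\,r}{m},$$

where $r$ is the correlation among time-points: $r = 1$ recovers the
single-time-point variance (repeated measures carry no new information),
$r = 0$ gives $V/m$. Published estimates of $r$ for gas exchange on the
same experimental units are near 0; the package default is the
deliberately conservative constant $r = 0.1$, configurable everywhere it
enters. `estimate_timepoint_correlation()` recovers $r$ from raw
repeated-measures data when available.

Two genuinely open choices were resolved as follows. The per-study
multi-time-point effect is the *mean of per-time-point lnR values* (not
the lnR of mean ratios): it preserves antisymmetry under swapping
treatments and is the quantity whose variance $V_y$ actually describes.
And the zero floor is applied to the raw values *before* time-point
averaging, since the floor is defined on the measurement scale.

## Zeros and negatives

Gas-exchange values of 0 are biologically common but undefined in a ratio.
Adding a small fixed constant is unstable across the field's wide range of
units, so the package floors instead: within one study (all values of one
outcome, both treatments, all time-points), negative values are set to 0
and anything below 1% of the study maximum is raised to exactly that
floor. The floor fraction is a parameter (`floor_fraction`, default 0.01).
The adjustment is idempotent and leaves the study maximum untouched.
Studies whose values are all non-positive cannot enter a ratio analysis
and are dropped with a warning.

## Estimation

**REML.** $\tau^2$ is estimated by restricted maximum likelihood via
Fisher scoring with step-halving, truncation at 0 each step, convergence
when successive iterates differ by less than $10^{-10}$, and a cap of 100
iterations (a classed error carrying the last iterate is raised beyond
that). The step-halving demands a *strict* likelihood improvement: a
non-strict test can ping-pong between two equal-likelihood points astride
an interior maximum. The same machinery estimates the residual $\tau^2$ of
meta-regressions (design-matrix REML) and the common subgroup $\tau^2$
(level-dummy design, equivalent to a mixed-effects model with fixed level
effects). The test suite cross-checks the scoring path against a
brute-force restricted-likelihood grid search at step $10^{-5}$.

**Pooling.** Summary effects use weights $1/(V_i + \tau^2)$, a normal
95% CI, and a normal-theory p-value. Knapp–Hartung is reserved for
meta-regression, where it is defined; applying it to the plain pooled mean
is a different (intercept-only) model and is not what the reported
summaries mean.

**Heterogeneity.** $Q$ is the fixed-effect weighted squared deviation
about the fixed-effect mean; $I^2 = (Q - df) \times 100/Q$, truncated at
0, with a $\chi^2_{k-1}$ p-value; homogeneity is conventionally rejected
at $p < 0.1$. Percentages are on the 0–100 scale throughout.

**Subgroups.** A common $\tau^2$ across levels (assumed, not tested) is
estimated once; level means are pooled with it; $Q_{between}$ — the
weighted squared deviation of level means about the grand mean — is
referred to $\chi^2$ with (levels − 1) df. The chi-square reference was
chosen over an F reference because the level means are normal-theory
weighted means with known variances under the model.

**Meta-regression.** Weighted least squares of $\mathrm{ln}R$ on numeric
moderators with weights $1/(V_i + \tau^2_{REML})$. Coefficient variances
are multiplied by the Knapp–Hartung factor (weighted residual sum of
squares over $k - p$, no truncation) and tested against $t_{k-p}$.
The incremental ("test of change") p-value for one moderator given the
other four is the F test of its coefficient in the full fit on the
complete-case subset, $F = t^2$ on $(1, k-p)$ df. Rank-deficient designs
error out naming the collinear columns.

**Derived quantities.** The raw average slope back-transforms an lnR-scale
line to the ratio scale over a moderator range
([`average_raw_slope()`]); the default range policy is the observed data
min/max, and the published colonization and year benchmarks are reproduced
with the explicit bounds [0, 100] and [1980, 2014]. The $R^2$ analog is
$(\tau^2_{total} - \tau^2_{residual})/\tau^2_{total} \times 100$,
truncated to [0, 100] and undefined when the moderator-free $\tau^2$ is 0
(reported as `NA`/"–"): with many small studies the total $\tau^2$ often
hits the 0 boundary, which is why the slope test, not $R^2$, is the
primary inferential summary. Weighted moderator correlations use the
intercept-only random-effects weights of the analyzed outcome, pairwise
complete, with t-approximation p-values.

**Influence and bias.** Cook's D uses the weighted hat matrix and the
Knapp–Hartung residual variance; the flag threshold is the conventional
$4/k$ (the source methodology names Cook's D but no cutoff). The
Begg–Mazumdar statistic correlates variance-stabilized deviates (effects
centered at the fixed-effect mean, divided by
$\sqrt{V_i - 1/\sum V_j^{-1}}$) with the variances, using tie-corrected
Kendall $\tau_b$ and the normal approximation. Leave-one-out re-estimates
$\tau^2$ in every refit (more conservative than freezing it) and reports
influence on the response-ratio scale — consistent with quoting changes
like "1.49 to 1.47" — naming the most influential study.

## The synthetic literature

`generate_literature()` draws, per study: five physiological moderators
(colonization uniform on [5, 95]%; shoot-DW and leaf-P effect-size ratios
log-normal with median 1.3; NM leaf N:P uniform on [5, 30], spanning the
N:P ≈ 16 P-limitation threshold; leaf N:P ratio log-normal with median
0.9), a publication year uniform on 1980–2014, a stress indicator
(fraction 0.3, additive lnR shift ln(1.72/1.39) ≈ 0.213 echoing the
stressed-vs-unstressed CER contrast, centered so the grand mean stays
$\mu$), small sample sizes (3–8 per treatment, equal within
multi-time-point studies), and a time-point count (75% single; the
remainder 2–5). The true effect is normal around the moderator-linked
mean with variance $\tau^2$; observed per-time-point effects add
exchangeably correlated noise (correlation `r_true`, default 0.1) whose
variance equals the non-parametric variance of the *true* sample sizes —
so the analysis weighting is exactly correct for the generated data and
parameter recovery is a fair test of the estimators, not of a
misspecification. NM means are log-normal around `nm_mean_scale` (default
10, a typical CER magnitude in µmol m⁻² s⁻¹). Data-quality features are
injected on top: a zero or small-negative reading per study with
probability `zero_value_rate` (default 0.003, the observed order of
magnitude: 3 adjustments in ~1300 studies) and hidden sample sizes with
probability `missing_n_fraction` (default 0.04, ≈ 42/1019).

What the generator does *not* emulate: correlated studies within articles,
species/fungus composition, heteroscedastic reporting conventions,
digitization error, or any publication-selection process. A green
recovery test therefore establishes estimator correctness under the
assumed model, not robustness to the real literature's full messiness.

**Calibration vs. robustness.** The acceptance-level calibration
experiments (parameter recovery at k = 500; the type-I error sweep of the
Knapp–Hartung slope test) run the generator with `stress_shift = 0`,
`zero_value_rate = 0`, `missing_n_fraction = 0`: those criteria are
statements about effects drawn exactly from $N(\mu, \tau^2)$. The zero
injection deliberately produces floor-adjusted outliers (a real
phenomenon — the most influential published CER study has lnR = 3.2) that
sit outside that parametric world; with it on, $\hat\tau^2$ would
correctly absorb the extra spread and the "bias" would measure the
injection rate, not the estimator. Robustness features are exercised by
their own structural tests instead.

Determinism: one root seed drives vectorized draws; the same config and
seed reproduce the table bit for bit (tested), and changing only the seed
changes the table. Derived per-replicate seeds in
`recovery_experiment()` are `seed + replicate`.

## Numerical and degenerate-input policy

- Non-positive means error (naming the study) rather than silently
  flooring: flooring is an explicit, per-study decision.
- `resolve_sample_size()` always returns ≥ 1; `pool_effects()` accepts a
  single study (with $\tau^2$ supplied or 0).
- $I^2$ lives in [0, 100); $R^2$ analog in [0, 100] or `NA`.
- Cook's D is defined as 0 for numerically exact fits (the 0/0 case).
- Report CSVs round slopes to 4 decimals and percents to 1, for
  side-by-side comparison with published tables; identical config and
  input produce byte-identical reports.

## Known limitations

- Studies derived from the same article are treated as independent, as in
  the source methodology; no hierarchical article-level model.
- No trim-and-fill, Egger regression, fail-safe N, or permutation
  moderator tests; no spline or multi-outcome joint models.
- The Begg–Mazumdar test is known to have low power at small k; the
  package reports $\tau$ and p, and treats "no bias" readings as a
  diagnostic note, not a verdict.
- The common-$\tau^2$ subgroup assumption is imposed, not tested.
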