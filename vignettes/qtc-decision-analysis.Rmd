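---
title: "Expected-utility decision analysis of antipsychotics under QTc prolongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected-utility decision analysis of antipsychotics under QTc prolongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtcda)
```

## The clinical problem and the model

Antipsychotics are the usual treatment for delirium, but most of them
prolong the heart-rate-corrected QT interval (QTc), and a QTc beyond
roughly 500 ms sharply raises the risk of torsade de pointes, a
potentially fatal arrhythmia. Choosing a drug for a patient whose
baseline QTc is already prolonged therefore trades treatment efficacy
against arrhythmia risk. `qtcda` encodes that trade-off as a single-stage
decision tree:

* a **decision node** selects one of the treatment options (six
  antipsychotics or placebo);
* a **chance node** resolves delirium to *improved* with the drug's
  transition probability $p$, or *unimproved* with $1 - p$;
* every leaf is valued by a QTc-dependent utility, evaluated at the
  on-treatment QTc interval — the patient's baseline QTc plus the drug's
  mean QTc shift $\Delta\mathrm{QTc}$.

The expected utility of a drug at baseline $b$ is

$$\mathrm{EU}(b) = p\,U_{\mathrm{imp}}(b + \Delta\mathrm{QTc})
  + (1-p)\,U_{\mathrm{unimp}}(b + \Delta\mathrm{QTc}),$$

and the analysis simply ranks options by $\mathrm{EU}$ across a grid of
baseline QTc values (default 420, 450, 480, 510 ms; values outside
300–700 ms only draw a warning, since they are not physiologic).

### Effect sizes and the odds-ratio transform

Published network meta-analyses report treatment effects on delirium as
odds ratios against placebo. With the day-3 placebo improvement
probability fixed at $p_0 = 0.5$, an odds ratio converts to a transition
probability by

$$p = \frac{A}{1 + A}, \qquad A = \mathrm{OR}\,\frac{p_0}{1 - p_0},$$

implemented in `or_to_probability()` with exact inverse
`probability_to_or()`. The packaged table
(`delirium_effect_table()`) carries, for amisulpride, haloperidol,
olanzapine, quetiapine, risperidone and ziprasidone, the transition
probability with its 95% plausible range and the mean QTc shift in ms
with its 95% CI.

Probability uncertainty is parameterized on the **log odds-ratio
scale**. The plausible ranges are strongly asymmetric on the probability
scale (amisulpride: 0.153–0.989 around 0.804) but symmetric on the
log-OR scale to within 0.02 — exactly what log-symmetric meta-analytic
CIs produce — so a normal distribution on log-OR can honour both bounds
while a normal on $p$ cannot. `effect_table()` validates this symmetry on
ingestion (tolerance 0.1 on the log-OR midpoint offset; the packaged
records are below 0.018) along with the ordering invariants of every
record, naming the offending row and field on failure.

### Utility curves

Utility declines with QTc. Because arrhythmia risk accelerates past
500 ms, the baseline curve is a decreasing sigmoid with its inflection
at `qtc_ref` = 500 ms,

$$U(q) = \mathrm{Min} + \frac{\mathrm{Max} - \mathrm{Min}}
  {1 + \exp\{\mathrm{Slope}\,(q - 500)\}},$$

concave (risk-averse) below the inflection and convex above it. Default
parameters: improved status Max = 100 (fixed), Min = 30; unimproved
status Max = 30, Min = 0 (fixed); Slope = 0.05 per ms. The improved
curve must dominate the unimproved curve pointwise; `utility_pair()`
rejects settings that cross. `utility_table()` reproduces the standard
presentation grid, with half-away-from-zero rounding for the integer
presentation copy.

For sensitivity analysis three variant families with the same
monotonicity but different risk attitudes are available: linear (second
derivative 0) and two exponentials (second derivative > 0 and < 0).
These families need endpoints, so they are anchored on a bounded QTc
domain, by default [380, 620] ms — wide enough to contain every
baseline-plus-shift the analysis visits — taking the value Max at the
left edge and Min at the right, clamped outside. The exponential form is
$u(q) = \mathrm{Min} + (\mathrm{Max}-\mathrm{Min})
\frac{e^{k s(q)} - 1}{e^{k} - 1}$ with $s$ the reversed normalized
position in the domain and the sign of $k$ (default magnitude 3)
selecting the curvature. Between identical anchors a convex decreasing
curve necessarily lies *below* the linear chord and a concave one above
it; the package enforces and tests exactly this orientation, since the
second-derivative sign is the defining constraint of each family.

## Ranking and the near-tie at 420 ms

```{r fit}
fit <- decision_analysis(delirium_effect_table())
summary(fit)
```

One numerical subtlety: at baseline 420 ms, amisulpride and quetiapine
differ by about $10^{-4}$ utility units — far below what three-decimal
input effect sizes can resolve. `rank_treatments()` therefore treats
utility differences below `tol = 0.005` (half of the two-decimal
reporting precision) as ties and breaks them by table order, so
amisulpride, listed first, leads at 420 ms while quetiapine leads
outright at 450 ms and beyond. With `tol = 0` the ranking is by raw
floating-point comparison instead. The per-draw comparisons inside the
probabilistic sensitivity analysis always use raw comparison: with
continuously sampled effects, exact ties have probability zero.

## Probabilistic sensitivity analysis

Effect-size uncertainty is propagated by Monte Carlo (`run_psa()`,
default 10,000 draws, seed 20210625). Per treatment and draw:

* the log odds ratio is drawn from
  $\mathcal{N}(\log\mathrm{OR},\ \sigma)$ with $\sigma$ = half-width of
  the log-OR plausible range divided by 1.959964, then mapped back
  through `or_to_probability()` — sampled probabilities always lie in
  (0, 1);
* the QTc shift is drawn from a natural-scale normal matched the same
  way to its 95% CI;
* draws are independent between the two quantities and across
  treatments (no correlation structure is assumed), and one draw matrix
  is shared across baseline columns, since the baseline only shifts the
  utility argument (`share_draws_across_baselines = FALSE` redraws per
  baseline).

Placebo enters each draw at its deterministic utility. Summaries per
option and baseline: mean and SD of utility, the Monte Carlo standard
error $\mathrm{SD}/\sqrt{n}$, the share of draws in which the option has
the highest utility among all seven (summing to 100% at each baseline),
and the share in which a drug strictly beats placebo.

A `truncated_normal_p` alternative samples the probability itself from a
normal truncated to (0, 1); it is provided for robustness comparison,
but the log-OR scale is the default because it is the only reading
consistent with the asymmetric probability ranges.

`quadrature_oracle()` computes the same mean utility deterministically
by 40-node Gauss–Hermite quadrature over the joint (log-OR, QTc-shift)
normal density. The test suite requires the Monte Carlo mean to sit
within three Monte Carlo standard errors of the quadrature value on
every drug × baseline cell, which both validates the sampler and
quantifies the Jensen gap: because the utility curve is concave left of
500 ms, mean utility under uncertainty is generally below the
point-estimate utility.

## Deterministic utility sweeps

`run_sensitivity_sweep()` re-runs the analysis over a grid of utility
settings: improved-curve Min in {10, 30, 50} × unimproved-curve Max in
{10, 30, 50} (combinations with the unimproved Max above the improved
Min are excluded, preserving dominance) × slope in {0.025, 0.05, 0.1},
crossed with the four curve families. Infeasible patterns are skipped
with a warning. The sweep reports the winning option per setting and
baseline and whether the modal winner matches the default-setting
winner. On the packaged table the prolonged-QTc baselines (≥ 450 ms) are
led by quetiapine in most settings, with amisulpride taking some of
them — the 420 ms near-tie means the modal winner at 420 can differ from
the default-setting tie-break.

## Synthetic data and what it shows

`generate_table()` draws latent per-treatment (mean, sd) pairs uniformly
from configurable ranges — on the log-OR scale for the improvement
effect, on the natural scale for the QTc shift — and emits point
estimates with mean ± 1.959964 sd bounds, transformed to the probability
scale where appropriate. Latent truth therefore lives on exactly the
scales the sampler assumes, so generated intervals are perfectly
log-symmetric and every generated table passes ingestion validation by
construction. Default ranges (log-OR mean in [0.4, 1.5], log-OR sd in
[0.4, 1.6], QTc-shift mean in [0, 15] ms, sd in [0.5, 3.5] ms) mirror
the magnitudes seen in the packaged table.

`recovery_experiment()` plants a designed winner — log-OR mean above
every competitor's range, minimal QTc shift, narrow CIs — and checks
that the deterministic argmax and the PSA majority vote both recover it
at every baseline. The test suite requires 20/20 seeds to succeed.

What passing these tests does *not* show: the generator emulates the
summary-statistic structure of meta-analytic effect tables, not
patient-level trial data. Real effect estimates are correlated through
the evidence network, placebo response varies with setting and day, and
QTc effects measured in schizophrenia trials are transplanted to
delirium patients. Synthetic recovery demonstrates that the pipeline's
inference is internally consistent, not that these epistemic choices are
correct.

## Numerical choices and problem sizes

* 95% multiplier fixed at 1.959964 throughout.
* Single RNG stream seeded once per PSA run (default seed 20210625);
  identical configuration and seed give bitwise-identical results and
  byte-identical report files.
* Rounding: machine CSVs are unrounded; presentation copies round
  utilities half away from zero to integers (utility lookup table) or
  two decimals (PSA means/SDs), shares to integer percentages.
* Ranking tie tolerance 0.005 utility units, ties by table order (see
  above); PSA per-draw argmax ties also fall to the first option in
  table order.
* Degenerate intervals are legal everywhere and collapse the PSA onto
  the deterministic analysis exactly; the test suite asserts this limit.
* Test problem sizes: 10,000-draw PSA runs for the summary-table and
  quadrature checks, one 100,000-draw sampling check for the
  plausible-range endpoints, 20-seed recovery runs at 1,000 draws. The
  full suite runs in a few seconds.

## Limitations

The model is a single-stage tree: no time structure, no costs, no
dosing, and the placebo response is fixed at 0.5 rather than sampled.
Utilities are stylized constructs on a 0–100 scale, not elicited
QALY weights; conclusions are only as strong as the sigmoid's
parameterization, which is why the sweep and the variant families are
part of the package's surface rather than an afterthought.
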