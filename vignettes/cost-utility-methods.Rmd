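---
title: "Methods: trial-based cost-utility analysis of a pulmonary-rehabilitation DTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis of a pulmonary-rehabilitation DTx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtxcua)
```

`dtxcua` implements the economic-evaluation chain for an 8-week, two-arm,
three-center randomized trial of a digital therapeutic (DTx) for pulmonary
rehabilitation in chronic respiratory disease (COPD, interstitial lung
disease, and others), compared with standard advice-based care. This
vignette is the package's own account of the model, the choices that were
genuinely open, and what the shipped synthetic data can and cannot show.

## From questionnaire to utility

The trial collected the 8-item COPD Assessment Test (CAT, items scored
0–5) at weeks 0, 4 and 8, but no generic preference-based instrument.
Utilities are therefore *mapped*: the default algorithm,
`cat_eq5d_model3()`, is a published ordinary-least-squares model estimated
in a comparable Korean hospital population,

$$ U = 1.0661 - 0.0103\,Q_3 - 0.0120\,Q_4 - 0.0168\,Q_5 - 0.0255\,Q_6 - 0.0125\,Q_8 , $$

with items Q1, Q2 and Q7 unused. Over the valid item range the prediction
lies in $[0.6806,\,1.0661]$.

Two consequences drive design choices elsewhere:

* **Predictions can exceed 1.** The intercept is 1.0661, and the
  trial-level QALY magnitudes are only consistent with *uncapped*
  predictions, so `cap_at_one = FALSE` is the default (the cap is provided
  as an explicit switch).
* **Partial CAT blocks are rejected.** If any of the eight items is
  missing, the visit is unmappable; imputation happens downstream at the
  utility level (last observation carried forward, `locf_impute_utilities()`),
  never at the item level.

Alternative published mappings can be supplied as small YAML files
(`read_mapping_algorithm()`); the package bundles no third-party
coefficients and treats algorithm choice as a deterministic
sensitivity-analysis dimension.

## QALYs, costs, imputation

QALYs accrue by the trapezoid rule over the visit grid
(`qaly_trapezoid()`): each consecutive visit pair contributes the mean of
its two utilities times the interval length in years. The annualization
denominator defaults to 365.25 days and is configurable: the trial's
printed 4-week interval QALYs slightly exceed what any utility
$\le 1.0661$ can produce under a 365.25-day year, so the original
denominator is not recoverable. The package does not force agreement;
every decision-relevant quantity it reports (ICUR, value-based price,
CEAC) is a ratio or threshold comparison in which the denominator cancels.

Costs enter as a per-patient ledger with categories MEDICAL,
PHARMACEUTICAL, DTX_FEE, CAREGIVING and TRANSPORT (`total_cost()`).
The base-case *healthcare-system* perspective counts the first three; the
*limited societal* scenario adds caregiving and transport while excluding
productivity losses. The DTx usage fee (93.17 USD for 8 weeks) is kept as
its own ledger line — it is counted inside the DTx arm's medical costs for
totals, but the pricing module must be able to remove it exactly. Korean
won convert at a configurable 1288 KRW/USD.

Missing cost amounts are imputed with the mean of observed amounts for the
same category at the same center, falling back to the pooled mean of the
other centers when a whole center lacks the category
(`impute_costs_center_mean()`). The cost-outlier scenario excludes
patients outside $(\mathrm{Q1} - 1.5\,\mathrm{IQR},\ \mathrm{Q3} +
1.5\,\mathrm{IQR})$ per category, computed over both arms pooled;
quartiles use the linear-interpolation convention (`stats::quantile`
type 7), which the source analysis did not specify, and both are
configurable.

## Incremental analysis, pricing, uncertainty

`incremental_analysis()` reports $\Delta C$, $\Delta Q$, the incremental
cost-utility ratio $\mathrm{ICUR} = \Delta C / \Delta Q$, the
cost-effectiveness-plane quadrant, and net monetary benefit
$\mathrm{NMB} = \lambda \Delta Q - \Delta C$ at a willingness-to-pay
threshold $\lambda$ (default 19,410 USD/QALY, the Korean reference
value). Sample SDs use the $n-1$ denominator. Boundary cases (a zero
delta) are classified treating zero as positive and flagged rather than
given their own sentinel; dominance (cheaper–better / costlier–worse) is
reported as a status alongside the raw ratio.

The value-based price of the DTx fee is the closed form
$\mathrm{VBP} = \lambda (Q_A - Q_B) + C_B - \mathrm{Othercosts}_A$
(`solve_vbp()`), i.e. the fee at which the ICUR equals $\lambda$;
`price_sweep()` is the equivalent brute-force curve, affine in the fee
with slope $1/\Delta Q$. Display rounding is *downward* to the whole
dollar, since any higher integer price exceeds the threshold.

The probabilistic sensitivity analysis (`run_psa()`) draws, per
iteration, each arm's mean cost from a gamma distribution (shape
$(m/s)^2$, scale $s^2/m$) and each arm's mean QALY from a normal. The
dispersion fed to each family is explicit and configurable because the
distribution *level* is a genuine modelling choice: the package default
uses the standard error of the mean for costs and the full sample SD for
utilities. That asymmetric default is the only combination under which
the PSA's plane geometry matches the base-case analysis this package
reproduces; both switches are echoed into every result object so a report
can never be ambiguous about which was used. Arms are sampled
independently — no cost–utility or between-arm correlation is imposed,
because none is estimable from arm-level summaries. The ICUR's 95% CI is
the 2.5th/97.5th percentile of per-iteration ratios; when $\Delta Q$
changes sign across iterations the interval is flagged, since ratios are
then not monotone in net benefit and the CEAC (`ceac()`) is the honest
summary. The one-way DSA (`one_way_dsa()`) varies the four arm-level
means over $\pm 1.96\,s/\sqrt{n}$ by default and accepts
alternative-mapping scenarios as an extra tornado bar.

## One-year Markov extrapolation

`markov_from_trial()` builds a five-state cohort model — NORMAL, MILD,
MODERATE, SEVERE on the mMRC dyspnea scale, plus absorbing DEATH — with a
4-week cycle. Choices the source analysis left open, fixed here as
defaults and all configurable:

* mMRC cut points 0/1/2/3–4 for the four living states (mMRC has five
  grades and the model needs four living states);
* 13 cycles × 28 days ≈ 364 days as "one year" (integral cycles);
* no half-cycle correction by default (a switch exists);
* transition matrices are arm-specific, time-homogeneous, and estimated by
  pooling all observed 4-week pairs (weeks 0→4 and 4→8); origin states
  never observed keep a stay-probability of 1 and are flagged;
* state costs are the mean observed per-4-week healthcare cost (patient
  total divided by the two trial intervals) among interval-opening visits
  in the state, state utilities the mean mapped utility in the state,
  both per arm, with unobserved states falling back to the arm mean;
* DEATH is reachable only if supplied explicitly — no deaths occurred in
  the trial and no external life table is imported.

Time-homogeneous transitions estimated from an 8-week window assume the
treatment effect persists for the whole year; the extrapolation should be
read as a scenario, not a forecast, and the package asserts only its
structural properties (occupancy conservation, absorbing death,
path-enumeration equivalence) plus the qualitative finding that the
1-year ICUR stays below the threshold under the default synthetic
conditions.

## What the synthetic generator emulates

`generate_trial()` exists so every downstream stage is testable without
the original patient-level data. Its defaults *are* the study conditions:
arms of 43/41 across 3 centers, total costs 390.40 (SD 193.09) and 305.06
(SD 220.18) USD, 8-week QALYs 0.1568 (SD 0.016) and 0.1473 (SD 0.013),
per-protocol completers 36/33, diagnosis mix ≈58% COPD / 30% ILD / 12%
other, baseline mMRC mean ≈1.3, and the 93.17 USD fee booked in the DTx
arm.

Mechanics, and the realism they buy:

* **Costs** are gamma draws moment-matched per arm (right-skewed,
  strictly positive, matching the family the PSA assumes), split into
  pharmaceutical/medical by a beta-noised share (mean 0.66,
  concentration 30).
* **Utilities** use a flat per-patient trajectory: a patient-level mean
  utility drawn from a *scaled beta* on the attainable mapping range,
  moment-matched to the arm target after subtracting the visit-level
  noise (SD 0.005). A beta is used rather than a truncated normal because
  the DTx arm's target mean sits close to the mapping ceiling; the beta
  honours the hard bounds while matching both moments, at the price of a
  ceiling-heavy marginal shape — a pattern real EQ-5D data share.
  Visit utilities are then converted to CAT items by greedy integer
  allocation over the five mapped items (largest coefficient first, with
  a final rounding bump on the smallest), leaving a quantization error
  below half the smallest coefficient; unmapped items are drawn
  independently.
* **mMRC trajectories** evolve under arm-specific tridiagonal 4-week
  transition matrices (DTx default: improve 0.25 / worsen 0.05; control:
  0.10 / 0.10), giving the Markov module estimable transitions.
* **Dropout** is missing-completely-at-random within arm down to the
  per-protocol counts — the source trial does not characterize its
  dropout mechanism — and blanks the week-8 CAT block; a small fraction
  of pharmaceutical amounts (5%) goes missing to exercise center-mean
  imputation.

What it deliberately does not emulate: within-patient correlation between
cost and utility beyond arm membership, the clinical endpoints (6-minute
walk distance, SGRQ, HADS), informative dropout, and the trial's interval
QALY pattern (the generator targets the 0–8-week totals only). Passing
tests on this generator therefore demonstrate correctness of the analysis
chain under the stated moment structure, not robustness to the
correlation patterns of real trial data.

At 2,000 patients per arm the empirical cost means recover their targets
within 2% and the QALY means within 0.002; the suite asserts this, and
the small problem sizes used throughout (84–4,000 patients, PSA at
1,000–200,000 iterations) keep the whole suite in the seconds range.

## Reproducibility and numerics

Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state (`generate_trial()` via its config,
`inject_missingness()` on a stream derived from the same seed offset by
one, `run_psa()` via `psa_config()`). Identical config and seed give
byte-identical outputs. Degenerate inputs follow explicit rules: zero
dispersion collapses PSA draws onto the point estimate; a zero QALY
difference yields an `UNDEFINED` ratio and NMB-based cost-effectiveness
flags; empty transition rows keep their state; all-equal cost vectors
give a collapsed IQR band that excludes nothing.
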