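---
title: "Methods: cost-effectiveness of post-RFA surveillance intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of post-RFA surveillance intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfacea)
```

## The decision problem

After radiofrequency ablation of early hepatocellular carcinoma, roughly
half of patients recur within a few years. Surveillance every 2–3 months
detects recurrence earlier than every 3–4 months — reflected in a higher
pooled 2-year recurrence-free survival (RFS) — but costs more per month
of follow-up. The package models this trade-off as a two-state Markov
cohort problem and asks whether the extra quality-adjusted life is worth
the extra cost at a willingness-to-pay (WTP) threshold of $10,888/QALY.

## Evidence synthesis

Per surveillance group, study-level 2-year RFS proportions are pooled by
inverse-variance weighting. The default is DerSimonian–Laird (DL)
random effects applied uniformly: when the between-study variance
$\tau^2$ estimates to zero the random-effects fit collapses exactly to
the fixed-effect fit, so nothing is lost by not switching estimators on
a heterogeneity test.

Two scales are offered. The default pools raw proportions with binomial
variance $p(1-p)/n$; `scale = "logit"` pools log-odds with variance
$1/(np(1-p))$ and back-transforms. The pooled group estimates here
(0.752 and 0.543) sit mid-range, where the two scales agree to well
under 0.01 (a tested invariant), so the simpler raw scale is the
default. Proportions of exactly 0 or 1 cannot be pooled on the logit
scale; they receive a $(x+0.5)/(n+1)$ continuity correction with a
warning. Confidence intervals use the normal multiplier 1.96 throughout;
no small-sample (Knapp–Hartung) correction is applied.

## From survival to transition probabilities

Under a constant hazard (the declining-exponential approximation), a
cumulative survival $S$ at $T$ months implies a monthly rate
$r = -\ln S/T$ and a monthly transition probability $p = 1-e^{-r}$:

```{r deale}
rate <- rate_from_survival(0.752, 24)
prob_from_rate(rate, 1)                      # 0.0118 -> "1.18%"
prob_from_rate(rate_from_survival(0.543, 24), 1)  # "2.51%"
```

By default the downstream model consumes these probabilities rounded to
4 decimals (1.18% and 2.51%) — the precision at which such models are
normally parameterised from a published input table — with
`use_printed_probabilities = FALSE` propagating full precision instead.
The three conversions round-trip to machine precision, and the
memorylessness identity
$p(a+b) = 1-(1-p(a))(1-p(b))$ is enforced by tests.

## The cohort model and its conventions

States are progression-free survival (PFS) and an absorbing
progression-or-death (PD) state; occupancy follows
$S_{PFS}(t) = (1-p)^t$ over 24 monthly cycles. Costs accrue only in PFS
(follow-up stops at progression or death), so discounted cost and QALYs
are both proportional to one number, the **discounted PFS-months** $M$:
cost $= cM$, QALYs $= uM/12$ with the utility $u$ an annual weight.
PD-or-death carries zero reward by default because the state pools
progression with death; an optional `pd_alive = TRUE` variant accrues
the PD utility (0.68) so that parameter can participate in sensitivity
analysis.

Cohort models differ in two conventions that matter over a 24-cycle
horizon: when within a cycle rewards are credited, and how an annual
discount rate is discretised. Both are explicit in `markov_spec()`:

* `reward_timing`: `end_of_cycle` ($\sum_{t=1}^{N} S(t)D(t)$),
  `start_of_cycle` ($\sum_{t=0}^{N-1} S(t)D(t)$), or `half_cycle`
  (their average, the usual half-cycle correction);
* `discount_timing`: `continuous_monthly`, $D(t) = 1.05^{-t/12}$, or
  `annual_step`, $D(t) = 1.05^{-\lfloor t/12\rfloor}$.

The package default is end-of-cycle with continuous monthly
discounting. Under it the base case gives

```{r conventions}
result <- run_full_analysis(default_config(), studies = NULL)
result$convention_diagnostics[, 1:6]
```

**Calibration note.** The published summary this analysis is benchmarked
against implies $M$ = 18.885 and 16.247 discounted PFS-months (its
printed costs divided by the monthly costs: 2212.66/117.16 and
1268.92/78.10). None of the six convention combinations reproduces
those figures; the closest, end-of-cycle, gives 19.785 and 16.949 —
4.3–4.8% higher, with start-of-cycle and half-cycle higher still. The
originating model was built in a commercial GUI whose exact accumulation
convention is not recoverable, so the package treats its own
conventions as first-class configuration, reports the implied-months
diagnostic (`cost / monthly cost`) for every convention, and documents
the residual gap rather than hiding it. Base-case comparisons against
the published table are therefore made at 5% relative tolerance.

The engine is verified against an independent geometric-series oracle:
under end-of-cycle timing $M = r(1-r^N)/(1-r)$ with
$r = (1-p)\,d$ and $d$ the per-cycle discount factor
(`closed_form_pfs_months()`), agreeing with the trace accumulation to
$10^{-9}$ over randomised $(p, d)$ pairs. Mass conservation and the
convention ordering start $\ge$ half $\ge$ end are tested invariants.

## Decision metrics

Incremental cost $\Delta C$ and effect $\Delta E$ are comparator minus
reference; the ICER $\Delta C/\Delta E$ is reported when defined, with
sign-based dominance classification otherwise. Net monetary benefit is
$\lambda E - C$; `decide()` prefers the higher NMB, which for
$\Delta E > 0$ is equivalent to ICER $< \lambda$ (a tested identity).
Exact NMB ties resolve to the cheaper strategy — a conservative-spending
convention — and to the reference when costs also tie.

## Deterministic sensitivity analysis

Parameter ranges follow the input table: 50%–200% of base for
transition probabilities and monthly costs, tabulated ranges for the
utilities (0.61–0.91 for PFS, 0.54–0.82 for PD), 0–5% for the discount
rate. The tornado's default target is the comparator strategy's
**absolute** NMB: under that target the PFS utility is the widest bar,
matching the benchmark ranking, whereas an incremental-NMB tornado
(kept as an option) is led by the transition probabilities instead —
the utility multiplies both strategies and largely cancels in the
difference.

Cost parameters act exactly linearly on NMB (cost $= cM$ with $M$
fixed), a tested identity that justifies evaluating tornado bars at the
range endpoints only. `threshold_analysis()` locates preference flips
by a fine grid scan followed by bisection to $10^{-6}$ of the range;
applied to the WTP itself the crossing equals the base-case ICER, and
applied to the comparator's transition probability the flip (computable
via `threshold_analysis(params, "p_comparator", strategies)`) lies
near 0.019 under the calibrated convention — below the 0.024 the
benchmark reports, another consequence of the unrecoverable upstream
convention. Two-way grids record the NMB-preferred label cell by cell;
under our calibration the preferred strategy is *not* constant over the
full PFS-utility × comparator-probability grid (it flips where low
utility meets high recurrence), so the benchmark's "always dominant"
reading should be interpreted under its own convention.

## Probabilistic sensitivity analysis

Utilities and probabilities are drawn from beta, costs from gamma
distributions, fitted by moment matching. The input table prints ranges
without saying what they are; the default reads them as 95% plausible
intervals, `sd = (high-low)/3.92` (`range_semantics = "ci95"`), with
`"minmax"` (`sd = (high-low)/sqrt(12)`) as the wider alternative.
Parameters are sampled independently (no correlation structure is
given); each parameter owns an RNG substream seeded `seed + row index`,
so appending a parameter never perturbs earlier draws, and zero-width
ranges degrade to point masses. The per-draw decision reuses the same
NMB comparison as `decide()`, making the acceptability curve consistent
with the deterministic decision rule by construction.

With these distributions the 10,000-draw acceptability curve at the
$10,888 threshold gives the intensive schedule a preference probability
of about 0.72 (seed 42) — far from the benchmark's reported 100%. The
reported certainty cannot arise from 50%–200% ranges read as 95%
intervals (min-max semantics are wider still); the benchmark's
distribution parameters were evidently much tighter than its printed
ranges. The package reports what its stated inputs imply.

## The synthetic evidence generator

`generate_study_set()` draws study-level true proportions logit-normally
around the group truth ($\tau^2$ on the logit scale keeps proportions in
(0,1)) and observed proportions binomially — exactly the two-level
structure the pooling estimator assumes. `emulate_paper_cohort()`
instantiates the benchmark's evidence base: 6 studies / 504 patients at
true RFS 0.752 and 9 studies / 1436 patients at 0.543, with the
published per-study sizes and designs. The benchmark prints only group
$I^2$ (59.3% and 70.2%), not $\tau^2$; the generator defaults
$\tau^2_{logit}$ = 0.05 and 0.08, chosen once so that the implied
heterogeneity at those sample sizes falls in the printed range. The
generator emulates only 24-month binary status: no event times,
censoring, curve digitisation error, or design-related bias, so recovery
tests validate the estimator under its own assumptions, not the quality
of real digitised evidence. DL coverage of the truth with $k=6$ studies
runs slightly below nominal (the known small-$k$ behaviour of DL
intervals, measured at ~0.90 over 500 seeded replicates in the
acceptance suite).

## Problem sizes and numerical choices

The shipped tests run the PSA at 10,000 draws (the benchmark's own
repetition count), the recovery study at 500 replicates of 6 studies,
and property checks at 100–1000 randomised cases — sizes chosen so the
full suite completes in well under a minute while keeping Monte Carlo
error small relative to the tolerances tested. Monetary outputs are
printed to cents and effects to 3 decimals, with full precision kept in
the returned objects; the summary table's incremental columns are
differences of its printed per-strategy columns, so it is internally
consistent at its own precision.

## Known limitations

* Exactly two strategies; no efficiency frontiers or extended dominance.
* No time-varying hazards: DEALE's constant-hazard assumption is
  maintained throughout the 24-month horizon.
* No correlated PSA sampling and no value-of-information analysis.
* The absolute benchmark figures (QALYs 1.196/1.029, costs
  $2212.66/$1268.92) are reproducible only to ~5% because the upstream
  accumulation convention is not recoverable; all downstream qualitative
  conclusions (decision at threshold, tornado ranking, threshold
  locations) are reported under the package's documented conventions.
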