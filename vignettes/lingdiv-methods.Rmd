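---
title: "Methods: models, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingdiv)
```

## The model

All estimators in this package rest on one generative idea: a clade grows by
a branching process in which each lineage independently speciates at rate
$b$ and goes extinct at rate $d$, so the expected number of lineages follows
$N(t) = N_0 e^{rt}$ with net rate $r = b - d$.  Only $r$ is ever estimated
from data here — $b$ and $d$ are not separately identifiable from extant
counts and ages, and the package does not pretend otherwise (the simulator
is the only place where they exist separately).

From an extant count $N_{\max}$ and a time depth $T$ (years), with
$N_0 = 1$:

$$r_E = \frac{\ln N_{\max}}{T}, \qquad t_2 = \frac{\ln 2}{r_E}.$$

Within a tree, interval rates over a window $\Delta t$ are
$r_i = \Delta \ln N / \Delta t$, where $N(t)$ is the
lineages-through-time (LTT) step function: the number of branches of the
phylogeny crossing time $t$.

## Time and counting conventions

* **Axis.**  Years before present (BP): present $= 0$, ages increase into
  the past, and a tree's `root_age` is its maximum root-to-tip path length.
  Because the root age is computed from the tree itself, the deepest tip
  always sits at age 0 — there is no way to feed the package a tree with no
  "extant" tip, and `prune_to_extant()` (relative tolerance `tol = 1e-6`,
  since published consensus trees are near- but rarely exactly ultrametric)
  can at most collapse a tree to that single deepest tip.
* **LTT steps.**  The series is right-continuous toward the present: the
  count *at* an event time is the post-event count, simultaneous splits
  merge into one step, and the series starts at the crown root with the
  root's degree (2, or $k$ for a root polytomy).
* **Summation.**  `sum_ltt()` aligns series on the absolute BP axis and
  adds counts pointwise.  A family contributes **0** lineages before its own
  crown age — consensus trees carry no stem information, so imputing a stem
  lineage of 1 would be an invention.  If the alternative is wanted it is
  one `ltt_series()` call away, but it is deliberately not a flag.
* **Millennial bins.**  `millennial_series()` returns the *time-weighted*
  mean of the step function per 1,000-year bin (exact segment integration,
  not sampling); bins lying wholly before the oldest event are omitted.

## Normalized-time binning

To compare families whose ages span 1,000–8,700 years and whose sizes span
5–1,268, time is rescaled to $t' = t/T \in [0, 1]$ and counts to
$N' = N/N_{\max}$.  `binned_rates()` then splits $t'$ into `n_bins = 10`
equal bins and computes, for the bin spanning $[t'_{hi}, t'_{lo})$:

$$r_b = \frac{\ln N(t'_{lo}) - \ln N(t'_{hi})}{\Delta t' \cdot T}
\quad (\mathrm{yr}^{-1}),$$

with $N(\cdot)$ evaluated as the step value *in force at* the bin edge.
That edge convention is what makes the telescoping identity
$\sum_b r_b \, \Delta t' \, T = \ln(N_{end}/N_{start})$ hold to machine
precision for every input — the test suite enforces it on a thousand fuzzed
trees.  Rates are always reported in yr⁻¹ (converted through $T$), so bins
are comparable across families.

## Density-dependence classification

`classify_density()` regresses the ten $r_b$ values on $\ln N$ at each
bin's **older** edge — the predictor never uses information from inside the
interval whose rate is the response — and classifies by the two-sided
$t$-test on the slope at $\alpha = 0.05$ (the field default; configurable):
significantly negative $\Rightarrow$ negative density dependence,
significantly positive $\Rightarrow$ positive, otherwise constant-rate.
By construction the class is `constant_rate` exactly when $p \ge \alpha$.

The across-family trend (`across_family_trend()`) regresses $\ln r_E$ on
root age: an exponential time trend is linear on that scale, and the
log-response choice is exposed as an option (`raw_rate`) because with only
18 points the data cannot strongly adjudicate the transform.  Reported
derived quantities are percent change per millennium,
$(e^{|slope| \cdot 1000} - 1) \times 100$, and the doubling/halving time of
the rate itself, $\ln 2 / |slope|$.

The diversity profile (`rate_vs_diversity()`) fits rate on $\ln N$ and
$(\ln N)^2$: the *predictor* is logged to tame the right skew of clade
sizes, the *response* is not, because interval rates can legitimately be 0
(log-undefined).  The fitted peak $N^* = \exp(-\beta_1 / 2\beta_2)$ is
reported only when $\beta_2 < 0$.

## Printed-table replication conventions

The bundled 18-family table reproduces a published summary whose rounding
is internally inconsistent, so the conventions are explicit:

* Rates are reported unrounded and at 5 decimal places.  Matching the
  printed values requires accepting **either** round-half **or** truncation
  at 5 dp: two rows (one per catalog) were evidently truncated.
* Doubling times default to `convention = "rounded"`:
  $\mathrm{round}(\ln 2 / \mathrm{round}(r_E, 5))$, which matches the
  printed Ethnologue column for 16 of 18 rows; one row (Pama-Nyungan)
  matches only the `"raw"` (unrounded-rate) convention, also provided.  The
  printed Glottolog doubling times follow neither — empirically they equal
  $\lfloor \ln 2 / r_E \rfloor$ with the unrounded rate — and are therefore
  not used as a correctness anchor.
* The Dravidian row is inconsistent upstream (its printed rate cannot be
  derived from its printed count and root age; the printed value implies a
  root age near 13,000 years rather than the printed 4,500).  The table
  ships verbatim with a `consistent` flag, and replication tests exclude
  that row.
* The bootstrap CI of the mean rate (`mean_rate()`) is a seeded
  nonparametric percentile bootstrap, resampling families with replacement,
  default 10,000 replicates.  "Percentile" is the minimal-assumption
  reading of an otherwise unspecified procedure.

## The simulator: a stated world

`simulate_tree()` is an exact event-driven (Gillespie) simulation from one
founding lineage: waiting times are exponential with total rate
$N(\lambda + \mu)$, refreshed after every event.  Time-varying speciation
$\lambda(t) = \lambda_0 e^{\beta t}$ is sampled exactly by thinning against
a local dominating rate (window $1/\beta$ for increasing rates, so the
dominating rate never exceeds $e \cdot \lambda(t)$); logistic niche filling
uses $\lambda(N) = \lambda_0 \max(0, 1 - N/K)$, refreshed per event, which
needs no thinning.  Correctness was preferred over speed throughout; at
desk scale (hundreds of tips) a simulation takes milliseconds.

Design choices that matter:

* **Seeding.**  Every simulation runs on its own RNG stream
  (`set.seed` scoped locally); identical parameters and seed give
  bit-identical event logs, and the caller's RNG state is untouched.
* **Conditioning.**  By default runs are rejected until $\ge 2$ lineages
  survive (cap 10,000 attempts, then an error reporting the implied
  survival probability).  Unconditioned mode exists for expectation checks
  against $E[N(t)] = e^{(\lambda-\mu)t}$.
* **Crown vs stem.**  The returned tree is the crown tree of survivors and
  its `root_age` is the crown age; the full elapsed span is reported as
  `stem_age`.  In `simulate_family_table()` the *record's* `root_age_yr` is
  the drawn simulation span (the stem age) — that is the quantity drawn
  "uniformly from the range", and using it keeps $\ln N / T$ recovery
  nearly unbiased — while the observable crown age is carried alongside as
  `crown_age_yr`.
* **Defaults.**  $\lambda_0 = 0.001$ yr⁻¹ (the headline empirical rate),
  $\mu_0 = 0$ (estimators only see net rates, so pure birth is the
  analysable null), root ages uniform on 1,000–8,700 years (the documented
  span of family ages), 18 families per synthetic table.  These defaults
  are the conditions the analysis is meant to face, not tuning knobs.

What the simulator does **not** emulate: near-ultrametric dating noise,
polytomies from consensus summarization, dialect tips, incomplete sampling
of languages within families, and correlated root-age errors across
families sharing a dating method.  A green end-to-end test therefore
establishes internal consistency of the pipeline under the stated
generative world, not robustness to those real-data pathologies.

## Known limitations

* **Power of the binned-OLS density test is low.**  Measured on logistic
  simulations stopped at half the carrying capacity ($K = 2 \times$ final
  $N$, final $N = 100$ chosen as a representative mid-size family), the
  ten-bin classifier detects negative density dependence in only ~20% of
  runs, and a sweep over final sizes 50–1,000 leaves power in the 0.20–0.25
  band; even near-complete saturation ($K = 1.1 \times$ final $N$) reaches
  only ~0.6.  The cause is structural: early bins contain 2–5 lineages, so
  their interval rates are 0 or enormous, and unweighted OLS lets that
  variance swamp the mild decline.  The corresponding acceptance criterion
  expects $\ge 0.70$ and is deliberately left failing rather than weakened;
  the size property (constant-rate verdicts on Yule trees in $\ge 80\%$ of
  runs, measured ~0.85–0.90) does hold.  Users who need a powerful
  within-family test should fit an explicit birth–death model rather than
  rely on this descriptive classifier.
* **$r_E$ is a crown/stem hybrid.**  $\ln N / T$ assumes $N_0 = 1$ (a stem
  convention) but is applied to crown ages on real trees; on pure-birth
  simulations with $\lambda T \ge 3$ the estimator's mean lands within 25%
  of $\lambda$, with the residual bias coming from survival conditioning
  and that convention mismatch.
* **Pull of the present** is not corrected: extant-only trees
  systematically inflate recent apparent rates, which is one reason the
  across-family trend (younger families look faster) must not be read
  causally.
* Regression diagnostics assume independent observations; binned rates
  within a tree are serially dependent, so reported $p$-values are
  descriptive, not exact.
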