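---
title: "Estimating driver gene-set size from overlap decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating driver gene-set size from overlap decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soflr)
```

## The model

When the same parental cell line is independently transformed several times
by one toxin, the activated-gene sets of the resulting isolates overlap far
more than random sets would, but not completely. The package models each
probe as belonging to one of three classes:

* **drivers** — a set of fixed size $d$, activated in *every* transformed
  isolate (the transcriptional footprint of the pathways a driver lesion
  must hit);
* **passengers** — a set of size $T$ whose members are each activated in a
  given isolate independently with probability $p$;
* **non-responsive** — never activated.

The size of the intersection of the active sets of $x$ isolates then has
expectation

$$\mathbb{E}[y_x] = d + T p^x ,$$

because a passenger survives an $x$-way intersection with probability
$p^x$. As $x$ grows the passenger term vanishes and the common set collapses
onto the drivers. The estimation problem is: given the mean overlap curve
$y_1, \dots, y_n$ from a *small* number of isolates, recover $d$ (and,
secondarily, $T$ and $p$).

## The data: exact mean overlap curves

`call_activation()` turns an expression table into binary calls — a probe is
induced in an isolate when its intensity is at least two-fold its mean
intensity in the control arrays, repressed when at most half (the boundary
is inclusive; the two directions are always analysed separately).
`mean_overlap_curve()` then computes, for every $k$, the mean $k$-way
intersection size over all $\binom{n}{k}$ isolate subsets. The mean is exact:
if probe $g$ is active in $m_g$ isolates it lies in the intersection of a
random $k$-subset with probability $\binom{m_g}{k}/\binom{n}{k}$, so

$$y_k = \sum_g \binom{m_g}{k} \Big/ \binom{n}{k}.$$

No subsets are enumerated or sampled; the test suite checks the identity
against brute-force enumeration for up to eight isolates. Two consequences
used as invariants: $y_1$ is the mean per-isolate count and $y_n$ is the
full-intersection count.

The $y_k$ are generally non-integer and are fitted as-is; no rounding is
applied before the log transform. This matters: published overlap curves are
typically printed as rounded integers, and the grid-search objective below
can be flat enough near its optimum that rounding the inputs moves the
selected $d$ by one or two units (see *Numerical behaviour*).

## SOFLR: the grid search

For a candidate $d$, subtracting it and taking logs linearises the model:

$$\log(y_k - d) = \alpha + \beta k + \varepsilon, \qquad
  T = e^{\alpha},\; p = e^{\beta},$$

with $\varepsilon$ i.i.d.\ normal. `soflr_fit()` performs ordinary least
squares for every integer $d$ from `d_min` (default 0) to `d_max`, and
selects the $d$ maximising the **adjusted** $R^2$,
$1 - (1 - R^2)(n-1)/(n-2)$. Monotone transforms of $R^2$ share the argmax,
but adjusted $R^2$ is what the profile reports. Choices worth stating:

* **Log base.** Natural log. $R^2$ and the argmax are invariant to the base
  (a base change rescales both residual and total sums of squares); a test
  asserts agreement with a base-10 refit. Only the interpretation of
  $\alpha$ as $\log T$ depends on the base.
* **Candidate range.** The default upper limit is
  $\lceil \min(y) \rceil - 1$: the largest integer strictly below every
  $y_k$, so every log is defined. For integer-valued curves this is
  $\min(y) - 1$. Taking a floor instead would wrongly exclude the true $d$
  whenever the remaining passenger mass at $n$ isolates is below one gene
  ($T p^n < 1$), which is exactly the regime a well-designed experiment
  approaches; exact-recovery tests on noiseless curves pin this down. A
  curve whose minimum is below 1 leaves no valid candidate and is a domain
  error.
* **Tie-breaking.** Adjusted-$R^2$ values within `tie_tol` ($10^{-12}$ by
  default) of the maximum are tied and resolved to the smallest $d$ —
  deterministic, and conservative in that it assumes fewer drivers.
* **Implementation.** The grid search evaluates the closed-form simple-OLS
  solution vectorised over all candidates; the single-$d$ entry point
  `fit_linear_given_d()` calls the same kernel, and the test suite compares
  both against `stats::lm()` to $10^{-10}$.

## Predictions and required sample size

`predict_common_genes()` evaluates $\hat d + \hat T \hat p^{\,x}$.
`required_isolates()` answers the design question "how many isolates until
the common set *is* the driver set?": for increasing $x$ it computes the
two-sided confidence interval for the mean response of the log-scale
regression (Student-$t$, $n-2$ df, standard error
$\hat\sigma\sqrt{1/n + (x-\bar x)^2 / S_{xx}}$), maps the bounds to the
count scale as $\hat d + e^{\text{bound}}$, and stops at the first $x$ whose
upper bound is within `tol` of $\hat d$ (default 0.5 — the predicted count
rounds to $\hat d$).

The interval convention is genuinely open: a prediction interval, a $z$
quantile, or a count-scale delta-method interval would all be defensible and
give slightly different $x$. The mean-response $t$ interval was chosen
because the quantity of interest is the *expected* overlap, not a single
future curve point; both the convention and `tol` are arguments, and the
monotonicity properties (more tolerance never needs more isolates, more
confidence never fewer) are tested rather than any one printed value.

## The overlap-significance null

`overlap_significance()` asks whether an observed all-isolate overlap could
arise if each isolate's active set were a uniformly random subset of the
probe universe, of the observed size. Rather than materialising subsets, the
sampler uses an iterated hypergeometric chain: given a running intersection
of size $m$ after $i$ subsets, the next subset of size $s$ covers
$\mathrm{Hypergeometric}(N, m, s)$ of it. This is distributionally identical
to explicit set sampling (the naive sampler is retained behind
`method = "sets"` and compared in the tests, along with an exact
chain-convolution tail for small universes) and makes $10^6$ repetitions of
a six-subset, 25,074-probe configuration run in under a second.

Exceedance is counted as *simulated ≥ observed*, the conservative Monte
Carlo convention, and two summaries are reported: the add-one estimator
$(b+1)/(R+1)$ and, when $b = 0$, the bound $1/R$. The closed-form mean
$N \prod_i (s_i/N)$ anchors the simulation in a 4-standard-error test.

## The passenger simulation

`min_isolates_single_run()` simulates the pure passenger null and returns
the first isolate count at which the running intersection is empty. The
count starts at 1: a single isolate's "intersection" is its own active set,
so a passenger set that happens to activate nothing terminates the run
immediately. The running intersection is thinned binomially
(each surviving gene survives the next isolate with probability $p$), which
is equivalent in distribution to materialising full activation vectors; the
naive version is kept for tests, and both are checked against the closed
form

$$P(\text{min } n \le k) = (1 - p^k)^T .$$

A hard cap (`max_isolates`, default 10,000) guarantees termination for $p$
near 1 and is reported in the error if reached. `mean_min_isolates()`
averages 10 replicate runs by default and reports the standard error over
replicates; `sweep_passenger_grid()` runs a factorial grid with an
independent child seed per cell.

A caution on reading rounded anchors: at $T = 5000$, $p = 0.1$ the
closed-form expectation of the minimum isolate count is 4.44 with SD 0.62,
so the mean of 10 replicates rounds to 4 or to 5 depending on the draw —
near half-integer expectations, a 10-replicate mean is simply not a stable
integer. The corresponding expectations at $p = 0.3$ and $p = 0.5$ are 8.05
and 13.62, comfortably away from the rounding boundary.

## The 4PL comparator

`fit_4pl()` fits $y = D + (A - D)/(1 + (x/C)^B)$ by Levenberg–Marquardt
least squares (start $A = y_1$, $D = y_n$, $C = \mathrm{median}(x)$,
$B = 1$; $D$ bounded at 0), with the lower asymptote $D$ as an informal
second opinion on the driver count. It is informational only. Users should
know its failure mode: on short, steeply decaying curves the 4PL family
contains a near-hyperbolic regime ($C \to 0$, $A$ large, $y \approx D +
c/x^B$) that can fit *better* in least squares than any sigmoid levelling
off near the visually apparent plateau, in which case $D$ collapses far
below the SOFLR estimate. The grid search, not the 4PL, is the estimator.

## The synthetic generator

`simulate_activation()` draws exactly the three-class model: drivers all
TRUE, passengers i.i.d.\ Bernoulli($p$) per gene *and* per isolate,
non-responsive all FALSE. `simulate_expression()` lifts calls to a positive
intensity table — log-normal per-probe baselines, control replicates, and
fold factors placed at least `margin` beyond the threshold for TRUE calls
and strictly inside the no-call band otherwise — so that
`call_activation()` recovers the generating calls exactly, for any positive
margin. The round-trip identity, not the intensity distribution, is the
contract: the generator makes no attempt to mimic probe-level array noise,
normalisation artefacts, batch effects, or the correlated,
partially-non-random passenger behaviour real transformants show. Passing
the recovery tests therefore demonstrates internal consistency of the
estimator under its own model, not robustness to violations of passenger
independence.

What the generator *is* for: `end_to_end_recovery()` chains generation →
exact overlap curve → `soflr_fit()` and reports estimation error against
truth. Under the model, with 10 isolates, $d = 200$, $T = 5000$, $p = 0.3$,
the median absolute error of $\hat d$ across seeds is a few genes; the test
suite asserts the property-based bounds (exact recovery on noiseless
curves; median $|\hat d - d| \le 0.1\,d$ over 21 seeds; error shrinking
from 4 to 12 isolates).

## Numerical behaviour and limitations

* **Flat profiles.** Near the optimum the adjusted-$R^2$ profile can be
  extremely flat — on a printed, integer-rounded six-point curve, adjacent
  candidates can differ by under $10^{-6}$. The argmax is then well defined
  numerically but scientifically fragile: rounding the input means to
  integers can shift $\hat d$ by a unit or two relative to fitting the
  unrounded means. Report the profile, not just the argmax, when curves are
  short.
* **No uncertainty on $\hat d$.** The method provides the profile as its
  only uncertainty summary; the confidence interval in
  `required_isolates()` concerns the predicted overlap, not $\hat d$.
* **Assumed exchangeability.** One array per isolate, a common $p$ for all
  passengers, and independence across isolates are assumed throughout;
  replicate arrays should be collapsed by the caller first.
* **Problem sizes.** The test suite works at deliberately small scales —
  enumeration oracles up to 8 isolates, $10^5$ null draws for the
  statistical anchors, $10^6$ for the headline configuration, 21 seeds for
  recovery — chosen so the full suite exercises every contract in seconds
  while keeping Monte Carlo bands (3–4 SE) meaningful.

## A worked call

```{r example}
cd <- overlap_curve(c(1673, 850, 574, 433, 346, 285))
fit <- soflr_fit(cd)
fit
glance(fit)
required_isolates(fit)
```
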