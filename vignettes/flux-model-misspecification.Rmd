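---
title: "Detecting and repairing missing reactions in overdetermined MFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and repairing missing reactions in overdetermined MFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmend)
```

## The estimation problem

Overdetermined metabolic flux analysis (MFA) treats the intracellular
metabolite balances at pseudo-steady state, `S v = 0`, as a linear
regression.  Splitting the stoichiometric matrix into the measured exchange
reactions and the unknown internal ones,

    S_E v_E + S_I v_I = 0,

and setting `y = -S_E v_E`, `X = S_I`, `beta = v_I` gives `y = X beta + e`.
When the number of balances exceeds the number of unknown internal fluxes
and `S_I` has full column rank, `beta` is estimable by ordinary least
squares, `(X'X)^{-1} X'y`, or — when the measurement-error covariance
`Cov(e)` is known — by generalized least squares, implemented here by
whitening with a Cholesky factor of `Cov(e)` and reusing the OLS path.
There is no intercept anywhere: `y` is a balance residual with no natural
mean term, which is also why the significance-of-regression ANOVA in
`regression_anova()` uses the uncentered decomposition `SST = y'y`.

`Cov(e)` is propagated from the per-measurement standard deviations as
`S_E diag(sd^2) S_E'`.  Balance rows untouched by any measured exchange
then have exactly zero variance, which would make the GLS weighting
singular.  `build_regression()` floors those diagonal entries at `1e-6`
times the smallest nonzero propagated variance (an absolute `1e-6` when
every sd is zero).  The floor approximates treating unmeasured balances as
hard constraints while keeping a single positive-definite-covariance code
path; the factor is configurable (`var_floor`) because curated models
sometimes need a softer constraint.

## What a missing reaction does to the estimate

If the true balance involves an additional block `S_O v_O` that the working
model omits, the misspecified OLS estimate acquires the closed-form bias

    bias = (S_I' S_I)^{-1} S_I' S_O v_O,

computed by `specification_bias()` (with a whitened analogue under GLS).
Two structural facts follow directly and are enforced as exact tests: the
bias vanishes when the omitted flux is zero, and when the omitted
stoichiometry is orthogonal to the retained columns.  The practical
consequence explored by `run_bias_experiment()` is less obvious: the bias
scales with the *correlation structure* of the stoichiometry, not with the
omitted flux alone, so removing a low-flux reaction can bias the remaining
estimates disproportionately, and a statistically significant regression
does not certify small flux biases.

A caveat about the significance direction: whether omitting a
*large*-flux reaction degrades the regression's ANOVA more than omitting a
small one depends on the measurement-error model.  Under purely
proportional noise, GLS whitening judges misfit relative to each
measurement's own scale and the intuitive ordering can invert.  With an
error model `sd = a + b |v_E|` that keeps a finite floor on small
measurements — the shape typically seen when standard deviations are
regressed on uptake rates — the large-flux omission degrades the fit most,
and that is the setting the package's tests exercise.

## The three specification tests

All three tests operate on the raw OLS problem by default (a `whiten`
switch runs them on the whitened problem instead; see "Raw or whitened?"
below).

**RESET** (`reset_test()`) augments the design with elementwise powers of
the fitted values, `yhat^2, ..., yhat^(p+1)`, a Taylor-series surrogate for
whatever the model is missing, and F-tests the joint contribution on
`(p, N-K-p)` degrees of freedom.  It needs no candidate stoichiometry.
Fitted values are scaled by `max(|yhat|)` before exponentiation; the
statistic is unchanged (it depends only on the augmented column space) but
fluxes of magnitude several hundred no longer overflow high powers.
`K` counts the columns of `X` only, since the model has no intercept.

**Nested F-test** (`f_test()`) fits `y = X beta + Z alpha + e` for a
candidate block `Z` and tests `H0: alpha = 0` via the drop in the residual
sum of squares, on `(o, N-K-o)` degrees of freedom.  `[X Z]` must have full
column rank; a violation is reported as an error naming the dependent
candidate columns, never silently as a zero statistic.

**Heteroscedasticity-consistent LM test** (`lm_test()`) residualizes `Z`
against the intercept-augmented design `[1 X]` (the intercept column is
part of the residualization recipe even though the model itself has none)
and forms the score statistic

    e' Zc ( (N-K)/(N-K-o) * Zc' Omega Zc )^{-1} Zc' e,   Omega = diag(e_i^2),

referred to a chi-square with `o` degrees of freedom.  The
degrees-of-freedom factor is grouped inside the inverse exactly as the
formula is conventionally printed.  When an omission leaves design rows
identically zero, the corresponding residuals are exactly zero and
`Zc' Omega Zc` can be singular; the statistic is then undefined and
`lm_test()` raises an error.  The benchmark harness counts such replicates
as non-rejections, the limiting behavior of the test as the
residual-weighted information vanishes — the same mechanism behind the
test's power loss when many reactions are missing.

Decisions are reported both ways (critical value and p value); RESET uses a
strict `>` against its critical value and the F/LM tests use `>=`, as the
definitions are conventionally written — ties occur with probability zero.
The default significance level is `0.05` throughout.

## Iterative repair

`resolve_model()` repairs a misspecified model from a candidate matrix
`S_A`: for each tuple size `k` in the schedule it F-tests every `k`-tuple
of remaining candidates against the current model, promotes the passing
tuples, and repeats until nothing passes.  Because "promote the passing
combination(s)" is ambiguous when passing tuples overlap, the default is
greedy promotion in descending-statistic order (ties broken
lexicographically by candidate id) with rank guarding, followed by a full
re-test in the next iteration; `promote = "single"` promotes only the top
tuple per iteration.  Both reach the same fixed point in the scenarios the
tests cover; the greedy default converges in fewer iterations.  The
schedule `k = 1` is the recommended default — pair testing (`k = c(1, 2)`)
recovers more omitted reactions but admits more false candidates, and its
cost grows combinatorially.  No multiple-testing correction is applied by
default (a Bonferroni-over-tuples option exists but is off), matching how
the procedure is conventionally run with a raw threshold.

## The synthetic-network engine

`random_stoichiometry()` draws networks with 2–4 participants per reaction
(at least one consumed and one produced; coefficient magnitudes from
`{1, 2}`), every metabolite participating in at least one reaction, and
full column rank.  `attach_exchanges()` designates the first `m_E`
metabolites as measured via an identity exchange block;
`sample_internal_fluxes()` draws internal fluxes as `B c` with `B` an
orthonormal null-space basis of the unmeasured balance block and
`c ~ Uniform(-1, 1)`; `simulate_measurements()` adds Gaussian noise with
standard deviation `CoV * |y_i|` to the measured rows only (zero-valued
noise-free measurements receive no noise — a proportional-noise model, not
an additive floor; a homoscedastic variant with fixed sd is available).
All randomness flows from explicit seeds through named sub-streams
(network, fluxes, noise, removal, decoys), so every dataset is a pure
function of its seed.

One generator decision deserves emphasis.  In a naive sparse ensemble a
large fraction of reactions is *structurally dead*: a metabolite touched by
a single reaction pins that reaction's steady-state flux to zero, and the
zeros cascade through the unmeasured kernel.  Omitting a dead reaction
creates no misspecification at all — the reduced model is still correct for
the data — so true-positive rates lose their meaning and the exact
noiseless invariant (an omitted reaction with nonzero flux is always
detected at `CoV = 0`) becomes unattainable.  When `m_E > 0`,
`random_stoichiometry()` therefore rejection-samples until the network is
*flux-consistent* with respect to the unmeasured balances: the null space
of `S_I_NE` has no structurally-zero coordinate, i.e. every reaction can
carry flux.  The allocation heuristic that makes this rejection practical
(two dealt slots per unmeasured metabolite; leftover slots steered by the
unmeasured-block slack) is only a proposal distribution — the accepted
ensemble is defined by the explicit rank/coverage/flux-support criteria.

What the generator does *not* emulate: biologically realistic topology
(hub metabolites, pathway structure, scale-free degrees), reaction
reversibility or thermodynamics, and any particular dead-reaction rate.
The last point matters when comparing detection rates with published
random-network studies: with few omitted reactions and low noise, the TP
rate of the F-test is governed almost entirely by the probability that the
omitted set carries no flux, which is an ensemble property, not a property
of the test.  In this package's flux-consistent ensemble that probability
is near zero, so low-`n_O` TP rates saturate near 1 where ensembles with
dead reactions report 0.7–0.9.  Passing the benchmark suite therefore
demonstrates the statistical machinery under controlled conditions, not a
statement about any particular real network.

## The benchmark harnesses

`run_detection_experiment()` estimates TP/FN/FP/TN rates per test: the TP
arm applies a test to a design with `n_O` randomly removed reactions (the
F/LM candidate block is the truth — the removed columns); the FP arm uses a
freshly drawn, linearly independent decoy block of the same size (for
RESET, the FP arm is the test on the full, correctly specified design).
`TP + FN = 1` and `FP + TN = 1` hold exactly by construction and are
asserted.  `detection_grid()` spans three geometries — 100 metabolites / 60
internal / 50 exchange fluxes with 2, 5 or 10 omissions; 50/30/25 with
2–10; 200/120/100 with 2–20 — each at noise CoV 1–20%.  The default of 200
replicates per cell keeps the whole grid inside a few minutes on one CPU
while leaving binomial standard errors near 0.02; the tests compare rates
at three binomial standard errors plus a 0.05 systematic allowance for the
generator-ensemble differences discussed above (0.03 for near-saturated
rates).

`run_resolver_experiment()` nests the repair procedure in the
two-level design used for case studies on curated models: an outer loop
removes `n_extra` reactions from a base network to form the true model
(those removals become decoy candidates), an inner loop simulates data,
removes `n_omit` further reactions, pools both sets as candidates, and
resolves.  Reported quantities are means (over outer replicates) of inner
medians of the never-promoted counts, split by provenance, with standard
errors.  The default base geometry (49 metabolites, 47 internal reactions,
34 measured exchanges) mirrors a small mammalian-cell metabolic model;
since no curated reference fluxes ship with the package, the true flux
vector is a null-space sample — a synthetic stand-in, which is why the
package asserts directional behavior (omitted reactions almost all
recovered; most decoys left alone) rather than specific remaining counts.
At 15 outer × 4 inner replicates the experiment runs in seconds.

## Numerical choices

* Rank decisions use singular values with threshold
  `max(dim) * eps * max(sv)` (overridable), both for estimability checks
  and the null-space split.
* Estimates are computed by QR factorization, never by explicitly forming
  `(X'X)^{-1}`; the tests verify agreement with the closed-form expressions
  to 1e-10 and with an exact rational-arithmetic oracle on integer toys.
* `sigma^2` in the OLS covariance is estimated by `SSE / (N - K)`.
* An exact fit (`SSE = 0`) is reported with `p = 0` and an `exact_fit`
  flag rather than `NaN`.
* Tuple promotion ties in the resolver are broken lexicographically for
  reproducibility.

## Known limitations

* The tests assume Gaussian noise; no normality checking is performed.
* Candidate generation from reaction databases is out of scope —
  candidates arrive as a stoichiometry table.
* The detection-rate benchmarks inherit the synthetic ensemble's
  idiosyncrasies discussed above; rates for small numbers of omitted
  reactions are ensemble-dependent and should not be read as universal
  operating characteristics.
* SBML import, reversibility semantics and compartment bookkeeping are not
  provided; models are plain coefficient tables with opaque identifiers.
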