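---
title: "Modelling replication rates under p-hacking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling replication rates under p-hacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrprates)
```

## The replication scenario

A research field tests hypotheses of which a fraction $\pi$ (the *base
rate*, also called the pre-study probability or prior odds) are true
effects. An original study rejects its null hypothesis with probability
$1-\beta_1$ when the effect is real and $\alpha_1$ when it is not. Only
significant results are considered for replication; an unbiased
replication study then rejects with probability $1-\beta_2$ (true
effect) or $\alpha_2$ (null). Two summary quantities follow from the
four compound outcome probabilities:

$$RR = \frac{\pi\,(1-\beta_1)(1-\beta_2) + (1-\pi)\,\alpha_1\alpha_2}
            {\pi\,(1-\beta_1) + (1-\pi)\,\alpha_1},
\qquad
FPR = \frac{(1-\pi)\,\alpha_1}{(1-\pi)\,\alpha_1 + \pi\,(1-\beta_1)}.$$

`replication_rate()` and `false_positive_rate()` implement these. $RR$
runs from $\alpha_2$ at $\pi=0$ (every significant result is a false
positive, and only chance can replicate it) to $1-\beta_2$ at $\pi=1$;
the package returns these endpoint limits exactly rather than through
the general quotient, and raises a classed error
(`qrprates_undefined_rate_error`) for the genuinely undefined $0/0$
cases instead of letting `NaN` propagate into tables.

The central modelling idea is that p-hacking changes the *effective*
$(\alpha_1, 1-\beta_1)$ of the original study — inflating the Type 1
error rate but also inflating power — and that both inflated values can
be plugged into the formulas above. `effective_rates()` returns this
pair for any strategy object: the rejection probability at $d = 0$ is
the effective Type 1 error rate, and at the design's $d > 0$ the
effective power.

## Test model

Original studies are modelled as one- or two-sample z-tests with known
unit variance: the test statistic is normal with unit variance and mean
$\delta = d\sqrt{n}$ (one-sample) or $\delta = d\sqrt{n/2}$ (two-sample
with $n$ per group), where $d$ is the standardized mean difference.
Two-sided tests reject on $|Z| > c$ and their power includes the
(negligible) lower-tail term exactly. The default study conditions are
$n = 20$ per group, $d \in \{0.2, 0.5, 0.8\}$,
$\alpha_1 \in \{0.5\%, 5\%\}$, one-sided, with a replication study at
$\alpha_2 = 5\%$ and $1-\beta_2 = 90\%$ — a small-sample experimental
field being replicated by a high-powered project. t-tests appear only in
the outlier-removal simulation, where the simulated researcher really
does run t-tests on data with estimated variance.

## The four strategies

**Selective reporting** (`qrp_selective_reporting(k)`): up to $k$
independent studies, publish the first significant one. The rejection
probability is $1-(1-p_1)^k$ with $p_1$ the single-study value; at
$k = 8$, $\alpha = 5\%$ one-sided this is $0.3366$, at $\alpha = 0.5\%$
only $0.0393$.

**Unreported dependent measures** (`qrp_multiple_measures(k, rho)`): one
study, $k$ equicorrelated measures with pairwise correlation $\rho$,
report any significant one. The rejection probability is one minus the
orthant probability $P(Z_1 \le c, \ldots, Z_k \le c)$ of an
equicorrelated multivariate normal. At $\rho = 0$ this coincides with
selective reporting; as $\rho \to 1$ the measures become redundant and
the probability falls to the single-test level. Ten measures at
$\rho = 0.2$ lift a one-sided 5% test to about 34%.

**Data peeking** (`qrp_data_peeking(schedule)`): test the accumulating
sample at each per-group size $n_1 < \cdots < n_k$ of a
`peek_schedule()`, stop at the first significant look. Because early
observations are reused, $\mathrm{Corr}(Z_i, Z_j) = \sqrt{n_i/n_j}$.
Two presets are shipped: `"steps-of-5"` (looks at $10, 15, \ldots, 45$)
and `"steps-of-10"` (looks at $10, 20, \ldots, 50$), the latter being
the schedule under which a two-sided 5% test inflates to about 14%.
One-sided tests are the package default everywhere — consistent with
the product-form selective-reporting model — while the 14% benchmark is
evaluated two-sided because that is how the sequential-testing
literature states it; both variants are supported.

**Selective outlier removal** (`qrp_outlier_removal()`): one data set,
re-analysed under up to five rules — t-tests keeping only scores within
3, 2.5, and 2 SDs of the group mean, a t-test keeping scores inside the
Tukey fences $[Q_1 - 1.5\,IQR,\ Q_3 + 1.5\,IQR]$, and finally a
rank-sum test — stopping at the first $p < \alpha$. No closed form
exists, so `estimate_rejection_prob()` simulates (default 10,000
experiments). Outliers are injected by adding $N(0, 10^2)$ noise to a
random 5% of values.

## Numerical choices

*Equicorrelated orthant probabilities* use the one-factor reduction
$Z_i = \sqrt{\rho}\,U + \sqrt{1-\rho}\,\varepsilon_i + \delta$, giving a
one-dimensional integral
$\int \phi(u)\,\Phi\!\big((c-\delta-\sqrt{\rho}\,u)/\sqrt{1-\rho}\big)^k\,du$
evaluated by adaptive quadrature to absolute tolerance $10^{-9}$.
Two-sided designs use the box version of the same integrand.

*Sequential (peeking) probabilities* exploit the Markov property of the
running z statistic: $Z_{j+1} = r_j Z_j + \sqrt{1-r_j^2}\,e_j +
(\delta_{j+1} - r_j \delta_j)$ with $r_j = \sqrt{n_j/n_{j+1}}$. The
probability that every look stays below its bound is computed by
propagating the subdensity of the surviving process through each look
with Simpson-rule integration (801 grid nodes, absolute error well
below $10^{-6}$). This recursion is deterministic at any number of
looks, which is why it is preferred over generic multivariate-normal
CDF routines whose quasi-Monte-Carlo error would make tabulated output
run-to-run unstable; the test suite cross-checks it against the
deterministic Miwa algorithm of the mvtnorm package and against raw
simulation.

*Outlier simulation details.* Filtering statistics (mean/SD, quartiles)
are computed per group and exclusion is applied per group, because
under $H_1$ the two group distributions differ and pooled filtering
would bias the effect estimate. Each SD rule is a single pass — the
criterion is applied once to the original sample statistics, not
iterated. Contamination is Bernoulli per observation at rate 0.05
rather than a fixed 5% count, and the effect $d$ is added to the
experimental group's mean before contamination noise. Quartiles default
to the linear-interpolation convention (`type = 7`), exposed as a
configuration knob since fence membership at $n = 20$ can flip under
Tukey's original hinges. The rank-sum step always runs on the
*unfiltered* data (it is the researcher's alternative route to taming
outliers, not a follow-up to exclusion) and uses the normal
approximation with continuity correction — with continuous data ties
have probability zero, and the approximation is accurate at $n = 20$
per group; the suite verifies exact agreement with
`stats::wilcox.test(exact = FALSE, correct = TRUE)`. Degenerate
filtered samples (fewer than two retained observations, or zero
variance) count as non-significant and the sequence continues; the
count of such cases is reported. All replicate data sets are drawn from
the seed before any analysis, so runs with the same seed and different
analysis sequences re-analyse identical data — sequence comparisons are
paired by construction. A `mode = "full_data_first"` variant prepends a
t-test on the complete data, modelling researchers who filter only
after an initial failed test.

## Good-practice references

Each strategy is compared against a researcher running a single
pre-planned analysis: one study (or one measure) at the design's sample
size for selective reporting and multiple measures; a single fixed-$n$
test at the schedule's *final* look for data peeking (a deliberately
conservative comparison — the good-practice researcher gets all the
data a peeker would ever collect); and the sequence truncated to its
first analysis for outlier removal. `evaluate_grid()` tabulates
effective rates, $FPR$, $RR$, and the shrinkage
$RR_{\mathrm{good}} - RR_{\mathrm{hacked}}$ over
$\pi \times k \times d \times \alpha_1$; shrinkage can be slightly
negative in outlier scenarios where exclusion genuinely improves power.
The base-rate grid defaults to steps of 0.05 with the endpoints handled
by the exact limit identities.

## The Monte-Carlo oracle

Every analytic quantity has a brute-force counterpart that simulates
researchers at the raw-data level: `oracle_rejection_prob()` draws the
$k$ studies, builds correlated measures from one shared factor
(realizing the exact equicorrelation matrix), accumulates peeking
samples incrementally (realizing $\sqrt{n_i/n_j}$ by literal data
reuse), or runs the contaminated-data pipeline; and
`simulate_replication_pipeline()` composes a full field — hypotheses
drawn at base rate $\pi$, p-hacked original studies, and replication
attempts drawn as Bernoulli at $(\alpha_2, 1-\beta_2)$, mirroring the
abstraction that a replication study enters the model only through its
two error probabilities (a raw-data replication would add nothing but
noise to that comparison). The test suite requires every analytic value
to agree with the oracle within three binomial standard errors at
$10^5$ replications across a parameter sweep.

## Problem sizes

The shipped tests use $10^5$ replications for oracle-vs-analytic
comparisons, $10^6$ for the multiple-measures benchmark cross-check,
and 10,000 simulated experiments for the outlier scenario — the size at
which its probability estimates are quoted; grid tests use a coarser
base-rate grid (steps of 0.1) than the reporting default. These sizes
put three-SE checks well inside a percentage point while keeping the
whole suite at about a minute of compute.

## Limitations

The analytic strategies assume known-variance z-tests, homogeneous
effect size across attempts, measures, and looks, and replication
success defined purely by significance (no direction-consistency
requirement, matching the all-or-none way replication projects score
outcomes). The synthetic conditions emulate idealised studies: clean
normal data (contaminated only in the outlier scenario), equal group
sizes, no publication-selection effects on the *replication* side, no
covariate hacking, and no correction for sequential testing. Passing
tests therefore demonstrate internal consistency of the model and
fidelity to its benchmark values, not that any empirical field obeys
these assumptions. Effects of combining several p-hacking strategies at
once are outside the model, and all strategy effects are upper bounds
that assume every researcher p-hacks.
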