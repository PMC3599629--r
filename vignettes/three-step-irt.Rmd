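---
title: "A three-step IRT strategy for evaluating rating scales in small samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-step IRT strategy for evaluating rating scales in small samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalestep)
```

Clinical questionnaires — depression severity scales are the motivating
case — are sums of ordinal items, and the sum score is routinely treated as
an interval measure of one underlying severity dimension. Whether that is
defensible is a measurement question, and at the sample sizes where new
instruments are first tried out (tens of patients, not thousands) it has to
be answered with methods that are honest about sampling noise. `scalestep`
implements a deliberately ordered strategy: start with the most
assumption-free analysis, and only buy into stronger parametric structure
when the weaker analysis has licensed it.

## Step 1: nonparametric scalability

For items $i$ and $j$ with ordinal scores $X_i, X_j$, the pairwise
Loevinger coefficient is

$$H_{ij} = \frac{\mathrm{Cov}(X_i, X_j)}{\mathrm{Cov}^{\max}(X_i, X_j)},$$

where the denominator is the covariance of the *comonotonic coupling* of
the two observed marginals: sort both score vectors and pair them
rank-wise. That coupling maximises the covariance over all pairings of the
two marginals (a rearrangement argument; the test suite checks it against
brute-force enumeration over all marginal pairings on a thousand small
matrices), so $H_{ij} \le 1$ always, $H_{ij} = 1$ exactly for data with no
Guttman errors, and $H_{ij} \approx 0$ for unrelated items. Item and total
coefficients aggregate numerators and denominators, not the ratios:
$H_i = \sum_{j \ne i} \mathrm{Cov}_{ij} / \sum_{j \ne i}
\mathrm{Cov}^{\max}_{ij}$ and likewise $H$ over all pairs, which makes $H$
a covariance-weighted mean of the $H_i$. The conventional reading of the
total: below 0.3 unscalable, 0.3–0.4 weak, 0.4–0.5 medium, 0.5+ strong.

Covariances use the divide-by-$n$ convention; the constant cancels in every
ratio. All Step-1 statistics are computed on listwise-complete cases —
with at most a handful of missing cells per instrument this loses a few
persons and keeps every pair of items on the same case base.

Three diagnostics accompany the coefficients:

* **Automatic item selection (AISP)** partitions items into scales
  bottom-up: seed with the most scalable significantly-positive pair, then
  greedily add the item that maximises the provisional scale's $H$ subject
  to the candidate's $H_i$ against the scale clearing the lower bound
  $c$ (default 0.3) and being significantly positive. Ties break to the
  lower item index, so the procedure is deterministic. Significance of
  "positive" uses the one-sided normal test $Z = r\sqrt{n-1}$ on the pair
  (or item–restscore) Pearson correlation, whose sign agrees with the sign
  of $H$; under independence $r$ has standard deviation
  $\approx 1/\sqrt{n-1}$. Items on distinct latent dimensions end up in
  distinct scales, so AISP doubles as a multidimensionality probe.
* **Monotonicity** by the restscore method: group persons on their total
  over the other items, merging adjacent rest scores left-to-right until
  each group holds `minsize` persons (default 15 — at $n \approx 60$ that
  yields a low, middle and high group; the trailing remainder joins the
  last group). Each item-step probability $P(X_i \ge k)$ must not decrease
  across ordered groups; decreases beyond `minvi` (default 0.03, the
  customary tolerance) are violations, tested one-sided with a
  two-proportion z-test.
* **Invariant item ordering** (non-intersection): order items by overall
  means, then check within restscore groups (excluding both items of a
  pair) that the conditional means preserve the order. The reversal
  tolerance defaults to 0.03 times the maximum category code, scaling the
  step-level convention to the score range; significance is a paired
  one-sided t-test. Crossing item response functions — typically items
  with very different discriminations — show up here.

### Resampling inference

Distributional theory for $H$ at $n \approx 60$ is not trustworthy, so
interval estimates come from the bootstrap: persons are resampled with
replacement (preserving the within-person dependence between items), the
statistic recomputed per replicate, and the percentile interval reported
(default $B = 1000$, level 0.90). Replicates where the statistic
degenerates (a resampled item with no variance) are dropped and counted; a
fit is flagged when more than 20% degenerate. Percentile rather than BCa:
at $B \ge 500$ and the effect sizes that matter here (is the lower bound
above 0.3 or not) the simpler method is adequate, and its endpoints are
order statistics of the replicate vector, which the tests verify directly.

For a suspect item the hypothesis $H_i = 0$ gets a sharper tool: permute
that item's responses across persons ($B = 500$), which preserves its
marginal distribution while severing its link to the scale, and compare the
observed $H_i$ with the percentile interval of the permuted null. An
observed value inside the null interval means the item's apparent
(non-)contribution is within chance variation. The pipeline triggers this
automatically for every item with $H_i$ below the lower bound.

Replicate-level seeds are derived from the user seed by counter, so results
do not depend on execution order.

## Step 2: the rating scale model as a gate

If Step 1 shows at least a weak scale ($H > 0.3$ and every $H_i > 0$),
parametric modelling is licensed. The Rasch rating scale model (RSM) is the
model the *sum score itself* presumes: one location $\beta_i$ per item, one
shared set of category thresholds, and equal discrimination, under which
the raw sum is a sufficient statistic for the person parameter. We fit it
by marginal maximum likelihood with an adjacent-category formulation,
$P(X_i = k \mid \theta) \propto \exp(k\theta - k\beta_i - \sum_{l \le k}
\tau_l)$, $\sum_l \tau_l = 0$. Identification fixes the item slope at 1 and
leaves the latent SD free; computationally we estimate in the equivalent
coordinates of a standard-normal latent with one common slope (reported as
`latent_sd`) so that one EM engine serves all models. The sufficiency
property is kept as a regression test: fitted person estimates on complete
data are a strictly increasing function of the raw sum score.

Whether equal discrimination is tenable is decided in the cumulative-logit
family where the constrained and free models nest cleanly: a graded
response fit with one shared slope versus item-specific slopes, compared by
likelihood ratio on $I - 1$ degrees of freedom. The package's gate to Step
3 is: LR significant at $\alpha = 0.05$, *or* fitted slope ratio
$\max_i a_i / \min_i a_i > 3$. The ratio clause (configurable) catches the
practically relevant failure — a few items doing most of the work — even
when $n$ is too small for the LR test to be powerful. The type-I error of
the LR test at the null is verified by simulation in the acceptance suite
(100 equal-slope replicates at $n = 300$; rejection rate must sit near the
nominal 5%).

## Step 3: the graded response model

With item weights free, Samejima's graded response model is used:
$P(X_i \ge k \mid \theta) = \mathrm{logistic}\!\left(a_i(\theta - b_i -
t_k)\right)$ with shared sum-zero thresholds $t_k$ (the default; an
item-specific-threshold variant is available and, on data generated with
common thresholds, reproduces the common fit within standard errors — a
property the tests check). The logistic scaling constant is 1 (no 1.7);
discriminations are reported on the logistic scale.

From the fit:

* **Person measures**: expected-a-posteriori estimates with posterior SDs,
  computed from each person's observed items only. Optionally the person
  mean is subtracted jointly from person estimates and item locations
  ("corrected" locations), which re-expresses item severities relative to
  the sample.
* **Item information**: Samejima's graded information
  $I_i(\theta) = a_i^2 \sum_k (w_k - w_{k+1})^2 / P_{ik}(\theta)$,
  $w_k = P^*_k(1 - P^*_k)$, which for a dichotomous item collapses to the
  familiar $a^2 P(1-P)$. The per-item *share* of instrument information is
  the trapezoidal integral of $I_i$ over the default grid $[-4, 4]$
  divided by the integral of the total, in percent; for display the share
  is bucketed to the nearest multiple of 5 with a "<5" floor, as
  approximate shares are conventionally reported. The raw shares are
  always retained and sum to 100.
* **Coverage**: quantiles of the person measures set against the range of
  item locations and category thresholds. The recurring clinical finding —
  items informative only in a narrow mid-severity band, nothing measuring
  the mildly depressed — appears here as person quantiles outside the
  threshold range.
* **Rank intervals**: a person's trait CI mapped to rank units by counting
  scored persons below each endpoint (`rank = 1 + #{strictly below}`, ties
  by person index), with relative ranks as percentages of the scored
  sample. This is the most honest way to communicate measurement precision
  to users of a ranking: at $n \approx 60$, a single person's 95% rank
  interval can easily span a third of the sample.
* **Profile flags**: constant responders and persons with standardized
  person log-likelihood below −2 at their EAP estimate are flagged —
  advisory only, never excluded, since an instrument evaluation must
  describe the sample it will actually face.

## Estimation engine and numerical choices

Both models are estimated by EM over a fixed Gauss–Hermite grid (41 nodes
by default; nodes and weights from the Golub–Welsch eigendecomposition).
The E-step computes per-person posteriors over the grid in one vectorised
pass; expected category-by-node counts come from `rowsum`. The M-step
maximises the expected complete-data log-likelihood with `nlminb` using
analytic gradients (verified against finite differences to $10^{-8}$ in
development). Because the M-step only ever improves the expected
log-likelihood from the current parameters, the marginal log-likelihood is
non-decreasing across iterations — a generalized-EM guarantee that the
test suite asserts on every fit trace. Convergence is declared at a
log-likelihood change below $10^{-5}$; non-convergence returns a flagged
fit rather than an error. Slopes above 20 flag a Heywood-type divergence.

Parameters are transformed to unconstrained coordinates (log slopes,
thresholds via log-increments, sum-zero enforced by centring), category
probabilities are floored at $10^{-12}$, and nested fits are warm-started
from the constrained solution — which also guarantees the LR statistic is
non-negative. Standard errors come from the central-finite-difference
Hessian of the marginal log-likelihood (step $10^{-4}$), pseudo-inverted
with a flag if near-singular, delta-method-mapped to the natural scale.
Items with unobserved categories are recoded before fitting (empty
categories merged downward) and the recode is logged on the fit object;
persons with missing cells contribute their observed items only
(full-information likelihood), in contrast to the listwise Step-1
statistics, because at $n \approx 61$ every person counts in a parametric
fit.

## What the synthetic generators emulate

The raw patient-level data behind the published evaluation were never
deposited; the printed tables ship as fixtures, and the generators exist so
that every stage of the pipeline is testable against known truth.

`generate_study_like()` emulates the published study's shape: 61
respondents, three blocks (9 items × 5 categories, 9 × 4, 10 × 7) scored
by one latent severity, discriminations and locations set to the published
item estimates, 0–4 missing cells per block, one constant and one
uniformly-random responder appended. Two generator constants were fixed by
calibration to the published summary tables and then left alone. First,
the latent SD is 1.7: with the published discriminations a standard-normal
latent implies total scalabilities far below the published ones, and the
published model's latent-scale identification is not recoverable; 1.7
reproduces the published scalability classes (two strong self-rating
scales, one weak observer scale). Second, the upper two thresholds of the
7-category block sit far out (+6, +10), reproducing the published marginal
table's hallmark: top observer-scale categories nearly empty, so that
category merging becomes necessary downstream — which exercises the
recoding path of the fitting engine exactly as the real data did.

The generators produce missingness completely at random (the few missing
cells in the study carry no mechanism information) and append aberrant
responders after coherent generation, labelled in the returned truth.
What passing tests on these data do *not* show: robustness to informative
missingness, to multidimensionality beyond block structure, to
differential item functioning across subgroups, or to rater effects in
observer-scored instruments — none of which the generating model contains.

## Problem sizes in the validation suite

The simulation experiments run at the sizes the properties demand and no
larger: parameter recovery at $n = 1000$ over 10 seeds (correlation with
truth $\ge 0.95$), LR type-I calibration with 100 replicates at $n = 300$,
permutation-null coverage with 100 seeded runs at the study's $n = 61$,
AISP block recovery over 20 seeds at $n = 500$, and bootstrap width
monotonicity with 50 replicates each at $n = 100$ vs $400$ ($B = 300$ for
that experiment; the monotone-width property does not depend on $B$).

## Known limitations

* The AISP is the greedy variant only; a genetic-search variant can find
  better partitions on pathological data.
* Percentile bootstrap intervals can undercover for $H$ near its upper
  bound; BCa would be the next refinement.
* The GRM assumes a normal latent trait; at $n \approx 61$ that choice is
  uncheckable from inside the model.
* Standard errors are asymptotic; with 2 observations per parameter they
  are indications, not guarantees — the same caveat the three-step
  strategy itself attaches to Step 3.
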