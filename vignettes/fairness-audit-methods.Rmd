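---
title: "Auditing subgroup fairness in anomaly detection: models and methods"
author: "fairuad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing subgroup fairness in anomaly detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairuad)
```

## The problem

Unsupervised anomaly detection (UAD) models for medical images are trained
only on samples labelled *normal* and score test samples by their deviation
from the learned normal distribution. When a demographic subgroup is
under-represented in the training data, its normal anatomy is learned less
well, its anomaly scores rise wholesale, and its members are flagged as
false positives more often — a direct fairness harm (unnecessary follow-up,
over-diagnosis) concentrated on already disadvantaged groups.

Quantifying this is not straightforward. A subgroup's scores can be shifted
relative to the rest of the population, so the standard per-group AUROC —
which ranks each subgroup only against itself — is blind to exactly the
failure mode of interest. `fairuad` implements the subgroup-AUROC (sAUROC)
family of metrics, the dataset-construction procedure needed to measure
them under controlled training compositions, and the statistical machinery
to summarize the results, driven end-to-end by a synthetic score generator
so that the whole workflow is testable without imaging data or trained
models.

## The subgroup-AUROC

For a subgroup $s$ of a population $P$, sweep a decision threshold $t$ over
the observed scores; a sample is flagged anomalous iff its score is
$\ge t$. At each $t$,

$$\mathrm{TPR}_P(t) = \frac{\mathrm{TP}_P(t)}{\mathrm{TP}_P(t) + \mathrm{FN}_P(t)},
\qquad
\mathrm{FPR}_s(t) = \frac{\mathrm{FP}_s(t)}{\mathrm{FP}_s(t) + \mathrm{TN}_s(t)},$$

i.e. the TPR is counted over *every* positive in the cohort while the FPR is
counted over the *subgroup's* negatives only. The sAUROC is the area under
the resulting curve,

$$\mathrm{sAUROC}(s) = \int_0^1 \mathrm{TPR}_P\!\left(\mathrm{FPR}_s^{-1}(x)\right)\,dx,$$

a threshold-free extension of the thresholded companion metric
$\mathrm{FPR}@x\%\mathrm{TPR}$ (`fpr_at_min_tpr()`), in which the single
threshold achieving a minimum population TPR is shared by all subgroups.
Sharing thresholds across subgroups is the substantive choice: at deployment
a screening model cannot threshold per subgroup (group membership may be
unavailable, and the number of thresholds grows combinatorially with
intersectional attributes), so fairness must be assessed at common operating
points. The relevant group-fairness criterion is *predictive equality*:
equal false-positive rates across subgroups.

### Numerical definition and its oracle

The integral above is not fully specified where $\mathrm{FPR}_s$ is flat
(the inverse does not exist). `fairuad` resolves this by integrating with
the trapezoidal rule over the finite set of achievable operating points —
the distinct observed scores plus a sentinel above the maximum, anchoring
the curve at $(0,0)$ and $(1,1)$. This reading has an exact closed-form
consequence: the trapezoidal area equals the tie-corrected Mann–Whitney
statistic between the population's positive scores and the subgroup's
negative scores (a pair with positive $>$ negative counts 1, a tie counts
$\tfrac12$). The test suite verifies this identity to $10^{-12}$ on hundreds
of small tied cohorts, which pins the implementation to an independent
brute-force oracle. Two limits follow and are tested exactly: when $s = P$
the sAUROC is the standard AUROC, and when all scores are tied it is 0.5.

Degenerate strata (no positives in the population, no negatives in the
subgroup) raise errors naming the empty stratum. Returning a sentinel value
instead would make unfairness-by-omission silent, which is the one failure
mode an audit tool must not have.

## Dataset construction

`make_eval_sets()` and `make_train_sweep()` reproduce the
composition-controlled experimental design:

* raw diagnostic label sets are consolidated to binary disease labels
  (`consolidate_label()`): normal iff only a no-finding marker is present;
* continuous age is binned to *young* ($\le 31$) and *old* ($\ge 61$),
  dropping the centre so the groups are separated by a clear gap
  (`bin_age()`);
* validation and test sets are drawn first, with a fixed prevalence
  (default 0.5) and exactly equal counts per (category × label) cell, so
  that metric differences between subgroups are not confounded by
  prevalence shifts;
* from the remaining normal data, one training set per grid proportion
  $p \in \{0, 0.1, \ldots, 1\}$ is drawn, each of exactly `n_train`
  samples with `round_half_up(p * n_train)` from one category.

Sampling is at **patient** granularity throughout: patients are drawn in
seeded random order, all of a drawn patient's images go to the same set
(capped at the cell's remaining need), and a used patient is retired from
every later set. This is the only policy that guarantees zero patient
overlap between train, validation and test when patients have multiple
images; the number of images contributed per patient is capped by the
cell's need rather than fixed, a choice the package makes explicitly since
no standard rule exists. Round-half-up is used for non-integer cell targets
because it is deterministic and keeps the training total exactly constant
(`round()`'s round-half-even would be equally deterministic but is a less
common convention in cohort construction). Training sets of *different*
proportions may share patients with one another — they are alternative
training worlds, never co-used — while each remains disjoint from
validation and test.

All splits are byte-identical under a fixed spec and seed; per-proportion
sub-seeds are derived arithmetically from the base seed so the grid can be
extended without disturbing existing draws.

## Fairness laws

Across a composition sweep, a subgroup's sAUROC is (empirically) linear in
its training representation $r$. `fit_law()` fits
$\mathrm{sAUROC} = a + b\,r$ by ordinary least squares to all
(proportion × seed) points, reporting the Pearson correlation on the same
points, and Gaussian confidence intervals of slope and intercept over
per-seed fits. Each category's law is expressed against its *own*
representation, so both categories of an attribute have comparable (and
here positive) slope conventions; the complementary-axis slope is the
negation. `interpolate_from_extremes()` exploits the law: two
measurements, at $r = 0$ and $r = 1$, predict the performance of any
intermediate composition. `interpolation_mae()` validates this per seed —
predicting every intermediate proportion from that seed's own endpoints —
and aggregates the per-seed MAE as mean and sd over seeds, so the reported
error reflects what a practitioner using two real training runs would see.

Design details worth stating:

* **Degenerate fits.** A perfectly flat response leaves the Pearson
  correlation undefined; it is reported as 0 with a `degenerate` flag
  rather than an error, so sweeps from null generators still summarize.
* **Confidence intervals.** `gaussian_ci()` is the normal approximation
  $\bar{x} \pm z_{(1+\gamma)/2}\, s/\sqrt{n}$ with the *sample* standard
  deviation; the default level 0.95 is a package choice.
* **Disparity at balance.** `balanced_disparity_report()` compares the two
  categories' seed-wise sAUROC values at the 50/50 composition with
  Welch's unequal-variance $t$-test (default $\alpha = 0.01$). A
  significant gap at balance is the "hardness" phenomenon: representation
  parity does not guarantee performance parity.
* **Fairest composition.** `fairest_composition()` returns the grid point
  minimizing the absolute between-category mean sAUROC gap, ties broken
  toward 0.5. With one rising and one falling law this is the grid point
  nearest the crossing of the two fitted lines — frequently *not* the
  balanced composition.

## Intersectional analysis

`intersectional_report()` applies the sAUROC definition unchanged to joint
subgroups: the TPR always comes from the entire cohort's positives, only
the negatives are restricted to the (catA, catB) cell. Because the
statistic is linear in the negative sample, the marginal sAUROC of a
category is exactly the negative-count-weighted mean of its cell sAUROCs —
an identity the tests assert — and every reported disparity
$\Delta$ is exactly reconstructible from the reported cell metrics.
Conditional disparities ($\Delta$ between the categories of one attribute,
holding the other fixed) are reported signed, with the magnitude being the
conventional $\Delta$; the conditioning category under which an
attribute's $|\Delta|$ is largest is flagged as *amplifying*.

## The synthetic generator

`generate_cohort()` emulates the statistical signature of a UAD model
trained at a given composition, without any model: a sample of category
$s$ with disease label $y$ scores

$$a = \sum_{\text{attributes}} \left[\mu_s + \beta_s (1 - r_s)\right]
      + \delta\, y + \varepsilon,
  \qquad \varepsilon \sim \mathcal{N}(0, \sigma^2),$$

with $r_s$ the category's training representation, $\mu_s$ its baseline
score level (*hardness*), $\beta_s \ge 0$ its sensitivity to missing
representation, $\delta$ the disease shift. The linear mean-shift mechanism
is the simplest one consistent with the empirically observed linear rise of
subgroup anomaly scores as representation shrinks; it is a modelling
choice, not a claim about any particular architecture's internals. Gaussian
noise is chosen because it buys closed-form oracles: with $\beta = 0$ and
equal $\mu$, every subgroup's expected sAUROC is
$\Phi\!\left(\delta / (\sigma\sqrt{2})\right)$, which the tests check
against Monte-Carlo estimates.

**Defaults** (the package's reference simulation conditions): one binary
attribute, $\mu = 0$, $\beta = 0.5$, $\delta = \sigma = 1$, 2000 normals
per category cell, prevalence 0.5, composition grid
$\{0, 0.1, \ldots, 1\}$, 10 seeds. All score parameters are expressed in
noise units ($\sigma = 1$). $\delta = 1$ places baseline performance near
sAUROC 0.76 — the realistic mid-range for screening models, where the
metric is responsive. $\beta = 0.5$ makes a fully unrepresented subgroup
drift half a noise-unit — large enough that the law's slope
(≈ 0.11 sAUROC per unit representation) dominates Monte-Carlo noise at
$n = 2000$ per cell, small enough that the $\Phi$ response stays close to
linear; the analytic curvature bound puts the two-point interpolation MAE
near 0.007, comfortably inside the 0.01 recovery band the tests assert.
Ten seeds per grid point mirror standard repeated-run reporting.

**A constraint on amplification demos.** With purely additive shifts the
direction of intersectional amplification depends on where the response
sits on $\Phi$: when the baseline separation exceeds $\sigma$
(e.g. $\delta = 2$), adverse shifts move the response into the
steeper region, so conditional disparities are *larger* under the adversely
shifted conditioning category — the compound-effect pattern. At
$\delta = 1$ the convexity runs the other way. The amplification
demonstrations therefore use $\delta = 2$ with shifts of $0.5$ on each
attribute, which also yields conditional $\Delta$s (≈ 0.065 vs ≈ 0.042)
of realistic magnitude.

Per-(grid point, seed) RNG streams are derived arithmetically from the base
seed, keeping every stream below $2^{31}$ and all cohorts reproducible
byte-for-byte.

### What the generator does and does not emulate

It reproduces: subgroup score-location shifts linear in missing
representation, the disease shift, hardness differences, compound
two-attribute effects, and seeded run-to-run variability. It does **not**
reproduce: non-Gaussian or heteroscedastic score distributions, per-sample
difficulty correlated with demographics, label noise, patient-level score
correlation (each synthetic patient has one image), or training-dynamics
effects. Passing tests therefore demonstrate the *metrics and workflow* are
correct and sensitive under the stated mechanism — not that any particular
real-world model obeys the mechanism.

## Problem sizes

The test suite and the acceptance script use: 200 random tied cohorts
(n ≤ 40) for the rank-statistic identity; 4 × 20,000-sample cohorts for the
Gaussian closed form; an 11 × 10 sweep at 2000 normals per cell for law
recovery; 10,000 simulations for Welch-null calibration; 20 replicate
experiments for disparity power; and 10 replicate cohorts of 16,000 samples
for the intersectional deltas. These sizes put Monte-Carlo error well below
every asserted band while keeping a full run in the tens of seconds.

## Known limitations

* The sAUROC compares score *rankings* across subgroups; it assumes scores
  are on a common scale across the cohort (true for a single model's
  outputs, not across models).
* Patient-capped sampling guarantees disjointness but means the number of
  images per patient entering a split depends on cell needs; studies
  requiring exactly one image per patient should pre-filter.
* `fairest_composition()` searches the measured grid only; it does not
  interpolate the crossing between grid points.
* The Welch convention for two exactly constant groups (p = 1 on equal
  means, p = 0 otherwise) is a pragmatic boundary rule; such data should
  not arise from any stochastic generator.
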