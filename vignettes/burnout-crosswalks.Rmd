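---
title: "Linking burnout scales to a common metric: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking burnout scales to a common metric: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnoutlink)
```

## The problem

Healthcare organizations measure physician burnout with different
instruments — most commonly the Maslach Burnout Inventory Emotional
Exhaustion (MBI-EE, 9 items coded 0–6) and Depersonalization (MBI-DP, 5
items) subscales, the Stanford Professional Fulfillment Index Work
Exhaustion (PFI-WE, 4 items coded 0–4) and Interpersonal Disengagement
(PFI-ID, 6 items) subscales, and the Mini-Z single-item burnout screen
(MZSIB, one item coded 1–5). Raw scores from different instruments are not
comparable until the scales are *linked*, i.e. statistically placed on one
metric. `burnoutlink` implements a single-group linking pipeline: the same
respondents answer the *target* scale (the one to be re-expressed) and the
*anchor* scale (the one whose metric is held fixed), and a crosswalk table
is estimated mapping each target raw score to an anchor-metric t-score and
an expected anchor raw score. Crosswalks support group-level comparisons
(mean scores, rates above a cut-point); they are not intended to translate
individual respondents' scores, which would be unreliable given the
standard errors involved.

## Model

Items are modeled with Samejima's graded response model (GRM). For an item
with $m$ ordered categories, discrimination $a > 0$, and strictly
increasing thresholds $b_1 < \dots < b_{m-1}$, the boundary curves are
logistic,

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}},$$

and the probability of category $k$ is the adjacent difference
$P_k = P^*_{k-1} - P^*_k$ (with $P^*_0 = 1$, $P^*_m = 0$). We use the
logistic metric without the historical 1.7 scaling constant; because the
simulator, estimator, and scoring functions share the convention, every
t-metric quantity is invariant to this choice. The latent trait $\theta$
is reported as a t-score $t = 50 + 10\,\theta$, so 50 is the mean and 10
the standard deviation of the population in which the anchor was
calibrated.

### Fixed-parameter calibration linking

`grm_calibrate()` maximizes the marginal likelihood by EM over a fixed
quadrature grid. With no fixed items the latent density is pinned to
N(0, 1) for identification. In linking runs the anchor item parameters are
supplied and held fixed while the target items and the normal latent mean
and SD are free; freeing the density is what places the target parameters
on the anchor metric even when the linking sample differs from the anchor
calibration population. `irt_link()` then builds the crosswalk as

1. summed-score EAP on the target items: for each raw score $s$,
   $\hat\theta_s = E[\theta \mid \mathrm{raw} = s]$ via the Lord–Wingersky
   likelihoods (`summed_score_likelihoods()`) and Bayes' rule on the grid;
   $t_s = 50 + 10\hat\theta_s$, $\mathrm{se}(t_s) = 10\,\mathrm{sd}(\theta
   \mid s)$;
2. the anchor test characteristic curve at $\hat\theta_s$ gives the
   expected anchor raw score $r_s$ (non-integer, as expected-score
   mappings are).

The conversion-table prior is N(0, 1) — the anchor calibration population —
rather than the sample density estimated during fixed calibration; this
makes the table a property of the anchor metric and makes self-linking
exactly reproduce the anchor's own raw-to-t table. The estimated density
is available via `prior = "estimated"` for sensitivity analysis.

### Equipercentile linking

`equipercentile_link()` matches mid-point-continuized percentile ranks
(the Kolen–Brennan convention): $PR_X(s) = 100[F(s-1) + f(s)/2]$, inverted
through the continuized anchor CDF. Zero-frequency scores inside the range
produce flat CDF stretches; the inverse takes the midpoint of a flat
stretch. No presmoothing is applied by default; optional log-linear
presmoothing (`smooth = degree`) is available because sparse tail scores
can otherwise dominate the tail of the mapping. t-scores are attached by
linear interpolation in the anchor raw-to-t table, so both methods report
on the same anchor IRT metric.

## Accuracy evaluation

`kfold_cv()` implements fivefold cross-validation: folds are seeded and
stratified on target raw-score quintiles (stabilizing sparse score levels);
for each fold the crosswalk is rebuilt on the other folds, and held-out
respondents' predicted t-scores (crosswalk at their target raw score) are
pooled against actual t-scores (pattern-level EAP from their anchor
responses under the fixed anchor parameters — the stricter comparator;
`actual = "summed"` switches to summed-score EAP). The pooled correlation,
mean difference (predicted − actual), and SD of the difference summarize
accuracy, and `select_method()` declares a winner only when one method has
the highest correlation, lowest absolute mean difference, and lowest SD
for *every* item set; otherwise it reports an explicit indeterminate
status.

## Cut-point equivalencies

Anchor cut-points are raw-score rules (e.g. emotional exhaustion raw ≥ 27,
depersonalization raw ≥ 10) with known t-scores on the anchor metric.
`closest_cutpoint()` returns the target raw score whose crosswalk row is
closest to the cut. When the anchor raw cut is supplied the match is made
on the predicted anchor raw-score column, because the cut is defined on
the raw metric and the published equivalencies across all item sets are
jointly consistent only under raw-score matching; matching on the t column
is available (`match = "t"`) and usually agrees, differing only when a cut
t falls nearly halfway between adjacent rows. Ties break toward the lower
raw score, the more sensitive screening choice. `cross_target_cutpoint()`
maps cuts between two targets linked to the same anchor metric and
*refuses* crosswalks whose anchor metrics differ — scores linked to the
exhaustion metric and to the depersonalization metric are not comparable.

## Inclusion rule and prorated totals

Respondents with at most one missing item response per scale (and at least
one observed item) are retained, matching common practice for these
instruments. A retained respondent with one missing item gets a prorated
raw total: round-half-up of (observed mean × item count). Round-half-up is
used rather than banker's rounding so proration is monotone in the
observed total. During likelihood-based calibration and EAP scoring,
missing responses are simply omitted (an MAR treatment); no imputation is
performed.

## Conditional reliability

`reliability_curve()` reports $\mathrm{rel}(\theta) = 1 - 1/I(\theta)$,
i.e. one minus the squared standard error relative to unit population
variance, floored at 0, across the anchor t-metric (default grid t = 20–80
by 0.5). The conventional adequacy thresholds are 0.70 for group-level and
0.90 for individual-level assessment; `reliable_range()` extracts the
maximal t-intervals above a threshold. Under this formula a single item
with discrimination ≤ 2.5 can never reach 0.70, which is why single-item
screens are adequate for screening but not for outcome measurement.

## Assumption checks

Linking presumes the two scales measure essentially one construct.
`assumption_check()` reports (1) the Pearson correlation of the
(prorated) raw totals, flagged against 0.75, and (2) a unidimensionality
screen: the ratio of the first to second eigenvalue of the polychoric
correlation matrix of the pooled items, flagged against 3. The polychoric
correlations are two-step maximum likelihood (thresholds from the
univariate margins, correlation by optimizing the bivariate-normal table
likelihood, with the bivariate normal CDF evaluated by 48-node
Gauss–Legendre quadrature). The eigenvalue screen is a deliberately
lightweight replacement for a full confirmatory factor analysis: it is
estimator-free, deterministic, and adequate for flagging gross
multidimensionality, but it is not a fit test.

## Subgroup invariance

`subgroup_invariance()` reruns the full linking separately in two
subgroups (e.g. early versus late survey responders, the usual proxy for
non-response bias) and compares the crosswalk t columns row by row. Under
a correctly specified model the crosswalk is a property of the item
parameters, not the population, so even a subgroup with a shifted trait
mean should produce the same table — the fixed-calibration step absorbs
the shift into the freed latent density. The default flag threshold of 3
t-units (0.3 SD) is a package default chosen as roughly the magnitude at
which a cut-point equivalency could move by one raw score; there is no
field-standard numeric criterion.

## The synthetic-data generator

`default_study_fixture()` emulates the structure the pipeline assumes: by
default 1355 respondents answer all five scales in one sitting, with the
target- and anchor-driving traits of each item set drawn from a bivariate
normal. Defaults and their rationale:

* `construct_correlation = 0.93`: with the fixture's item reliabilities
  this yields raw-score correlations near 0.78–0.84 for the multi-item
  item sets, the range reported for these instruments in practice. The
  single-item screen attenuates to about 0.65–0.70 — a single item with
  discrimination capped at 2.5 cannot reach 0.76, a known limitation of
  the fixture rather than of the method.
* Item parameters are invented, deterministic constants with
  discriminations in [1, 2.5] and thresholds spread over about
  [−2.5, 2.5], so raw-score distributions are non-degenerate; they are
  fixtures, not estimates of any real instrument's parameters.
* `missing_rate = 0.01` MCAR: real surveys of this kind have sparse item
  missingness; 1% is a guess in the absence of a published rate, and
  MCAR is assumed because no mechanism is documented.
* The subgroup label is assigned independently of the trait; the
  `subgroup_shift` knob creates a detectable trait shift for
  non-invariance testing.

Passing tests on this generator show the machinery is correct under the
model's own assumptions (normal traits, GRM responses, MCAR missingness).
They do not show robustness to multidimensionality, non-normal trait
distributions, informative missingness, or item drift between
populations — the situations the assumption checks and invariance tools
are there to detect.

## Numerical choices

* Quadrature: 61 equally spaced nodes on [−6, 6] with normalized prior
  weights; the test-suite's independent oracles use 2001 nodes on [−8, 8].
* EM: convergence when the maximum absolute parameter change is below
  1e-4, cap 500 cycles (non-convergence is a warning and a flagged
  result, never silent); M-step per-item BFGS on the reparameterization
  log a, b1, log-diffs, which keeps thresholds ordered by construction.
* Start values: a = 1, thresholds from inverse-logistic cumulative
  category proportions.
* Empty categories in free items are collapsed into the adjacent lower
  category with a recorded recode map (strict mode aborts instead).
* Raw scores with vanishing marginal probability in a conversion table
  are flagged rather than dropped.

## Problem sizes in the shipped tests

The package's own test-suite exercises calibration recovery at n = 2000
(three seeds), fixed-calibration density recovery at n = 5000, fivefold
cross-validation at n = 5000, and Monte-Carlo scoring checks at 2×10^5
draws; these sizes give sampling error comfortably below the asserted
tolerances while keeping the default test run fast.

## Known limitations

* The GRM is unidimensional per item set; no differential-item-functioning
  or multidimensional analysis is provided.
* Equipercentile standard errors are not computed (the `se_t` column of an
  equipercentile crosswalk is `NA`).
* The fixed-calibration latent density is normal with free mean/SD, not an
  empirical histogram; this is identifiable and standard but can misfit
  strongly skewed populations.
* Crosswalks are for aggregate, group-level use only.
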