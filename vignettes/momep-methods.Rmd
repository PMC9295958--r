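---
title: "Multi-objective MEP classifiers: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective MEP classifiers: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momep)
```

`momep` evolves binary classifiers for grayscale medical images with
multi-expression programming (MEP), a linear flavour of genetic programming,
under an NSGA-II style multi-objective search, and ships the surrounding
apparatus: image descriptors, Pareto-front voting, data-complexity measures
and a non-parametric comparison suite. This vignette is the package's own
account of the science: the model, the conventions it fixes where the method
leaves choices open, and what the synthetic benchmarks do and do not show.

## The classification model

An instance is a vector of `m` real features with a label in {-1, +1}
(+1 = pathology present). An MEP chromosome is an ordered list of `L` genes;
each gene is a terminal (a feature reference or a real constant) or an
arithmetic operator whose operands strictly precede it. Every gene is
therefore the root of a valid expression, so a single genome encodes `L`
candidate classifiers and one forward pass evaluates all of them in
`O(L n)`. A gene's raw output is squashed by the sigmoid into `[0, 1]` and
thresholded: an instance is predicted positive iff its score strictly
exceeds the threshold, so `t = 1` is the all-negative classifier.

Two measures drive the search:

* the **X measure** scores each of the `L` sub-expressions and picks the
  best one inside a chromosome (ties go to the earliest gene);
* the **Y objectives** form the multi-objective fitness of that best
  sub-expression; all components live in `[0, 1]` and are maximized.

The four pairings are fixed:

| model | X (selects the sub-expression) | Y (NSGA-II objectives)            | #objectives |
|-------|--------------------------------|-----------------------------------|-------------|
| A     | mean accuracy over the grid    | accuracy at each grid threshold   | `|grid|`    |
| B     | AUC over the grid              | TP-rate means in fixed FP-rate bins | `n_bins`  |
| C     | geometric mean at one threshold| (sensitivity, specificity)        | 2           |
| D     | mean of per-threshold GMs      | GM at each grid threshold         | `|grid|`    |

Model C is defined on a single threshold (default 0.5); the others use the
pre-established grid, by default the 10 values 0.05, 0.15, ..., 0.95. The
number and placement of the pre-established thresholds is not pinned by the
method's description, so the grid is a reported, configurable parameter.

### Conventions the equations leave open

* **Empty classes.** Sensitivity (specificity) is 0 when the positive
  (negative) class is empty, and a geometric mean with an undefined factor
  is 0. This keeps every objective total and penalizes degenerate splits.
* **Model B's histogram.** The objective's name mentions TP/FN rates but
  its construction fixes FP rates on the x-axis; we implement the
  construction: equal-width FP-rate bins over `[0, 1]` (last bin
  right-closed), each bin reporting the mean TP rate it received, empty
  bins 0.
* **AUC.** Computed from the grid's (FP-rate, TP-rate) points anchored at
  (0,0) and (1,1), trapezoid rule after sorting by FP rate. On a dense grid
  this coincides with Mann-Whitney pair counting (a tested equivalence).
* **Function set.** The method names arithmetic operators but never lists
  them; the default is `{+, -, *, /, min, max}` with protected division
  (returns the numerator when the denominator's magnitude is below 1e-12).
  Raw gene values are clamped to 1e6 in magnitude so that evaluation is
  total and the sigmoid never sees a non-finite value.
* **Constants.** Terminals may be uniform random constants, default range
  `[-1, 1]`.
* **Hyperparameters.** Defaults (all exposed): `L = 30`, population 100,
  generations 100, crossover probability 0.9, per-gene mutation probability
  0.05, binary tournament.

## The search

The loop is elitist (mu + lambda). Fitness is the **dominance rank**: the
number of population members that dominate a solution, exactly as the
method words it (a dominance *count*, not canonical front-peeling; the two
agree on the rank-0 set, which is all a run returns). Diversity uses a
**crowding distance**: on each objective a solution's contribution is the
mean of its distances to the nearest other value at-or-below and
at-or-above it, averaged over objectives. The wording does not address
boundaries, so we keep the canonical behaviour: holders of an extreme value
on any non-degenerate objective get `+Inf` (fronts of one or two solutions
are all `+Inf`), and zero-range objectives contribute 0. Exact duplicates
contribute 0 on the duplicated coordinates. Survivor selection and
tournaments order by (rank ascending, crowding descending) with the genome
serialization string as a documented deterministic tie-break. Duplicate
objective vectors stay in the population but collapse to one representative
in any reported front.

A "dominance model between two classifiers" is referenced by the method
without specification; standard Pareto dominance is used and the comparison
is a single, replaceable function (`dominates()`).

## Voting and the evaluation protocol

A trained run returns a Pareto front. At test time the front votes: the
electorate is every (classifier, threshold) pair — this is the only reading
under which "considering all examined threshold values" makes thresholds
enter the test-time vote. The majority label uses the floor formula
`floor(1/2 + (sum - 1/2)/r)`, which is 1 iff strictly more than half the
voters say 1; even-electorate ties therefore resolve to 0 (negative). The
accompanying prose rule resolves ties to positive instead and is available
behind `rule = "ties_positive"`. An ensemble AUC needs scores, which voting
does not produce; the vote *fraction* serves as the ensemble score — an
artifact convention, reported as such.

The protocol: per run, a seeded stratified split into `round(2n/3)`
training and the remaining third test instances (explicit split sizes can
override the rounding to mirror published splits such as 212/107), one
evolutionary run, one voted evaluation; accuracy/AUC are averaged over
runs. The per-run fronts are then pooled, re-filtered to the non-dominated
subset (the *general Pareto front*) and voted again; since runs have their
own test sets, the general front is voted on each run's test set and the
accuracies averaged.

The strategy comparison pits this simultaneous multi-objective search
against plain voting built from the *same objectives*: one independent
single-criterion run per objective component, all resulting specialists
pooled into one voting ensemble. For a single-objective model the two arms
coincide.

## Image descriptors

* **Moments** — mean, standard deviation, skewness, kurtosis, minimum,
  maximum of the intensities. Population (biased) moments, kurtosis as
  excess; zero-variance images return skewness = kurtosis = 0. Fixed
  because the choice is otherwise undocumented.
* **HOG** — square-root gamma normalization, `[-1, 0, 1]` central
  differences with replicated borders, unsigned orientations in `[0, pi)`,
  per-cell histograms with linear interpolation between bin centres at
  `k pi / n_bins`, block normalization (L2 default, additive stabilizer),
  concatenation over block strides. The full-scale mammogram
  parameterisation (720 x 1152 window, 16 x 16 block, 8 x 8 cell, 8 bins)
  is expressible; the default window is 64 x 64, which keeps the descriptor
  informative at a fraction of the cost. The published feature count of
  458,172 per image is not matched by any standard HOG length formula with
  the stated parameters, and no attempt is made to match it.
* **Kernel descriptors** — a single-level gradient match kernel: patch
  similarity is a sum over pixel pairs of normalized gradient magnitudes
  (divided by `sqrt(mean-square magnitude + contrast^2)`, contrast 0.8)
  weighted by Gaussian kernels over orientation unit vectors and normalized
  positions. Patches are embedded against a seeded, uniformly sampled basis
  (a Nystroem-style finite-dimensional approximation), averaged over a grid
  lattice and compacted by kernel PCA to `kdesdim` components. Hierarchical
  and colour/LBP kernels are out of scope. Basis size and kernel bandwidths
  (orientation 0.5, position 0.3) are free parameters of this construction,
  chosen once at values that keep the Gram matrix well-conditioned on
  8-16 pixel patches.

## Data complexity

`F1` is the maximum per-feature Fisher discriminant ratio
`(mu_pos - mu_neg)^2 / (var_pos + var_neg)` (population variances; mean
aggregation available — published values are too small to disambiguate the
aggregator). `N2` is the ratio of summed nearest same-class to nearest
other-class distances. `T2` is `n / (m + 1)`: the published per-split
values for six-feature moment tables (30.2857 for 212 training points)
force the denominator to count the label column; the bare `n / m` form is
a flag away.

## The comparison suite

Wins/ties/losses, the sign test, Wilcoxon signed-ranks, Friedman,
Iman-Davenport and Nemenyi are implemented from their defining equations
rather than delegated, because the tie and zero conventions are part of
the method: sign-test wins count ties as wins for the first algorithm
("better or the same"; half-tie counting behind a flag), Wilcoxon zero
differences contribute half their rank to each sum, and the exact one-sided
p-value `P(rank sum <= T)` comes from the null distribution over sign
assignments of the nonzero differences (convolution; full enumeration is
the test oracle), switching to the normal approximation beyond N = 25.
Base R's `friedman.test` and `wilcox.test` serve as independent
cross-checks in the test suite. Nemenyi uses the published q constants for
k = 2..10 at alpha 0.05/0.10; `CDf = q sqrt(k(k+1)/(6 N))`, and
`autoplot()` renders the critical-difference diagram. The Friedman decision
defaults to the chi-squared quantile at `k - 1` degrees of freedom with an
override for exact-table critical values (published analyses sometimes use
7.7 rather than 7.815 at three degrees of freedom).

## The synthetic generator

Real mammogram repositories cannot be bundled, so a seeded generator
stands in. Feature tables are two spherical Gaussians separated by a
configurable mean shift — the simplest geometry with a known Bayes
boundary (a 3-sigma shift on one feature puts the Bayes accuracy near
0.93). Images are Gaussian-noise backgrounds plus, for positives, an
additive Gaussian-blurred disc — the simplest lesion that leaves a
signature in moments, gradient histograms and kernel descriptors alike.
Labels are written as -1/+1; the positive count is exactly
`round(n * positive_fraction)`; every image draws from its own seed
sub-stream.

What this does *not* emulate: mammographic anatomy, calcification/mass
subtypes, intensity heterogeneity between acquisition systems, label
noise, or the strong class imbalance of clinical archives. Passing the
learning checks therefore shows that the pipeline can extract a real
signal end-to-end and that its components compose correctly — not that the
method reaches clinical accuracy on real images.

## Problem sizes, and what the seeded checks show

The test suite runs at deliberately small scales: descriptor checks on
8-64 pixel images; oracle equivalences on 100 random instances each
(50-member populations for dominance ranks, dense 1000-point threshold
grids for AUC, full `2^N` enumeration up to N = 12 for Wilcoxon); learning
checks on `n = 300`, `m = 6`, 3-sigma separation with population 60 over
50 generations and 3 runs; the suite's global-null calibration uses 200
random 12 x 4 tables.

A property worth stating plainly: with many objectives (models A, B and D
carry 10), large parts of a population become mutually non-dominated, the
front fills with threshold-specialists, and the all-thresholds voting
electorate dilutes. Model B is the extreme case — an all-positive
classifier occupies an FP-rate bin no good classifier touches, so it is
*never* dominated and always votes. On the easy synthetic benchmark model
B's voted ensemble therefore sits well below what its best single front
member achieves (which is routinely above 0.95 accuracy) and below the
other three models. The learning checks in
`tests/testthat/test-acceptance.R` assert a uniform accuracy level for all
four models anyway and are allowed to fail loudly for model B rather than
be weakened: a red result there documents the method's behaviour, not a
broken implementation — the oracle-equivalence tests pin the components.

## Known limitations

* Many-objective dilution of the voted ensemble, as above.
* The KD implementation is the single-level gradient kernel only, with a
  direct (quadratic in patch size) match-kernel evaluation — adequate at
  package scales, not for full mammograms.
* Constants are drawn once per gene from a fixed range; there is no local
  search over constants.
* The general Pareto front pools objective vectors measured on different
  training splits; their mutual dominance comparison inherits that noise.
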