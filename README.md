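# momep

Multi-objective evolution of interpretable binary classifiers for grayscale
medical images, with the surrounding apparatus needed to study them:
image descriptors, Pareto-front voting ensembles, data-complexity measures
and a non-parametric classifier-comparison suite.

## The problem and the method

Automated mammogram triage is a binary classification problem: given an
image summarised by `m` real features, predict pathological (+1) or healthy
(-1). `momep` attacks it with **multi-expression programming (MEP)**, a
linear flavour of genetic programming: a chromosome is an ordered list of
`L` genes, each either a terminal (feature `F_k` or a constant) or an
arithmetic operator over earlier genes, so every gene is the root of a
candidate expression and one genome encodes `L` classifiers at once. A
gene's output is squashed to `[0, 1]` by the sigmoid and thresholded
(`positive iff score > t`).

The search is an NSGA-II style elitist loop. Inside a chromosome an
**X measure** picks the best sub-expression; that sub-expression's
**Y objective vector** is maximized under Pareto dominance with
dominance-count ranks and crowding-distance diversity. Four
objective-combination models are built in:

| model | X | Y |
|---|---|---|
| A | average accuracy over the threshold grid | per-threshold accuracies |
| B | AUC over the grid | TP-rate means over fixed FP-rate bins |
| C | geometric mean (GM) of class accuracies at one threshold | (sensitivity, specificity) |
| D | average per-threshold GM | per-threshold GMs |

A run returns the Pareto front; at test time the front votes with one
ballot per (classifier, threshold) pair, the majority label given by
`floor(1/2 + (sum - 1/2)/r)`. The evaluation protocol averages voted
accuracy/AUC over seeded two-thirds/one-third splits and also votes the
cross-run *general Pareto front* (the non-dominated subset of the pooled
fronts). Alongside, the package computes the data-complexity measures F1
(maximal per-feature Fisher discriminant ratio), N2 (intra/inter
nearest-neighbour distance ratio) and T2 (points per dimension,
`n / (m + 1)`), and a full comparison battery: wins/ties/losses, sign test,
exact Wilcoxon signed-ranks, Friedman, Iman-Davenport and Nemenyi with
critical-difference diagrams.

Real mammogram repositories are not bundled; a seeded synthetic generator
produces grayscale images (Gaussian background plus blurred-disc lesions)
and feature tables (two shifted Gaussians) with controllable separation,
imbalance and noise. See `vignettes/momep-methods.Rmd` for the full account
of models, conventions and limitations.

## A worked example

```r
library(momep)

# a 300-instance, 6-feature problem with a 3-sigma shift on feature 1
d <- sim_features(n = 300, m = 6, class_mean_shift = c(3, 0, 0, 0, 0, 0), seed = 42)
parts <- split_data(d, seed = 42)
complexity_report(parts$train, parts$test)
#> # A tibble: 2 × 6
#>   split     n     m    F1    N2    T2
#>   <chr> <int> <int> <dbl> <dbl> <dbl>
#> 1 train   200     6  6.19 0.608  28.6
#> 2 test    100     6  5.48 0.607  14.3

pr <- run_protocol(d, model_spec("C"), n_runs = 3, seed = 42,
                   population_size = 60, generations = 50)
pr
#> <momep_protocol> model C, 3 runs
#>   average voted test accuracy: 0.9300 (AUC -)
#>   general-front (optimal) accuracy: 0.9500 (AUC -); front size 3
```

The complexity table says the problem is easy (F1 ≈ 6: one feature alone
nearly separates the classes; N2 < 1: points sit closer to their own class
than to the other; T2 ≈ 29 training points per dimension). The protocol
then reports the two ensemble measures: the voted test accuracy averaged
over the three runs (0.930) and the accuracy of voting the general Pareto
front pooled from all runs (0.950) — at the Bayes accuracy of about
0.93 for a 3-sigma shift. Model C keeps a single decision threshold, so no
ensemble AUC is reported for it.

The comparison suite works on any problems-by-algorithms performance
table:

```r
tab <- cbind(A = c(61.28, 46.86, 50.41, 9.20), B = c(49.16, 49.48, 47.77, 40.15),
             C = c(41.74, 53.19, 51.69, 63.68), D = c(54.89, 49.77, 49.16, 38.59))
fr <- friedman_rank_test(tab)
fr
#> Friedman: chi2_F = 2.1000 (df = 3), critical 7.8147, p = 0.5519
#>    A    B    C    D 
#> 2.75 3.00 1.75 2.50
autoplot(nemenyi(fr))   # critical-difference diagram
```

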