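---
title: "Filter and metaheuristic feature selection for clinical risk tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter and metaheuristic feature selection for clinical risk tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioselect)
```

## The problem

Clinical risk tables such as the 13-predictor Cleveland heart-disease data
mix a handful of genuinely prognostic variables with attributes that carry
little signal for the outcome. cardioselect implements the two standard
ways of finding the informative subset and makes them comparable under one
evaluation harness:

* **filter selection** — univariate scores (chi-square, mutual information,
  ANOVA F) computed directly from feature/outcome statistics, aggregated
  into one overall ranking, with top-k selection;
* **wrapper selection** — a search over binary feature-inclusion masks
  guided by the cross-validated error of a trained model, here carried out
  by three metaheuristics: a genetic algorithm (GA), a binary particle
  swarm (PSO), and an ant colony system (ACO).

All user-facing functions take a data frame of predictors and a 0/1 label
vector and return tibbles, so the stages chain with the pipe.

## The wrapper fitness

All three metaheuristics maximize the same quantity,

$$f(x) = \frac{1}{1 + g(x)},$$

where $g(x) \ge 0$ is the error of a wrapped model restricted to the
feature subset $x$. Since $g \ge 0$, $f \in (0, 1]$, is strictly
decreasing in $g$, and equals 1 exactly when the subset predicts
perfectly. The default $g$ is the root-mean-squared error of a
random-forest regressor predicting the 0/1 label, estimated from the
forest's out-of-bag samples. Out-of-bag error was chosen over an inner
cross-validation because it needs a single forest fit per subset, is an
honest out-of-sample estimate, and — with a fixed forest seed — makes the
fitness of a mask a *deterministic* function of the data. That determinism
is exploited by `fitness_function()`, which memoises fitness per mask:
late in a search (and across repeated runs on the same cohort) most
proposed subsets have been seen before, and the search cost collapses to
the number of *distinct* masks visited. The objective is pluggable: any
function `(data, labels) -> error` can replace the forest, and the
unit tests drive the optimizers with a cheap least-squares probe.

An empty subset is never scored; every operator that could produce an
all-zero mask repairs it by switching one uniformly chosen bit on.

## The filter stage

`chi_square_scores()` uses the class-sum convention: per feature, the
"observed" values are the per-class sums of the (nonnegative) feature, the
"expected" values split the feature's total in proportion to class sizes,
and the statistic is $\sum_c (O_c - E_c)^2 / E_c$. This is the standard
top-k chi-square filter for tabular features: it requires no binning
policy, at the price of treating the feature as a count-like quantity
(hence the nonnegativity requirement; `filter_rank()` shifts
negative-valued features by their minimum for this filter only).

`anova_f_scores()` is the one-way ANOVA F statistic,
$F = (\mathrm{SSB}/df_1)/(\mathrm{SSW}/df_2)$ with $df_1 = k - 1$ and
$df_2 = n - k$ for $k$ classes. A feature that is constant within classes
but differs between them has $\mathrm{SSW} = 0$; it is reported as `Inf`
and ranks above every finite score, which is the only ordering consistent
with "larger F is better".

`mutual_info_scores()` estimates $I(X;Y)$ in nats. Nominal features use
the plug-in estimate over the empirical contingency table. Numeric
features use a nearest-neighbour estimator (3 neighbours by default) of
the Ross type for continuous–discrete pairs, with a seeded micro-jitter
($10^{-10}$ of the feature scale) breaking ties; estimates are clipped at
zero since mutual information is nonnegative.

`aggregate_ranks()` sums the three raw scores per feature and ranks by
the descending total. The published reference table this package ships
(`cleveland_reference_scores()`) presents exactly this structure: its
Total column is verifiably the row sum of the three score columns and its
rank column is monotone in the total, so summed raw scores — not summed
per-filter ranks — is the aggregation implemented. Ties break toward the
earlier feature in schema order, deterministically. Two printed rows of
the reference table (`cp`, `thal`) are arithmetically inconsistent with
their own score columns; they are flagged in the shipped CSV and excluded
from exact-reproduction checks.

No attempt is made to reproduce the reference table's *absolute* scores
from the raw Cleveland file: they depend on an unstated preprocessing.
Only the aggregation from printed scores onward is treated as exactly
reproducible.

## The three searches

**GA** (`run_ga()`): population of 20 bit-string chromosomes, 50
generations (100 for longer runs). Parents are drawn by
fitness-proportional selection within a random subset of 5 individuals;
every pair undergoes single-point crossover; each gene flips with
probability `per_gene_mutation_prob`. The published mutation settings
1000/100/5 are read as flip probabilities 1/1000, 1/100 and 1/5 — the only
reading that maps all three onto $[0,1]$ — with 1/100 as default. One
elite individual is carried forward unchanged; elitism is not part of the
published parameter block, but it makes the best-fitness trace provably
non-decreasing (the property the tests assert) and can be disabled.

**PSO** (`run_pso()`): particles carry continuous positions and velocities,
one dimension per feature. The velocity update is
$v' = w v + c_1 r_1 (p - x) + c_2 r_2 (p_n - x)$ with $w = 0.9$,
$c_1 = c_2 = 0.5$, independent uniform draws per component per term, and
the position update is $x' = x + v'$. The neighbourhood best $p_n$ is
taken over each particle's $k = 30$ nearest particles (self included)
under the Minkowski norm of order $P = 2$ on positions. Because the
updates are continuous but the problem is a subset search, a transfer
rule is needed: a mask bit is sampled as 1 with probability
$S(x_d) = 1/(1+e^{-x_d})$ — the standard binary-PSO construction.
Velocities *and* positions are clamped to $\pm 6$, the range where the
sigmoid is effectively saturated, so no bit's probability ever freezes at
exactly 0 or 1. Swarm size is not part of the published block; the
default of 40 keeps a 30-neighbour topology meaningful.

**ACO** (`run_aco()`): features are independent nodes. An ant picks
features without replacement with probability
$P(i) \propto \tau(i)^\alpha \eta(i)^\beta$ ($\alpha = 1, \beta = 2$),
renormalized over the remaining candidates after each roulette draw.
After each iteration the trail evaporates and receives deposits,
$\tau(i) \leftarrow \rho \tau(i) + \sum_k \Delta\tau_k(i)$ with
$\rho = 0.5$; ant $k$ deposits its fitness on every feature of its subset
(the classical Ant System rule — the deposit magnitude is a design choice
here, kept commensurate with the $1/(1+g)$ fitness). The heuristic
$\eta(i)$ is the min–max-normalized ANOVA F score of feature $i$, floored
at 0.01 so every feature remains reachable; a per-feature desirability is
the conventional meaning of heuristic information in ACO feature
selection. Trails are floored at $10^{-6}$, keeping every selection
probability positive. The subset size per ant is a parameter; by default
it is drawn once per run uniformly between $\lceil d/2 \rceil$ and
$d - 1$, reflecting that published runs reduced 13 features to 9–10
without stating the size in advance. Deposits come from all ants by
default; an iteration-best variant is available by configuration.

## Evaluation harness

`evaluate_subset()` trains any of nine registered classifiers (logistic
regression, kNN, SVM, naive Bayes, random forest, grid-searched random
forest, gradient boosting, decision tree, neural network — all delegated
to established implementations) on a masked feature set under a seeded
protocol, by default stratified 5-fold cross-validation. Confusion counts
and class-1 scores are *pooled* over folds before metrics are computed;
pooling avoids per-fold metrics with zero denominators and makes the
counts sum exactly to the cohort size. The metric set is precision,
recall, specificity, accuracy, F-score, the classification error rate
(`100 - 100*accuracy`) and the rank-based (Mann–Whitney) AUC. The
grid-searched forest explores trees {100, 200, 500} × max depth {3, 5,
unlimited} × min leaf {1, 5}, chosen by internal 3-fold CV accuracy.

The holdout alternative and all seeds are explicit, so every number the
harness produces is reproducible. No claim is made about matching any
externally published accuracy on the Cleveland data: the train/test split
behind such numbers is unstated, so the package's own tests instead
verify metric identities, oracle agreement, and recovery behaviour
(below), plus the qualitative property that wrapper-selected subsets stay
within a few accuracy points of the all-feature baseline.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws a cohort shaped like the Cleveland table: five
numeric vitals from normal distributions (clamped to the schema's
physiological bounds where declared, e.g. ST depression at 0) and eight
nominal attributes from categorical distributions over the distributed
integer codes, with marginals close to the real table's. The label is
Bernoulli with probability
$\mathrm{logit}^{-1}(\beta_0 + \sum_{j \in S} \beta_j z_j)$ over
*standardized* features, so coefficients are comparable across numeric
and coded-nominal features. Everything outside the informative set $S$ is
independent of the label by construction. The default is $n = 500$ with
three informative features (`thalach` $\beta = -1.5$, `oldpeak`
$\beta = +1.5$, `cp` $\beta = +1.0$ — signs matching the clinical
direction of these variables) and ten noise features.

The generator deliberately does **not** model correlations between
predictors, nonlinearity, or interactions. Passing recovery tests on
these cohorts therefore shows that the searches find *independent*
additive signal; it does not certify behaviour under collinear predictors,
where wrapper methods may legitimately drop one of two redundant
informative features.

The recovery experiment the acceptance checks run: one seeded $n = 500$
cohort; 20 runs per optimizer (GA population 20 × 50 generations; PSO
100 iterations — reduced from the 1000-iteration default, which adds
nothing on a 13-bit space; ACO 100 iterations × 5 ants) against one
shared memoised fitness (100-tree forests); the mean selection frequency
over informative features must exceed the mean over noise features by at
least 0.2. Observed margins are far clearer than that bound for GA and
PSO (≈ 0.7; informative frequency 1.0) and clear it for ACO (≈ 0.3),
whose margin is structurally compressed because each ant must select
`n_select` ≈ 7–12 of 13 features, forcing a high noise baseline.

## Numerical choices and degenerate inputs

* Chi-square: zero feature total scores 0 with a warning; negative input
  errors (shift/scale first).
* F statistic: zero within-group variance reports `Inf` (warned), which
  sorts above all finite scores; zero between- and within-group variance
  scores 0.
* Undefined metric ratios (empty prediction margins) report 0 with a
  warning rather than `NaN`.
* Rank ties: `ties.method = "first"` throughout — earlier feature wins —
  so rankings are permutations and runs are reproducible.
* All stochastic operators accept an explicit seed and restore the
  caller's RNG state; low-level operators (`mutate_mask()`,
  `roulette_select()`, ...) draw from the surrounding stream when no seed
  is given, which is how the run functions compose them.
* Mode imputation (the default missing-value strategy) keeps all rows of
  a Cleveland-dialect table, consistent with downstream record counts on
  the full 303-record table; row dropping is available by flag. Which of
  the two the original analyses used is not stated anywhere; both are
  first-class.

## Problem sizes used by the shipped checks

Unit tests drive the search logic with a 150-patient cohort and a
least-squares objective; oracle checks use 100 random tables of at most
20 rows × 5 features, 1,000 random confusion matrices, and 10,000-draw
frequency tests. The acceptance script and the end-to-end tests run the
full recovery experiment described above (≈ 60 optimizer runs, a few
thousand distinct forest fits after memoisation) and a 5-fold
cross-validated comparison of selected subsets against the all-feature
baseline on the same cohort. These sizes were chosen as the smallest that
exercise every code path at the study's stated conditions.

## Known limitations

* The chi-square filter's class-sum convention is scale-dependent;
  features on large scales get large scores. That matches the reference
  aggregation's behaviour (raw-score totals are dominated by large-scale
  features) but means the *filter* ranking is not scale-invariant.
* The continuous-position binary PSO is one of several defensible
  binarizations; transfer-function shape changes exploration behaviour.
* ACO's heuristic definition follows the normalized-filter-score reading;
  the phrase it interprets is ambiguous in its source, and a
  frequency-based heuristic would behave differently on the first
  iterations.
* The wrapper objective regresses on a 0/1 target with a forest
  regressor (as specified by the published parameter block) rather than
  classifying; `objective` is pluggable for users who prefer
  misclassification- or log-loss-based fitness.
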