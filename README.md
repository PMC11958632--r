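# cardioselect

Feature selection for binary clinical risk classification, built around
the 13-predictor Cleveland heart-disease table (and any table with the
same shape: numeric and coded-nominal predictors plus a 0/1 outcome).

Clinical tables mix a few genuinely prognostic variables with attributes
that carry little outcome signal. cardioselect implements both standard
routes to the informative subset and one harness to compare them:

* a **univariate filter stage** — chi-square, mutual information and
  ANOVA F scores per feature, aggregated into one overall ranking with
  top-k selection;
* three **metaheuristic wrapper searches** over binary
  feature-inclusion masks — a genetic algorithm, a binary particle
  swarm, and an ant colony system — all maximizing the wrapper fitness

  ```
  f(x) = 1 / (1 + g(x))
  ```

  where `g(x) >= 0` is the out-of-bag RMSE of a random-forest regressor
  restricted to subset `x` (pluggable);
* an **evaluation harness** with stratified cross-validation, pooled
  confusion-matrix metrics (precision, recall, specificity, accuracy,
  F-score, classification error %) plus rank-based AUC, and a registry
  of nine classifiers (LR, KNN, SVM, NB, RF, grid-searched RF, XGB,
  decision tree, neural net) delegated to established implementations;
* a **synthetic cohort generator** with a logistic outcome model and
  known informative features, so the whole pipeline is testable without
  any download.

Everything takes a data frame first and returns tibbles; results have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(cardioselect)

# a Cleveland-shaped cohort with known signal: thalach, oldpeak and cp
# are informative, the other ten features are noise
cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 42))
labels <- cohort$labels

# filter stage: three univariate scores, aggregated ranking
ranks <- filter_rank(cohort$data, labels, seed = 1)
head(dplyr::arrange(ranks, overall_rank), 5)
#>   feature  chi_square mutual_information f_statistic  total overall_rank
#> 1 thalach     354.               0.128        125.   479.              1
#> 2 oldpeak      51.6              0.0865        79.2  131.              2
#> 3 cp           10.3              0.0370        37.1   47.5             3
#> 4 trestbps      2.59             0.00665        1.10   3.69            4
#> 5 sex           0.908            0.00257        2.57   3.48            5
```

The three planted features head the ranking; `select_top_k(ranks, 3)`
returns their mask. The wrapper route searches masks directly:

```r
ga <- run_ga(cohort$data, labels, ga_config(generations = 25, seed = 7))
glance(ga)
#>   method best_fitness best_objective n_selected selected
#> 1 ga            0.718          0.392          8 sex,cp,fbs,thalach,oldpeak,...
```

Best fitness 0.718 means the selected 8-feature subset reaches an
out-of-bag RMSE of 0.392 on the 0/1 outcome (`f = 1/(1+g)`); the subset
contains all three informative features. `autoplot(ga)` draws the
convergence trace. Evaluating that subset:

```r
evaluate_subset(cohort$data, labels, ga$best_mask, classifier = "RF",
                protocol = eval_protocol(folds = 5, seed = 11), seed = 3)
#>   accuracy precision recall specificity f_score   auc
#> 1    0.788     0.785  0.785       0.791   0.785 0.863
```

i.e. 78.8% cross-validated accuracy and AUC 0.863 on a cohort whose
irreducible noise keeps perfect classification out of reach.
`compare_methods()` runs the full before/after-selection comparison over
any set of methods and classifiers, and `run_pso()` / `run_aco()` are
drop-in alternatives to `run_ga()`. Real Cleveland-dialect files load
with `read_cleveland()` (with `"?"` missing tokens, mode imputation or
row dropping, and schema validation); `inst/cli/cardioselect` exposes
the same pipeline as a shell command.

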