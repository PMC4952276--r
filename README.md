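# confens

Per-sample confidence-weighted ensembles of disjoint sparse linear
classifiers, for predicting binary phenotypes (risk group, vital status,
receptor status, …) from omics matrices such as gene expression or DNA
methylation.

Molecular measurements drift between laboratories, batches and patients,
and often only *part* of the feature space drifts. `confens` trains a
sequence of L1-sparse linear classifiers on mutually disjoint feature
subsets, and then — separately for every test sample — estimates how
trustworthy each classifier's input features currently look, so that
classifiers standing on shifted features are down-weighted for exactly the
samples where they would mislead.

## The method in brief

For a test sample $X_s$:

* Every selected feature $f$ has a Gaussian-process regressor $g_f$
  predicting it from its most dependent peers $\Phi_f$ (chosen by the
  maximal information coefficient, top $\max(5, \lceil 5\%\rceil)$).
  Its reliability is the two-sided tail probability
  $c_f = 2F\!\left(-\bigl|\tfrac{X_{s,f}-\mu_{g_f}}{\sigma_{g_f}}\bigr|\right)$.
* Classifier $l_i$ aggregates its features,
  $c^1_{l_i} = \sum_f c_f |w_{l_i}(f)| / \sum_f |w_{l_i}(f)|$,
  and adds an output confidence from its decision value
  $c^2_{l_i} = 1 - 2F(-|d_i - \mu_{l_i}|/\sigma_{l_i})$.
* The prediction is the weighted vote
  $\hat y_s = \mathrm{sign}\bigl(\sum_i c_{l_i} l_i(X_s) / \sum_i c_{l_i}\bigr)$
  with $c_{l_i} = c^1_{l_i} c^2_{l_i}$.

Training removes each classifier's selected features from the pool before
fitting the next one, so the feature sets are disjoint and the ensemble
spreads over redundant signal instead of reusing it.

## Worked example

```r
library(confens)

dat <- generate_sim_data(sim_config(seed = 11))   # block-correlated omics
set.seed(11)
model <- fit_disjoint_ensemble(dat$train, dat$train_labels, n_learners = 2)
model
#> <confens_ensemble> 2 learner(s), 16 selected feature(s)
#>   L1: 9 feature(s): B1_F1, B1_F4, B1_F5, B1_F6, B1_F9, B2_F1, B2_F4, ...
#>   L2: 7 feature(s): B1_F2, B1_F3, B1_F7, B1_F10, B2_F7, B2_F9, B2_F10

pred <- predict(model, dat$test)
head(pred[, c("sample_id", "label", "vote_score",
              "c1_L1", "c2_L1", "c_L1", "c1_L2", "c_L2")], 3)
#>   sample_id label vote_score c1_L1 c2_L1   c_L1 c1_L2   c_L2
#> 1    test_1    -1         -1 0.354 0.336 0.1189 0.389 0.2039
#> 2    test_2     1          1 0.667 0.909 0.6065 0.630 0.5277
#> 3    test_3    -1         -1 0.423 0.051 0.0216 0.512 0.0862

auc_score(pred$vote_score, dat$test_labels)
#> [1] 0.8730905
```

`c1_L1` is how trustworthy learner 1's features look for that sample
(1 = every feature at its predicted value), `c2_L1` how decisive its
decision value is, `c_L1` their product — the learner's voting weight.
Sample `test_3` shows the mechanism: both learners vote with tiny weights
(0.02 / 0.09) because their decision values are near the ambiguous zone,
yet the weighted vote still resolves the label. `explain_prediction(pred)`
breaks the weights down to individual feature reliabilities, and
`sample_model_graph()` / `ppi_subnetwork()` / `build_cooccurrence_graph()`
turn models into annotated igraph objects (GraphML/DOT export via
`write_graphml()`).

Probe-level input is collapsed with `aggregate_expression()` (per-gene
median) or `aggregate_methylation()` (promoter probes only, median beta)
plus `handle_missing()`. A command-line front end over the same functions
ships in `inst/cli/confens.R` (subcommands `preprocess`, `train`,
`predict`, `visualize`, `simulate`, `benchmark`).

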