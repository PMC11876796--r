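# stcausal

Causality-aware imputation and Granger-graph discovery for spatiotemporal
time series, in R.

## What it does, and for whom

Sensor networks (air quality, traffic) and time-course gene-expression
panels produce multivariate series `X ∈ R^{N×T}` with missing entries
(mask `M ∈ {0,1}^{N×T}`) and a relation graph `A ∈ R^{N×N}`, usually built
by thresholding a Gaussian kernel of pairwise distances
(`A_ij = exp(-D_ij²/σ²)` zeroed below a cutoff).  Two confounders
contaminate such data: shared background noise recorded by every sensor,
and non-causal shortcut edges that distance-based graphs create between
sensors that do not actually influence one another.

`stcausal` trains a spatiotemporal graph attention network that fills in
the missing cells **and** decides, for every (query cell, context cell)
pair, whether the context cell Granger-causes the query.  Each
graph-restricted attention edge carries, besides its correlation weight
`α = softmax((W_Q h_q)ᵀ(W_K h_k)/√d)`, a Bernoulli *causal gate*
`β ~ Bernoulli(ρ)` with learned probability
`ρ = σ(w_cᵀ[W_Qc h_q; W_Kc h_k] + b_c)`, relaxed by a binary Gumbel-Softmax
during training:

    h_out(i,t) = (1/Z) Σ_{i'∈N(i)} Σ_{t'} β·α·MLP([h_q; h_k]),   Z = Σ β·α.

An l1 penalty on the gate probabilities makes each ρ behave as a gradient
threshold: pairs whose messages genuinely reduce the imputation loss
saturate at 1, the rest at 0 (the package ships a standalone
gradient-descent oracle for exactly this dynamic, `theorem1_oracle()`).
The decoder attends from each cell embedding over a bank of learnable
prompts — a frontdoor adjustment that conditions predictions through the
embedding and the dataset's global context instead of confounder shortcuts.
Pooling the hard evaluation gates over both time axes (max, normalised by
`T²`) and averaging over windows yields an N×N causal-weight matrix that
can be scored against a known regulatory or physical graph by rank AUC.

Intended users: anyone imputing sensor or expression time series who also
wants the *directed influence structure* among the series — with a
simulator (`synthetic_dataset()`) that plants a ground-truth Granger graph,
injects the two confounders, and applies benchmark missingness, so the
whole pipeline is testable without external data.

## Worked example

```r
library(stcausal)

set_global_seed(1)
data <- synthetic_dataset(seed = 1)     # 15 series x 480 steps, planted graph,
                                        # AR(1) background, 5 shortcut edges,
                                        # 25% point missing
data$series
#> <st_series> 15 series x 480 steps; 75.1% observed; 50 graph edges

model <- train_imputer(
  data$series,
  config = model_config(),              # d = 32, L = 2, 4 heads, 1000 prompts
  tc = train_config(lr = 2e-3, max_epochs = 30, gate_warmup = 12,
                    lambda_ramp = "quadratic", ramp_horizon = 300,
                    gate_lr_scale = 0.2, seed = 1))   # ~2 min on one CPU

Y_hat <- impute(model, data$series)
evaluate_imputation(Y_hat, data$Y, data$eval_mask)$mae
#> [1] 1.253
evaluate_imputation(impute_column_mean(data$series), data$Y, data$eval_mask)$mae
#> [1] 1.003   # cross-sectional mean baseline
evaluate_imputation(impute_locf(data$series), data$Y, data$eval_mask)$mae
#> [1] 1.485   # carry-forward baseline

graph <- extract_causal_matrix(model, data$series, truth = t(data$G_true))
auc_causal(graph)
#> [1] 0.875
rho_convergence_fraction(graph$meta$rho_values)
#> [1] 0.56
```

After this two-minute desk-scale run the extracted causal weights already
rank the planted edges far above chance (AUC 0.875 versus 0.5 random) and
the imputer beats carry-forward, though not yet the cross-sectional mean:
the network is still far from its trained regime at 30 epochs.  Longer
training keeps improving it (a 240-epoch run of the same code reaches
MAE 1.056), and the gate-commitment statistics sharpen with it; the methods
vignette discusses what these desk-scale runs do and do not demonstrate.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/stcausal simulate --seed 1 --out_dir sim
Rscript inst/cli/stcausal train --seed 1 --out_dir sim \
    --data.series sim/series.csv --data.adjacency sim/series.csv.adj.csv
Rscript inst/cli/stcausal discover --seed 1 --out_dir sim \
    --data.series sim/series.csv --data.adjacency sim/series.csv.adj.csv
```

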