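---
title: "Causality-aware imputation and Granger-graph discovery for spatiotemporal series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causality-aware imputation and Granger-graph discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sensor networks and gene-expression panels produce multivariate time series
`X` (N series x T steps) with missing entries recorded in a binary mask `M`,
plus a relation graph `A` — typically built by thresholding a Gaussian kernel
of pairwise distances.  Imputation must reconstruct the missing cells.  Two
confounders contaminate such data: *shared background noise* (a latent
process recorded by every sensor) and *non-causal shortcut edges* (nearby
sensors connected by distance even though wind, terrain or regulation
decouples them).  A model free to exploit every correlation will lean on
these backdoor paths and overfit.

`stcausal` implements a graph attention network that imputes missing values
while *simultaneously* deciding, for every (query cell, context cell) pair,
whether the context cell actually influences the query — a relaxed,
unconstrained form of Granger causality appropriate for imputation, where
future context is legitimate evidence.

## Model

The encoder stacks, per layer: a *skip projection*
`H_skip = H_prev + MLP(X) * M + m * (1 - M)` (the learned token `m` stands in
for missing cells, so masked values can never leak); a per-series *temporal
transformer* (post-norm, sinusoidal position encodings, no cross-series
mixing); *spatiotemporal causal attention* (SCA); and a residual layer norm.

SCA restricts each query `(i, t)` to the graph neighbourhood of `i` at all
time steps.  Each pair carries a correlation weight
`alpha = softmax((Wq h_q)'(Wk h_k) / sqrt(d_h))` over the query's full
context and a *causal gate* `beta ~ Bernoulli(rho)`,
`rho = sigmoid(wc' [Wqc h_q; Wkc h_k] + b_c)`, relaxed by a binary
Gumbel-Softmax at temperature `tau` during training and hard-thresholded at
0.5 during evaluation.  The output is
`h_out = sum(beta * alpha * v) / Z` with messages `v = MLP([h_q; h_k])` and
`Z = sum(beta * alpha)` (floored at 1e-8); when every gate is open `Z = 1`
and SCA is plain neighbour attention.

The decoder attends from each cell embedding over a bank of `N_P` learnable
prompts (projected keys/values, residual query path, linear projection +
layer norm, scalar head).  The prompt bank realises a frontdoor adjustment:
predictions are conditioned through the embedding and marginalised over the
dataset's global contexts, rather than free to exploit confounder shortcuts.

Training minimises the masked mean absolute error over artificially
re-masked observed cells plus an l1 penalty on the gate probabilities,
`lambda * sum(rho) / n_targets` (both terms divided by the same count, so
each gate's sparsity pressure sits on the same scale as each cell's error
gradient and `lambda` keeps its reference calibration at any batch or
graph size; [`masked_mae_loss()`] also offers the gate-averaged form).
Under this loss each gate's dynamics reduce to a
gradient threshold: holding the rest of the network fixed, a gate whose
message-path gradient exceeds the l1 pressure saturates at 1, anything
weaker saturates at 0 ([`theorem1_oracle()`] iterates the literal update and
is checked in the tests over a grid of configurations).  The operational
convergence measure is [`rho_convergence_fraction()`]: the share of gate
probabilities outside (0.1, 0.9).

The node-level causal graph is extracted by [`extract_causal_matrix()`]:
hard evaluation gates are assembled per window into the 4-way array indexed
by (target, t, source, t'), max-pooled over both time axes, normalised by
`T^2`, and averaged over windows.  [`auc_causal()`] scores the resulting
weights against a known graph by midrank AUC (diagonal excluded).

## Parameters that matter

* `d = 32` embedding width, `L = 2` layers for up to 36 series (4 beyond),
  4 attention heads — the reference configuration.  The gate probability is
  shared across heads: one causal verdict per pair.
* `tau = 0.5`, fixed; no annealing schedule.
* `n_prompts = 1000`, inside the stable range (a few hundred to ~1400).
* `lambda_l1 = 0.001`, with both loss terms normalised by the loss-target
  count (see above), optionally ramped quadratically across training so
  that full sparsity pressure arrives only once the message paths are
  informative.
* Optimiser: Adam, learning rate 8e-4 under a cosine schedule, batch size 8,
  per-batch artificial masking rates {0.2, 0.5, 0.8}, at most 300 epochs
  with early-stopping patience 40 on a 10% window hold-out whose artificial
  mask (p = 0.5) is drawn once.  These are the package defaults for
  real-scale data; the desk-scale protocol below shortens them.

## Initialisation choices (and why they are load-bearing)

Three initialisation decisions were made after observing concrete failure
modes at desk scale; all are ordinary neural-network practice:

* **Prompts initialise `Normal(0, 1)`.**  With near-zero prompts the
  projected keys are dominated by the shared projection bias, prompt
  attention is numerically uniform, and the decoder emits a constant — the
  whole network then trains toward predicting the unconditional mean and
  cannot escape (gradients to the prompts stay three orders of magnitude too
  small).  Unit-scale prompts give differentiated attention from step one.
* **Attention scorers `Wq`, `Wk` start at `2 I` plus small noise, the
  message MLP starts near an identity on the key embedding, and the
  transformer's output projections start small** (near-identity residual
  blocks).  Together these let the sinusoidal position encodings express an
  immediate *same-time* attention prior across series — the single most
  useful inductive bias for sensor imputation — which training then refines.
  Random scorers at this data scale never discover temporal alignment.
* **The gate scorer carries a learnable bias `b_c` initialised to
  `logit(0.9)`** so gates start open.  Starting near 0.5 makes early
  attention output extremely noisy; closing all gates then reduces the loss
  before the messages have learned anything, and the causal graph dies with
  them (everything converges to 0).  Open gates let attention learn first;
  the l1 pressure and the gradient threshold prune afterwards.  The bias is
  the one architectural addition to the gate scorer, which the reference
  formulation writes without a bias term.

## The synthetic study set

[`synthetic_dataset()`] generates the reference conditions used throughout
the tests: 15 series, 20 windows of 24 steps, from a sparse stationary VAR
(off-diagonal edge density 0.15, lag 1, self-persistence on the diagonal,
companion spectral radius rescaled to 0.75, unit innovations, 100-step
burn-in).  The planted Granger graph is the support of the coefficient
tensor.  Confounders follow the two real-world mechanisms: a shared AR(1)
background process (coefficient 0.5, unit scale) added to every series, and
5 non-causal shortcut edges inserted into the adjacency between pairs with
no planted edge in either direction.  The adjacency is the symmetrised
planted graph plus self-loops plus those shortcuts — the analogue of a
distance-built sensor graph that contains real links, their reverses, and
spurious ones.  Evaluation masks 25% of cells at random (point missing);
block missing (contiguous per-series outage runs, whole-node spans) is also
implemented.

What this emulates well: linear cross-series dynamics with a known ground
truth, temporally correlated confounding, spurious graph edges, benchmark
missingness rates.  What it does not: nonlinear regulation, heavy-tailed
noise, seasonality, sensor drift, or realistic missing-data mechanisms
(missingness here is independent of values).  Passing the test suite
therefore demonstrates mechanism recovery under controlled conditions, not
field performance.

## Desk-scale protocol and problem sizes

All training-based tests and the acceptance script run the reference
conditions at desk scale: N = 15, 20 windows of T = 24, d = 32, L = 2,
30 epochs, one CPU (about two minutes per run).  Four protocol options make
the method behave sensibly when the optimiser-step budget is two to three
orders of magnitude below the reference protocol's:

* learning rate 2e-3 (compressed-cosine compensation; reference 8e-4);
* `gate_warmup = 12`: gates start forced open so attention and messages
  train first — otherwise closing all gates is immediately loss-optimal
  while messages are still noise, and the causal graph dies with them;
* `lambda_ramp = "quadratic"` with `ramp_horizon = 300`: sparsity pressure
  follows the reference schedule, so truncated runs apply only its early
  part instead of full pressure on an untrained network;
* `gate_lr_scale = 0.2`: gate-scorer updates run slower than the rest,
  enforcing the separation of timescales the convergence analysis assumes.

What such runs demonstrate — and what they do not.  Within this budget the
pipeline reliably recovers the planted graph far above chance (AUC ~0.9),
the theorem-oracle and enumeration checks are exact, and the imputer beats
carry-forward.  The *trained-regime* properties — beating the
cross-sectional-mean baseline, near-total gate commitment (the reference
setting reports 98%), gate-weight separation between shortcut and true
edges, and the fine ablation ordering (sub-1% MAE differences in the
reference results) — emerge only after hundreds to thousands of optimiser
steps: a 720-step run of the same code reaches MAE 1.056 against the
column-mean baseline's 1.003 and still improving, and a linear oracle with
graph + temporal + cross-sectional features shows 0.934 is attainable.
Desk-scale executions of those checks therefore measure training progress,
not the method's ceiling.

## Numerical notes

* Softmax reductions subtract per-context maxima; uniform draws for the
  Gumbel noise are clamped to [1e-6, 1 - 1e-6]; gate probabilities are
  clamped to (1e-7, 1 - 1e-7) before logs.
* The attention normaliser `Z` is floored at 1e-8; queries whose gates all
  close output a zero vector and are flagged in the gate state.
* Degenerate inputs: an all-missing series trains (the missing token and
  temporal prior still define predictions) but cannot beat baselines;
  queries need at least the self-loop, so adjacencies with empty
  neighbourhoods are rejected on construction.
* Evaluation-time gates are deterministic (`beta = 1[rho >= 0.5]`), so
  imputation and extraction are exactly reproducible.
* The per-pair attention kernels run in C++ (column-contiguous transposed
  buffers); the message MLP's second (linear) layer is applied after
  aggregation, which is algebraically identical and removes the dominant
  per-pair matrix products.  Gradients of every module are verified against
  central finite differences in the test suite.

## Known limitations

* Scoring uses the evaluation mask only (held-out, originally observed
  cells); cells missing in the source data have no ground truth and are
  never scored.
* The causal matrix is graph-restricted: pairs outside the adjacency can
  never be discovered (they receive weight 0), which matches the method's
  O(ET) design but caps recall when the input graph is incomplete.
* With hard evaluation gates the extracted weights are averages of {0, 1}
  max-pools; graded rankings come from averaging across windows, so very
  short series give coarse AUC resolution.
* HDF5 input is not supported in this implementation; the delimited-text
  contract (CSV/TSV series, mask, dense or edge-list adjacency) is the
  supported interchange format.
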