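# bcenet

Directed (effective) brain connectivity from ROI time series, and
classification of the resulting brain networks.

Correlation-based functional connectomes are undirected: they cannot say
which region drives which. `bcenet` estimates a *weighted directed*
connectome from multivariate regional BOLD time series with a gated
generative-adversarial network, and classifies populations of such
connectomes with a hierarchical graph neural network. Both networks are
implemented from first principles (explicit forward/backward passes,
Adam), so the package has no deep-learning dependencies. It is aimed at
researchers studying effective connectivity and network-based diagnosis
(e.g. mild cognitive impairment vs. controls), and at anyone who needs a
fully testable, simulation-backed pipeline for directed-network recovery.

## The models

**Connectivity estimator.** For time series `X ∈ R^{t×v}` (z-scored per
region), region *i*'s generative module predicts

    X̂[τ, i] = w2ᵀ tanh( W1 (g_i ⊙ X[τ−ℓ, ·]) + b1 ) + b2,

where the causal gate `g_i ∈ R^v` (with the structural zero `g_i[i] = 0`)
scales every other region's lagged signal at the module's input. Replacing
column *i* of `X` with its prediction gives one synthetic sample per
region; a shared two-hidden-layer ReLU discriminator separates real from
synthetic time-point rows, estimating the KL divergence between them from
its logits. The generator minimizes

    ‖X̂ − X‖² + λ·(1/v)·Σ|g| + β·Σ_i KL̂(X ‖ X̃_i)

(optimized in per-time-point units; λ = 0.1, β = 1 by default) with Adam
at learning rate 0.001 for 3000 epochs, interleaving 1000 discriminator
updates. Entry `(m, i)` of the trained gate matrix is the directed
influence `m → i`; `extract_connectome()` returns it signed or absolute.

**Graph classifier.** Three stages of graph convolution
`N' = ReLU(D̃^{-1/2} Ã D̃^{-1/2} N W)` and TopK pooling (learnable
projection scores, keep the best `p` nodes, tanh-score gating) each emit a
per-feature L1 readout; the concatenated readout `Gr = r1‖r2‖r3` feeds a
64/32 MLP with softmax, trained with cross-entropy. Pearson correlation
and bivariate Granger causality (nested least-squares F-tests) are
included as reference estimators, along with ACC/SEN/SPE/F1 metrics,
stratified 10-fold cross-validation, AUROC/AUPRC structure-recovery
scores, Welch's t-test, and a seeded nonlinear-VAR simulator with known
ground-truth graphs.

## Worked example

Simulate a sparse directed network, estimate it from the series alone, and
score the recovery against the ground truth:

```r
library(bcenet)

net <- sample_directed_graph(8, density = 0.25, seed = 1)
net
#> <ground_truth_network> 8 regions, 11 directed edges

ts <- simulate_nonlinear_var(
  net, simulation_config(8, 600, edge_density = 0.25, noise_sd = 0.1,
                         nonlinearity = "identity", seed = 1))
ts
#> <roi_timeseries> 600 time points x 8 regions

fit <- train_bcen(ts, bcen_config(generator_epochs = 500,
                                  discriminator_epochs = 167, seed = 1))
fit
#> <bcen_fit> 8 regions, 500 generator epochs, 167 discriminator epochs
#>   final recon 1980.5, mean |gate| 0.09647

est <- extract_connectome(fit)
recovery_scores(est, net)
#> $auroc
#> [1] 1
#> $auprc
#> [1] 1

recovery_scores(bivariate_granger(ts, lag = 1)$connectome, net)$auroc
#> [1] 0.996
```

Here ranking the absolute gates separates the 11 true edges from the 45
absent ones perfectly (AUROC/AUPRC 1), slightly ahead of the bivariate
Granger baseline (0.996) even though the simulated dynamics are exactly
the linear VAR that Granger tests assume.

For classification, `make_group_dataset()` builds a labeled two-class
graph population, and

```r
ds  <- make_group_dataset(60, 30, n_perturbed_edges = 10, effect_size = 0.8,
                          noise_sd = 0.1, seed = 1)
cfg <- hrgnn_config(pool_keep = 40, epochs = 120, seed = 1)
cv  <- kfold_cross_validate(ds, hrgnn_model_factory(cfg), k = 10, seed = 1)
cv$pooled
#> ACC 100.00  SEN 100.00  SPE 100.00  F1 100.00  (tp 60 fp 0 tn 60 fn 0)
```

`sweep_pool_keep()` tabulates the same cross-validation over a range of
pooling parameters (one shared fold split) to reproduce the pooling
ablation design.

## Command line

A thin wrapper over the same functions ships in `inst/exec/bcenet`:

```sh
bcenet simulate --regions 10 --timepoints 135 --density 0.2 --seed 1 --out-prefix toy
bcenet estimate --input toy.ts.tsv --epochs-gen 3000 --epochs-disc 1000 --out net.tsv
bcenet baseline --method granger --input toy.ts.tsv --out gc.tsv
bcenet recover  --estimate net.tsv --truth toy.truth.tsv
```

All artifacts are header-bearing TSV (square matrix or
source/target/weight edge list) with full-precision floats, so every
write→read round-trip is bit-exact.

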