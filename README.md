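# mmcrl — multimodal causal representation learning with sparse latent graphs

Biomedical studies increasingly record several measurement channels per
subject — sleep monitoring alongside retinal imaging, anthropometrics
alongside blood panels. `mmcrl` is an R toolkit for the corresponding
latent-variable problem: each observed modality `x^(m)` is generated by a
small block of modality-specific latent causal factors `z^(m)` plus
domain-specific noise `eta^(m)`,

    z_i = g_i(Pa(z_i), eps_i)        (acyclic latent causal relations,
                                      parents possibly in other modalities)
    x^(m) = g_x^(m)(z^(m), eta^(m))  (smooth invertible mixing)

with all exogenous variables `eps_i` and `eta^(m)` mutually independent.
When the causal links *between* modalities are sparse, each latent
component is identifiable from observational data up to a permutation
and an invertible scalar transform, and the cross-modal causal graph is
recoverable. The package provides the full desk-scale pipeline around
that claim:

* **Simulator** (`scm_spec()`, `sample_scm()`, `simulate_dataset()`):
  multimodal datasets from a known sparse latent SCM — random acyclic
  latent graphs with a controllable fraction of absent cross-modal links
  (`sparsity_ratio`; 0 = fully connected), calibrated tanh-network
  structural functions with additive standard-normal noise, and
  invertible LeakyReLU-MLP mixing verified by numerical Jacobian rank
  checks. Ground truth (latents, noise, adjacency) is retained;
  archives round-trip through a plain-text format (`write_mmds()` /
  `read_mmds()`).
* **Estimator** (`config_for_dataset()`, `mmcrl_train()`): per-modality
  variational encoders/decoders, per-component conditional affine flows
  gated by a learnable cross-modal adjacency matrix, trained under
  `L = a_R * L_recon + a_I * L_ind + a_S * ||gates||_1`, where `L_ind`
  drives the estimated noise vector toward an independent standard
  normal (aggregate Gaussian-moment KL + higher-order cross-moment
  penalty + per-sample posterior KL). Training uses a delayed sparsity
  ramp, gate-temperature annealing, and an unsupervised
  canonical-correlation re-alignment of each modality's code. All
  networks, gradients and the optimizer are implemented in base R.
* **Evaluation** (`evaluate_fit()`, `mcc()`, `r2_score()`, `shd()`,
  `run_case()`, `ablation_sparsity()`): component identification scored
  by the mean correlation coefficient (Spearman, optimal assignment via
  an in-package Hungarian solver) and out-of-sample kernel-ridge R²;
  graph recovery scored by the structural Hamming distance between the
  thresholded learned adjacency (relabelled by the MCC assignment) and
  the true cross-modal graph.

## Worked example

The packaged "case 1" study: two modalities, two latent and one
domain-specific variable each, 15 observed dimensions in total, two
sparse cross-modal causal links, n = 10000 samples per seed:

```r
library(mmcrl)
rep <- run_case(1, seeds = 1:3, n = 10000)
print(rep)
#> case 1 over 3 seeds (n = 10000 )
#>  seed       mcc        r2 shd
#>     1 0.8739853 0.9317573   0
#>     2 0.8957521 0.9445162   0
#>     3 0.8586434 0.9320666   1
#> medians: MCC 0.874  R2 0.932  SHD 0
```

Per seed, `run_case()` simulates a fresh ground-truth model, fits the
estimator from observations alone, and scores it: `mcc` is the mean
absolute Spearman correlation between true and estimated latent
components after optimal matching (1 = perfect component-wise
identification), `r2` the mean out-of-sample R² of kernel regressions
predicting each true component from the estimated ones (1 = all latent
information recovered), and `shd` the number of edge differences between
the recovered and true cross-modal causal graphs (0 = exact recovery).
Here the cross-modal graph is recovered exactly in the median seed and
the estimated components carry ~93% of the latent variance.

Single objects are just as accessible:

```r
ds  <- simulate_dataset(case_spec(1, seed = 1), n = 10000)
fit <- mmcrl_train(ds, config_for_dataset(ds, seed = 1))
evaluate_fit(fit, ds)
#> eval: MCC 0.874 (spearman), R2 0.932, SHD (cross-modal) 0, SHD (full) 0
```

The sparsity ablation reproduces the qualitative claim that sparser
cross-modal structure improves identification: `ablation_sparsity(c(0,
1/3, 5/9, 2/3), n_seeds = 3, case_id = 2)` reports mean MCC by ratio,
lowest at 0 (fully connected).

## Scope

The estimator assumes the number of latent components per modality is
known, observations are i.i.d. rows, and the latent graph is acyclic.
Image modalities, shared (directly common) latent variables, and
constraint-based structure discovery on the recovered components are out
of scope; the methods vignette (`vignettes/mmcrl-methods.Rmd`) documents
the model, the estimation design decisions and their rationale, and
known limitations.
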