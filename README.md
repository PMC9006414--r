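# pdsmcca

Parameter-decomposition sparse multi-view canonical correlation analysis
(PDSMCCA) for multimodal imaging quantitative traits, with the plain
sparse multi-view CCA (SMCCA) baseline, a nested cross-validation
grid-search harness, and a latent-factor synthetic benchmark generator.

## What it is for

Different imaging modalities (e.g. AV45-PET, FDG-PET and VBM-processed
sMRI) measure the same brains on a common region atlas. Some regions
co-vary across *all* modalities; others are informative in only one.
PDSMCCA finds, for K ≥ 2 views `X_k` (samples × features), canonical
weights that maximize all pairwise associations while *attributing* each
selected feature: every weight is decomposed as `v_k = b_k + s_k`, and

    min over B, S of
      sum_{k<j} 1/2 ||X_k(b_k+s_k) - X_j(b_j+s_j)||^2
        + lambda_B ||B||_{1,1} + lambda_S ||S||_{2,1}
      subject to ||X_k(b_k+s_k)||_2 = 1

where the l2,1 penalty on `S = [s_1..s_K]` zeroes whole feature rows
(features shared by all modalities survive), and the element-wise l1
penalty on `B` keeps modality-specific features. Association strength is
reported as the canonical correlation coefficient (CCC), the Pearson
correlation of two views' canonical variates computed with the true
within-view covariance, so it always lies in [-1, 1].

The model is fit by alternating convex search with iteratively reweighted
diagonal linear systems (compiled inner loop), and penalties are tuned by
nested five-fold cross-validation over the grid {0.01, 0.1, 1, 10, 100}.
Intended users: biostatisticians and imaging-genetics researchers working
with aligned multimodal matrices of regional quantitative traits.

## Worked example

The built-in benchmark (`data1_spec()`) draws three 120 × 200 views from a
rank-one latent-factor design whose true weights share the support 81–120
(block values 1, 2, −1), plus Gaussian noise of variance 0.01:

```r
library(pdsmcca)
ds  <- generate_multiview(data1_spec(noise_level = 0.01, seed = 7))
fit <- fit_pdsmcca(ds, lambda_B = 10, lambda_S = 0.1)
fit
#> PDSMCCA fit: lambda_B = 10, lambda_S = 0.1; 93 iterations (converged), final objective 0.195417
pairwise_ccc(center_views(ds), fit$weights)
#>          pair       ccc
#> 1 view1-view2 0.9870463
#> 2 view1-view3 0.9842051
#> 3 view2-view3 0.9881683
fit$weights
#> weight_decomposition: p = 200, K = 3; nonzeros B = 0, S rows = 43
support_metrics(fit$weights, ds$truth)$per_view
#>   view precision recall flagged
#> 1    1 0.9523810      1   FALSE
#> 2    2 0.9523810      1   FALSE
#> 3    3 0.9302326      1   FALSE
```

All three pairwise CCCs are ≈ 0.98 — the views' latent signal is
recovered — and the decomposition puts the signal where it belongs: on
this all-shared design the specific matrix `B` is empty and the row
support of `S` (43 rows) covers the true block 81–120 with recall 1 and
precision ≈ 0.95. Penalty tuning with the full protocol is one call:

```r
cv <- nested_cv(ds, "pdsmcca", seed = 8)   # ~3 min on one core
cv$mean_sd                                  # per-pair train/test mean ± SD
```

An end-to-end run that writes weights, CCC summaries, CV results and a log
to disk is `run_experiment(out_dir, synthetic = "data1", seed = 1)`; the
same drivers are exposed as a command-line tool in `inst/cli/pdsmcca.R`
(subcommands `simulate`, `fit`, `cv`, `report`).

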