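# morphoflow

Tumor phenotypes on preoperative multimodal MRI are usually summarized by
hand-crafted radiomics or by segmentation volumes. `morphoflow` takes a
dynamical-systems view instead: it treats each tumor's multimodal appearance
as a point on a low-dimensional latent manifold, asks whether the population
organizes into a small number of *attractor basins* (stable morphologic
regimes), and probes how trajectories on that manifold could be analysed —
and, in simulation, steered — as a continuous flow. It is aimed at
researchers in computational neuro-oncology and biomedical image analysis
who want a fully testable, desk-scale implementation of that pipeline.

The package implements the whole chain:

1. **Phantom cohort** — a synthetic generator of 4-channel (T1, T1Gd, T2,
   FLAIR) brain-tumor volumes with three hidden morphotypes (necrotic
   rim-enhancing / intermediate / compact-enhancing), survival times
   stochastically ordered by morphotype, and an age covariate that carries
   most of the hazard. Every downstream stage runs with no external data.
2. **Preprocessing** — header QC (fail-closed), trilinear resampling to a
   cubic grid, per-volume percentile normalization
   (clip to the [1st, 99th] percentiles, rescale to [0, 1]), packaging,
   and uniform patch sampling within brain bounds.
3. **Autoencoder** — a 3-D convolutional autoencoder
   (4 stride-2 Conv3D blocks, channel progression c1→c2→c3→c4, global
   pooling + FC to a latent vector z = f_enc(x); mirrored transposed-conv
   decoder) trained with Adam on the L1 objective
   `L_AE = ||x − x̂||₁` with early stopping. Conv kernels, backprop and the
   optimizer are implemented in the package (Rcpp + R); no external
   deep-learning framework is required.
4. **Case embeddings** — z̄ = (1/8) Σ z_i over patch encodings, PCA
   diagnostics, and a decoder-sensitivity stability index
   `s(z̄) = E_ε ||f_dec(z̄+ε) − f_dec(z̄)||₁ / ||ε||₂`, ε ~ N(0, 0.10² I).
5. **Attractors** — K-means on z̄ with a K = 2…10 validity scan
   (silhouette, Davies–Bouldin, Calinski–Harabasz), seed-robustness via
   pairwise adjusted Rand indices, a permutation test of the silhouette,
   and canonical low/intermediate/high-risk ordering by Kaplan–Meier
   median survival.
6. **Survival stages** — Kaplan–Meier + multigroup log-rank (pairwise
   Benjamini–Hochberg), bootstrap Spearman ρ for the stability–survival
   association, and ridge-penalized Cox models with cross-validated
   Harrell's C.
7. **Voxel sensitivity maps** — Gaussian intensity bumps
   (kernel 7, σ = 1 voxel, amplitude `0.9·U(1,6)`) on FLAIR at random
   foreground voxels; per-voxel `Shift(v)` (latent displacement) and
   `Flip(v)` (attractor change) maps normalized by coverage
   `Hit(v)`, with ICC(3,1) test–retest reliability.
8. **Latent dynamics** — a neural-ODE vector field ż = f_θ(z) (MLP,
   hidden [256, 128]) trained on k-NN edge displacements (k = 8), RK4
   integration (Δt = 0.05), divergence maps on the PCA plane, Lyapunov
   exponents from paired trajectories, and dynamic attractors from
   long-term (200-step) integration endpoints.
9. **Control** — deterministic open-loop control of
   ż = f_θ(z) + B u(t) minimizing
   `J = ||z_T − z*||² + λ∫||u||² dt` by gradient descent through the
   unrolled integrator (exact hand-derived adjoint), and a desk-scale
   soft actor–critic agent on a PCA-compressed observation.

## Worked example

The one-call interface chains every stage on a 30-case phantom at the tiny
CPU configuration (about 3 minutes on one core):

```r
library(morphoflow)
cfg <- pipeline_config("run1", n_cases = 30, grid = 32, seed = 42,
                       permutations = 20, sac_timesteps = 1500)
run_pipeline(cfg)

read.csv("run1/survival/km_medians.csv")
#>   group  n median
#> 1     0 12  180.0
#> 2     1  7  642.5
#> 3     2  6  286.0

read.csv("run1/attractors/risk_order.csv")
#>   label  n km_median rank         risk
#> 1     1  7     642.5    1          low
#> 2     2  6     286.0    2 intermediate
#> 3     0 12     180.0    3         high

read.csv("run1/dynamics/lyapunov.csv")
#>      lambda  lambda_sd n_starts
#> 1 0.4417496 0.05746271       10
```

The Kaplan–Meier medians show the three discovered attractors stratifying
survival (180 vs 286 vs 642 days among training cases with events), and
`canonical_risk_order()` relabels the arbitrary K-means indices into
low/intermediate/high-risk basins. The Lyapunov estimate (λ ≈ 0.44 ± 0.06
here) summarizes how quickly nearby latent trajectories of the learned flow
separate; values near zero indicate metastable dynamics. The deterministic
controller's per-case table (`run1/control/deterministic_control.csv`)
reports, for each start, the terminal distance to the low-risk centroid
with and without control — on this run every trajectory was steered to
within 10% of its uncontrolled terminal distance, with median reductions
above 90%.

Each stage is equally usable on its own (`generate_cohort()`,
`preprocess_cohort()`, `ae_train()`, `embed_cohort()`, `fit_attractors()`,
`logrank()`, `ridge_cox()`, `sensitivity_maps()`, `train_field()`,
`dynamic_attractors()`, `deterministic_control()`, `train_sac()`, …), and
fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()`s. A thin command-line wrapper lives at
`inst/cli/morphoflow.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch at desk scale against the installed
package (every stage from phantom generation through SAC control) and
writes the machine-readable report to `--out`. The quantitative acceptance
properties themselves — oracle equivalences, analytic dynamical limits,
recovery of planted structure, statistical calibration and control
guarantees — live in `tests/testthat/test-acceptance.R` and run with the
ordinary test suite.

## Limitations

The phantom is schematic (ellipsoidal anatomy, designed morphotype
contrasts); green tests certify the pipeline's correctness and calibration,
not clinical performance on real MRI. The learned vector field encodes
cross-sectional manifold geometry, not observed temporal evolution, and the
control stages are in-silico demonstrations. See the methods vignette
(`vignettes/morphoflow-methods.Rmd`) for the full modeling account.
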