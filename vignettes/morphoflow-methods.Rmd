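---
title: "morphoflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphoflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphoflow` treats a tumor's multimodal MRI appearance as a point on a
low-dimensional latent manifold and the population as samples from a small
number of attractor basins. This vignette is the package's own account of
the science: the models and their assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. Nothing here states an
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The pipeline as a model

The chain is: standardize volumes → encode patches to a latent space →
average to case embeddings z̄ → cluster z̄ into attractors → relate
attractors and latent stability to survival → probe voxel-level sensitivity
→ fit a continuous latent flow ż = f(z) → steer the flow toward the
low-risk basin.

Two modeling commitments run through everything:

* **Intensity structure is sufficient.** All stages consume normalized
  channel intensities on a cubic grid; no segmentation is required at
  inference (an optional fifth segmentation channel is accepted at training
  time only, so that no label information leaks into the unsupervised
  analyses).
* **Cross-sectional geometry, not time.** The vector field is trained on
  displacement vectors between neighbouring *cases*, so its flow encodes
  how morphologies vary across the population, not how any one tumor
  evolved. Trajectories, Lyapunov exponents and control results are
  in-silico hypotheses about morphodynamic continuity.

## 2. Preprocessing

* **Resampling.** Trilinear interpolation with the corner-aligned
  convention; nearest-neighbour for label masks. Corner alignment makes
  affine ramps exactly affine after resampling and preserves label sets,
  which is what the oracle tests assert.
* **Normalization.** Per volume, intensities are clipped to the empirical
  1st/99th percentiles and mapped affinely to [0, 1]. We use the
  inverted-ECDF percentile (R's `type = 1`): with it the clip bounds are
  order statistics, at least 1% of mass lands exactly on each bound, and
  normalization is *exactly idempotent* — re-normalizing a normalized
  volume is the identity. Interpolating percentile definitions break
  idempotence at order 1/n. Percentiles are computed over all voxels,
  background included; a constant volume maps to all zeros by convention.
* **Brain bounds.** Patch corners are uniform over the bounding box of
  voxels whose channel-max is positive; an empty foreground degenerates to
  whole-volume bounds. Patches use 0-based, half-open index ranges.

## 3. Autoencoder

Four Conv3D blocks (kernel 3, stride 2, pad 1), each followed by
per-channel normalization and ReLU, then global mean pooling and a linear
map to the latent; the decoder mirrors with transposed convolutions and a
sigmoid output. The objective is mean absolute error; optimization is Adam
with early stopping on validation loss.

Numerical choices worth knowing:

* **Transposed-conv kernel 4.** Kernel 4 / stride 2 / pad 1 doubles the
  spatial edge exactly without output padding; only block counts and
  strides are architecturally fixed, so the kernel size is ours.
* **Sigmoid output.** Inputs are normalized to [0, 1]; bounding the decoder
  the same way makes the untrained model a well-defined baseline and the
  L1 objective scale-free.
* **Normalization layer.** Per-channel moments over spatial positions
  (deterministic per sample, batch-size independent); running statistics
  are used in eval mode. When a block's spatial extent is a single voxel
  (the innermost block of very small test patches) batch moments are
  degenerate and the layer freezes to its running statistics.
* **Reconstruction metrics.** MSE over full tensors; SSIM and PSNR on the
  central axial slice per channel, averaged (uniform 7×7 SSIM window,
  K1 = 0.01, K2 = 0.03, data range 1 — the window and constants are
  documented defaults, not tuned). A perfect reconstruction reports
  100 dB PSNR so aggregates stay finite.
* **Tiny configuration.** `ae_config_tiny()` (channels 8→16→32→64, latent
  16, 16- or 32-voxel patches) exists so every property is testable on one
  CPU; all quantitative properties asserted in the tests are
  architecture-size-agnostic.

The whole network — vol2col/col2vol convolution kernels, batch-norm
forward/backward, Adam — is implemented in the package and gradient-checked
against finite differences in the test suite, because no deep-learning
framework is available in the target environment.

## 4. Case embeddings and stability

z̄ averages eight patch encodings (uniform within brain bounds); when the
patch equals the volume the average degenerates to a single encoding. The
stability index

s(z̄) = E[ ‖f_dec(z + ε) − f_dec(z)‖₁ / ‖ε‖₂ ],  ε ~ N(0, 0.10² I)

is estimated from 4 patches × 4 perturbations (16 decodes). The expectation
is taken **jointly over patches and perturbations** — the per-patch latents
z are drawn fresh rather than perturbing z̄ itself; this reads the
estimation protocol literally and keeps s attached to regions of the
manifold the case actually occupies. L1 here is the *sum* of absolute
values (so a 1-D linear decoder has s = Σ|w| exactly, the closed form the
tests assert); the autoencoder training loss uses the mean. Low s means a
flat, stable manifold region. The stored embedding table always keeps raw
values; z-scoring happens only inside model-fitting stages.

## 5. Attractors

K-means (k-means++ via `stats::kmeans`, 10 internal restarts, 100
iterations) on raw z̄ with a K = 2…10 scan; the selected K maximizes the
silhouette, with Davies–Bouldin and Calinski–Harabasz reported for
concordance. Robustness is certified by the adjusted Rand index over all
pairs of 10 seeded refits, and significance by a permutation test: each
latent coordinate is shuffled independently across cases (marginals
preserved, dependence destroyed), K-means refit, and the silhouette
recomputed, with p = (1 + #{null ≥ observed}) / (1 + B) so p is never
zero. The literal alternative — reassigning whole latent vectors to
different case IDs — leaves the point cloud unchanged and is exposed
behind `scheme = "reassign"` only for completeness.

Attractor indices are arbitrary; `canonical_risk_order()` maps them to
low/intermediate/high risk by descending Kaplan–Meier median survival of
training cases, breaking ties by mean survival and then cluster size, and
sorting clusters without survival data last.

## 6. Survival stages

Kaplan–Meier, log-rank (hypergeometric variance, ties aggregated at event
times) and ridge-penalized Cox models are fitted by the survival package;
hand-computed product-limit and O−E/V oracles live in the tests. Cox ties
use the Efron approximation. Every analysis applies the same cohort rule:
training split with non-missing survival. Covariates are z-scored inside
`ridge_cox()` by default, so hazard ratios are per SD; `standardize =
FALSE` reports native units (e.g. per year of age) — both scalings are
legitimate readings and the output records which one was used.
Zero-variance covariates are pinned to HR 1. Cross-validated concordance
fits the penalized model on each training fold and scores its linear
predictor on the held-out fold. The bootstrap Spearman stage resamples
cases with replacement (percentile 2.5/97.5 interval) and reports the point
estimate's two-sided large-sample p alongside.

## 7. Voxel sensitivity maps

Gaussian bumps (7³ kernel, σ = 1 voxel, peak 1) are added to the FLAIR
channel at random foreground voxels (channel-max > 0.15) with amplitude
0.9 · s, s ~ U(1, 6), then clipped to [0, 1]; the additive-positive sign is
the physiologic reading of FLAIR hyperintensity. Encoding patch positions
are fixed across bumps within a case, so latent displacements are
bump-driven only. Shift and Flip maps divide the bump-weighted deposits by
coverage Hit(v) = Σ bump_i(v), floored at 1e-6. Replicates for ICC(3,1)
reuse identical centers with re-sampled amplitudes; ICC of zero-variance
maps (e.g. Flip maps when no boundary crossing occurs) is 0 by convention,
not NaN.

## 8. Latent dynamics

The vector field is an MLP (tanh hidden layers, widths [256, 128] at full
scale) trained by Adam with a linearly decaying learning rate on all
directed k-NN edges (k = 8): inputs z_i, targets z_j − z_i. Edge
displacements carry no time unit, so the implicit edge time-step is 1 and
its units are absorbed into f_θ. Integration is classical RK4 with
Δt = 0.05. Divergence is computed on the PCA plane (field lifted through
the first two principal axes and projected back, central differences);
the Lyapunov exponent evolves paired trajectories with separation 1e-4,
renormalizing every 10 steps (the interval is our choice; the estimate is
insensitive to it on linear test fields, where the tests require 5%
accuracy). A case counts as converged when its trailing-20-step state
variance, normalized by the cohort embedding variance, falls below 0.05 —
"normalized endpoint variance" is not otherwise pinned down, and this
definition is stated openly. Endpoints are clustered with K-means (K = 3)
into dynamic attractor labels.

## 9. Control

Controlled dynamics ż = f(z) + B u(t) with B defaulting to the top-8
principal directions of the embedding cloud (orthonormal columns; the rank
and construction of B are design choices). The deterministic controller
minimizes J = ‖z_T − z*‖² + λ∫‖u‖² dt over an open-loop sequence by
projected gradient descent with backtracking through the unrolled RK4
integrator; the gradient is an exact hand-derived adjoint that consumes the
MLP's vector-Jacobian products, verified against finite differences in the
tests. "Within 10% of the target" is ambiguous (10% of what?); success is
defined relative to the same-start uncontrolled terminal distance, with an
absolute-radius variant (10% of the cohort RMS norm) reported alongside —
neither is asserted as canonical. The SAC agent is a minimal hand-written
implementation (Gaussian tanh-squashed policy, twin critics with Polyak
targets, fixed entropy temperature α = 0.1, γ = 0.995, horizon 60) on a
standardized PCA observation; network sizes and replay settings are
deliberately desk-scale and documented, not claimed faithful to any
reference implementation. The expected qualitative ordering — the
deterministic controller meets the strict 10% criterion more often than the
SAC policy, which still beats the uncontrolled baseline in mean terminal
distance — is asserted as a property, not as specific percentages.

## 10. The phantom: what it emulates, and what it does not

The generator emulates the *statistical structure* the pipeline assumes:

* three morphotypes with graded lesion architecture — type 0 aggressive
  (necrotic fraction 0.55, bright irregular rim 0.95 with multiplicative
  texture sd 0.10, FLAIR halo 10% of the edge), type 1 intermediate
  (necrosis 0.30, dim enhancement 0.55, halo 5%), type 2 compact
  (necrosis 0.05, homogeneous enhancement 0.90, halo 2%);
* survival drawn from an exponential model whose log-rate is linear in
  standardized age (log HR = log 1.3 per SD, making age the dominant
  single covariate) plus a morphotype scale (defaults 300/420/540 days);
  censoring is an independent coin (rate 0.2) with a U(0, T) censor time;
* a train/valid split, resection categories and a quarantined truth file
  (`*_truth.csv`) that no pipeline stage reads.

Geometric nuisance is deliberately modest: lesion radius 13.5–14.5% of the
edge, per-axis anisotropy 0.95–1.05, center jitter ±5%, sized so the whole
edema halo stays inside the brain ellipsoid. This is the generator's
**separability contract**: morphotype contrast must dominate within-type
variance, because that is the world in which attractor recovery is a
well-posed test. Two failure modes found during design are worth recording:
(i) with a wide halo near the brain boundary, variable mask clipping of the
edema shell injected a dominant within-type latent factor that split the
aggressive morphotype across clusters; (ii) intermediate enhancement at
0.65 made type 1's mean T1Gd nearly cancel against type 0's bright-rim ×
large-core mix. The defaults above remove both, and the end-to-end
acceptance test verifies recovery under them.

What the phantom does **not** emulate: anatomy (a brain is an ellipsoid),
MRI physics, bias fields, scanner effects, registration error, partial
volume, or any real biological coupling between appearance and outcome. A
green end-to-end test therefore establishes that the pipeline recovers
designed structure at desk scale — it says nothing about clinical
performance on real cohorts.

## 11. Reproducibility

Every stochastic component takes a seed and restores the caller's RNG
state; the pipeline propagates one global seed (default 42) to each stage
and writes a manifest with the config hash and per-file MD5 checksums, so
deterministic stages reproduce byte-identical artifacts. Volumes are stored
as native RDS tensors (the R analogue of a compressed array container) and
optionally as per-channel NIfTI-1 files written by the package's own
minimal, round-trip-tested writer.

## 12. Known limitations

* Desk-scale budgets: the tiny autoencoder and short schedules trade
  fidelity for CPU runtime; reconstruction quality metrics at this scale
  are not comparable to full-resolution GPU training.
* The latent flow is identified only up to the cross-sectional geometry;
  k-NN tangent supervision averages outgoing displacements and cannot
  recover a time direction.
* The SAC agent is a minimal implementation intended as a baseline
  demonstration; it is not tuned and does not implement automatic entropy
  targeting or n-step returns.
* ICC(3,1) is computed per case over masked voxels and averaged; it
  assumes the two replicates share the rater structure (identical centers),
  which the API enforces.
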