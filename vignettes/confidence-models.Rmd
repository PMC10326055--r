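---
title: "Models and methods: performance-optimized decision confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: performance-optimized decision confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metacognet)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices that were genuinely open, and
what the synthetic-data results do and do not establish. It states no
empirical numbers beyond those the test suite and `scripts/acceptance.R`
themselves compute.

## Stimulus model

A raw image has pixels in [0, 1]. Processing is contrast scaling, then
normalization, then noise, then a hard threshold:

  x' = clamp(2 μ p − 1 + ε, −1, 1),    ε ~ Normal(0, σ²).

`μ` (dimensionless, usually in [0.1, 1]) scales signal strength; `σ` sets
the pixel-noise scale on the [−1, 1] range. The source formulation calls σ
a "variance", but the values it takes (up to 4 on a [−1, 1] pixel scale)
only make sense as a standard deviation, so `apply_contrast_noise()`
treats σ as an sd by default and offers `sigma_is_variance = TRUE` for the
literal reading. Gabor patches use a cosine grating (phase zero at the image
center — unstated in the source, chosen for symmetry), orientation measured
from vertical, a Gaussian envelope of sd 4 px and spatial frequency 0.3
cycles/px. Superimposed stimuli take the pixel-wise maximum of the two
contrast-scaled images *before* noise is added once.

Four training regimes control the joint distribution of (μ, σ):
`standard` (μ ~ U(0.1, 1), σ ~ U(range)), `fixed_mu` (μ = 0.5),
`fixed_sigma` (σ at the range midpoint), and `fixed_mu_over_sigma`
(σ = 3.75 μ). The noise range is [1, 2] for the image-classification tasks
and [0.5, 1] for the orientation task.

## Synthetic stimuli: what they emulate, what they do not

No external image set ships with the package. The two-class generator
(`make_synthetic_classes()`) stands in for a handwritten-digit pair: two
fixed prototypes — a horizontal and a vertical bar under a shared Gaussian
envelope — interpolated toward a class-neutral blob with weight
`separation / (separation + 1)`, plus a small random affine warp (rotation
sd 6°, anisotropic log-scale sd 0.05, translation sd 1 px) and log-normal
amplitude jitter (sd 0.1) per sample. The bar orientations were chosen so
the class difference is a gross, low-frequency shape difference, as it is
for typical digit pairs; that is what lets an unsupervised two-dimensional
autoencoder discover the class structure. The default `separation = 5` makes
the pair cleanly discriminable on clean images while leaving the noisy task
at threshold, mirroring how digit pairs behave under the same processing.

What passing tests on these stimuli show: that the *mechanisms* — emergent
PE bias, the meta-d′/d′ dissociation, the latent-geometry explanation, the
single-unit opt-out signature, the lesion dissociations — arise from
performance optimization on high-dimensional stimuli with variable contrast
and noise. What they do not show: quantitative agreement with results on
real handwritten digits or natural images; within-class variability here is
far simpler than handwriting.

The 2-d latent-evidence generator (`sample_latent_evidence()`) draws from
two rotated anisotropic Gaussians with controllable axis angles and
anisotropy, and exists so the ideal-observer machinery can be tested by
exact parameter recovery, independent of any trained autoencoder.

## Networks and training

The encoder is 3 conv layers (32 channels, kernel 3, stride 2, batch norm,
leaky ReLU slope 0.01) followed by fully connected layers of 256 and 128
units (batch norm + leaky ReLU) and a linear 100-unit output. The
supervised model adds a classification head (softmax for 10-way, a single
sigmoid p(s2) for two-choice) and a sigmoid confidence head trained with
binary cross-entropy toward 1 when the *current* classification output is
correct (the correctness target is recomputed every step from the live
class head, in training mode). Both losses are summed; Adam, lr 5e-4,
batch 32, 5 epochs at full scale. The actor–critic variant replaces the
heads with a 3-way softmax actor (LEFT, RIGHT, OPT-OUT) and a linear
critic; correct decisions earn reward 1, errors 0, and opting out earns
r_opt-out, initialized at 0.5 and updated after each batch to
min(previous-batch non-opt-out accuracy, 0.75). The critic minimizes a
Huber loss on reward; the actor loss is −log p(a) δ with δ = r − v. At full
scale training runs 5000 iterations, lr 1e-3, batch 32.

Because no deep-learning framework is a dependency, the package carries its
own small engine (`R/nn-engine.R`): activations are feature × batch
matrices in a channel-first planar layout, convolutions are an index gather
plus one matrix product, and their adjoints use a `rowsum()` scatter.
Weights and biases are initialized fan-in-scaled uniform
(±1/√fan_in) so runs are reproducible across platforms; the test suite
checks every layer's analytic gradient against central differences.
Batch-norm uses batch statistics during training and running statistics
(momentum 0.1, eps 1e-5) at evaluation. Decisions at evaluation are argmax;
an RL trial is an opt-out when OPT-OUT is the argmax over all three
actions, and accuracy is computed over LEFT/RIGHT trials only. Sampling
the actor stochastically at evaluation is available in principle but argmax
is the default, matching how accuracy and opt-out rate are defined.

## The latent ideal observer

A denoising VAE (same encoder trunk, two 2-unit heads for posterior means
and log-variances; decoder 128 → 256 fully connected, then three
transposed convolutions — kernel 4, stride 2, channels 32, 32, 1 — ending
in tanh) is trained for 20 epochs at full scale to reconstruct the *clean*
(pre-noise) image, with the reconstruction error summed over pixels and
averaged over the batch, plus the KL divergence of q(z|x) from the unit
normal. Summing (not averaging) the pixel error keeps the reconstruction
and KL terms on the scales at which a 2-d latent neither collapses nor
ignores the prior.

Class-conditional bivariate Gaussians are fitted to the latent embeddings
of labelled images. By default the fit uses posterior *means* — a
lower-variance estimate of the layout than posterior samples; fitting to
samples is available (`use_posterior_samples = TRUE`) since the source
leaves this unstated. Priors are 0.5/0.5. The ideal observer computes the
posterior by Bayes rule (densities via Cholesky factorization), decides by
argmax, and reports the maximum posterior as confidence; an exact tie (a
probability-zero event) deterministically chooses s1, so confidence is
always ≥ 0.5. Condition-level accuracy and confidence are Monte-Carlo
averages over latents drawn from a test-condition distribution (default
10⁴ draws; closed forms are unavailable because unequal covariances make
the optimal boundary non-quadratic).

Latent geometry: each class covariance is eigendecomposed; the anisotropy
ratio is √(λ₁/λ₂) and each major axis has an angle in [0°, 180°). The
inter-axis separation θ is canonicalized to [0°, 90°] (min(d, 180 − d)):
axes are undirected, so d and 180 − d describe the same configuration, and
this convention is the one invariant under joint rotations of both classes.
Isotropic classes are flagged degenerate with θ = 0.

## Type-1 and type-2 measures

`dprime()` is z(HR) − z(FAR) with hit = responding s2 to s2; if any
stimulus × response cell is empty, 0.5 is added to every cell (log-linear
correction). `fit_meta_dprime()` bins confidence at empirical quantiles
(default 4 bins — the source states quantile criteria but not a count; the
bin count is an exposed parameter), forms the stimulus × response × rating
table (same 0.5 correction when any cell is empty), and maximizes the
type-2 likelihood under the equal-variance meta-SDT model with the type-2
criterion tied to the type-1 relative criterion c′ = c/d′. Rating criteria
are parameterized as positive gaps from the meta criterion so ordering is
maintained by construction; optimization uses `nlminb`. Response-specific
meta-d′ maximizes the same likelihood restricted to one response.
Degenerate confidence distributions (too few distinct quantiles) raise an
explicit error rather than returning a number. Type-2 noise
(`add_type2_noise()`) clips confidence to [1e-6, 1 − 1e-6], adds
Normal(0, ξ) on the logit scale (ξ is a variance), and maps back.

The blindsight analysis re-derives the *entire* operating point from the
post-lesion record: confidence criteria from the empirical confidence
distribution (automatic, since binning is quantile-based), and the type-1
criterion from the median of the decision variable
(`dprime_empirical()`). A 0.01× first-layer lesion displaces the decision
output's operating point far past the nominal 0.5 criterion — every trial
would receive the same response, and criterion-bound d′ would conflate that
induced response bias with a loss of sensitivity the lesioned network does
not actually have.

## Experiments

PE-bias runners calibrate contrast per condition by a grid sweep with
linear interpolation to the target accuracy (75% for two-choice), then
gate every comparison on accuracy balance before reporting confidence: the
tolerance is 1 percentage point plus twice the binomial standard error of
the accuracy difference at the effective (non-opt-out) trial count, so the
gate scales from desk-size runs to full test sets. The dissociation battery
presents s1 at a fixed intermediate contrast and sweeps s2 over five
contrasts, injects type-2 noise (reference ξ = 1.2, the fitted full-scale
value), and fits response-specific meta-d′ per condition. The evidence grid
evaluates superimposed stimuli over all (μ_s1, μ_s2) combinations and
regresses per-cell mean confidence on the BE predictor (μ_s2 − μ_s1; a
logit-transformed-DV variant is tried and kept when it fits better, with R²
always computed back on the raw confidence scale so models remain
comparable), the RCE predictor (mean contrast of the chosen class), the
ideal observer's per-cell confidence, and a noise ceiling (the mean pattern
of the other replicates).

Decoding analyses train a bias-free linear probe with a sigmoid output on
concatenated activations — all six tap points (11,236 features) or the
penultimate 100 — by Adam with cross-entropy; evidence estimates average
|w|·x over negative-weight dimensions (e_s1) and w·x over positive-weight
dimensions (e_s2), and a decoder with single-signed weights raises an error
because the estimates are undefined there. Choice probability is the area
under the nonparametric ROC (trapezoidal, hence exactly the rank-sum
statistic under ties); the high-confidence threshold is 0.75.

Simulated TMS adds independent Gaussian noise (variance ξ) to one encoder
block's activations after its nonlinearity; lesions scale them. ξ = 0 and
scale = 1 are exact no-ops, and perturbation at one block leaves upstream
activations bit-identical (both regression-tested).

Single-unit analysis regresses each penultimate unit's activation onto the
logits of the s2-choice and opt-out outputs, classifies units by the sign
of ΔR², takes the preferred class from the decision-fit slope, and compares
normalized activity across T_in / T_S / T_opp choices with paired t-tests.
Normalized activity subtracts each neuron's across-trial minimum and
divides by the mean of per-neuron variances (default: its square root, for
dimensional consistency; the literal variance mode is retained). Pooling
*centered* per-neuron variances — rather than the variance of the flattened
activation matrix — is what makes the measure invariant to adding a
constant to any one neuron, which the source's verbal description requires
but its formula leaves ambiguous (its own figure caption describes a
different, baseline-referenced normalization; the discrepancy is inherited,
not resolvable here).

## Problem sizes

The test suite and acceptance script use desk-scale versions of the study
design, chosen so each mechanism is comfortably detectable at the package's
default seeds: two network replicates per experiment (the full design uses
100), supervised training of 3–4 epochs on ~1,200–2,000 generated images,
RL training of 1,200–2,000 iterations (full design 5,000), 500–3,000
evaluation trials per condition, VAE training of 8 epochs on 1,200 images
(full design 20 epochs on a full training set), and Monte-Carlo/recovery
suites at n = 10⁴–10⁵. Replicate counts and sizes are exposed as
parameters everywhere (`n_networks`, `train_n`, `epochs`, `iterations`,
`n_trials`), so full-scale runs are configuration changes, not code
changes.

## Known limitations

* The desk-scale fixed-μ regime produces only a weak and replicate-noisy
  reversal of the PE bias on the two-class synthetic task: with confidence
  saturating on an easy two-choice task, the noise-tracking component of
  confidence is comparable in size to contrast-extrapolation variability
  across small replicate counts. The full-scale design (10-way
  classification at threshold difficulty, 100 replicates) is where this
  manipulation has its power.
* The engine is CPU-bound R; it is fast enough for the desk-scale designs
  here (≈70 ms per training iteration at batch 32) but not for
  CIFAR-10-class residual networks, whose architecture is documented but
  out of scope.
* meta-d′ assumes Gaussian type-2 distributions; after severe lesions the
  confidence distributions are strongly non-Gaussian and small negative
  meta-d′ values can occur.
* The MNIST IDX loader (`read_idx_images()`) is provided for users who
  have the files locally, but nothing in the package or its tests depends
  on it.
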