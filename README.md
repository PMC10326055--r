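# metacognet

Performance-optimized neural network models of decision confidence, in R.

## The scientific problem

When an observer classifies a noisy stimulus, they can also report
*confidence* — a prediction of the probability that the decision is correct.
Psychophysics has documented systematic dissociations between decisions and
confidence that look irrational under the classical detection-theoretic
account. In the standard two-dimensional signal-detection picture, each
stimulus class contributes an evidence dimension, and the optimal confidence
rule is the **balance of evidence** (BE), `e_s2 − e_s1`. Yet behavior is
often better described by a **response-congruent evidence** (RCE) heuristic
that ignores the evidence against the choice, producing the **positive
evidence (PE) bias** (higher confidence when both signal and noise are high,
despite matched accuracy) and a dissociation in which type-2 sensitivity
(meta-d′) falls while type-1 sensitivity (d′) rises.

`metacognet` implements, end to end, a modeling program that resolves this
tension: train a convolutional network jointly to classify 32×32 stimuli and
to predict its own probability of being correct
(`p(ŷ = y) = g_conf(f(x))`), or train an actor–critic network on an opt-out
task where declining to decide earns a small guaranteed reward
(`r_opt-out = min(p(correct), 0.75)`, updated per batch). The biased
confidence behavior *emerges* from performance optimization. A denoising
variational autoencoder then compresses the stimulus distribution into a
two-dimensional latent space; bivariate Gaussians fitted per class define a
Bayesian ideal observer,

    p(y = s1 | z) = p(z | s1) p(s1) / [ p(z | s1) p(s1) + p(z | s2) p(s2) ],
    ŷ = argmax posterior,   confidence = max posterior,

whose confidence function — under the empirically fitted latent structure of
elongated (σ_major/σ_minor ≈ 2.4) and *non-parallel* (θ ≈ 51°) class
distributions — reproduces the same "irrational" biases. The package also
includes the analyses built on this core: maximum-likelihood meta-d′ with
response-specific variants, contrast calibration, the PE-bias and
dissociation batteries, evidence-grid regressions (BE vs RCE vs ideal
observer), PCA population geometry, single-unit opt-out analyses with
normalized activity, linear probe decoders with signed-weight evidence
estimates and ROC/choice-probability analyses, and simulated TMS
(additive activation noise) and lesions (activation scaling), including the
blindsight configuration.

Everything runs on synthetic data generated in-package (Gabor patches for
the orientation task; a two-class image generator standing in for a
handwritten-digit pair), so no downloads are required. A small vectorized
neural-network engine (conv / transposed-conv / batch-norm / Adam) backs the
models; its gradients are verified against numerical derivatives in the test
suite.

## A worked example

Train an actor–critic network on the opt-out orientation task and look at
its implicit confidence behavior:

```r
library(metacognet)

net <- build_confidence_network("rl_gabor", seed = 7)
net <- train_rl_actor_critic(net, iterations = 1500, seed = 8)

for (mu in c(0.1, 0.5, 1)) {
  b <- gabor_batch(800, mu = mu, sigma = 0.75, seed = 100 + round(100 * mu))
  s <- summarize_record(evaluate_trials(net, b))
  cat(sprintf("mu=%.2f  accuracy=%.3f  opt-out=%.3f\n",
              mu, s$accuracy, s$opt_out_rate))
}
#> mu=0.10  accuracy=0.598  opt-out=0.860
#> mu=0.50  accuracy=0.950  opt-out=0.278
#> mu=1.00  accuracy=0.994  opt-out=0.019
```

The network opts out most when the stimulus is weakest — the opt-out rate is
an implicit confidence report. Its penultimate layer reproduces the
single-neuron signature seen in parietal cortex: decision neurons (those
with `R²_decision > R²_opt-out`) are most active when their preferred
stimulus is chosen, intermediate when the network opts out, and least active
when the opposite stimulus is chosen:

```r
b   <- gabor_batch(3000, seed = 99)
rec <- evaluate_trials(net, b, store_activations = TRUE)
us  <- single_unit_analysis(attr(rec, "activations")$encoder_out, rec)
dn  <- subset(us$units, class == "decision")
colMeans(dn[, c("act_t_in", "act_t_s", "act_t_opp")])
#>  act_t_in   act_t_s act_t_opp
#>  3.13      2.14      1.21
us$tests$t_in_vs_t_s$p.value      # 2.8e-15
us$tests$t_s_vs_t_opp$p.value     # 2.6e-12
```

Higher-level experiments are driven through the harness, e.g.

```r
cfg <- experiment_config("blindsight", n_networks = 2, seed = 1)
dir <- run_experiment(cfg)
report_experiment(dir)
```

or from a shell via `inst/cli/confidence-lab.R`.

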