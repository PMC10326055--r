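# Shared fixtures: small trained models are expensive, so they are built
# once per test run and memoized here. All sizes are desk-scale versions of
# the full study conditions.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_test_pool <- function() memo("test_pool", function() {
  make_synthetic_classes(600, 5, seed = 5000)
})

train_small_net <- function(seed, regime_name = "standard",
                            sigma_range = c(1, 2), train_n = 1200,
                            epochs = 3) {
  pool <- make_synthetic_classes(train_n %/% 2, 5, seed = seed)
  reg <- regime(regime_name, sigma_range = sigma_range)
  batch <- make_stimulus_batch(pool$raw, pool$labels, reg = reg,
                               seed = seed + 1)
  net <- build_confidence_network("two_choice", seed = seed + 2)
  train_supervised(net, batch, epochs = epochs, seed = seed + 3)
}

fix_std_nets <- function() memo("std_nets", function() {
  lapply(c(100, 197), train_small_net)
})

fix_fixedmu_nets <- function() memo("fixedmu_nets", function() {
  lapply(c(300, 397), train_small_net, regime_name = "fixed_mu")
})

fix_blindsight_nets <- function() memo("blindsight_nets", function() {
  lapply(c(500, 597), train_small_net, sigma_range = c(3, 4))
})

fix_rl_nets <- function() memo("rl_nets", function() {
  lapply(c(700, 797), function(s) {
    net <- build_confidence_network("rl_gabor", seed = s)
    train_rl_actor_critic(net, iterations = 1200, seed = s + 1)
  })
})

fix_vae <- function() memo("vae", function() {
  pool <- make_synthetic_classes(600, 5, seed = 900)
  vae <- build_vae(seed = 901)
  train_vae(vae, pool$raw, pool$labels, epochs = 8, seed = 902)
})

# mean accuracy over nets at contrast mu, for calibration sweeps
pool_accuracy_fn <- function(nets, pool, sigma, n_trials = 400, seed = 7) {
  cb <- get("condition_batch", asNamespace("metacognet"))
  function(mu) {
    mean(vapply(seq_along(nets), function(i) {
      b <- cb(pool$raw, pool$labels, mu, sigma, n_trials,
              seed = seed + i + round(1e4 * mu))
      summarize_record(evaluate_trials(nets[[i]], b))$accuracy
    }, numeric(1)))
  }
}

# forward-simulated meta-SDT observer: type-1 from N(+-d/2) vs criterion c1,
# type-2 from the meta-level distributions truncated to the response side
simulate_meta_observer <- function(d, meta_d, n, c1 = 0, seed = 1) {
  set.seed(seed)
  lab <- sample(1:2, n, TRUE)
  x <- stats::rnorm(n, ifelse(lab == 1, -d / 2, d / 2))
  dec <- ifelse(x > c1, 2L, 1L)
  mc <- (c1 / d) * meta_d
  mu2 <- ifelse(lab == 1, -meta_d / 2, meta_d / 2)
  u <- stats::runif(n)
  x2 <- numeric(n)
  hi <- dec == 2L
  p_mc <- stats::pnorm(mc - mu2)
  x2[hi] <- stats::qnorm(p_mc[hi] + u[hi] * (1 - p_mc[hi])) + mu2[hi]
  x2[!hi] <- stats::qnorm(u[!hi] * p_mc[!hi]) + mu2[!hi]
  rec <- data.frame(label = lab, decision = dec,
                    confidence = pmin(abs(x2 - mc) / 4, 1), opt_out = FALSE)
  rec$correct <- rec$decision == rec$label
  rec
}
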