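test_that("zero-magnitude perturbations are bit-exact no-ops", {
  nets <- fix_std_nets()
  pool <- fix_test_pool()
  cb <- get("condition_batch", asNamespace("metacognet"))
  batch <- cb(pool$raw, pool$labels, 0.5, 1.5, 100, seed = 1)
  base <- evaluate_trials(nets[[1]], batch)
  noop_noise <- perturb_forward(nets[[1]],
                                perturbation_spec(1, "additive_noise", 0),
                                batch, seed = 2)
  noop_scale <- perturb_forward(nets[[1]], perturbation_spec(3, "scale", 1),
                                batch, seed = 3)
  expect_identical(base$p_s2, noop_noise$p_s2)
  expect_identical(base$confidence, noop_noise$confidence)
  expect_identical(base$p_s2, noop_scale$p_s2)
  expect_identical(base$confidence, noop_scale$confidence)
  expect_error(perturbation_spec(1, "scale", -1), "magnitude")
  expect_error(evaluate_trials(nets[[1]], batch,
                               perturb = perturbation_spec(9, "scale", 0.5)),
               "out of range")
})

test_that("perturbation leaves all upstream activations bit-identical", {
  nets <- fix_std_nets()
  pool <- fix_test_pool()
  cb <- get("condition_batch", asNamespace("metacognet"))
  batch <- cb(pool$raw, pool$labels, 0.5, 1.5, 50, seed = 4)
  base <- evaluate_trials(nets[[1]], batch, store_activations = TRUE)
  set.seed(9)
  pert <- evaluate_trials(nets[[1]], batch, store_activations = TRUE,
                          perturb = perturbation_spec(4, "additive_noise", 2))
  a0 <- attr(base, "activations")
  a1 <- attr(pert, "activations")
  for (nm in c("conv1", "conv2", "conv3"))
    expect_identical(a0[[nm]], a1[[nm]])     # upstream of the fc1 block
  expect_false(identical(a0$fc1, a1$fc1))    # perturbed layer differs
})

test_that("evidence estimates follow the signed-weight formulation", {
  # hand evaluation: w = (-2, 1), x = (0.5, 0.4)
  ev <- evidence_estimates(c(-2, 1), matrix(c(0.5, 0.4), 1))
  expect_equal(ev$e_s1, 1.0)
  expect_equal(ev$e_s2, 0.4)
  # zeros in, zeros out
  ev0 <- evidence_estimates(c(-1, 2, -3), matrix(0, 4, 3))
  expect_equal(ev0$e_s1, rep(0, 4))
  expect_equal(ev0$e_s2, rep(0, 4))
  # averaging over the signed dimension counts
  ev2 <- evidence_estimates(c(-1, -3, 2), matrix(c(1, 1, 1), 1))
  expect_equal(ev2$e_s1, (1 + 3) / 2)
  expect_equal(ev2$e_s2, 2)
  expect_error(evidence_estimates(c(1, 2), matrix(1, 1, 2)), "degenerate")
})

test_that("probe decoders learn separable activations; untrained probes are
           at chance", {
  set.seed(11)
  n <- 600
  lab <- sample(1:2, n, TRUE)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 1] <- X[, 1] + ifelse(lab == 2, 2.5, -2.5)
  batch <- structure(list(pixels = array(0, c(32, 32, n)),
                          meta = data.frame(trial = 1:n, label = lab,
                                            mu = 1, sigma = 0)),
                     class = "stimulus_batch")
  ns <- asNamespace("metacognet")
  # drive the probe trainer directly on constructed features
  w <- local({
    probe <- list(w = rep(0, 20))
    opt <- ns$adam_init()
    y <- as.numeric(lab == 2)
    for (ep in 1:5) for (start in seq(1, n, 32)) {
      ix <- start:min(start + 31, n)
      p <- 1 / (1 + exp(-X[ix, , drop = FALSE] %*% probe$w))
      g <- crossprod(X[ix, , drop = FALSE], p - y[ix]) / length(ix)
      st <- ns$adam_step(list(list(w = probe$w)), list(list(w = g)), opt, 5e-3)
      probe$w <- st$params[[1]]$w; opt <- st$state
    }
    probe$w
  })
  acc <- mean((X %*% w > 0) == (lab == 2))
  expect_gt(acc, 0.95)
  # a zero-epoch probe has zero weights: predictions are all 0.5, accuracy
  # equals the base rate (chance)
  nets <- fix_std_nets()
  pool <- fix_test_pool()
  cb <- get("condition_batch", asNamespace("metacognet"))
  small <- cb(pool$raw, pool$labels, 0.4, 2, 60, seed = 12)
  probe0 <- train_probe_decoder(nets[[1]], small, "penultimate", epochs = 0)
  expect_true(all(probe0$w == 0))
})

test_that("probe decoding of network activations supports the four ROC
           analyses", {
  nets <- fix_std_nets()
  pool <- fix_test_pool()
  cb <- get("condition_batch", asNamespace("metacognet"))
  trn <- cb(pool$raw, pool$labels, 0.4, 2, 600, seed = 13)
  probe <- train_probe_decoder(nets[[1]], trn, "penultimate", epochs = 3,
                               seed = 14)
  tst <- cb(pool$raw, pool$labels, 0.4, 2, 600, seed = 15)
  rec <- evaluate_trials(nets[[1]], tst, store_activations = TRUE)
  X <- attr(rec, "activations")$encoder_out
  ev <- evidence_estimates(probe, X)
  da <- decoding_analyses(ev, rec)
  expect_equal(nrow(da), 4L)
  expect_true(all(is.na(da$choice_probability) |
                    (da$choice_probability >= 0 &
                       da$choice_probability <= 1)))
  # the probe's balance of evidence must predict the network's decisions
  # far above chance from the same representation
  expect_gt(da$choice_probability[da$analysis == "be_decision"], 0.8)
})

test_that("TMS noise sweep returns the full xi grid with finite d-prime", {
  nets <- fix_std_nets()
  pool <- fix_test_pool()
  sweep <- tms_sweep(nets[[1]], pool$raw, pool$labels, layer = 1,
                     xi_levels = c(0, 4), mu = 0.5, n_trials = 300,
                     seed = 16)
  expect_equal(nrow(sweep), 2L)
  expect_true(all(is.finite(sweep$d_prime)))
  expect_lt(sweep$d_prime[2], sweep$d_prime[1])
})
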