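test_that("contrast calibration inverts an analytic psychometric function", {
  # accuracy(mu) = Phi(2 mu): target 0.75 has the closed-form solution
  # qnorm(0.75) / 2 ~ 0.3372
  grid <- seq(0, 1, length.out = 101)
  cal <- calibrate_contrast(function(mu) pnorm(2 * mu), 0.75, grid)
  expect_lt(abs(cal$contrast - qnorm(0.75) / 2), 0.011)
  # chance target: minimal grid contrast plus a warning
  expect_warning(low <- calibrate_contrast(function(mu) pnorm(2 * mu) ,
                                           0.5, grid),
                 "minimal contrast")
  expect_equal(low$contrast, 0)
  expect_error(calibrate_contrast(function(mu) pnorm(2 * mu), 0.999, grid),
               "not reachable")
})

test_that("superimposed batches label the higher-contrast class", {
  pool <- make_synthetic_classes(30, 5, seed = 1)
  r1 <- pool$raw[, , pool$labels == 1, drop = FALSE]
  r2 <- pool$raw[, , pool$labels == 2, drop = FALSE]
  b <- superimposed_batch(r1, r2, mu_s1 = c(0.9, 0.2), mu_s2 = c(0.3, 0.8),
                          sigma = 0, n = 10, seed = 2)
  expect_equal(b$meta$label, rep(c(1L, 2L), 5))
  expect_true(all(b$pixels >= -1 & b$pixels <= 1))
})

test_that("identical PE conditions give zero differences and pass the gate", {
  # an evaluator driven only by the trial metadata, independent of pixels
  fake <- structure(list(), class = "fake_eval")
  registerS3method("evaluate_trials", "fake_eval",
                   function(net, batch, ...) {
                     n <- nrow(batch$meta)
                     set.seed(sum(batch$meta$label) %% 1000L)
                     rec <- data.frame(batch$meta,
                                       decision = sample(1:2, n, TRUE),
                                       confidence = runif(n),
                                       opt_out = FALSE)
                     rec$correct <- rec$decision == rec$label
                     rec
                   },
                   envir = environment(evaluate_trials))
  pool <- make_synthetic_classes(50, 5, seed = 3)
  res <- pe_bias_v1(list(fake, fake), low_pe = c(0.4, 1),
                    high_pe = c(0.4, 1),
                    stimuli = list(raw = pool$raw, labels = pool$labels),
                    n_trials = 200, seed = 4)
  expect_true(res$balanced)
  expect_equal(res$confidence_diff, 0)
  expect_equal(res$accuracy_diff, 0)
})

test_that("pe_bias_v2 validates the contrast ordering", {
  pool <- make_synthetic_classes(20, 5, seed = 5)
  r1 <- pool$raw[, , pool$labels == 1, drop = FALSE]
  r2 <- pool$raw[, , pool$labels == 2, drop = FALSE]
  expect_error(pe_bias_v2(list(), r1, r2, mu_nontarget_low = 0.6,
                          mu_nontarget_high = 0.7),
               "below target")
})

test_that("confidence regressions recover constructed generative rules", {
  set.seed(6)
  mu_values <- seq(0.1, 1, length.out = 12)
  cells <- expand.grid(mu_s1 = mu_values, mu_s2 = mu_values)
  rce <- ifelse(cells$mu_s2 > cells$mu_s1, cells$mu_s2, cells$mu_s1)
  mk_grid <- function(conf) {
    g <- cbind(cells, accuracy = 0.75, confidence = conf, rce = rce)
    class(g) <- c("grid_result", "data.frame")
    g
  }
  # confidence an exact linear function of RCE
  r_exact <- confidence_regressions(list(mk_grid(0.2 + 0.6 * rce),
                                         mk_grid(0.2 + 0.6 * rce)))
  expect_equal(r_exact$per_net$r2_rce, c(1, 1), tolerance = 1e-9)
  expect_true(r_exact$noise_ceiling_available)
  expect_equal(r_exact$per_net$r2_ceiling, c(1, 1), tolerance = 1e-9)
  # confidence = BE + independent noise: BE fits better than RCE
  be <- cells$mu_s2 - cells$mu_s1
  conf_be <- 0.5 + 0.3 * be + rnorm(nrow(cells), sd = 0.02)
  r_be <- suppressWarnings(
    confidence_regressions(list(mk_grid(pmin(pmax(conf_be, 0), 1)))))
  expect_gt(r_be$per_net$r2_be, r_be$per_net$r2_rce)
  expect_warning(confidence_regressions(list(mk_grid(conf_be))),
                 "noise ceiling")
  # the ideal-observer predictor column is honored
  io_conf <- 0.4 + 0.5 * rce
  r_io <- suppressWarnings(
    confidence_regressions(list(mk_grid(0.4 + 0.5 * rce)),
                           io_confidence = io_conf))
  expect_equal(r_io$per_net$r2_io, 1, tolerance = 1e-9)
})

test_that("type-2 noise fitting recovers the injected noise level", {
  recs <- lapply(1:3, function(i) simulate_meta_observer(1.5, 1.5, 8000,
                                                         seed = 70 + i))
  # target pattern = meta-d' measured after injecting xi = 1 noise
  target <- sapply(seq_along(recs), function(i)
    fit_meta_dprime(add_type2_noise(recs[[i]], 1, seed = 200 + i))$meta_d_prime)
  fit <- fit_type2_noise(recs, target, xi_grid = c(0.25, 0.5, 1, 1.5, 2),
                         seed = 300)
  expect_equal(fit$xi, 1)
})
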