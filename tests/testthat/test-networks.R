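test_that("network heads have the stated shapes and normalizations", {
  pool <- make_synthetic_classes(8, 5, seed = 1)
  batch <- make_stimulus_batch(pool$raw, pool$labels, mu = 0.8, sigma = 0.5,
                               seed = 2)
  ns <- asNamespace("metacognet")
  ten <- build_confidence_network("ten_choice", seed = 3)
  fw <- ns$net_forward(ten, batch$pixels)
  expect_equal(dim(fw$class), c(16L, 10L))
  expect_equal(rowSums(fw$class), rep(1, 16), tolerance = 1e-6)
  expect_equal(nrow(fw$features), 100L)  # encoder output dimensionality
  two <- build_confidence_network("two_choice", seed = 4)
  fw2 <- ns$net_forward(two, batch$pixels)
  expect_length(fw2$class, 16L)          # single p(class = s2) per trial
  expect_true(all(fw2$class > 0 & fw2$class < 1))
  expect_true(all(fw2$conf > 0 & fw2$conf < 1))
  rl <- build_confidence_network("rl_gabor", seed = 5)
  fw3 <- ns$net_forward(rl, batch$pixels)
  expect_equal(rowSums(fw3$actor), rep(1, 16), tolerance = 1e-6)
})

test_that("supervised training reduces loss and learns the task", {
  # easy conditions: separable classes under mild noise
  pool <- make_synthetic_classes(400, 5, seed = 11)
  batch <- make_stimulus_batch(pool$raw, pool$labels, mu = 0.9, sigma = 0.4,
                               seed = 12)
  net <- build_confidence_network("two_choice", seed = 13)
  net <- train_supervised(net, batch, epochs = 3, seed = 14)
  log <- attr(net, "training_log")
  expect_lt(log$loss[nrow(log)], log$loss[1])
  held <- make_synthetic_classes(250, 5, seed = 15)
  hb <- make_stimulus_batch(held$raw, held$labels, mu = 0.9, sigma = 0.4,
                            seed = 16)
  rec <- evaluate_trials(net, hb)
  expect_gt(mean(rec$correct), 0.95)
  # confidence discriminates correct from error trials held out under the
  # harder standard regime
  hb2 <- make_stimulus_batch(held$raw, held$labels,
                             reg = regime("standard"), seed = 17)
  rec2 <- evaluate_trials(net, hb2)
  if (any(!rec2$correct))
    expect_gt(mean(rec2$confidence[rec2$correct]),
              mean(rec2$confidence[!rec2$correct]))
  expect_error(train_supervised(net,
                                list(pixels = array(0, c(32, 32, 0)),
                                     meta = batch$meta[0, ])),
               "empty")
})

test_that("training is bit-reproducible given identical seeds", {
  pool <- make_synthetic_classes(60, 5, seed = 21)
  batch <- make_stimulus_batch(pool$raw, pool$labels, mu = 0.8, sigma = 1,
                               seed = 22)
  one <- function() {
    net <- build_confidence_network("two_choice", seed = 23)
    train_supervised(net, batch, epochs = 1, seed = 24)
  }
  a <- one(); b <- one()
  expect_identical(a$encoder[[1]]$params$W, b$encoder[[1]]$params$W)
  expect_identical(a$heads$conf$params$W, b$heads$conf$params$W)
})

test_that("behavioral records have per-trial integrity", {
  nets <- fix_rl_nets()
  b <- gabor_batch(400, seed = 31)
  rec <- evaluate_trials(nets[[1]], b)
  expect_equal(nrow(rec), 400L)
  nOO <- !rec$opt_out
  expect_equal(rec$correct[nOO], (rec$decision == rec$label)[nOO])
  expect_true(all(is.na(rec$correct[rec$opt_out])))
  # RL accuracy excludes opt-out trials from the denominator
  s <- summarize_record(rec)
  expect_equal(s$accuracy, mean((rec$decision == rec$label)[nOO]))
  # decisions take the LEFT/RIGHT argmax even on opt-out trials
  expect_equal(rec$decision, ifelse(rec$p_left >= rec$p_right, 1L, 2L))
  expect_equal(rec$opt_out,
               rec$p_optout > pmax(rec$p_left, rec$p_right))
})

test_that("RL training keeps the guaranteed reward in range and learns
           contrast-dependent opting out", {
  nets <- fix_rl_nets()
  for (net in nets)
    expect_true(net$r_opt_out >= 0 && net$r_opt_out <= 0.75)
  # opt-out rate is non-increasing in contrast at fixed noise (5-point grid,
  # allowing small sampling wiggle)
  for (net in nets) {
    oo <- sapply(seq(0.15, 0.95, length.out = 5), function(mu) {
      b <- gabor_batch(500, mu = mu, sigma = 0.75,
                       seed = 41 + round(100 * mu))
      mean(evaluate_trials(net, b)$opt_out)
    })
    expect_true(all(diff(oo) < 0.05))
    expect_lt(oo[5], oo[1])
  }
})

test_that("checkpoints round-trip through a single-file archive", {
  net <- build_confidence_network("two_choice", seed = 51)
  path <- file.path(tempdir(), "net.rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(net2$encoder[[1]]$params$W, net$encoder[[1]]$params$W)
  expect_identical(net2$task, net$task)
  expect_identical(net2$seed, net$seed)
})
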