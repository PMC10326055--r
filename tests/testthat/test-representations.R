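test_that("PCA geometry: variance fractions, low-rank data, permutation", {
  set.seed(1)
  A <- matrix(rnorm(200 * 8), 200, 8)
  g <- pca_geometry(A)
  expect_equal(sum(g$var_frac), 1, tolerance = 1e-9)
  # data spanned by two fixed directions + tiny noise
  v1 <- rnorm(20); v2 <- rnorm(20)
  low <- outer(rnorm(300), v1) + outer(rnorm(300), v2) +
    matrix(rnorm(300 * 20, sd = 1e-3), 300, 20)
  gl <- pca_geometry(low)
  expect_gt(sum(gl$var_frac[1:2]), 0.999)
  # neuron permutation leaves scores unchanged up to sign
  perm <- sample(20)
  gp <- pca_geometry(low[, perm])
  expect_lt(min(abs(cor(gl$scores[, 1], gp$scores[, 1]) - c(-1, 1))), 1e-6)
  expect_error(pca_geometry(matrix(1, 5, 3)), "rank")
})

test_that("geometry regressions report exact fits for constructed data", {
  set.seed(2)
  n <- 400
  pc1 <- rnorm(n)
  scores <- cbind(pc1, abs(pc1))
  geom <- structure(list(scores = scores, loadings = diag(2),
                         var_frac = c(0.7, 0.3)), class = "pca_geometry")
  p_s2 <- 1 / (1 + exp(-3 * pc1))
  rec <- data.frame(label = ifelse(pc1 > 0, 2L, 1L),
                    decision = ifelse(p_s2 > 0.5, 2L, 1L),
                    confidence = 1 / (1 + exp(-2 * abs(pc1))),
                    p_s2 = p_s2, opt_out = FALSE)
  rec$correct <- rec$decision == rec$label
  r <- geometry_regressions(geom, rec)
  expect_equal(r$acc_pc1_class, 1)            # separable 1-d logistic case
  expect_equal(r$r2_abs_pc1_pc2, 1)           # PC2 constructed as |PC1|
  expect_equal(r$r2_pc1_decision, 1, tolerance = 1e-6)
  expect_equal(r$r2_pc2_confidence, 1, tolerance = 1e-6)
  expect_error(geometry_regressions(geom, transform(rec, label = 1L)),
               "single stimulus")
})

test_that("rectified decision output maps p(s2) to p(chosen)", {
  rec <- data.frame(p_s2 = c(0.2, 0.5, 0.9))
  expect_equal(rectified_decision_output(rec), c(0.8, 0.5, 0.9))
})

test_that("normalized activity matches a brute-force implementation", {
  # hand-sized matrix: 3 trials x 2 neurons, integer activations
  A <- matrix(c(1, 4, 2,
                5, 5, 8), 3, 2)
  out <- normalized_activity(A, mode = "variance")
  # independent elementwise oracle
  oracle <- A
  for (j in 1:2) oracle[, j] <- A[, j] - min(A[, j])
  pooled <- (var(A[, 1]) + var(A[, 2])) / 2
  oracle <- oracle / pooled
  expect_equal(out, oracle)
  out_sd <- normalized_activity(A, mode = "sd")
  expect_equal(out_sd, oracle * sqrt(pooled))
  # each neuron's minimum trial maps to exactly 0
  expect_equal(apply(out, 2, min), c(0, 0))
  # constant neuron normalizes to all zeros
  B <- cbind(A[, 1], 3)
  expect_equal(normalized_activity(B)[, 2], rep(0, 3))
  expect_error(normalized_activity(matrix(2, 4, 3)), "dispersion")
})

test_that("normalized activity is translation-invariant per neuron", {
  set.seed(3)
  A <- matrix(rnorm(50 * 4), 50, 4)
  B <- A; B[, 2] <- B[, 2] + 7
  # adding a constant to one neuron changes only that neuron's minimum,
  # leaving all normalized values unchanged
  expect_equal(normalized_activity(A), normalized_activity(B),
               tolerance = 1e-12)
  expect_equal(normalized_activity(A, "variance"),
               normalized_activity(B, "variance"), tolerance = 1e-12)
})

test_that("constructed decision units are classified and partitioned", {
  set.seed(4)
  n <- 600
  dv <- rnorm(n)          # latent decision variable
  cv <- rnorm(n)          # latent confidence variable
  p_right <- 1 / (1 + exp(-3 * dv))
  p_optout <- 1 / (1 + exp(-2 * cv))
  rec <- data.frame(label = ifelse(dv > 0, 2L, 1L),
                    decision = ifelse(dv > 0, 2L, 1L),
                    p_right = p_right, p_optout = p_optout,
                    opt_out = p_optout > pmax(p_right, 1 - p_right))
  rec$correct <- TRUE
  acts <- cbind(dv + rnorm(n, sd = 0.05),      # decision unit, prefers s2
                -dv + rnorm(n, sd = 0.05),     # decision unit, prefers s1
                cv + rnorm(n, sd = 0.05),      # confidence unit
                rnorm(n))                      # uninformative
  us <- single_unit_analysis(acts, rec)
  expect_equal(us$units$class[1:3], c("decision", "decision", "confidence"))
  expect_gt(us$units$r2_decision[1], 0.9)
  expect_lt(us$units$r2_opt_out[1], 0.1)
  expect_equal(us$units$t_in[1:2], c(2L, 1L))
  # Delta R2 partitions every unit into exactly one category
  expect_true(all(us$units$class %in% c("decision", "confidence")))
  expect_equal(us$n_decision + us$n_confidence, 4L)
})

test_that("records without opt-out trials flag the missing T_S condition", {
  set.seed(5)
  n <- 60
  rec <- data.frame(label = rep(1:2, n / 2), decision = rep(1:2, n / 2),
                    p_right = runif(n, 0.4, 0.6),
                    p_optout = runif(n, 0, 0.2), opt_out = FALSE)
  rec$correct <- TRUE
  expect_warning(us <- single_unit_analysis(matrix(rnorm(n * 3), n, 3), rec),
                 "T_S")
  expect_true(all(is.na(us$units$act_t_s)))
})
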