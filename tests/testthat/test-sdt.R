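mk_rec <- function(label, decision, confidence = 0.5) {
  r <- data.frame(label = label, decision = decision,
                  confidence = confidence, opt_out = FALSE)
  r$correct <- r$label == r$decision
  r
}

test_that("d-prime matches the double inverse-normal computation", {
  # HR = FAR gives 0
  r <- mk_rec(rep(1:2, each = 100), rep(rep(1:2, each = 50), 2))
  expect_equal(dprime(r)$d_prime, 0)
  # HR = 0.84, FAR = 0.16: qnorm oracle
  r2 <- mk_rec(rep(1:2, each = 100),
               c(rep(2, 16), rep(1, 84), rep(2, 84), rep(1, 16)))
  expect_equal(dprime(r2)$d_prime, qnorm(0.84) - qnorm(0.16),
               tolerance = 1e-12)
  expect_lt(abs(dprime(r2)$d_prime - 1.989), 0.01)
  # perfect hit rate stays finite under the zero-cell correction
  r3 <- mk_rec(rep(1:2, each = 50), c(rep(1, 50), rep(2, 50)))
  expect_true(is.finite(dprime(r3)$d_prime))
  expect_error(dprime(mk_rec(rep(1, 10), rep(1, 10))), "both stimulus")
})

test_that("meta-d' recovers forward-simulated observers", {
  n <- 60000
  # SDT-ideal observer: confidence from the same decision variable gives
  # meta-d' = d'
  set.seed(31)
  lab <- sample(1:2, n, TRUE)
  x <- rnorm(n, ifelse(lab == 1, -1, 1))
  rec <- mk_rec(lab, ifelse(x > 0, 2L, 1L), 1 / (1 + exp(-2 * abs(x))))
  f <- fit_meta_dprime(rec, 4, response_specific = TRUE)
  expect_lt(abs(f$d_prime - 2), 0.05)
  expect_lt(abs(f$meta_d_prime - f$d_prime), 0.1)
  expect_lt(abs(f$meta_d_s1 - 2), 0.15)
  expect_lt(abs(f$meta_d_s2 - 2), 0.15)
  # forward-generated observer with meta-d' < d'
  r2 <- simulate_meta_observer(2, 1, n, seed = 32)
  expect_lt(abs(fit_meta_dprime(r2, 4)$meta_d_prime - 1), 0.1)
  # hypersensitive observer, biased type-1 criterion
  r3 <- simulate_meta_observer(1, 1.5, n, c1 = 0.3, seed = 33)
  expect_lt(abs(fit_meta_dprime(r3, 4)$meta_d_prime - 1.5), 0.12)
  # confidence independent of correctness carries no type-2 information
  set.seed(34)
  rec$confidence <- runif(n)
  expect_lt(abs(fit_meta_dprime(rec, 4)$meta_d_prime), 0.05)
})

test_that("degenerate confidence distributions are reported explicitly", {
  r <- mk_rec(rep(1:2, 50), rep(1:2, 50), confidence = 0.7)
  expect_error(fit_meta_dprime(r), "degenerate")
  expect_error(bin_confidence(rep(0.5, 100)), "degenerate")
})

test_that("type-2 noise leaves xi = 0 unchanged and degrades meta-d'", {
  r <- simulate_meta_observer(2, 2, 5000, seed = 41)
  expect_identical(add_type2_noise(r, 0), r)
  pert <- add_type2_noise(r, 3, seed = 42)
  expect_true(all(pert$confidence >= 0 & pert$confidence <= 1))
  expect_error(add_type2_noise(r, -1), "xi")
  # expected meta-d' is non-increasing in xi (5-point sweep, averaged reps)
  xis <- c(0, 0.5, 1, 2, 4)
  md <- sapply(xis, function(xi) {
    mean(sapply(1:8, function(rep) {
      fit_meta_dprime(add_type2_noise(r, xi, seed = 100 * rep + xi), 4)$meta_d_prime
    }))
  })
  expect_true(all(diff(md) < 0.05))      # monotone up to simulation error
  expect_lt(md[5], md[1] - 0.5)          # and substantially degraded overall
})

test_that("empirical-criterion d-prime recovers sensitivity under response bias", {
  set.seed(51)
  n <- 20000
  lab <- sample(1:2, n, TRUE)
  x <- rnorm(n, ifelse(lab == 1, -0.75, 0.75))
  # decision variable displaced far past the nominal criterion: every trial
  # gets the same response, but the median split recovers d' ~ 1.5
  rec <- mk_rec(lab, rep(2L, n))
  rec$p_s2 <- 1 / (1 + exp(-(x + 20)))
  expect_lt(abs(dprime(rec)$d_prime), 0.1)
  expect_lt(abs(dprime_empirical(rec)$d_prime - 1.5), 0.12)
})

test_that("choice probability equals the rank-sum statistic", {
  set.seed(61)
  iv <- c(rnorm(300, 1), rnorm(200))
  dv <- rep(c(TRUE, FALSE), c(300, 200))
  cp <- roc_choice_probability(iv, dv)$choice_probability
  w <- wilcox.test(iv[dv], iv[!dv], exact = FALSE)$statistic
  expect_lt(abs(cp - w / (300 * 200)), 1e-10)
  # with heavy ties
  ivt <- sample(1:5, 500, TRUE)
  cpt <- roc_choice_probability(ivt, dv)$choice_probability
  wt <- wilcox.test(ivt[dv], ivt[!dv], exact = FALSE)$statistic
  expect_lt(abs(cpt - wt / (300 * 200)), 1e-10)
  # trivial endpoints
  expect_equal(roc_choice_probability(c(1, 1, 2, 2),
                                      c(FALSE, FALSE, TRUE, TRUE))$choice_probability, 1)
  expect_equal(roc_choice_probability(rep(1, 10),
                                      rep(c(TRUE, FALSE), 5))$choice_probability, 0.5)
  expect_error(roc_choice_probability(1:5, rep(TRUE, 5)), "both classes")
})
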