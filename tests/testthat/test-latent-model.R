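# independent bivariate-normal density (solve/det path, distinct from the
# package's Cholesky implementation) for the Bayes-posterior oracle
bvn_dens_oracle <- function(z, mu, cv) {
  d <- z - mu
  exp(-0.5 * sum(d * solve(cv, d))) / (2 * pi * sqrt(det(cv)))
}

random_cg <- function(seed) {
  set.seed(seed)
  rc <- function() {
    a <- matrix(rnorm(4), 2)
    crossprod(a) + diag(0.3, 2)
  }
  class_gaussians(rnorm(2), rc(), rnorm(2), rc(),
                  prior_s1 = runif(1, 0.2, 0.8))
}

test_that("ideal-observer posterior agrees with an independent Bayes oracle", {
  for (k in 1:100) {
    cg <- random_cg(k)
    z <- rnorm(2, sd = 2)
    p <- io_posterior(cg, z)
    f1 <- bvn_dens_oracle(z, cg$mean$s1, cg$cov$s1) * cg$prior[1]
    f2 <- bvn_dens_oracle(z, cg$mean$s2, cg$cov$s2) * cg$prior[2]
    expect_lt(abs(p[1] - f1 / (f1 + f2)), 1e-6)
    expect_equal(unname(p[1] + p[2]), 1, tolerance = 1e-12)
  }
})

test_that("posterior symmetry, decisions, confidence and tie-breaks", {
  cg <- class_gaussians(c(-1, 0), diag(2), c(1, 0), diag(2))
  # on the symmetry axis both classes are equally likely; tie goes to s1
  p <- io_posterior(cg, c(0, 3))
  expect_equal(unname(p[1]), 0.5, tolerance = 1e-12)
  dc <- io_decide_confidence(cg, rbind(c(0, 3), c(-1, 0), c(1, 0)))
  expect_equal(dc$decision, c(1L, 1L, 2L))
  expect_equal(dc$confidence[1], 0.5)
  expect_true(all(dc$confidence >= 0.5))
  # z at the s1 mean of a well-separated pair: near-certain s1
  far <- class_gaussians(c(-4, 0), diag(0.25, 2), c(4, 0), diag(0.25, 2))
  dcf <- io_decide_confidence(far, c(-4, 0))
  expect_equal(dcf$decision, 1L)
  expect_gt(dcf$confidence, 0.99)
})

test_that("posterior is monotone along the line between shared-cov means", {
  cg <- class_gaussians(c(-1, -1), diag(2), c(2, 1), diag(2))
  t <- seq(0, 1, length.out = 50)
  zs <- cbind(2 - 3 * t, 1 - 2 * t)   # from s2 mean to s1 mean
  p1 <- io_posterior(cg, zs)[, 1]
  expect_true(all(diff(p1) > 0))
})

test_that("latent geometry: degenerate flag, construction, rotation invariance", {
  iso <- class_gaussians(c(0, 0), diag(2), c(1, 1), diag(2))
  g <- latent_geometry(iso)
  expect_equal(g$ratio, 1)
  expect_true(g$degenerate)
  expect_equal(g$theta, 0)
  ns <- asNamespace("metacognet")
  cg <- class_gaussians(c(0, 0), ns$axis_cov(2, 1, 30),
                        c(1, 0), ns$axis_cov(2, 1, 81.4))
  g2 <- latent_geometry(cg)
  expect_equal(g2$theta, 51.4, tolerance = 1e-6)
  expect_equal(g2$ratio, 2, tolerance = 1e-9)
  # joint rotation leaves ratio and inter-axis angle unchanged
  for (rot in c(17, 49, 133)) {
    R <- ns$rot2(rot)
    cgr <- class_gaussians(c(0, 0), R %*% cg$cov$s1 %*% t(R),
                           as.vector(R %*% c(1, 0)),
                           R %*% cg$cov$s2 %*% t(R))
    gr <- latent_geometry(cgr)
    expect_equal(gr$ratio, g2$ratio, tolerance = 1e-9)
    expect_equal(gr$theta, g2$theta, tolerance = 1e-6)
  }
})

test_that("class-Gaussian fitting is consistent and deterministic", {
  spec <- latent_evidence_spec(mean_s1 = c(-0.5, 1), mean_s2 = c(1, -0.3),
                               sd_major = 1.5, sd_minor = 0.7,
                               axis_angle_s1 = 40, axis_angle_s2 = 120)
  z <- sample_latent_evidence(spec, 10000, seed = 9)
  cg <- fit_class_gaussians_latent(z)
  # recovered means within 3 standard errors
  for (k in 1:2) {
    zi <- as.matrix(z[z$label == k, c("z1", "z2")])
    se <- sqrt(diag(cov(zi)) / nrow(zi))
    mu_true <- if (k == 1) spec$mean_s1 else spec$mean_s2
    expect_true(all(abs(cg$mean[[k]] - mu_true) < 3.5 * se + 1e-12))
    expect_identical(cg$cov[[k]], t(cg$cov[[k]]))
  }
  expect_identical(fit_class_gaussians_latent(z), cg)
  expect_error(fit_class_gaussians_latent(z[z$label == 1, ][1:2, ]),
               "3 samples")
  expect_error(class_gaussians(c(0, 0), matrix(c(1, 2, 3, 1), 2),
                               c(1, 1), diag(2)), "symmetric")
})

test_that("condition-level evaluation is self-consistent and MC-stable", {
  ns <- asNamespace("metacognet")
  cg <- class_gaussians(c(-1, 0), ns$axis_cov(2, 1, 30),
                        c(1, 0), ns$axis_cov(2, 1, 81.4))
  a <- io_evaluate_condition(cg, cg, n_mc = 1e5, seed = 1)
  b <- io_evaluate_condition(cg, cg, n_mc = 1e5, seed = 2)
  expect_lt(abs(a$accuracy - b$accuracy), 0.01)
  expect_lt(abs(a$confidence - b$confidence), 0.01)
  # when test = train, mean confidence matches accuracy up to MC error and
  # is never below it by more than that error (proper confidence)
  expect_gt(a$confidence, a$accuracy - 0.01)
  expect_warning(io_evaluate_condition(cg, cg, n_mc = 50), "n_mc")
})

test_that("class Gaussians serialize to readable text and back", {
  cg <- random_cg(5)
  path <- file.path(tempdir(), "cg.json")
  write_class_gaussians(cg, path)
  cg2 <- read_class_gaussians(path)
  expect_equal(cg2$mean$s1, cg$mean$s1)
  expect_equal(cg2$cov$s2, cg$cov$s2)
  expect_equal(unname(cg2$prior[1]), unname(cg$prior[1]))
})

test_that("matched-accuracy conditions with higher evidence yield higher
           ideal-observer confidence under the fitted latent structure", {
  # two-class structure with the study's latent statistics; the high-PE
  # condition scales both class means and the spread so that accuracy is
  # matched while total evidence is larger
  ns <- asNamespace("metacognet")
  cv1 <- ns$axis_cov(2.44, 1, 30)
  cv2 <- ns$axis_cov(2.44, 1, 81.4)
  train <- class_gaussians(c(-1.5, 0), cv1, c(1.5, 0), cv2)
  low <- class_gaussians(c(-1, 0), cv1, c(1, 0), cv2)
  high <- class_gaussians(c(-2.2, 0), 2.2^2 / 1 * cv1, c(2.2, 0),
                          2.2^2 / 1 * cv2)
  a_lo <- io_evaluate_condition(train, low, n_mc = 4e4, seed = 3)
  a_hi <- io_evaluate_condition(train, high, n_mc = 4e4, seed = 4)
  expect_lt(abs(a_lo$accuracy - a_hi$accuracy), 0.03)  # matched accuracy
  expect_gt(a_hi$confidence, a_lo$confidence)          # higher-PE confidence
})
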