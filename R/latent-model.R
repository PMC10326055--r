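#' Denoising variational autoencoder and latent ideal observer
#'
#' A denoising VAE maps a noisy 32x32 stimulus to a two-dimensional latent
#' posterior q(z|x) and reconstructs the clean (pre-noise) stimulus from a
#' latent sample. Bivariate Gaussians fitted to the class-conditional latent
#' embeddings define a Bayesian ideal observer whose decision is the maximum
#' posterior class and whose confidence is the maximum posterior probability.
#'
#' @name latent_model
NULL

#' Build an (untrained) denoising VAE
#'
#' Encoder: the standard convolutional trunk through the 128-unit layer,
#' ending in two 2-unit linear heads for the posterior means and
#' log-variances. Decoder: fully-connected layers of 128 and 256 units, then
#' three transposed convolutions (kernel 4, stride 2; 32, 32 and 1 channels)
#' up to 32x32, with a final tanh squashing to \[-1, 1\].
#'
#' @param seed integer seed for initialization.
#' @export
build_vae <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enc <- build_encoder()[1:15]  # through fc2 block (128 units)
  heads <- list(mean = nn_dense(128L, 2L), logvar = nn_dense(128L, 2L))
  dec <- list(nn_dense(2L, 128L), nn_lrelu(),
              nn_dense(128L, 256L), nn_lrelu(),         # read as a 4x4x16 map
              nn_convT(4L, 4L, 16L, 32L), nn_lrelu(),
              nn_convT(8L, 8L, 32L, 32L), nn_lrelu(),
              nn_convT(16L, 16L, 32L, 1L), nn_tanh())
  structure(list(encoder = enc, heads = heads, decoder = dec, seed = seed),
            class = "denoising_vae")
}

# posterior parameters in engine orientation: mean/logvar are 2 x N
vae_encode <- function(vae, px, training = FALSE) {
  N <- dim(px)[3]
  fw <- stack_forward(vae$encoder, pixels_to_act(px), training = training)
  hm <- layer_forward(vae$heads$mean, fw$out, training)
  hv <- layer_forward(vae$heads$logvar, fw$out, training)
  list(mean = hm$out, logvar = hv$out, enc_caches = fw$caches,
       mean_cache = hm$cache, logvar_cache = hv$cache, N = N)
}

#' Train the denoising VAE
#'
#' Loss per batch: mean over samples of the summed squared reconstruction
#' error against the clean (pre-noise, clamped) target, plus the KL
#' divergence of q(z|x) from the unit normal prior.
#'
#' @param vae from [build_vae()].
#' @param raw 32 x 32 x N array of raw class images in \[0, 1\].
#' @param labels class labels (kept with the VAE for later fitting).
#' @param reg training [regime()] for (mu, sigma) sampling (default the
#'   standard regime).
#' @param epochs,lr,batch_size training hyperparameters (defaults 20, 5e-4, 32).
#' @param seed integer seed.
#' @return trained VAE with `training_log` attribute.
#' @export
train_vae <- function(vae, raw, labels, reg = regime("standard"), epochs = 20,
                      lr = 5e-4, batch_size = 32, seed = NULL) {
  stopifnot(inherits(vae, "denoising_vae"))
  n <- dim(raw)[3]
  if (!is.null(seed)) set.seed(seed)
  opt <- adam_init()
  log <- data.frame(epoch = integer(), recon = numeric(), kl = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    rec_l <- kl_l <- c()
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      m <- length(ix)
      ms <- sample_regime(reg, m)
      clean <- 2 * sweep(raw[, , ix, drop = FALSE], 3L, ms$mu, "*") - 1
      clean <- pmin(pmax(clean, -1), 1)
      noisy <- clean + array(stats::rnorm(length(clean), 0,
                                          rep(ms$sigma, each = 1024L)),
                             dim = dim(clean))
      noisy <- pmin(pmax(noisy, -1), 1)
      en <- vae_encode(vae, noisy, training = TRUE)
      eps <- matrix(stats::rnorm(2 * m), 2, m)
      sd_z <- exp(0.5 * en$logvar)
      z <- en$mean + sd_z * eps                         # 2 x m
      dfw <- stack_forward(vae$decoder, z, training = TRUE)
      xhat <- dfw$out                                   # 1024 x m
      tgt <- matrix(clean, nrow = 1024L)
      diff <- xhat - tgt
      rec_loss <- sum(diff^2) / m
      kl <- sum(-0.5 * (1 + en$logvar - en$mean^2 - exp(en$logvar))) / m
      dxhat <- 2 * diff / m
      dbw <- stack_backward(vae$decoder, dfw$caches, dxhat)
      dz <- dbw$da
      dmean <- dz + en$mean / m
      dlogvar <- dz * eps * 0.5 * sd_z + 0.5 * (exp(en$logvar) - 1) / m
      bm <- layer_backward(vae$heads$mean, en$mean_cache, dmean)
      bv <- layer_backward(vae$heads$logvar, en$logvar_cache, dlogvar)
      bwe <- stack_backward(vae$encoder, en$enc_caches, bm$da + bv$da)
      all_layers <- c(vae$encoder, vae$heads, vae$decoder)
      all_grads <- c(bwe$grads, list(bm$grads, bv$grads), dbw$grads)
      st <- adam_step(get_params(all_layers), all_grads, opt, lr)
      ne <- length(vae$encoder)
      vae$encoder <- set_params(vae$encoder, st$params[seq_len(ne)])
      vae$heads$mean$params <- st$params[[ne + 1L]]
      vae$heads$logvar$params <- st$params[[ne + 2L]]
      vae$decoder <- set_params(vae$decoder, st$params[-seq_len(ne + 2L)])
      opt <- st$state
      for (i in seq_along(vae$encoder)) {
        if (vae$encoder[[i]]$type == "bn")
          vae$encoder[[i]] <- bn_update_running(vae$encoder[[i]],
                                                en$enc_caches[[i]])
      }
      rec_l <- c(rec_l, rec_loss); kl_l <- c(kl_l, kl)
    }
    log <- rbind(log, data.frame(epoch = ep, recon = mean(rec_l),
                                 kl = mean(kl_l)))
  }
  attr(vae, "training_log") <- log
  vae
}

#' Embed stimuli in the VAE latent space
#'
#' @param vae trained VAE.
#' @param px 32 x 32 x N array of processed pixels in \[-1, 1\] (or a
#'   `stimulus_batch`).
#' @param sample draw z ~ q(z|x) instead of returning the posterior means.
#' @param seed seed for posterior sampling.
#' @return data.frame(z1, z2, var1, var2) of posterior parameters (or
#'   samples).
#' @export
vae_embed <- function(vae, px, sample = FALSE, seed = NULL) {
  if (inherits(px, "stimulus_batch")) px <- px$pixels
  en <- vae_encode(vae, px, training = FALSE)
  v <- exp(en$logvar)                                   # 2 x N
  z <- en$mean
  if (sample) {
    if (!is.null(seed)) set.seed(seed)
    z <- z + sqrt(v) * matrix(stats::rnorm(length(z)), 2, ncol(z))
  }
  data.frame(z1 = z[1, ], z2 = z[2, ], var1 = v[1, ], var2 = v[2, ])
}

#' Reconstruct stimuli through the VAE
#'
#' @param vae trained VAE.
#' @param px pixels array or `stimulus_batch`.
#' @return 32 x 32 x N array of denoised reconstructions in \[-1, 1\].
#' @export
vae_reconstruct <- function(vae, px) {
  if (inherits(px, "stimulus_batch")) px <- px$pixels
  en <- vae_encode(vae, px, training = FALSE)
  dfw <- stack_forward(vae$decoder, en$mean, training = FALSE)
  array(dfw$out, dim = c(IMG_SIZE, IMG_SIZE, en$N))
}

#' Class-conditional latent Gaussians
#'
#' Container for the fitted bivariate Gaussians p(z|s1), p(z|s2) and class
#' priors, the basis of the latent ideal observer.
#'
#' @param mean_s1,mean_s2 2-vectors.
#' @param cov_s1,cov_s2 symmetric positive-definite 2x2 matrices.
#' @param prior_s1 prior probability of s1 (default 0.5).
#' @export
class_gaussians <- function(mean_s1, cov_s1, mean_s2, cov_s2,
                            prior_s1 = 0.5) {
  for (cv in list(cov_s1, cov_s2)) {
    if (max(abs(cv - t(cv))) > 1e-8 || any(eigen(cv)$values <= 0))
      stop("covariances must be symmetric positive definite")
  }
  structure(list(mean = list(s1 = mean_s1, s2 = mean_s2),
                 cov = list(s1 = (cov_s1 + t(cov_s1)) / 2,
                            s2 = (cov_s2 + t(cov_s2)) / 2),
                 prior = c(s1 = prior_s1, s2 = 1 - prior_s1)),
            class = "class_gaussians")
}

#' Fit class Gaussians to labelled latent samples
#'
#' @param latents data.frame with columns z1, z2, label (1 = s1, 2 = s2).
#' @param prior_s1 prior (default 0.5 as used throughout).
#' @export
fit_class_gaussians_latent <- function(latents, prior_s1 = 0.5) {
  fits <- lapply(1:2, function(k) {
    zi <- as.matrix(latents[latents$label == k, c("z1", "z2")])
    if (nrow(zi) < 3) stop("need at least 3 samples per class")
    list(mean = colMeans(zi), cov = stats::cov(zi))
  })
  class_gaussians(fits[[1]]$mean, fits[[1]]$cov, fits[[2]]$mean,
                  fits[[2]]$cov, prior_s1)
}

#' Fit class Gaussians from a trained VAE
#'
#' Embeds a labelled batch and fits per-class bivariate Gaussians. By
#' default the fit uses the posterior means (a lower-variance estimate of
#' the latent layout); set `use_posterior_samples = TRUE` to fit to samples
#' from q(z|x) instead.
#'
#' @param vae trained VAE.
#' @param batch labelled `stimulus_batch`.
#' @param use_posterior_samples fit to posterior samples rather than means.
#' @param seed seed for posterior sampling.
#' @export
fit_class_gaussians <- function(vae, batch, use_posterior_samples = FALSE,
                                seed = NULL) {
  emb <- vae_embed(vae, batch, sample = use_posterior_samples, seed = seed)
  emb$label <- batch$meta$label
  fit_class_gaussians_latent(emb)
}

#' Latent geometry statistics
#'
#' Per-class PCA of the fitted covariances: anisotropy ratio
#' sd(major)/sd(minor) and major-axis angles, plus the angular separation
#' between the two major axes. Because axes are undirected, separations d
#' and 180 - d describe the same configuration; theta is canonicalized to
#' \[0, 90\], making it invariant under joint rotations of both classes.
#' Isotropic classes are flagged degenerate and given angle 0.
#'
#' @param cg a [class_gaussians()].
#' @return list with ratio_s1, ratio_s2, ratio (average), angle_s1,
#'   angle_s2, theta, degenerate.
#' @export
latent_geometry <- function(cg) {
  stopifnot(inherits(cg, "class_gaussians"))
  one <- function(cv) {
    e <- eigen(cv, symmetric = TRUE)
    ratio <- sqrt(e$values[1] / e$values[2])
    deg <- (e$values[1] - e$values[2]) / e$values[1] < 1e-9
    ang <- if (deg) 0 else (atan2(e$vectors[2, 1], e$vectors[1, 1]) *
                              180 / pi) %% 180
    list(ratio = ratio, angle = ang, degenerate = deg)
  }
  g1 <- one(cg$cov$s1); g2 <- one(cg$cov$s2)
  degenerate <- g1$degenerate || g2$degenerate
  d <- abs(g1$angle - g2$angle) %% 180
  list(ratio_s1 = g1$ratio, ratio_s2 = g2$ratio,
       ratio = mean(c(g1$ratio, g2$ratio)),
       angle_s1 = g1$angle, angle_s2 = g2$angle,
       theta = if (degenerate) 0 else min(d, 180 - d),
       degenerate = degenerate)
}

# log density of bivariate normal, z: n x 2
bvn_logdens <- function(z, mu, cv) {
  ch <- chol(cv)
  d <- sweep(z, 2L, mu, "-")
  u <- d %*% chol2inv(ch) * d
  -0.5 * rowSums(u) - log(2 * pi) - sum(log(diag(ch)))
}

#' Ideal-observer posterior
#'
#' Bayes rule over the two fitted class Gaussians with the stored priors.
#'
#' @param cg a [class_gaussians()].
#' @param z a 2-vector or n x 2 matrix of latent points.
#' @return matrix with columns p_s1, p_s2 (rows sum to 1).
#' @export
io_posterior <- function(cg, z) {
  stopifnot(inherits(cg, "class_gaussians"))
  z <- matrix(z, ncol = 2)
  l1 <- bvn_logdens(z, cg$mean$s1, cg$cov$s1) + log(cg$prior[1])
  l2 <- bvn_logdens(z, cg$mean$s2, cg$cov$s2) + log(cg$prior[2])
  m <- pmax(l1, l2)
  p1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  cbind(p_s1 = p1, p_s2 = 1 - p1)
}

#' Ideal-observer decision and confidence
#'
#' Decision is the maximum-posterior class (ties broken toward s1);
#' confidence is the maximum posterior probability, hence always >= 0.5.
#'
#' @inheritParams io_posterior
#' @return data.frame(decision, confidence) with decision in {1, 2}.
#' @export
io_decide_confidence <- function(cg, z) {
  p <- io_posterior(cg, z)
  data.frame(decision = ifelse(p[, 1] >= p[, 2], 1L, 2L),
             confidence = pmax(p[, 1], p[, 2]))
}

#' Trial-level ideal-observer record
#'
#' Applies the training-distribution posterior to labelled latent points and
#' returns a behavioral record comparable to network output.
#'
#' @param cg training-distribution [class_gaussians()].
#' @param latents data.frame(z1, z2, label).
#' @export
io_evaluate_trials <- function(cg, latents) {
  dc <- io_decide_confidence(cg, as.matrix(latents[, c("z1", "z2")]))
  rec <- data.frame(trial = seq_len(nrow(latents)), label = latents$label,
                    decision = dc$decision, confidence = dc$confidence,
                    opt_out = FALSE)
  rec$correct <- rec$decision == rec$label
  class(rec) <- c("behavioral_record", "data.frame")
  rec
}

#' Condition-level ideal-observer evaluation
#'
#' Monte-Carlo expectation, over latents drawn from a test distribution, of
#' the correctness of the training-distribution decision rule and of its
#' confidence.
#'
#' @param cg_train training-distribution [class_gaussians()].
#' @param test either a [class_gaussians()] describing the test-condition
#'   latent distribution, or a data.frame(z1, z2, label) of latent samples.
#' @param n_mc Monte-Carlo sample count when `test` is a distribution.
#' @param seed integer seed.
#' @return list(accuracy, confidence, n).
#' @export
io_evaluate_condition <- function(cg_train, test, n_mc = 10000, seed = NULL) {
  stopifnot(inherits(cg_train, "class_gaussians"))
  if (inherits(test, "class_gaussians")) {
    if (n_mc < 100) warning("n_mc < 100: Monte-Carlo estimate will be noisy")
    if (!is.null(seed)) set.seed(seed)
    lab <- ifelse(stats::runif(n_mc) < test$prior[1], 1L, 2L)
    z <- matrix(0, n_mc, 2)
    for (k in 1:2) {
      i <- lab == k
      if (!any(i)) next
      cv <- test$cov[[k]]; mu <- test$mean[[k]]
      e <- matrix(stats::rnorm(2 * sum(i)), ncol = 2) %*% chol(cv)
      z[i, ] <- sweep(e, 2L, mu, "+")
    }
    latents <- data.frame(z1 = z[, 1], z2 = z[, 2], label = lab)
  } else {
    latents <- test
  }
  rec <- io_evaluate_trials(cg_train, latents)
  list(accuracy = mean(rec$correct), confidence = mean(rec$confidence),
       n = nrow(rec))
}

#' Latent ideal observer over images
#'
#' Pairs a trained VAE (for embedding images) with training-distribution
#' class Gaussians, so the ideal observer can be evaluated on the same
#' stimulus batches as the networks.
#'
#' @param vae trained VAE.
#' @param cg training-distribution [class_gaussians()].
#' @export
io_observer <- function(vae, cg) {
  stopifnot(inherits(vae, "denoising_vae"), inherits(cg, "class_gaussians"))
  structure(list(vae = vae, cg = cg), class = "io_observer")
}

#' @rdname evaluate_trials
#' @export
evaluate_trials.io_observer <- function(net, batch, ...) {
  emb <- vae_embed(net$vae, batch)
  emb$label <- batch$meta$label
  rec <- io_evaluate_trials(net$cg, emb)
  rec$mu <- batch$meta$mu
  rec$sigma <- batch$meta$sigma
  rec
}

#' Serialize class Gaussians as plain text
#'
#' @param cg a [class_gaussians()].
#' @param path file path (JSON).
#' @export
write_class_gaussians <- function(cg, path) {
  jsonlite::write_json(list(mean_s1 = cg$mean$s1, cov_s1 = cg$cov$s1,
                            mean_s2 = cg$mean$s2, cov_s2 = cg$cov$s2,
                            prior_s1 = unname(cg$prior[1])),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_class_gaussians
#' @export
read_class_gaussians <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class_gaussians(x$mean_s1, matrix(x$cov_s1, 2, 2, byrow = TRUE),
                  x$mean_s2, matrix(x$cov_s2, 2, 2, byrow = TRUE),
                  x$prior_s1)
}
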