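#' Simulated TMS, lesions, blindsight and evidence decoding
#'
#' Perturbations act on the activations of one encoder block (after its
#' nonlinearity): additive Gaussian noise of variance xi models TMS;
#' multiplicative scaling (e.g. 0.01) models a lesion. A linear probe over
#' concatenated layer activations provides independent per-trial evidence
#' estimates for the ROC / choice-probability analyses.
#'
#' @name perturbations
NULL

#' Perturbation specification
#'
#' @param layer encoder block index 1..6 (conv1, conv2, conv3, fc1, fc2,
#'   encoder output). Layer 1 stands in for V1; layer 6 is the penultimate
#'   (pre-head) representation.
#' @param kind "additive_noise" (magnitude = noise variance xi) or "scale"
#'   (magnitude = scaling factor).
#' @param magnitude non-negative scalar.
#' @export
perturbation_spec <- function(layer, kind = c("additive_noise", "scale"),
                              magnitude) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("magnitude must be >= 0")
  structure(list(layer = as.integer(layer), kind = kind,
                 magnitude = magnitude), class = "perturbation_spec")
}

#' Forward pass under perturbation
#'
#' Evaluates a batch with the specified layer's activations perturbed before
#' all subsequent layers. A scale factor of 1 or noise variance of 0 is an
#' exact no-op.
#'
#' @param net trained network.
#' @param spec a [perturbation_spec()].
#' @param batch a `stimulus_batch`.
#' @param seed integer seed for the noise draw.
#' @param ... passed to [evaluate_trials()].
#' @return a `behavioral_record`.
#' @export
perturb_forward <- function(net, spec, batch, seed = NULL, ...) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$kind == "additive_noise" && spec$magnitude == 0)
    return(evaluate_trials(net, batch, ...))
  if (spec$kind == "scale" && spec$magnitude == 1)
    return(evaluate_trials(net, batch, ...))
  evaluate_trials(net, batch, perturb = spec, ...)
}

#' TMS noise sweep
#'
#' Evaluates a network over contrast levels and noise intensities xi applied
#' to one layer, reporting d', mean confidence and meta-d' per cell.
#'
#' @param net trained two-choice network.
#' @param raw,labels labelled raw-image pool.
#' @param layer perturbed encoder block (1 = first layer / V1 analogue,
#'   6 = penultimate).
#' @param xi_levels noise variances (default 5 levels from 1 to 5, preceded
#'   by 0 for the unperturbed baseline).
#' @param mu,sigma stimulus contrast level(s) and noise.
#' @param n_trials trials per cell.
#' @param n_conf_bins,seed as elsewhere.
#' @return tidy data.frame(xi, mu, accuracy, d_prime, confidence, meta_d).
#' @export
tms_sweep <- function(net, raw, labels, layer, xi_levels = c(0, 1, 2, 3, 4, 5),
                      mu = 0.55, sigma = 2, n_trials = 1000,
                      n_conf_bins = 4, seed = 1) {
  rows <- list()
  for (m in mu) for (xi in xi_levels) {
    batch <- condition_batch(raw, labels, m, sigma, n_trials,
                             seed = seed + round(1000 * m))
    rec <- perturb_forward(net, perturbation_spec(layer, "additive_noise", xi),
                           batch, seed = seed + round(100 * xi))
    t1 <- dprime(rec)
    md <- tryCatch(fit_meta_dprime(rec, n_conf_bins)$meta_d_prime,
                   error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <-
      data.frame(xi = xi, mu = m, accuracy = mean(rec$correct),
                 d_prime = t1$d_prime, confidence = mean(rec$confidence),
                 meta_d = md)
  }
  do.call(rbind, rows)
}

#' Blindsight lesion analysis
#'
#' Scales first-layer activations by a small factor (default 0.01) in
#' networks trained under high sensory noise, then evaluates d', meta-d'
#' and the overlap of correct/incorrect confidence distributions over a
#' contrast sweep. Both criteria are re-derived from the post-lesion
#' empirical distributions: confidence criteria via [bin_confidence()]
#' (which always uses the record at hand) and the type-1 criterion via
#' [dprime_empirical()], because the lesion displaces the operating point
#' of the decision output far past the nominal 0.5 criterion.
#'
#' @param nets list of trained two-choice networks (trained with
#'   sigma in \[3, 4\]).
#' @param raw,labels labelled raw-image pool.
#' @param factor lesion scaling factor (1 = control, exact no-op).
#' @param mu_levels contrast sweep (default 5 levels 0.5..0.9).
#' @param sigma evaluation noise (default 4).
#' @param n_trials trials per contrast per net.
#' @param n_conf_bins,seed as elsewhere.
#' @return list(per_cell = tidy table with lesioned and control rows,
#'   overlap = per-net confidence-density overlap coefficients).
#' @export
run_blindsight <- function(nets, raw, labels, factor = 0.01,
                           mu_levels = seq(0.5, 0.9, length.out = 5),
                           sigma = 4, n_trials = 1000, n_conf_bins = 4,
                           seed = 1) {
  rows <- list(); overlaps <- list()
  for (i in seq_along(nets)) {
    conf_c <- conf_e <- list(lesion = c(), control = c())
    for (m in mu_levels) {
      batch <- condition_batch(raw, labels, m, sigma, n_trials,
                               seed = seed + 31L * i + round(100 * m))
      for (arm in c("lesion", "control")) {
        f <- if (arm == "lesion") factor else 1
        rec <- perturb_forward(nets[[i]],
                               perturbation_spec(1L, "scale", f), batch)
        # re-derive the whole operating point from the post-lesion record:
        # decisions from the median of the decision variable, correctness
        # and meta-d' from those decisions
        rec$decision <- ifelse(rec$p_s2 > stats::median(rec$p_s2), 2L, 1L)
        rec$correct <- rec$decision == rec$label
        t1 <- dprime(rec)
        md <- tryCatch(fit_meta_dprime(rec, n_conf_bins)$meta_d_prime,
                       error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(net = i, arm = arm, mu = m, accuracy = mean(rec$correct),
                     d_prime = t1$d_prime, meta_d = md,
                     confidence = mean(rec$confidence))
        conf_c[[arm]] <- c(conf_c[[arm]], rec$confidence[rec$correct])
        conf_e[[arm]] <- c(conf_e[[arm]], rec$confidence[!rec$correct])
      }
    }
    overlaps[[i]] <- data.frame(
      net = i,
      overlap_lesion = density_overlap(conf_c$lesion, conf_e$lesion),
      overlap_control = density_overlap(conf_c$control, conf_e$control))
  }
  list(per_cell = do.call(rbind, rows), overlap = do.call(rbind, overlaps))
}

# overlap coefficient of two kernel density estimates on a common support
density_overlap <- function(x, y, n_grid = 512) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  rng <- range(c(x, y))
  if (diff(rng) < 1e-12) return(1)
  bw <- max(stats::bw.nrd0(c(x, y)), 1e-6)
  dx <- stats::density(x, bw = bw, from = rng[1] - 3 * bw,
                       to = rng[2] + 3 * bw, n = n_grid)
  dy <- stats::density(y, bw = bw, from = rng[1] - 3 * bw,
                       to = rng[2] + 3 * bw, n = n_grid)
  sum(pmin(dx$y, dy$y)) * diff(dx$x[1:2])
}

#' Train a linear probe decoder on network activations
#'
#' A single linear layer with a sigmoid nonlinearity and no bias term,
#' trained by Adam with binary cross-entropy to predict the stimulus class
#' from the concatenated activations of all layers (11,236 features) or
#' from the penultimate layer alone.
#'
#' @param net trained network.
#' @param batch labelled training `stimulus_batch` (typically at the
#'   calibrated 75 percent-accuracy contrast).
#' @param scope "all_layers" or "penultimate".
#' @param epochs,lr,batch_size training hyperparameters (defaults 5, 5e-4, 32).
#' @param seed integer seed.
#' @return a `probe_decoder`: list(w, scope).
#' @export
train_probe_decoder <- function(net, batch, scope = c("all_layers",
                                                      "penultimate"),
                                epochs = 5, lr = 5e-4, batch_size = 32,
                                seed = NULL) {
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  X <- probe_features(net, batch, scope)
  y <- as.numeric(batch$meta$label == 2L)
  w <- rep(0, ncol(X))
  opt <- adam_init()
  n <- nrow(X)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1L, n)]
        z <- X[ix, , drop = FALSE] %*% w
        p <- 1 / (1 + exp(-z))
        g <- crossprod(X[ix, , drop = FALSE], p - y[ix]) / length(ix)
        st <- adam_step(list(list(w = w)), list(list(w = g)), opt, lr)
        w <- st$params[[1]]$w
        opt <- st$state
      }
    }
  }
  structure(list(w = as.vector(w), scope = scope), class = "probe_decoder")
}

# concatenated activation features for the probe
probe_features <- function(net, batch, scope) {
  rec <- evaluate_trials(net, batch, store_activations = TRUE)
  acts <- attr(rec, "activations")
  if (scope == "penultimate") acts$encoder_out
  else do.call(cbind, acts)
}

#' Independent evidence estimates from decoder weights
#'
#' e_s1 is the mean of |w| * x over the negative-weight dimensions; e_s2 the
#' mean of w * x over the positive-weight dimensions. A decoder with no
#' negative or no positive weights is degenerate and raises an error.
#'
#' @param w decoder weight vector (or `probe_decoder`).
#' @param x activation matrix (trials x features) aligned with `w`.
#' @return data.frame(e_s1, e_s2) per trial.
#' @export
evidence_estimates <- function(w, x) {
  if (inherits(w, "probe_decoder")) w <- w$w
  x <- matrix(x, ncol = length(w))
  neg <- w < 0; pos <- w > 0
  if (!any(neg) || !any(pos))
    stop("degenerate decoder: needs both negative and positive weights")
  e_s1 <- as.vector(x[, neg, drop = FALSE] %*% abs(w[neg])) / sum(neg)
  e_s2 <- as.vector(x[, pos, drop = FALSE] %*% w[pos]) / sum(pos)
  data.frame(e_s1 = e_s1, e_s2 = e_s2)
}

#' The four decoding ROC analyses
#'
#' Given per-trial evidence estimates and the network's behavior, computes
#' choice probability for: (1) BE predicting decisions (e_s2 - e_s1 vs
#' s2-decision); (2) RCE predicting decisions (average of the two
#' response-conditioned curves); (3) BE predicting high confidence
#' (response-congruent minus response-incongruent evidence vs
#' confidence > threshold); (4) RCE predicting high confidence.
#'
#' @param ev data.frame(e_s1, e_s2) from [evidence_estimates()].
#' @param record aligned `behavioral_record`.
#' @param conf_threshold high-confidence threshold (default 0.75).
#' @return data.frame(analysis, dv, choice_probability).
#' @export
decoding_analyses <- function(ev, record, conf_threshold = 0.75) {
  dec_s2 <- record$decision == 2L
  be <- ev$e_s2 - ev$e_s1
  cp1 <- roc_choice_probability(be, dec_s2)$choice_probability
  cp2 <- mean(c(roc_choice_probability(ev$e_s1, !dec_s2)$choice_probability,
                roc_choice_probability(ev$e_s2, dec_s2)$choice_probability))
  hi <- record$confidence > conf_threshold
  be_conf <- ifelse(dec_s2, ev$e_s2 - ev$e_s1, ev$e_s1 - ev$e_s2)
  rce_conf <- ifelse(dec_s2, ev$e_s2, ev$e_s1)
  cp3 <- if (length(unique(hi)) < 2) NA_real_ else
    roc_choice_probability(be_conf, hi)$choice_probability
  cp4 <- if (length(unique(hi)) < 2) NA_real_ else
    roc_choice_probability(rce_conf, hi)$choice_probability
  data.frame(analysis = c("be_decision", "rce_decision", "be_confidence",
                          "rce_confidence"),
             dv = c("decision", "decision", "confidence", "confidence"),
             choice_probability = c(cp1, cp2, cp3, cp4))
}
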