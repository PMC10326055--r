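#' Performance-optimized confidence networks
#'
#' A shared convolutional encoder maps a 32x32 stimulus to a 100-dimensional
#' feature vector; task-specific heads read out a decision and either an
#' explicit confidence estimate (supervised tasks) or an opt-out action
#' policy plus value estimate (reinforcement learning).
#'
#' Encoder: 3 convolutional layers (32 channels, kernel 3, stride 2, batch
#' normalization, leaky ReLU slope 0.01) followed by fully-connected layers
#' of 256 and 128 units (batch norm + leaky ReLU) and a final linear layer of
#' 100 units.
#'
#' @name networks
NULL

# activation tap points (after these encoder layers) used for probing and
# perturbation: conv1..conv3 blocks, fc1, fc2, encoder output
ENC_BLOCK_ENDS <- c(3L, 6L, 9L, 12L, 15L, 16L)
ENC_BLOCK_NAMES <- c("conv1", "conv2", "conv3", "fc1", "fc2", "encoder_out")

build_encoder <- function() {
  list(nn_conv(32L, 32L, 1L, 32L), nn_batchnorm(32L, S = 256L), nn_lrelu(),
       nn_conv(16L, 16L, 32L, 32L), nn_batchnorm(32L, S = 64L), nn_lrelu(),
       nn_conv(8L, 8L, 32L, 32L), nn_batchnorm(32L, S = 16L), nn_lrelu(),
       nn_dense(512L, 256L), nn_batchnorm(256L), nn_lrelu(),
       nn_dense(256L, 128L), nn_batchnorm(128L), nn_lrelu(),
       nn_dense(128L, 100L))
}

#' Build a confidence network
#'
#' @param task `"two_choice"` (binary classification; the decision head emits
#'   p(class = s2)), `"ten_choice"` (10-way softmax head), or `"rl_gabor"`
#'   (actor over LEFT/RIGHT/OPT-OUT plus a critic).
#' @param seed integer seed for weight initialization (fan-in-scaled
#'   uniform) and, for multi-class data, the seeded draw of the two-class
#'   pair.
#' @return a `confidence_network` (or actor-critic variant) object.
#' @export
build_confidence_network <- function(task = c("two_choice", "ten_choice",
                                              "rl_gabor"), seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  enc <- build_encoder()
  heads <- switch(task,
    two_choice = list(class = nn_dense(100L, 1L), conf = nn_dense(100L, 1L)),
    ten_choice = list(class = nn_dense(100L, 10L), conf = nn_dense(100L, 1L)),
    rl_gabor = list(actor = nn_dense(100L, 3L), critic = nn_dense(100L, 1L)))
  class_pair <- if (task == "ten_choice") NULL else sort(sample.int(10L, 2L))
  structure(list(task = task, encoder = enc, heads = heads,
                 class_pair = class_pair, seed = seed,
                 r_opt_out = if (task == "rl_gabor") 0.5 else NULL),
            class = "confidence_network")
}

# pixels (32 x 32 x N) -> planar input matrix (1024 x N)
pixels_to_act <- function(px) matrix(px, nrow = 1024L)

# forward through encoder + heads. Head outputs are returned trial-major
# (N x K probabilities); internal activations stay feature-major (F x N).
net_forward <- function(net, px, training = FALSE, store = FALSE,
                        perturb = NULL) {
  N <- dim(px)[3]
  fw <- stack_forward(net$encoder, pixels_to_act(px), training = training,
                      store = store, perturb = perturb)
  feat <- fw$out
  out <- list(features = feat, enc_caches = fw$caches, N = N)
  if (store) {
    acts <- lapply(fw$acts[ENC_BLOCK_ENDS], t)  # trial-major for analyses
    names(acts) <- ENC_BLOCK_NAMES
    out$activations <- acts
  }
  for (h in names(net$heads)) {
    hf <- layer_forward(net$heads[[h]], feat, training = training)
    z <- hf$out                                  # K x N
    out[[paste0(h, "_cache")]] <- hf$cache
    out[[h]] <- switch(h,
      class = if (net$task == "ten_choice") t(apply(z, 2L, function(v) {
                e <- exp(v - max(v)); e / sum(e)
              })) else as.vector(1 / (1 + exp(-z))),
      conf = as.vector(1 / (1 + exp(-z))),
      actor = softmax_rows(t(z)),
      critic = as.vector(z))
  }
  out
}

# one optimizer step given per-head logit gradients (K x N, by head name)
net_backward_step <- function(net, fw, dlogits, opt, lr) {
  grads_heads <- list()
  dfeat <- 0
  for (h in names(dlogits)) {
    bw <- layer_backward(net$heads[[h]], fw[[paste0(h, "_cache")]],
                         dlogits[[h]])
    grads_heads[[h]] <- bw$grads
    dfeat <- dfeat + bw$da
  }
  bwe <- stack_backward(net$encoder, fw$enc_caches, dfeat)
  all_layers <- c(net$encoder, net$heads)
  all_grads <- c(bwe$grads, grads_heads[names(net$heads)])
  st <- adam_step(get_params(all_layers), all_grads, opt, lr)
  ne <- length(net$encoder)
  net$encoder <- set_params(net$encoder, st$params[seq_len(ne)])
  for (i in seq_along(net$heads))
    net$heads[[i]]$params <- st$params[[ne + i]]
  # batch-norm running statistics
  for (i in seq_along(net$encoder)) {
    if (net$encoder[[i]]$type == "bn")
      net$encoder[[i]] <- bn_update_running(net$encoder[[i]],
                                            fw$enc_caches[[i]])
  }
  list(net = net, opt = st$state)
}

#' Train a supervised confidence network
#'
#' Joint optimization of a classification loss (cross-entropy or binary
#' cross-entropy) and a confidence loss (binary cross-entropy against a
#' target of 1 when the current classification output is correct, else 0),
#' summed and minimized with Adam.
#'
#' @param net a `confidence_network` from [build_confidence_network()].
#' @param batch a `stimulus_batch` of processed training images; labels must
#'   be in 1..K (1..2 for two-choice, where class 2 is "s2").
#' @param epochs,lr,batch_size training hyperparameters (defaults 5, 5e-4, 32).
#' @param seed integer seed for shuffling.
#' @return the trained network, with a `training_log` attribute
#'   (data.frame of per-epoch mean losses).
#' @export
train_supervised <- function(net, batch, epochs = 5, lr = 5e-4,
                             batch_size = 32, seed = NULL) {
  stopifnot(inherits(net, "confidence_network"),
            net$task %in% c("two_choice", "ten_choice"))
  n <- nrow(batch$meta)
  if (n == 0) stop("empty training data")
  if (!is.null(seed)) set.seed(seed)
  opt <- adam_init()
  log <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      px <- batch$pixels[, , ix, drop = FALSE]
      y <- batch$meta$label[ix]
      m <- length(ix)
      fw <- net_forward(net, px, training = TRUE)
      if (net$task == "two_choice") {
        p <- fw$class
        tgt <- as.numeric(y == 2L)
        dclass <- matrix((p - tgt) / m, nrow = 1L)
        correct <- as.numeric((p > 0.5) == (tgt == 1))
        loss_cls <- -mean(tgt * log(pmax(p, 1e-12)) +
                            (1 - tgt) * log(pmax(1 - p, 1e-12)))
      } else {
        P <- fw$class
        oh <- matrix(0, m, ncol(P)); oh[cbind(seq_len(m), y)] <- 1
        dclass <- t(P - oh) / m
        correct <- as.numeric(max.col(P) == y)
        loss_cls <- -mean(log(pmax(P[cbind(seq_len(m), y)], 1e-12)))
      }
      pc <- fw$conf
      dconf <- matrix((pc - correct) / m, nrow = 1L)
      loss_conf <- -mean(correct * log(pmax(pc, 1e-12)) +
                           (1 - correct) * log(pmax(1 - pc, 1e-12)))
      step <- net_backward_step(net, fw, list(class = dclass, conf = dconf),
                                opt, lr)
      net <- step$net; opt <- step$opt
      losses <- c(losses, loss_cls + loss_conf)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
  }
  attr(net, "training_log") <- log
  net
}

#' Generate a batch of Gabor orientation-discrimination stimuli
#'
#' Tilt is drawn uniformly from {-5, +5} degrees (label 1 = left, 2 = right)
#' and (mu, sigma) per trial from the RL training regime
#' (mu in \[0.1, 1\], sigma in \[0.5, 1\]) unless fixed values are supplied.
#'
#' @param n number of trials.
#' @param mu,sigma optional fixed contrast/noise (otherwise regime-sampled).
#' @param seed integer seed.
#' @return a `stimulus_batch`.
#' @export
gabor_batch <- function(n, mu = NULL, sigma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- list(gabor_patch(gabor_spec(-5)), gabor_patch(gabor_spec(5)))
  labels <- sample(1:2, n, replace = TRUE)
  raw <- array(0, dim = c(IMG_SIZE, IMG_SIZE, n))
  for (i in seq_len(n)) raw[, , i] <- base[[labels[i]]]
  if (is.null(mu)) {
    reg <- regime("standard", mu_range = c(0.1, 1), sigma_range = c(0.5, 1))
    make_stimulus_batch(raw, labels, reg = reg)
  } else {
    make_stimulus_batch(raw, labels, mu = mu, sigma = sigma)
  }
}

#' Train the actor-critic network on the opt-out orientation task
#'
#' On each trial an action is sampled from the actor (LEFT, RIGHT, OPT-OUT).
#' Correct decisions earn reward 1, incorrect 0; OPT-OUT earns the guaranteed
#' reward r_opt-out, initialized at 0.5 and updated after every batch to
#' min(previous-batch non-opt-out accuracy, 0.75). The critic minimizes a
#' smooth-L1 (Huber) loss predicting reward; the actor minimizes
#' -log p(a) * (r - v).
#'
#' @param net an `rl_gabor` network from [build_confidence_network()].
#' @param iterations,lr,batch_size training hyperparameters
#'   (defaults 5000, 1e-3, 32).
#' @param seed integer seed (stimuli, action sampling).
#' @return the trained network with a `training_log` attribute (per-100-batch
#'   running accuracy, opt-out rate and r_opt-out).
#' @export
train_rl_actor_critic <- function(net, iterations = 5000, lr = 1e-3,
                                  batch_size = 32, seed = NULL) {
  stopifnot(inherits(net, "confidence_network"), net$task == "rl_gabor")
  if (!is.null(seed)) set.seed(seed)
  opt <- adam_init()
  base <- list(gabor_patch(gabor_spec(-5)), gabor_patch(gabor_spec(5)))
  r_opt <- net$r_opt_out
  log <- data.frame(iteration = integer(), accuracy = numeric(),
                    opt_out_rate = numeric(), r_opt_out = numeric())
  acc_acc <- c(); acc_opt <- c()
  for (it in seq_len(iterations)) {
    labels <- sample(1:2, batch_size, replace = TRUE)
    ms <- data.frame(mu = stats::runif(batch_size, 0.1, 1),
                     sigma = stats::runif(batch_size, 0.5, 1))
    raw <- array(unlist(base[labels]), dim = c(IMG_SIZE, IMG_SIZE, batch_size))
    px <- 2 * sweep(raw, 3L, ms$mu, "*") - 1
    px <- px + stats::rnorm(length(px), 0, rep(ms$sigma, each = 1024L))
    px <- pmin(pmax(px, -1), 1)
    dim(px) <- dim(raw)
    fw <- net_forward(net, px, training = TRUE)
    P <- fw$actor
    a <- apply(P, 1L, function(p) sample.int(3L, 1L, prob = p))
    optout <- a == 3L
    correct <- a == labels
    r <- ifelse(optout, r_opt, as.numeric(correct))
    v <- as.vector(fw$critic)
    delta <- r - v
    # actor: d/dlogits of mean(-log p_a * delta_detached)
    oh <- matrix(0, batch_size, 3L); oh[cbind(seq_len(batch_size), a)] <- 1
    dactor <- t((P - oh) * delta) / batch_size
    # critic: Huber gradient wrt v is -clamp(delta, -1, 1)
    dcritic <- matrix(-pmin(pmax(delta, -1), 1) / batch_size, nrow = 1L)
    step <- net_backward_step(net, fw, list(actor = dactor, critic = dcritic),
                              opt, lr)
    net <- step$net; opt <- step$opt
    if (any(!optout)) r_opt <- min(mean(correct[!optout]), 0.75)
    acc_acc <- c(acc_acc, mean(correct[!optout]))
    acc_opt <- c(acc_opt, mean(optout))
    if (it %% 100L == 0L) {
      log <- rbind(log, data.frame(iteration = it,
                                   accuracy = mean(acc_acc, na.rm = TRUE),
                                   opt_out_rate = mean(acc_opt),
                                   r_opt_out = r_opt))
      acc_acc <- c(); acc_opt <- c()
    }
  }
  net$r_opt_out <- r_opt
  attr(net, "training_log") <- log
  net
}

#' Evaluate a trained network trial-by-trial
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' records one row per trial. Decisions are made by argmax; for the RL task a
#' trial is an opt-out when OPT-OUT is the argmax over all three actions, and
#' accuracy-bearing decisions take the argmax over LEFT/RIGHT only.
#'
#' @param net a trained network.
#' @param batch a `stimulus_batch`.
#' @param store_activations also record activations at the six tap points
#'   (conv1..3, fc1, fc2, encoder_out) as an `"activations"` attribute.
#' @param perturb optional [perturbation_spec()] applied during the forward
#'   pass.
#' @param chunk internal evaluation chunk size.
#' @param ... passed to methods.
#' @return a `behavioral_record` data.frame with columns trial, label, mu,
#'   sigma, decision, confidence, opt_out, correct plus raw head outputs
#'   (p_s2 / p_left, p_right, p_optout, value).
#' @export
evaluate_trials <- function(net, batch, ...) UseMethod("evaluate_trials")

#' @rdname evaluate_trials
#' @export
evaluate_trials.confidence_network <- function(net, batch,
                                               store_activations = FALSE,
                                               perturb = NULL, chunk = 256L,
                                               ...) {
  stopifnot(inherits(batch, "stimulus_batch"))
  n <- nrow(batch$meta)
  pert <- NULL
  if (!is.null(perturb)) {
    stopifnot(inherits(perturb, "perturbation_spec"))
    if (perturb$layer < 1L || perturb$layer > length(ENC_BLOCK_ENDS))
      stop("perturbation layer index out of range")
    pert <- list(after = ENC_BLOCK_ENDS[perturb$layer], kind = perturb$kind,
                 magnitude = perturb$magnitude)
  }
  rows <- list(); acts <- NULL
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    fw <- net_forward(net, batch$pixels[, , ix, drop = FALSE],
                      training = FALSE, store = store_activations,
                      perturb = pert)
    m <- length(ix)
    meta <- batch$meta[ix, , drop = FALSE]
    if (net$task == "rl_gabor") {
      P <- fw$actor
      optout <- max.col(P, ties.method = "first") == 3L
      dec <- ifelse(P[, 1L] >= P[, 2L], 1L, 2L)
      df <- data.frame(meta, decision = dec,
                       confidence = 1 - P[, 3L], opt_out = optout,
                       p_left = P[, 1L], p_right = P[, 2L], p_optout = P[, 3L],
                       value = as.vector(fw$critic))
    } else if (net$task == "two_choice") {
      p <- as.vector(fw$class)
      df <- data.frame(meta, decision = ifelse(p > 0.5, 2L, 1L),
                       confidence = as.vector(fw$conf), opt_out = FALSE,
                       p_s2 = p)
    } else {
      P <- fw$class
      df <- data.frame(meta, decision = max.col(P, ties.method = "first"),
                       confidence = as.vector(fw$conf), opt_out = FALSE)
    }
    df$correct <- ifelse(df$opt_out, NA, df$decision == df$label)
    rows[[length(rows) + 1L]] <- df
    if (store_activations) {
      if (is.null(acts)) acts <- fw$activations
      else acts <- Map(rbind, acts, fw$activations)
    }
  }
  rec <- do.call(rbind, rows)
  rec$trial <- seq_len(nrow(rec))
  class(rec) <- c("behavioral_record", "data.frame")
  if (store_activations) attr(rec, "activations") <- acts
  rec
}

#' Save / load a network checkpoint
#'
#' Single-file archive of parameters, architecture tag and seed.
#' @param net network object.
#' @param path file path.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) readRDS(path)
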