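# Minimal vectorized neural-network engine.
#
# Activations are carried between layers as a matrix of shape F x N: one
# column per sample, one row per feature. Convolutional feature maps use a
# channel-first planar layout (row index = channel + C * (spatial - 1),
# spatial positions column-major over the map). With this layout a
# convolution is a single gather (im2col) followed by one crossprod, its
# backward pass one crossprod plus a rowsum scatter, and no transposes are
# needed anywhere in the conv stack; fully-connected layers are crossprods
# on the same orientation.

nn_rand_init <- function(n_in, dims) {
  # fan-in-scaled uniform: U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and biases
  b <- 1 / sqrt(n_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

# ---- index machinery -------------------------------------------------------

# Gather indices for a convolution inH x inW x inC -> outH x outW with kernel
# k, stride s, zero padding p. Returns a (k*k*inC) x (outH*outW) matrix of
# indices into the per-sample channel-first planar layout
# (index = c + inC * ((h-1) + inH * (w-1))), with D + 1 marking padded taps.
# Tap rows are ordered channel fastest, then kernel row, then kernel column,
# matching the weight-matrix row order.
conv_indices <- function(inH, inW, inC, k, s, p) {
  outH <- (inH + 2L * p - k) %/% s + 1L
  outW <- (inW + 2L * p - k) %/% s + 1L
  D <- inH * inW * inC
  oh <- rep(seq_len(outH), times = outW)
  ow <- rep(seq_len(outW), each = outH)
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  ih <- outer(kh - p, (oh - 1L) * s, "+")              # k2 x So
  iw <- outer(kw - p, (ow - 1L) * s, "+")
  valid <- ih >= 1L & ih <= inH & iw >= 1L & iw <= inW
  spat <- (ih - 1L) + inH * (iw - 1L)                  # 0-based spatial offset
  spat[!valid] <- NA
  k2 <- k * k
  So <- outH * outW
  idx <- matrix(0L, inC * k2, So)
  for (c in seq_len(inC))
    idx[c + inC * (seq_len(k2) - 1L), ] <- c + inC * spat
  idx[is.na(idx)] <- D + 1L
  list(idx = idx, outH = outH, outW = outW, D = D, k2C = inC * k2, So = So)
}

# planar (D x N) -> patch matrix (k2C x So*N)
im2col <- function(xb, ci) {
  xb2 <- rbind(xb, 0)
  P0 <- xb2[as.vector(ci$idx), , drop = FALSE]         # (k2C*So) x N
  dim(P0) <- c(ci$k2C, ci$So * ncol(xb))
  P0
}

# patch matrix (k2C x So*N) -> planar (D x N), accumulating duplicate taps
col2im <- function(P0, ci, N) {
  dim(P0) <- c(ci$k2C * ci$So, N)
  idxv <- as.vector(ci$idx)
  acc <- rowsum(P0, group = idxv)                      # sorted unique indices
  out <- matrix(0, ci$D + 1L, N)
  out[sort(unique(idxv)), ] <- acc
  out[seq_len(ci$D), , drop = FALSE]
}

# ---- layers ----------------------------------------------------------------

nn_conv <- function(inH, inW, inC, outC, k = 3L, stride = 2L, pad = 1L) {
  ci <- conv_indices(inH, inW, inC, k, stride, pad)
  list(type = "conv", ci = ci, inC = inC, outC = outC,
       params = list(W = nn_rand_init(k * k * inC, c(k * k * inC, outC)),
                     b = as.vector(nn_rand_init(k * k * inC, outC))))
}

# Transposed convolution inH -> inH*stride (kernel 4, stride 2, pad 1 doubles
# the map). Internally reuses the gather indices of the reverse convolution.
nn_convT <- function(inH, inW, inC, outC, k = 4L, stride = 2L, pad = 1L) {
  outH <- inH * stride
  ci <- conv_indices(outH, outH, outC, k, stride, pad)  # reverse conv: out -> in
  stopifnot(ci$So == inH * inW)
  list(type = "convT", ci = ci, inC = inC, outC = outC,
       S_out = outH * outH,
       params = list(W = nn_rand_init(k * k * inC, c(k * k * outC, inC)),
                     b = as.vector(nn_rand_init(k * k * inC, outC))))
}

nn_dense <- function(n_in, n_out) {
  list(type = "dense", inC = n_in, outC = n_out,
       params = list(W = nn_rand_init(n_in, c(n_in, n_out)),
                     b = as.vector(nn_rand_init(n_in, n_out))))
}

# batch normalization over C channels, each spanning S spatial positions
nn_batchnorm <- function(C, S = 1L, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", C = C, S = S, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       run_mean = rep(0, C), run_var = rep(1, C))
}

nn_lrelu <- function(slope = 0.01) list(type = "lrelu", slope = slope)
nn_tanh <- function() list(type = "tanh")
nn_sigmoid <- function() list(type = "sigmoid")

layer_forward <- function(layer, x, training = FALSE) {
  N <- ncol(x)
  switch(layer$type,
    conv = {
      P0 <- im2col(x, layer$ci)
      out <- crossprod(layer$params$W, P0)             # outC x So*N
      dim(out) <- c(layer$outC * layer$ci$So, N)
      out <- out + rep(layer$params$b, layer$ci$So)
      list(out = out, cache = list(P0 = P0))
    },
    convT = {
      x0 <- x
      dim(x0) <- c(layer$inC, layer$ci$So * N)
      P0 <- layer$params$W %*% x0                      # k2*outC x So*N
      out <- col2im(P0, layer$ci, N)
      out <- out + rep(layer$params$b, layer$S_out)
      list(out = out, cache = list(x0 = x0))
    },
    dense = {
      out <- crossprod(layer$params$W, x) + layer$params$b
      list(out = out, cache = list(x = x))
    },
    bn = {
      xc <- x
      dim(xc) <- c(layer$C, layer$S * N)
      if (training) {
        mu <- rowMeans(xc)
        v <- rowMeans(xc^2) - mu^2
        inv_sd <- 1 / sqrt(v + layer$eps)
        xhat <- (xc - mu) * inv_sd
        cache <- list(xhat = xhat, inv_sd = inv_sd, mu = mu, v = v)
      } else {
        inv_sd <- 1 / sqrt(layer$run_var + layer$eps)
        xhat <- (xc - layer$run_mean) * inv_sd
        cache <- list(xhat = xhat, inv_sd = inv_sd)
      }
      out <- layer$params$gamma * xhat + layer$params$beta
      dim(out) <- dim(x)
      list(out = out, cache = cache)
    },
    lrelu = {
      fac <- layer$slope + (1 - layer$slope) * (x > 0)
      list(out = x * fac, cache = list(fac = fac))
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = list(out = out))
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = list(out = out))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  N <- ncol(dout)
  switch(layer$type,
    conv = {
      d0 <- dout
      dim(d0) <- c(layer$outC, layer$ci$So * N)
      dW <- tcrossprod(cache$P0, d0)                   # k2C x outC
      db <- rowSums(matrix(rowSums(dout), layer$outC, layer$ci$So))
      dP0 <- layer$params$W %*% d0                     # k2C x So*N
      da <- col2im(dP0, layer$ci, N)
      list(da = da, grads = list(W = dW, b = db))
    },
    convT = {
      db <- rowSums(matrix(rowSums(dout), layer$outC, layer$S_out))
      dP0 <- im2col(dout, layer$ci)                    # k2*outC x So*N
      dW <- tcrossprod(dP0, cache$x0)                  # k2*outC x inC
      da <- crossprod(layer$params$W, dP0)             # inC x So*N
      dim(da) <- c(layer$inC * layer$ci$So, N)
      list(da = da, grads = list(W = dW, b = db))
    },
    dense = {
      dW <- tcrossprod(cache$x, dout)
      db <- rowSums(dout)
      da <- layer$params$W %*% dout
      list(da = da, grads = list(W = dW, b = db))
    },
    bn = {
      dc <- dout
      dim(dc) <- c(layer$C, layer$S * N)
      dgamma <- rowSums(dc * cache$xhat)
      dbeta <- rowSums(dc)
      dxhat <- layer$params$gamma * dc
      da <- cache$inv_sd * (dxhat - rowMeans(dxhat) -
                              cache$xhat * rowMeans(dxhat * cache$xhat))
      dim(da) <- dim(dout)
      list(da = da, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = list(da = dout * cache$fac, grads = NULL),
    tanh = list(da = dout * (1 - cache$out^2), grads = NULL),
    sigmoid = list(da = dout * cache$out * (1 - cache$out), grads = NULL),
    stop("unknown layer type: ", layer$type))
}

# Running-statistics update for batch-norm layers after a training forward pass.
bn_update_running <- function(layer, cache) {
  m <- layer$momentum
  layer$run_mean <- (1 - m) * layer$run_mean + m * cache$mu
  layer$run_var <- (1 - m) * layer$run_var + m * cache$v
  layer
}

# Forward through a list of layers (x: F x N). `perturb` is an optional list
# (after = layer index, kind = "additive_noise"|"scale", magnitude = numeric)
# applied to the activations emitted by that layer; `store` collects the
# post-layer activations.
stack_forward <- function(layers, x, training = FALSE, store = FALSE,
                          perturb = NULL) {
  caches <- vector("list", length(layers))
  acts <- if (store) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x, training = training)
    x <- fw$out
    caches[[i]] <- fw$cache
    if (!is.null(perturb) && perturb$after == i) {
      if (perturb$kind == "additive_noise") {
        x <- x + matrix(stats::rnorm(length(x), 0, sqrt(perturb$magnitude)),
                        nrow(x), ncol(x))
      } else {
        x <- x * perturb$magnitude
      }
    }
    if (store) acts[[i]] <- x
  }
  list(out = x, caches = caches, acts = acts)
}

stack_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- bw$da
    grads[i] <- list(bw$grads)   # keep NULLs for parameter-free layers
  }
  list(da = dout, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

# params/grads: nested list layers -> named params. Returns updated params+state.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      key <- paste0(i, ".", nm)
      m <- state$m[[key]]
      v <- state$v[[key]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$m[[key]] <- m
      state$v[[key]] <- v
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * (m / bc1) /
        (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

get_params <- function(layers) lapply(layers, function(l) l$params)

set_params <- function(layers, params) {
  for (i in seq_along(layers)) layers[[i]]$params <- params[[i]]
  layers
}

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1L, max))
  z / rowSums(z)
}
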