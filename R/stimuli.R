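#' Stimulus generation and processing
#'
#' Images are 32x32 grayscale grids. Raw images have pixel values in \[0, 1\];
#' processed stimuli are scaled by a contrast factor mu, normalized to
#' \[-1, 1\], corrupted with i.i.d. Gaussian pixel noise of scale sigma and
#' finally clamped back to \[-1, 1\] (a hard-tanh threshold).
#'
#' @name stimuli
NULL

IMG_SIZE <- 32L

#' Apply contrast scaling, normalization, pixel noise and clamping
#'
#' Implements the stimulus processing chain
#' \code{clamp(2 * mu * p - 1 + eps, -1, 1)} with \code{eps ~ N(0, sigma^2)}.
#' `sigma` is interpreted as the noise standard deviation on the \[-1, 1\]
#' pixel scale by default; set \code{sigma_is_variance = TRUE} to interpret it
#' as a variance instead.
#'
#' @param image numeric matrix or 3-d array of raw pixels in \[0, 1\]
#'   (H x W or H x W x N).
#' @param mu contrast factor, >= 0.
#' @param sigma noise scale parameter, >= 0.
#' @param seed optional integer seed making the noise reproducible.
#' @param sigma_is_variance treat `sigma` as a variance rather than a
#'   standard deviation.
#' @return array of the same shape with values in \[-1, 1\], with attributes
#'   `mu` and `sigma` recording the trial parameters.
#' @export
apply_contrast_noise <- function(image, mu, sigma, seed = NULL,
                                 sigma_is_variance = FALSE) {
  if (!is.numeric(image) || anyNA(image) || any(!is.finite(image)))
    stop("image must be finite numeric")
  if (any(image < 0) || any(image > 1)) stop("raw pixels must lie in [0, 1]")
  if (mu < 0) stop("mu must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sd <- if (sigma_is_variance) sqrt(sigma) else sigma
  out <- 2 * mu * image - 1
  if (sd > 0) out <- out + stats::rnorm(length(out), 0, sd)
  out <- pmin(pmax(out, -1), 1)
  dim(out) <- dim(image)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Gabor patch specification
#'
#' @param tilt orientation in degrees from vertical; the discrimination task
#'   uses -5 (left) and +5 (right).
#' @param envelope_sd standard deviation of the centered Gaussian envelope,
#'   in pixels.
#' @param spatial_frequency grating frequency in cycles per pixel.
#' @param size image side length in pixels.
#' @export
gabor_spec <- function(tilt, envelope_sd = 4, spatial_frequency = 0.3,
                       size = IMG_SIZE) {
  stopifnot(is.numeric(tilt), length(tilt) == 1L, envelope_sd > 0,
            spatial_frequency > 0, size >= 4)
  structure(list(tilt = tilt, envelope_sd = envelope_sd,
                 spatial_frequency = spatial_frequency, size = as.integer(size)),
            class = "gabor_spec")
}

#' Generate a Gabor patch
#'
#' A cosine grating (phase zero at the image center) at the requested spatial
#' frequency, oriented `tilt` degrees from vertical, windowed by a centered
#' Gaussian envelope and rescaled to \[0, 1\].
#'
#' @param spec a [gabor_spec()].
#' @return a size x size matrix of raw pixel values in \[0, 1\].
#' @export
gabor_patch <- function(spec) {
  stopifnot(inherits(spec, "gabor_spec"))
  n <- spec$size
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - ctr, each = n), n, n)   # column offset
  y <- matrix(rep(seq_len(n) - ctr, times = n), n, n)  # row offset
  th <- spec$tilt * pi / 180
  # coordinate along the axis orthogonal to the (near-vertical) stripes
  u <- x * cos(th) - y * sin(th)
  grating <- cos(2 * pi * spec$spatial_frequency * u)
  env <- exp(-(x^2 + y^2) / (2 * spec$envelope_sd^2))
  (grating * env + 1) / 2
}

#' Superimpose two contrast-scaled stimuli
#'
#' Pixel-wise maximum of the two images; visual noise is added after
#' superimposition by the callers that need it.
#'
#' @param x_s1,x_s2 images of identical dimensions.
#' @return element-wise maximum.
#' @export
superimpose <- function(x_s1, x_s2) {
  if (!identical(dim(x_s1), dim(x_s2)))
    stop("superimpose: image dimensions differ")
  pmax(x_s1, x_s2)
}

#' Contrast/noise training regime
#'
#' The four regimes under which networks are trained:
#' \describe{
#'   \item{standard}{mu ~ U(0.1, 1), sigma ~ U(sigma_range)}
#'   \item{fixed_mu}{mu = 0.5, sigma ~ U(sigma_range)}
#'   \item{fixed_sigma}{mu ~ U(0.1, 1), sigma = midpoint of sigma_range}
#'   \item{fixed_mu_over_sigma}{mu ~ U(0.1, 1), sigma = 3.75 * mu}
#' }
#' The default noise range \[1, 2\] matches the digit-classification task; the
#' orientation-discrimination (RL) task uses \[0.5, 1\].
#'
#' @param name regime name.
#' @param mu_range contrast range (or constant for fixed_mu).
#' @param sigma_range noise range (constants are collapsed from it).
#' @param ratio sigma/mu ratio for fixed_mu_over_sigma.
#' @export
regime <- function(name = c("standard", "fixed_mu", "fixed_sigma",
                            "fixed_mu_over_sigma"),
                   mu_range = c(0.1, 1), sigma_range = c(1, 2), ratio = 3.75) {
  name <- match.arg(name)
  structure(list(name = name, mu_range = mu_range, sigma_range = sigma_range,
                 ratio = ratio), class = "regime")
}

#' Sample (mu, sigma) pairs under a regime
#'
#' @param reg a [regime()].
#' @param n number of pairs.
#' @param seed optional integer seed.
#' @return data.frame with columns `mu`, `sigma`.
#' @export
sample_regime <- function(reg, n, seed = NULL) {
  stopifnot(inherits(reg, "regime"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- switch(reg$name,
    fixed_mu = rep(0.5, n),
    stats::runif(n, reg$mu_range[1], reg$mu_range[2]))
  sigma <- switch(reg$name,
    standard = stats::runif(n, reg$sigma_range[1], reg$sigma_range[2]),
    fixed_mu = stats::runif(n, reg$sigma_range[1], reg$sigma_range[2]),
    fixed_sigma = mean(reg$sigma_range),
    fixed_mu_over_sigma = reg$ratio * mu)
  data.frame(mu = mu, sigma = rep(sigma, length.out = n))
}

#' Build a processed stimulus batch
#'
#' Takes raw images in \[0, 1\], samples per-trial (mu, sigma) under a regime
#' (or uses fixed values), and applies the full processing chain. The result
#' is the standard container consumed by training and evaluation.
#'
#' @param raw 3-d array H x W x N of raw pixels in \[0, 1\].
#' @param labels integer class labels of length N.
#' @param reg a [regime()], or NULL when `mu`/`sigma` are given explicitly.
#' @param mu,sigma explicit per-trial (recycled) contrast and noise values,
#'   used when `reg` is NULL.
#' @param seed integer seed controlling both the regime draw and the noise.
#' @return a `stimulus_batch`: list(pixels = H x W x N array in \[-1, 1\],
#'   meta = data.frame(trial, label, mu, sigma)).
#' @export
make_stimulus_batch <- function(raw, labels, reg = NULL, mu = NULL,
                                sigma = NULL, seed = NULL) {
  n <- dim(raw)[3]
  stopifnot(length(labels) == n)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(reg)) {
    ms <- sample_regime(reg, n)
  } else {
    ms <- data.frame(mu = rep(mu, length.out = n),
                     sigma = rep(sigma, length.out = n))
  }
  px <- 2 * sweep(raw, 3L, ms$mu, "*") - 1
  sds <- rep(ms$sigma, each = prod(dim(raw)[1:2]))
  px <- px + stats::rnorm(length(px), 0, sds)
  px <- pmin(pmax(px, -1), 1)
  dim(px) <- dim(raw)
  structure(list(pixels = px,
                 meta = data.frame(trial = seq_len(n), label = labels,
                                   mu = ms$mu, sigma = ms$sigma)),
            class = "stimulus_batch")
}

#' Serialize / restore a stimulus batch
#'
#' Pixels are stored in a single-file archive; the per-trial metadata table
#' round-trips bit-exactly through a text table alongside it.
#'
#' @param batch a `stimulus_batch`.
#' @param path base path (two files are written: `<path>.rds` and
#'   `<path>_meta.csv`).
#' @export
write_stimulus_batch <- function(batch, path) {
  stopifnot(inherits(batch, "stimulus_batch"))
  saveRDS(batch$pixels, paste0(path, ".rds"))
  meta <- batch$meta
  for (nm in names(meta))   # 17 significant digits round-trip doubles exactly
    if (is.double(meta[[nm]])) meta[[nm]] <- sprintf("%.17g", meta[[nm]])
  utils::write.csv(meta, paste0(path, "_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_batch
#' @export
read_stimulus_batch <- function(path) {
  structure(list(pixels = readRDS(paste0(path, ".rds")),
                 meta = utils::read.csv(paste0(path, "_meta.csv"))),
            class = "stimulus_batch")
}

#' Load images from IDX files (optional)
#'
#' Reader for the standard IDX image/label format used by the MNIST digit
#' set. Images are resized from 28x28 to 32x32 by bilinear interpolation and
#' rescaled to \[0, 1\]. Entirely optional: nothing else in the package
#' requires these files.
#'
#' @param image_file,label_file paths to IDX image and label files.
#' @param n maximum number of images to read.
#' @return list(raw = 32 x 32 x N array in \[0, 1\], labels = integer vector).
#' @export
read_idx_images <- function(image_file, label_file, n = Inf) {
  con <- file(image_file, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  stopifnot(magic == 2051L)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "big")
  n_img <- min(hdr[1], n)
  h <- hdr[2]; w <- hdr[3]
  px <- readBin(con, "integer", n_img * h * w, size = 1, signed = FALSE)
  raw28 <- array(px / 255, dim = c(w, h, n_img))
  con2 <- file(label_file, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  stopifnot(magic2 == 2049L)
  readBin(con2, "integer", 1, size = 4, endian = "big")
  labels <- readBin(con2, "integer", n_img, size = 1, signed = FALSE)
  raw <- array(0, dim = c(IMG_SIZE, IMG_SIZE, n_img))
  for (i in seq_len(n_img)) raw[, , i] <- bilinear_resize(t(raw28[, , i]), IMG_SIZE)
  list(raw = raw, labels = labels)
}

bilinear_resize <- function(m, out) {
  n <- nrow(m)
  # align-corners-false convention
  src <- (seq_len(out) - 0.5) * n / out - 0.5
  lo <- pmin(pmax(floor(src), 0), n - 1)
  hi <- pmin(lo + 1, n - 1)
  w <- src - lo
  w[src < 0] <- 0
  i0 <- lo + 1; i1 <- hi + 1
  rows <- m[i0, , drop = FALSE] * (1 - w) + m[i1, , drop = FALSE] * w
  t(t(rows[, i0, drop = FALSE]) * (1 - w) + t(rows[, i1, drop = FALSE]) * w)
}
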