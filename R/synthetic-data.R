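#' Synthetic two-class images and latent-evidence generators
#'
#' Download-free stand-ins: (a) a two-class image generator emulating the
#' class structure of a handwritten-digit pair (fixed prototypes plus smooth
#' per-sample deformation), and (b) a two-dimensional latent-evidence
#' generator with controllable per-class anisotropy and major-axis angle.
#'
#' @name synthetic_data
NULL

#' Fixed class prototypes
#'
#' Two deterministic 32x32 prototypes with a gross shape difference, the way
#' a typical handwritten-digit pair differs: a horizontal and a vertical bar
#' (Gaussian cross-section, sd 3 px) under a shared Gaussian envelope, plus
#' the common (class-neutral) centered blob used to interpolate class
#' separation. Values in \[0, 1\].
#'
#' @return list(common, s1, s2) of 32 x 32 matrices.
#' @export
synthetic_prototypes <- function() {
  n <- IMG_SIZE; ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  y <- matrix(rep(seq_len(n) - ctr, times = n), n, n)
  env <- exp(-(x^2 + y^2) / (2 * 8^2))
  list(common = exp(-(x^2 + y^2) / (2 * 6^2)),
       s1 = pmin(exp(-y^2 / (2 * 3^2)) * env * 1.6, 1),   # horizontal bar
       s2 = pmin(exp(-x^2 / (2 * 3^2)) * env * 1.6, 1))   # vertical bar
}

# small random affine warp (rotation + anisotropic scale + translation),
# bilinear resampling, zero padding outside the grid
warp_image <- function(m, theta, sx, sy, tx, ty) {
  n <- nrow(m)
  ctr <- (n + 1) / 2
  gx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  gy <- matrix(rep(seq_len(n) - ctr, times = n), n, n)
  ct <- cos(theta); st <- sin(theta)
  srcx <- (gx * ct - gy * st) / sx + ctr - tx
  srcy <- (gx * st + gy * ct) / sy + ctr - ty
  x0 <- floor(srcx); y0 <- floor(srcy)
  fx <- srcx - x0; fy <- srcy - y0
  val <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= n
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  v <- val(y0, x0) * (1 - fx) * (1 - fy) + val(y0, x0 + 1) * fx * (1 - fy) +
    val(y0 + 1, x0) * (1 - fx) * fy + val(y0 + 1, x0 + 1) * fx * fy
  matrix(v, n, n)
}

#' Generate labelled two-class raw images
#'
#' Each sample interpolates between a class-neutral prototype and one of two
#' class prototypes with weight \code{separation / (separation + 1)}, then
#' receives a small random affine warp (rotation sd 6 degrees, scale sd 5\%,
#' translation sd 1 px) and multiplicative amplitude jitter (sd 10\%),
#' mimicking handwriting-like within-class variability. At separation 0 the
#' two class distributions coincide.
#'
#' @param n_per_class samples per class.
#' @param separation class separation (effect size), >= 0. Default 5 gives a
#'   cleanly discriminable pair, standing in for a typical digit pair.
#' @param seed integer seed.
#' @return list(raw = 32 x 32 x 2n array in \[0, 1\], labels = integer vector
#'   of 1s and 2s).
#' @export
make_synthetic_classes <- function(n_per_class, separation = 5, seed = NULL) {
  stopifnot(n_per_class > 0, separation >= 0)
  if (!is.null(seed)) set.seed(seed)
  pr <- synthetic_prototypes()
  w <- separation / (separation + 1)
  protos <- list(pr$common * (1 - w) + pr$s1 * w,
                 pr$common * (1 - w) + pr$s2 * w)
  n <- 2L * n_per_class
  labels <- rep(1:2, each = n_per_class)
  ord <- sample.int(n)        # interleave classes
  labels <- labels[ord]
  raw <- array(0, dim = c(IMG_SIZE, IMG_SIZE, n))
  for (i in seq_len(n)) {
    img <- warp_image(protos[[labels[i]]],
                      theta = stats::rnorm(1, 0, 6 * pi / 180),
                      sx = exp(stats::rnorm(1, 0, 0.05)),
                      sy = exp(stats::rnorm(1, 0, 0.05)),
                      tx = stats::rnorm(1, 0, 1), ty = stats::rnorm(1, 0, 1))
    img <- img * exp(stats::rnorm(1, 0, 0.1))
    raw[, , i] <- pmin(pmax(img, 0), 1)
  }
  list(raw = raw, labels = labels)
}

#' Latent-evidence distribution specification
#'
#' Two rotated anisotropic bivariate Gaussians in a 2-d evidence space.
#' Angles are the orientations of the major axes, in degrees in [0, 180).
#'
#' @param mean_s1,mean_s2 class mean 2-vectors.
#' @param sd_major,sd_minor principal-axis standard deviations
#'   (sd_major >= sd_minor > 0), shared by both classes.
#' @param axis_angle_s1,axis_angle_s2 major-axis angles in degrees.
#' @param prior_s1 prior probability of class s1.
#' @export
latent_evidence_spec <- function(mean_s1 = c(0, 0), mean_s2 = c(0, 0),
                                 sd_major = 1, sd_minor = 1,
                                 axis_angle_s1 = 0, axis_angle_s2 = 0,
                                 prior_s1 = 0.5) {
  if (!(sd_major >= sd_minor && sd_minor > 0))
    stop("need sd_major >= sd_minor > 0")
  if (prior_s1 < 0 || prior_s1 > 1) stop("prior_s1 must be a probability")
  structure(list(mean_s1 = mean_s1, mean_s2 = mean_s2, sd_major = sd_major,
                 sd_minor = sd_minor,
                 axis_angle_s1 = axis_angle_s1 %% 180,
                 axis_angle_s2 = axis_angle_s2 %% 180, prior_s1 = prior_s1),
            class = "latent_evidence_spec")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# rotated covariance with major axis at `deg` degrees
axis_cov <- function(sd_major, sd_minor, deg) {
  R <- rot2(deg)
  R %*% diag(c(sd_major^2, sd_minor^2)) %*% t(R)
}

#' Sample labelled latent evidence
#'
#' @param spec a [latent_evidence_spec()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame(z1, z2, label) with label in {1, 2} (1 = s1).
#' @export
sample_latent_evidence <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "latent_evidence_spec"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  lab <- ifelse(stats::runif(n) < spec$prior_s1, 1L, 2L)
  e <- matrix(stats::rnorm(2 * n), n, 2)
  e <- sweep(e, 2L, c(spec$sd_major, spec$sd_minor), "*")
  z <- matrix(0, n, 2)
  for (k in 1:2) {
    i <- lab == k
    if (!any(i)) next
    R <- rot2(if (k == 1) spec$axis_angle_s1 else spec$axis_angle_s2)
    mu <- if (k == 1) spec$mean_s1 else spec$mean_s2
    z[i, ] <- sweep(e[i, , drop = FALSE] %*% t(R), 2L, mu, "+")
  }
  data.frame(z1 = z[, 1], z2 = z[, 2], label = lab)
}
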