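#' Type-1 and type-2 signal detection theory
#'
#' d-prime measures how well decisions discriminate the two stimulus
#' classes; meta-d-prime measures, on the same scale, how well confidence
#' ratings discriminate correct from incorrect decisions. meta-d' is fitted
#' by maximum likelihood under the equal-variance type-2 SDT model, with the
#' type-2 criterion tied to the type-1 relative criterion c' = c/d'.
#'
#' @name sdt
NULL

#' Type-1 sensitivity
#'
#' d' = z(HR) - z(FAR) for a two-choice record (hit = responding s2 to s2).
#' Opt-out trials are excluded. If any stimulus-response cell is empty, 0.5
#' is added to all cells (log-linear correction) so d' stays finite.
#'
#' @param record a `behavioral_record`, or a data.frame with columns `label`
#'   and `decision` in {1, 2}.
#' @return list(d_prime, criterion, hr, far).
#' @export
dprime <- function(record) {
  r <- record[!record$opt_out %in% TRUE, , drop = FALSE]
  if (length(unique(r$label)) < 2L)
    stop("record must contain both stimulus classes")
  n_s1 <- sum(r$label == 1L); n_s2 <- sum(r$label == 2L)
  hits <- sum(r$label == 2L & r$decision == 2L)
  fas <- sum(r$label == 1L & r$decision == 2L)
  cells <- c(hits, n_s2 - hits, fas, n_s1 - fas)
  if (any(cells == 0L)) {
    hr <- (hits + 0.5) / (n_s2 + 1)
    far <- (fas + 0.5) / (n_s1 + 1)
  } else {
    hr <- hits / n_s2
    far <- fas / n_s1
  }
  list(d_prime = stats::qnorm(hr) - stats::qnorm(far),
       criterion = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
       hr = hr, far = far)
}

#' Type-1 sensitivity with an empirically placed criterion
#'
#' d' computed by splitting a continuous decision variable at its empirical
#' median rather than at the model's nominal response criterion. Lesions
#' and other perturbations can displace the operating point of the decision
#' output so far that every trial receives the same response, which makes
#' criterion-bound d' degenerate even though the decision variable still
#' carries stimulus information; the median split measures the preserved
#' sensitivity independent of that induced response bias (the same logic
#' by which confidence criteria are re-derived from the empirical
#' confidence distribution).
#'
#' @param record a two-choice `behavioral_record`.
#' @param dv per-trial decision variable (defaults to the `p_s2` column;
#'   higher values favor responding s2).
#' @return as [dprime()].
#' @export
dprime_empirical <- function(record, dv = record$p_s2) {
  r <- record[!record$opt_out %in% TRUE, , drop = FALSE]
  dv <- dv[!record$opt_out %in% TRUE]
  r$decision <- ifelse(dv > stats::median(dv), 2L, 1L)
  dprime(r)
}

#' Bin confidence by empirical quantiles
#'
#' Confidence criteria are placed at the empirical quantiles of the observed
#' confidence distribution (so every record defines its own criteria, which
#' is what makes post-lesion analyses meaningful).
#'
#' @param confidence numeric vector.
#' @param n_bins number of bins (default 4).
#' @return integer vector of bin indices 1..n_bins (1 = lowest confidence),
#'   or an error if the confidence distribution is degenerate.
#' @export
bin_confidence <- function(confidence, n_bins = 4) {
  br <- stats::quantile(confidence, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7)
  br <- unique(br)
  if (length(br) < 3L)
    stop("degenerate confidence distribution: cannot form confidence bins")
  findInterval(confidence, br[-c(1L, length(br))]) + 1L
}

# counts[stimulus, response, rating]
type2_counts <- function(label, decision, rating, n_bins) {
  counts <- array(0L, dim = c(2L, 2L, n_bins))
  for (s in 1:2) for (r in 1:2) {
    i <- label == s & decision == r
    counts[s, r, ] <- tabulate(rating[i], nbins = n_bins)
  }
  counts
}

# conditional type-2 probabilities P(rating = k | stimulus, response) under
# the meta-SDT model. Means at -meta_d/2 (s1) and +meta_d/2 (s2); meta
# criterion at cprime * meta_d; t2 criteria parameterized by positive gaps.
type2_probs <- function(meta_d, gaps_r1, gaps_r2, cprime, n_bins) {
  mc <- cprime * meta_d
  means <- c(-meta_d / 2, meta_d / 2)
  # r1 side: boundaries descending from mc; rating k in (a_k, a_{k-1})
  a <- c(mc, mc - cumsum(gaps_r1), -Inf)
  b <- c(mc, mc + cumsum(gaps_r2), Inf)
  P <- array(0, dim = c(2L, 2L, n_bins))
  for (s in 1:2) {
    m <- means[s]
    denom1 <- stats::pnorm(mc - m)
    denom2 <- 1 - denom1
    for (k in seq_len(n_bins)) {
      P[s, 1L, k] <- (stats::pnorm(a[k] - m) - stats::pnorm(a[k + 1L] - m)) /
        max(denom1, 1e-12)
      P[s, 2L, k] <- (stats::pnorm(b[k + 1L] - m) - stats::pnorm(b[k] - m)) /
        max(denom2, 1e-12)
    }
  }
  P
}

fit_meta_d_counts <- function(counts, cprime, d_init, responses = 1:2) {
  n_bins <- dim(counts)[3]
  nll <- function(par) {
    meta_d <- par[1]
    g1 <- exp(par[2:n_bins])
    g2 <- exp(par[(n_bins + 1):(2 * n_bins - 1)])
    P <- type2_probs(meta_d, g1, g2, cprime, n_bins)
    -sum(counts[, responses, , drop = FALSE] *
           log(pmax(P[, responses, , drop = FALSE], 1e-12)))
  }
  init <- c(d_init, rep(log(0.5), 2 * (n_bins - 1)))
  fit <- stats::nlminb(init, nll, lower = c(-10, rep(-8, 2 * (n_bins - 1))),
                       upper = c(10, rep(3, 2 * (n_bins - 1))))
  list(meta_d = fit$par[1],
       t2c_r1 = cprime * fit$par[1] - cumsum(exp(fit$par[2:n_bins])),
       t2c_r2 = cprime * fit$par[1] +
         cumsum(exp(fit$par[(n_bins + 1):(2 * n_bins - 1)])),
       logLik = -fit$objective, convergence = fit$convergence)
}

#' Fit meta-d' by maximum likelihood
#'
#' Confidence is binned by empirical quantiles ([bin_confidence()]); type-2
#' response counts are fit under the equal-variance meta-SDT model with the
#' type-2 criterion constrained to the type-1 relative criterion. If any
#' stimulus x response x rating cell is empty, 0.5 is added to every cell
#' (log-linear correction). Response-specific fits maximize the likelihood
#' of the type-2 data for one response at a time.
#'
#' @param record a two-choice `behavioral_record` with graded confidence
#'   (opt-out trials are dropped).
#' @param n_conf_bins number of confidence bins (default 4).
#' @param response_specific also fit meta-d' separately for s1 and s2
#'   responses.
#' @return an `sdt_summary` list: d_prime, criterion, meta_d_prime,
#'   (optionally meta_d_s1, meta_d_s2), type-2 criteria, and the count table.
#' @export
fit_meta_dprime <- function(record, n_conf_bins = 4,
                            response_specific = FALSE) {
  r <- record[!record$opt_out %in% TRUE, , drop = FALSE]
  t1 <- dprime(r)
  rating <- bin_confidence(r$confidence, n_conf_bins)
  counts <- type2_counts(r$label, r$decision, rating, n_conf_bins)
  if (any(counts == 0L)) counts <- counts + 0.5
  cprime <- t1$criterion / t1$d_prime
  if (!is.finite(cprime)) cprime <- 0
  fit <- fit_meta_d_counts(counts, cprime, d_init = t1$d_prime)
  out <- list(d_prime = t1$d_prime, criterion = t1$criterion,
              meta_d_prime = fit$meta_d, t2c_r1 = fit$t2c_r1,
              t2c_r2 = fit$t2c_r2, counts = counts,
              n_conf_bins = n_conf_bins, logLik = fit$logLik)
  if (response_specific) {
    out$meta_d_s1 <- fit_meta_d_counts(counts, cprime, t1$d_prime,
                                       responses = 1L)$meta_d
    out$meta_d_s2 <- fit_meta_d_counts(counts, cprime, t1$d_prime,
                                       responses = 2L)$meta_d
  }
  structure(out, class = "sdt_summary")
}

#' Add type-2 noise to confidence ratings
#'
#' Models the additional accumulation of noise between the decision and the
#' confidence report: confidence is mapped through the logit, Gaussian noise
#' of variance xi is added, and the result is mapped back through the
#' sigmoid. Confidence is clipped to \[1e-6, 1 - 1e-6\] before the logit.
#'
#' @param record a `behavioral_record`.
#' @param xi noise variance (>= 0).
#' @param seed integer seed.
#' @return the record with perturbed confidence.
#' @export
add_type2_noise <- function(record, xi, seed = NULL) {
  if (xi < 0) stop("xi must be >= 0")
  if (xi == 0) return(record)
  if (!is.null(seed)) set.seed(seed)
  eps <- 1e-6
  p <- pmin(pmax(record$confidence, eps), 1 - eps)
  lg <- log(p / (1 - p)) + stats::rnorm(length(p), 0, sqrt(xi))
  record$confidence <- 1 / (1 + exp(-lg))
  record
}

#' Nonparametric ROC curve and choice probability
#'
#' Sweeps all thresholds of a scalar independent variable against a binary
#' dependent variable; choice probability is the area under the ROC curve
#' (trapezoidal rule, equivalent to the rank-sum statistic).
#'
#' @param iv numeric vector (higher values predict dv = 1/TRUE).
#' @param dv binary vector (logical or 0/1).
#' @return list(roc = data.frame(fpr, tpr), choice_probability).
#' @export
roc_choice_probability <- function(iv, dv) {
  dv <- as.logical(dv)
  if (length(unique(dv)) < 2L) stop("dv must contain both classes")
  ord <- order(iv, decreasing = TRUE)
  dvo <- dv[ord]; ivo <- iv[ord]
  tp <- cumsum(dvo); fp <- cumsum(!dvo)
  keep <- c(ivo[-1] != ivo[-length(ivo)], TRUE)  # collapse tied thresholds
  tpr <- c(0, tp[keep] / sum(dv))
  fpr <- c(0, fp[keep] / sum(!dv))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), choice_probability = auc)
}
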