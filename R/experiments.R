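#' Behavioral experiments: calibration, PE bias, dissociation, evidence grid
#'
#' Runners for the psychophysics battery. Each runner takes a list of
#' trained evaluators (confidence networks or [io_observer()]s), generates
#' the test stimuli for its conditions, evaluates trial-by-trial behavior
#' and returns tidy per-evaluator condition summaries plus paired tests.
#'
#' @name experiments
NULL

#' Summarize a behavioral record
#'
#' @param rec a `behavioral_record`.
#' @return list(accuracy, confidence, opt_out_rate, n). Accuracy excludes
#'   opt-out trials from the denominator.
#' @export
summarize_record <- function(rec) {
  list(accuracy = mean(rec$correct[!rec$opt_out]),
       confidence = mean(rec$confidence),
       opt_out_rate = mean(rec$opt_out), n = nrow(rec))
}

# draw n trials from a labelled raw-image pool and process at fixed (mu, sigma)
condition_batch <- function(raw, labels, mu, sigma, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ix <- sample.int(length(labels), n, replace = TRUE)
  make_stimulus_batch(raw[, , ix, drop = FALSE], labels[ix], mu = mu,
                      sigma = sigma)
}

#' Build superimposed two-class stimuli
#'
#' Each trial superimposes one s1 and one s2 exemplar, contrast-scaled
#' separately, by pixel-wise maximum; noise is added once, afterwards. The
#' trial label is the class with the higher contrast (ties are labelled at
#' random).
#'
#' @param raw_s1,raw_s2 arrays of raw exemplars per class.
#' @param mu_s1,mu_s2 per-trial (recycled) contrasts.
#' @param sigma noise level.
#' @param n number of trials.
#' @param seed integer seed.
#' @return a `stimulus_batch` with extra meta columns mu_s1, mu_s2.
#' @export
superimposed_batch <- function(raw_s1, raw_s2, mu_s1, mu_s2, sigma, n,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu_s1 <- rep(mu_s1, length.out = n)
  mu_s2 <- rep(mu_s2, length.out = n)
  i1 <- sample.int(dim(raw_s1)[3], n, replace = TRUE)
  i2 <- sample.int(dim(raw_s2)[3], n, replace = TRUE)
  px <- array(0, dim = c(IMG_SIZE, IMG_SIZE, n))
  for (i in seq_len(n)) {
    a <- 2 * mu_s1[i] * raw_s1[, , i1[i]] - 1
    b <- 2 * mu_s2[i] * raw_s2[, , i2[i]] - 1
    px[, , i] <- superimpose(a, b)
  }
  px <- px + stats::rnorm(length(px), 0, sigma)
  px <- pmin(pmax(px, -1), 1)
  label <- ifelse(mu_s1 > mu_s2, 1L, ifelse(mu_s2 > mu_s1, 2L,
                                            sample(1:2, n, replace = TRUE)))
  meta <- data.frame(trial = seq_len(n), label = label,
                     mu = pmax(mu_s1, mu_s2), sigma = sigma,
                     mu_s1 = mu_s1, mu_s2 = mu_s2)
  structure(list(pixels = px, meta = meta), class = "stimulus_batch")
}

#' Calibrate contrast to a target performance level
#'
#' Sweeps a contrast grid with a user-supplied evaluator and locates the
#' contrast achieving the target by linear interpolation between the
#' bracketing grid points.
#'
#' @param eval_fn function(mu) returning the performance measure (accuracy
#'   or d') at contrast mu.
#' @param target target performance level.
#' @param mu_grid contrast grid to sweep.
#' @return a `calibration_result`: list(contrast, achieved, target, grid,
#'   values). If the target is at or below the measure everywhere, the
#'   minimal grid contrast is returned with a warning; an unreachable target
#'   above the sweep range is an error.
#' @export
calibrate_contrast <- function(eval_fn, target, mu_grid) {
  vals <- vapply(mu_grid, eval_fn, numeric(1))
  if (target > max(vals))
    stop("target performance ", target, " not reachable on the grid (max ",
         round(max(vals), 3), ")")
  if (target <= min(vals)) {
    warning("target at or below the whole sweep; returning minimal contrast")
    mu <- mu_grid[which.min(mu_grid)]
    return(structure(list(contrast = mu, achieved = vals[which.min(mu_grid)],
                          target = target, grid = mu_grid, values = vals),
                     class = "calibration_result"))
  }
  cross <- which(diff(sign(vals - target)) != 0)
  if (length(cross) == 0L) {
    i <- which.min(abs(vals - target))
    mu <- mu_grid[i]
  } else {
    i <- cross[1]
    f <- (target - vals[i]) / (vals[i + 1] - vals[i])
    mu <- mu_grid[i] + f * (mu_grid[i + 1] - mu_grid[i])
  }
  structure(list(contrast = mu,
                 achieved = stats::approx(mu_grid, vals, xout = mu)$y,
                 target = target, grid = mu_grid, values = vals),
            class = "calibration_result")
}

# paired comparison machinery shared by both PE-bias runners. The default
# balance tolerance is 1 percentage point plus twice the binomial sampling
# standard error of the accuracy difference at the trial count used, so the
# gate scales sensibly from desk-size runs up to full test sets.
pe_compare <- function(per_net, accuracy_tol = NULL, n_trials = NULL) {
  low <- per_net[per_net$condition == "low_pe", ]
  high <- per_net[per_net$condition == "high_pe", ]
  stopifnot(nrow(low) == nrow(high))
  d_acc <- high$accuracy - low$accuracy
  d_conf <- high$confidence - low$confidence
  n <- nrow(low)
  if (is.null(accuracy_tol)) {
    abar <- mean(c(low$accuracy, high$accuracy))
    n_eff <- if (is.null(n_trials)) Inf else {
      oo <- if ("opt_out_rate" %in% names(per_net))
        mean(per_net$opt_out_rate) else 0
      max(n_trials * (1 - oo), 2)   # accuracy only counts decision trials
    }
    se_binom <- if (is.finite(n_eff))
      sqrt(2 * abar * (1 - abar) / (n_eff * n)) else 0
    accuracy_tol <- 0.01 + 2 * se_binom
  }
  balanced <- abs(mean(d_acc)) <= accuracy_tol
  tt <- function(x, y) {
    if (length(x) < 2) return(list(p.value = NA_real_, estimate = mean(y - x)))
    stats::t.test(y, x, paired = TRUE)
  }
  res <- list(summary = per_net, balanced = balanced,
              accuracy_tol = accuracy_tol,
              accuracy_diff = mean(d_acc), confidence_diff = mean(d_conf),
              accuracy_test = tt(low$accuracy, high$accuracy),
              confidence_test = tt(low$confidence, high$confidence))
  if ("opt_out_rate" %in% names(per_net) &&
      any(per_net$opt_out_rate > 0, na.rm = TRUE)) {
    res$opt_out_diff <- mean(high$opt_out_rate - low$opt_out_rate)
    res$opt_out_test <- tt(low$opt_out_rate, high$opt_out_rate)
  }
  if (!balanced)
    warning("PE-bias accuracy balance gate failed: |diff| = ",
            round(abs(mean(d_acc)), 4), " > tol ", round(accuracy_tol, 4))
  res
}

#' PE bias, version 1 (contrast/noise manipulation)
#'
#' Evaluates each network in a low-PE (low contrast, low noise) and a
#' high-PE (high contrast, high noise) condition, pre-calibrated to matched
#' accuracy, and compares confidence (or opt-out rate for the RL task)
#' across conditions. Accuracy balance is asserted before any confidence
#' comparison is reported.
#'
#' @param evaluators list of trained evaluators.
#' @param low_pe,high_pe c(mu, sigma) for the two conditions.
#' @param stimuli either "gabor" or list(raw =, labels =) image pool.
#' @param n_trials trials per condition per evaluator.
#' @param seed integer seed.
#' @param accuracy_tol balance tolerance (default: max of 1 percentage point
#'   and 2 cross-net standard errors of the paired difference).
#' @param measure_fn optional function(record) returning the confidence
#'   measure (defaults to mean confidence; used to test alternative
#'   dependent variables such as |PC1| or the rectified decision output).
#' @return a `pe_bias_result` list (per-net summary, paired tests, balance
#'   gate).
#' @export
pe_bias_v1 <- function(evaluators, low_pe, high_pe, stimuli = "gabor",
                       n_trials = 1000, seed = 1, accuracy_tol = NULL,
                       measure_fn = NULL) {
  conds <- list(low_pe = low_pe, high_pe = high_pe)
  rows <- list()
  for (i in seq_along(evaluators)) {
    for (cn in names(conds)) {
      mu <- conds[[cn]][1]; sig <- conds[[cn]][2]
      batch <- if (identical(stimuli, "gabor")) {
        gabor_batch(n_trials, mu = mu, sigma = sig,
                    seed = seed + 1000L * i +
                      (round(1e4 * mu) + 31L * round(1e4 * sig)) %% 99991L)
      } else {
        condition_batch(stimuli$raw, stimuli$labels, mu, sig, n_trials,
                        seed = seed + 1000L * i +
                      (round(1e4 * mu) + 31L * round(1e4 * sig)) %% 99991L)
      }
      rec <- evaluate_trials(evaluators[[i]], batch,
                             store_activations = !is.null(measure_fn))
      s <- summarize_record(rec)
      conf <- if (is.null(measure_fn)) s$confidence else measure_fn(rec)
      rows[[length(rows) + 1L]] <-
        data.frame(net = i, condition = cn, mu = mu, sigma = sig,
                   accuracy = s$accuracy, confidence = conf,
                   opt_out_rate = s$opt_out_rate)
    }
  }
  per_net <- do.call(rbind, rows)
  structure(pe_compare(per_net, accuracy_tol, n_trials = n_trials),
            class = "pe_bias_result")
}

#' PE bias, version 2 (superimposed stimuli)
#'
#' Both classes are superimposed in every image; the task is to report which
#' class has the higher contrast. The low-PE condition pairs a target
#' contrast of 0.5 with a calibrated lower nontarget contrast; the high-PE
#' condition pairs a target contrast of 1.0 with a higher nontarget
#' contrast, both pre-calibrated to matched accuracy.
#'
#' @param evaluators list of trained two-choice evaluators.
#' @param raw_s1,raw_s2 raw exemplar pools per class.
#' @param mu_target_low,mu_target_high target contrasts (defaults 0.5, 1.0).
#' @param mu_nontarget_low,mu_nontarget_high calibrated nontarget contrasts
#'   (must be below their targets).
#' @param sigma noise level.
#' @param n_trials,seed,accuracy_tol as in [pe_bias_v1()].
#' @return a `pe_bias_result`.
#' @export
pe_bias_v2 <- function(evaluators, raw_s1, raw_s2, mu_target_low = 0.5,
                       mu_target_high = 1.0, mu_nontarget_low,
                       mu_nontarget_high, sigma = 1.5, n_trials = 1000,
                       seed = 1, accuracy_tol = NULL) {
  if (mu_nontarget_low >= mu_target_low ||
      mu_nontarget_high >= mu_target_high)
    stop("nontarget contrast must be below target contrast")
  conds <- list(low_pe = c(mu_target_low, mu_nontarget_low),
                high_pe = c(mu_target_high, mu_nontarget_high))
  rows <- list()
  for (i in seq_along(evaluators)) {
    for (cn in names(conds)) {
      tgt <- conds[[cn]][1]; ntg <- conds[[cn]][2]
      set.seed(seed + 1000L * i +
                 (round(1e4 * tgt) + 31L * round(1e4 * ntg)) %% 99991L)
      # target class random per trial
      tgt_is_s1 <- stats::runif(n_trials) < 0.5
      batch <- superimposed_batch(raw_s1, raw_s2,
                                  mu_s1 = ifelse(tgt_is_s1, tgt, ntg),
                                  mu_s2 = ifelse(tgt_is_s1, ntg, tgt),
                                  sigma = sigma, n = n_trials)
      rec <- evaluate_trials(evaluators[[i]], batch)
      s <- summarize_record(rec)
      rows[[length(rows) + 1L]] <-
        data.frame(net = i, condition = cn, mu_target = tgt,
                   mu_nontarget = ntg, accuracy = s$accuracy,
                   confidence = s$confidence, opt_out_rate = s$opt_out_rate)
    }
  }
  per_net <- do.call(rbind, rows)
  structure(pe_compare(per_net, accuracy_tol, n_trials = n_trials),
            class = "pe_bias_result")
}

#' Type-1 / type-2 dissociation battery
#'
#' Five conditions: s1 is always presented at the intermediate contrast
#' `mu_s1`, while the s2 contrast sweeps `mu_s2_levels` (condition 3 equals
#' `mu_s1`). Confidence receives type-2 noise of variance `xi` before
#' meta-d' is fitted (response-specifically).
#'
#' @param evaluators list of trained two-choice evaluators.
#' @param raw,labels labelled raw-image pool.
#' @param mu_s2_levels five s2 contrasts (increasing).
#' @param mu_s1 fixed s1 contrast (defaults to the middle s2 level).
#' @param sigma noise level (default 2, the digit-task dissociation value).
#' @param xi type-2 noise variance (default 1.2, the fitted reference).
#' @param n_trials trials per condition per evaluator.
#' @param n_conf_bins confidence bins for meta-d'.
#' @param seed integer seed.
#' @return list(per_condition = tidy data.frame, summary = condition means,
#'   s1_rank_correlation = Spearman correlation of response-specific
#'   meta-d' for s1 responses with d' across conditions).
#' @export
type1_type2_dissociation <- function(evaluators, raw, labels,
                                     mu_s2_levels = c(0.05, 0.16, 0.36,
                                                      0.58, 0.81),
                                     mu_s1 = mu_s2_levels[3], sigma = 2,
                                     xi = 1.2, n_trials = 2000,
                                     n_conf_bins = 4, seed = 1) {
  stopifnot(length(mu_s2_levels) >= 2)
  rows <- list()
  for (i in seq_along(evaluators)) {
    for (ci in seq_along(mu_s2_levels)) {
      set.seed(seed + 137L * i + ci)
      ix <- sample.int(length(labels), n_trials, replace = TRUE)
      mu_trial <- ifelse(labels[ix] == 1L, mu_s1, mu_s2_levels[ci])
      batch <- make_stimulus_batch(raw[, , ix, drop = FALSE], labels[ix],
                                   mu = mu_trial, sigma = sigma)
      rec <- evaluate_trials(evaluators[[i]], batch)
      rec <- add_type2_noise(rec, xi)
      fit <- tryCatch(fit_meta_dprime(rec, n_conf_bins,
                                      response_specific = TRUE),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        net = i, condition = ci, mu_s1 = mu_s1, mu_s2 = mu_s2_levels[ci],
        accuracy = mean(rec$correct),
        d_prime = if (is.null(fit)) NA else fit$d_prime,
        meta_d = if (is.null(fit)) NA else fit$meta_d_prime,
        meta_d_s1 = if (is.null(fit)) NA else fit$meta_d_s1,
        meta_d_s2 = if (is.null(fit)) NA else fit$meta_d_s2)
    }
  }
  per <- do.call(rbind, rows)
  agg <- stats::aggregate(per[, c("accuracy", "d_prime", "meta_d",
                                  "meta_d_s1", "meta_d_s2")],
                          by = list(condition = per$condition), mean,
                          na.rm = TRUE)
  rc <- stats::cor(agg$d_prime, agg$meta_d_s1, method = "spearman")
  list(per_condition = per, summary = agg, s1_rank_correlation = rc, xi = xi)
}

#' Fit the type-2 noise variance to a target meta-d' pattern
#'
#' Grid search: for each candidate xi, type-2 noise is injected into the
#' stored records, meta-d' refit per condition, and the xi minimizing the
#' squared error to the target pattern is returned.
#'
#' @param records list of `behavioral_record`s (one per condition).
#' @param target_meta_d numeric vector of target meta-d' values.
#' @param xi_grid candidate variances (default 20 values from 0.1 to 2).
#' @param n_conf_bins,seed as elsewhere.
#' @export
fit_type2_noise <- function(records, target_meta_d,
                            xi_grid = seq(0.1, 2, length.out = 20),
                            n_conf_bins = 4, seed = 1) {
  stopifnot(length(records) == length(target_meta_d))
  mse <- vapply(xi_grid, function(xi) {
    md <- vapply(seq_along(records), function(i) {
      rec <- add_type2_noise(records[[i]], xi, seed = seed + i)
      tryCatch(fit_meta_dprime(rec, n_conf_bins)$meta_d_prime,
               error = function(e) NA_real_)
    }, numeric(1))
    mean((md - target_meta_d)^2, na.rm = TRUE)
  }, numeric(1))
  list(xi = xi_grid[which.min(mse)], mse = mse, xi_grid = xi_grid)
}

#' Accuracy and confidence over the sensory-evidence grid
#'
#' Evaluates superimposed stimuli over all combinations of s1 and s2
#' contrasts, recording per-cell mean accuracy, confidence and the mean
#' response-congruent evidence (the contrast of the chosen class, the RCE
#' predictor).
#'
#' @param evaluator trained two-choice evaluator.
#' @param raw_s1,raw_s2 raw exemplar pools.
#' @param mu_values contrast grid (the full design uses 100 values in
#'   \[0.1, 1\]; scale down for desk-size runs).
#' @param sigma noise level (default 1.5).
#' @param n_per_cell trials per grid cell.
#' @param seed integer seed.
#' @return a `grid_result`: data.frame(mu_s1, mu_s2, accuracy, confidence,
#'   rce).
#' @export
evidence_grid <- function(evaluator, raw_s1, raw_s2,
                          mu_values = seq(0.1, 1, length.out = 100),
                          sigma = 1.5, n_per_cell = 8, seed = 1) {
  cells <- expand.grid(mu_s1 = mu_values, mu_s2 = mu_values)
  set.seed(seed)
  n <- nrow(cells) * n_per_cell
  mu_s1 <- rep(cells$mu_s1, each = n_per_cell)
  mu_s2 <- rep(cells$mu_s2, each = n_per_cell)
  batch <- superimposed_batch(raw_s1, raw_s2, mu_s1, mu_s2, sigma, n)
  rec <- evaluate_trials(evaluator, batch)
  rce <- ifelse(rec$decision == 1L, mu_s1, mu_s2)
  cell_id <- rep(seq_len(nrow(cells)), each = n_per_cell)
  cells$accuracy <- as.vector(tapply(as.numeric(rec$correct), cell_id, mean))
  cells$confidence <- as.vector(tapply(rec$confidence, cell_id, mean))
  cells$rce <- as.vector(tapply(rce, cell_id, mean))
  structure(cells, class = c("grid_result", "data.frame"))
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) /
  sum((obs - mean(obs))^2)

#' Compare confidence strategies on the evidence grid
#'
#' Ordinary least squares on the grid cells: confidence regressed on the
#' balance-of-evidence predictor (mu_s2 - mu_s1; a logit transform of
#' confidence is tried and kept when it improves the fit, with R-squared
#' always computed back on the raw confidence scale), the
#' response-congruent-evidence predictor (contrast of the chosen class) and,
#' optionally, the latent ideal observer's per-cell confidence. The noise
#' ceiling regresses each replicate's cells on the mean pattern of the other
#' replicates.
#'
#' @param grids list of `grid_result`s (one per network replicate).
#' @param io_confidence optional per-cell ideal-observer confidence (same
#'   cell order as the grids).
#' @return list(per_net = data.frame of R-squared per predictor,
#'   means = column means, noise_ceiling_available).
#' @export
confidence_regressions <- function(grids, io_confidence = NULL) {
  stopifnot(length(grids) >= 1)
  eps <- 1e-6
  per <- lapply(seq_along(grids), function(i) {
    g <- grids[[i]]
    be <- g$mu_s2 - g$mu_s1
    conf <- g$confidence
    # BE: raw DV vs logit DV, keep the better (R^2 on the raw scale)
    f_raw <- stats::lm(conf ~ be)
    r2_raw <- r_squared(conf, stats::fitted(f_raw))
    lg <- log(pmin(pmax(conf, eps), 1 - eps) /
                (1 - pmin(pmax(conf, eps), 1 - eps)))
    f_lg <- stats::lm(lg ~ be)
    r2_lg <- r_squared(conf, 1 / (1 + exp(-stats::fitted(f_lg))))
    r2_be <- max(r2_raw, r2_lg)
    r2_rce <- r_squared(conf, stats::fitted(stats::lm(conf ~ g$rce)))
    r2_io <- if (is.null(io_confidence)) NA_real_ else
      r_squared(conf, stats::fitted(stats::lm(conf ~ io_confidence)))
    r2_ceil <- if (length(grids) >= 2) {
      others <- rowMeans(sapply(grids[-i], function(h) h$confidence))
      r_squared(conf, stats::fitted(stats::lm(conf ~ others)))
    } else NA_real_
    data.frame(net = i, r2_be = r2_be, r2_rce = r2_rce, r2_io = r2_io,
               r2_ceiling = r2_ceil)
  })
  per <- do.call(rbind, per)
  if (length(grids) < 2)
    warning("fewer than 2 replicates: noise ceiling unavailable")
  list(per_net = per,
       means = colMeans(per[, -1, drop = FALSE], na.rm = TRUE),
       noise_ceiling_available = length(grids) >= 2)
}
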