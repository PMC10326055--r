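#' Population geometry and single-unit analyses
#'
#' PCA of penultimate-layer activations, regressions linking the top
#' components to stimulus class, decisions, correctness and confidence, and
#' the single-unit opt-out analysis with min-subtracted, dispersion-scaled
#' normalized activity.
#'
#' @name representations
NULL

#' PCA of an activation matrix
#'
#' Centered principal component analysis of a trial x neuron matrix. Sign
#' convention (applied when a `behavioral_record` is supplied): PC1 is
#' oriented so s2 trials have positive mean, PC2 so correct trials have
#' positive mean.
#'
#' @param activations trial x neuron matrix.
#' @param record optional aligned `behavioral_record` for the sign
#'   convention.
#' @return a `pca_geometry`: list(scores, loadings, var_frac).
#' @export
pca_geometry <- function(activations, record = NULL) {
  activations <- as.matrix(activations)
  if (nrow(activations) < 2 || ncol(activations) < 2)
    stop("need at least 2 trials and 2 neurons")
  if (all(abs(activations - mean(activations)) < 1e-14))
    stop("activation matrix has rank 0 after centering")
  pc <- stats::prcomp(activations, center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  if (!is.null(record)) {
    if (mean(scores[record$label == 2L, 1]) < 0) {
      scores[, 1] <- -scores[, 1]; loadings[, 1] <- -loadings[, 1]
    }
    ok <- which(record$correct %in% TRUE)
    if (length(ok) > 0 && ncol(scores) >= 2 && mean(scores[ok, 2]) < 0) {
      scores[, 2] <- -scores[, 2]; loadings[, 2] <- -loadings[, 2]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings, var_frac = vf),
            class = "pca_geometry")
}

logit_clip <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Regressions linking the top PCs to behavior
#'
#' Logistic fits (reported as prediction accuracy at a 0.5 threshold):
#' PC1 -> stimulus class, PC2 -> correctness. Linear fits (reported as
#' R-squared): |PC1| -> PC2, PC1 -> logit of the decision output,
#' PC2 -> logit of the confidence output.
#'
#' @param geom a [pca_geometry()].
#' @param record aligned `behavioral_record`; the decision-output fit needs
#'   a `p_s2` (or `p_right`) column.
#' @return list of named accuracies and R-squared values.
#' @export
geometry_regressions <- function(geom, record) {
  stopifnot(inherits(geom, "pca_geometry"))
  pc1 <- geom$scores[, 1]; pc2 <- geom$scores[, 2]
  if (length(unique(record$label)) < 2L)
    stop("degenerate record: single stimulus class")
  log_acc <- function(x, y) {
    # separable data make glm complain about fitted 0/1 probabilities; the
    # prediction accuracy we report is well-defined regardless
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    mean((stats::fitted(fit) > 0.5) == y)
  }
  lin_r2 <- function(x, y) r_squared(y, stats::fitted(stats::lm(y ~ x)))
  dec_out <- if ("p_s2" %in% names(record)) record$p_s2 else record$p_right
  res <- list(acc_pc1_class = log_acc(pc1, record$label == 2L),
              acc_pc2_correct = log_acc(pc2[!record$opt_out],
                                        record$correct[!record$opt_out]),
              r2_abs_pc1_pc2 = lin_r2(abs(pc1), pc2))
  res$r2_pc1_decision <- if (is.null(dec_out)) NA_real_ else
    lin_r2(pc1, logit_clip(dec_out))
  res$r2_pc2_confidence <- lin_r2(pc2, logit_clip(record$confidence))
  res
}

#' Rectified decision output
#'
#' Maps the continuous two-choice decision output p(s2) to the probability
#' assigned to the decision actually made, max(p, 1 - p); an alternative
#' confidence-like dependent variable for the PE-bias analyses.
#'
#' @param record a two-choice `behavioral_record` with a `p_s2` column.
#' @export
rectified_decision_output <- function(record) pmax(record$p_s2, 1 - record$p_s2)

#' Normalized single-unit activity
#'
#' Subtracts each neuron's across-trial minimum and divides by a pooled
#' dispersion: the across-trial variance of each neuron, averaged over all
#' neurons. Pooling per-neuron (centered) variances keeps the measure
#' invariant when a constant is added to any one neuron's activations,
#' which a flattened all-activations variance would not be. The default
#' divides by the pooled standard deviation (dimensionally consistent);
#' `mode = "variance"` divides by the pooled variance itself (the literal
#' reading of the source formulation).
#'
#' @param activations trial x neuron matrix.
#' @param mode "sd" (default) or "variance".
#' @return matrix of normalized activities (each neuron's minimum maps to 0).
#' @export
normalized_activity <- function(activations, mode = c("sd", "variance")) {
  mode <- match.arg(mode)
  activations <- as.matrix(activations)
  if (nrow(activations) < 2) stop("need at least 2 trials")
  ctr <- sweep(activations, 2L, apply(activations, 2L, min), "-")
  disp <- mean(apply(activations, 2L, stats::var))
  if (disp < 1e-24) stop("zero pooled dispersion: constant activations")
  ctr / if (mode == "sd") sqrt(disp) else disp
}

#' Single-unit decision/confidence classification and opt-out analysis
#'
#' For each penultimate-layer neuron, linear fits predict the logit of the
#' actor's s2-choice output and of its opt-out output, giving R2_decision
#' and R2_opt-out; the sign of Delta R2 = R2_decision - R2_opt-out
#' classifies each neuron as a decision or a confidence neuron. Decision
#' neurons get a preferred class T_in from the decision-fit slope, and their
#' mean normalized activity is compared across trials where the preferred
#' class (T_in), the opposite class (T_opp) or the sure-target/opt-out
#' (T_S) was chosen, with paired t-tests across decision neurons.
#'
#' @param activations trial x neuron matrix (penultimate layer).
#' @param record aligned RL-task `behavioral_record` with columns `p_right`
#'   (p of choosing s2), `p_optout`, `decision`, `opt_out`.
#' @param mode normalization mode, see [normalized_activity()].
#' @return a `unit_stats` list: per-neuron table (r2_decision, r2_opt_out,
#'   delta_r2, class, t_in, mean normalized activity per condition) and
#'   paired tests t_in vs t_s and t_s vs t_opp.
#' @export
single_unit_analysis <- function(activations, record, mode = "sd") {
  activations <- as.matrix(activations)
  stopifnot(nrow(activations) == nrow(record))
  y_dec <- logit_clip(record$p_right)
  y_opt <- logit_clip(record$p_optout)
  M <- ncol(activations)
  r2_dec <- r2_opt <- slope <- numeric(M)
  for (j in seq_len(M)) {
    x <- activations[, j]
    if (stats::sd(x) < 1e-12) {
      r2_dec[j] <- r2_opt[j] <- 0; slope[j] <- 0
    } else {
      fd <- stats::lm(y_dec ~ x)
      r2_dec[j] <- r_squared(y_dec, stats::fitted(fd))
      slope[j] <- stats::coef(fd)[2]
      r2_opt[j] <- r_squared(y_opt, stats::fitted(stats::lm(y_opt ~ x)))
    }
  }
  delta <- r2_dec - r2_opt
  cls <- ifelse(delta > 0, "decision", "confidence")
  t_in <- ifelse(slope > 0, 2L, 1L)
  norm <- normalized_activity(activations, mode = mode)
  has_ts <- any(record$opt_out)
  if (!has_ts) warning("no opt-out trials: T_S condition unavailable")
  cond_mean <- function(idx) if (any(idx)) colMeans(norm[idx, , drop = FALSE])
    else rep(NA_real_, M)
  act_tin <- act_topp <- rep(NA_real_, M)
  chose_s1 <- !record$opt_out & record$decision == 1L
  chose_s2 <- !record$opt_out & record$decision == 2L
  m_s1 <- cond_mean(chose_s1); m_s2 <- cond_mean(chose_s2)
  act_tin <- ifelse(t_in == 2L, m_s2, m_s1)
  act_topp <- ifelse(t_in == 2L, m_s1, m_s2)
  act_ts <- cond_mean(record$opt_out)
  units <- data.frame(neuron = seq_len(M), r2_decision = r2_dec,
                      r2_opt_out = r2_opt, delta_r2 = delta, class = cls,
                      t_in = t_in, act_t_in = act_tin, act_t_s = act_ts,
                      act_t_opp = act_topp)
  dn <- units[units$class == "decision", ]
  ttests <- list(t_in_vs_t_s = NULL, t_s_vs_t_opp = NULL)
  if (has_ts && nrow(dn) >= 3) {
    ttests$t_in_vs_t_s <- stats::t.test(dn$act_t_in, dn$act_t_s,
                                        paired = TRUE)
    ttests$t_s_vs_t_opp <- stats::t.test(dn$act_t_s, dn$act_t_opp,
                                         paired = TRUE)
  }
  structure(list(units = units, tests = ttests,
                 n_decision = sum(cls == "decision"),
                 n_confidence = sum(cls == "confidence"),
                 has_ts = has_ts),
            class = "unit_stats")
}
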