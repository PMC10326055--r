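#' Configuration-driven experiment harness
#'
#' Each registered experiment trains its networks from scratch on generated
#' stimuli, runs the corresponding analysis and writes an archive directory
#' of tidy tables plus a machine-readable summary. Every run is fully
#' reproducible from its configuration and seed.
#'
#' @name harness
NULL

#' Experiment configuration
#'
#' @param experiment registered experiment name (see [list_experiments()]).
#' @param n_networks number of network replicates (full-scale runs use 100;
#'   desk-scale defaults are small).
#' @param seed global seed; per-network and per-batch streams are derived
#'   from it deterministically.
#' @param ... experiment-specific overrides (e.g. train_n, epochs,
#'   iterations, n_trials, regime, separation).
#' @export
experiment_config <- function(experiment, n_networks = 2, seed = 1, ...) {
  structure(c(list(experiment = experiment, n_networks = n_networks,
                   seed = seed), list(...)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file with at least an `experiment` field.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}

cfg_get <- function(cfg, name, default) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}

net_seed <- function(cfg, i) (cfg$seed * 131L + 7919L * i) %% 2147483647L

# ---- shared training helpers ----------------------------------------------

train_synthetic_nets <- function(cfg, regime_name = "standard",
                                 sigma_range = c(1, 2)) {
  train_n <- cfg_get(cfg, "train_n", 1200L)
  epochs <- cfg_get(cfg, "epochs", 4L)
  separation <- cfg_get(cfg, "separation", 5)
  reg <- regime(regime_name, sigma_range = sigma_range)
  nets <- vector("list", cfg$n_networks)
  pools <- vector("list", cfg$n_networks)
  for (i in seq_len(cfg$n_networks)) {
    s <- net_seed(cfg, i)
    pool <- make_synthetic_classes(train_n %/% 2L, separation, seed = s)
    batch <- make_stimulus_batch(pool$raw, pool$labels, reg = reg,
                                 seed = s + 1L)
    net <- build_confidence_network("two_choice", seed = s + 2L)
    nets[[i]] <- train_supervised(net, batch, epochs = epochs, seed = s + 3L)
    pools[[i]] <- pool
  }
  test_pool <- make_synthetic_classes(cfg_get(cfg, "test_n", 1000L) %/% 2L,
                                      separation,
                                      seed = cfg$seed * 977L + 13L)
  list(nets = nets, pools = pools, test_pool = test_pool)
}

train_rl_nets <- function(cfg) {
  iters <- cfg_get(cfg, "iterations", 2000L)
  nets <- vector("list", cfg$n_networks)
  for (i in seq_len(cfg$n_networks)) {
    s <- net_seed(cfg, i)
    net <- build_confidence_network("rl_gabor", seed = s)
    nets[[i]] <- train_rl_actor_critic(net, iterations = iters, seed = s + 1L)
  }
  nets
}

# average accuracy at contrast mu over nets (gabor or pooled stimuli)
mean_accuracy_fn <- function(nets, sigma, n_trials, seed, pool = NULL) {
  function(mu) {
    accs <- vapply(seq_along(nets), function(i) {
      batch <- if (is.null(pool))
        gabor_batch(n_trials, mu = mu, sigma = sigma,
                    seed = seed + i + round(1e4 * mu))
      else condition_batch(pool$raw, pool$labels, mu, sigma, n_trials,
                           seed = seed + i + round(1e4 * mu))
      summarize_record(evaluate_trials(nets[[i]], batch))$accuracy
    }, numeric(1))
    mean(accs)
  }
}

# ---- experiment registry ---------------------------------------------------

exp_pe_bias_v1 <- function(cfg) {
  tr <- train_synthetic_nets(cfg, cfg_get(cfg, "regime", "standard"))
  n_trials <- cfg_get(cfg, "n_trials", 800L)
  sig <- cfg_get(cfg, "sigmas", c(1, 2))
  grid <- seq(0.05, 1, length.out = cfg_get(cfg, "n_grid", 40L))
  cal <- lapply(sig, function(s)
    calibrate_contrast(mean_accuracy_fn(tr$nets, s, 400L, cfg$seed,
                                        pool = tr$test_pool),
                       target = 0.75, mu_grid = grid))
  res <- pe_bias_v1(tr$nets, low_pe = c(cal[[1]]$contrast, sig[1]),
                    high_pe = c(cal[[2]]$contrast, sig[2]),
                    stimuli = list(raw = tr$test_pool$raw,
                                   labels = tr$test_pool$labels),
                    n_trials = n_trials, seed = cfg$seed)
  list(tables = list(per_net = res$summary),
       summary = list(balanced = res$balanced,
                      accuracy_diff = res$accuracy_diff,
                      confidence_diff = res$confidence_diff,
                      confidence_p = res$confidence_test$p.value,
                      mu_low = cal[[1]]$contrast, mu_high = cal[[2]]$contrast))
}

exp_pe_bias_v1_rl <- function(cfg) {
  nets <- train_rl_nets(cfg)
  n_trials <- cfg_get(cfg, "n_trials", 1500L)
  grid <- seq(0.02, 1, length.out = cfg_get(cfg, "n_grid", 40L))
  cal <- lapply(c(0.5, 1), function(s)
    calibrate_contrast(mean_accuracy_fn(nets, s, 400L, cfg$seed),
                       target = 0.75, mu_grid = grid))
  res <- pe_bias_v1(nets, low_pe = c(cal[[1]]$contrast, 0.5),
                    high_pe = c(cal[[2]]$contrast, 1),
                    stimuli = "gabor", n_trials = n_trials, seed = cfg$seed)
  list(tables = list(per_net = res$summary),
       summary = list(balanced = res$balanced,
                      accuracy_diff = res$accuracy_diff,
                      opt_out_diff = res$opt_out_diff,
                      opt_out_p = res$opt_out_test$p.value,
                      mu_low = cal[[1]]$contrast, mu_high = cal[[2]]$contrast))
}

exp_pe_bias_v2 <- function(cfg) {
  tr <- train_synthetic_nets(cfg)
  pool <- tr$test_pool
  raw1 <- pool$raw[, , pool$labels == 1L, drop = FALSE]
  raw2 <- pool$raw[, , pool$labels == 2L, drop = FALSE]
  sigma <- cfg_get(cfg, "sigma", 1.5)
  cal_fn <- function(target_mu) function(nt) {
    accs <- vapply(seq_along(tr$nets), function(i) {
      set.seed(cfg$seed + i + round(1e4 * nt))
      tgt_is_s1 <- stats::runif(300L) < 0.5
      b <- superimposed_batch(raw1, raw2,
                              ifelse(tgt_is_s1, target_mu, nt),
                              ifelse(tgt_is_s1, nt, target_mu), sigma, 300L)
      summarize_record(evaluate_trials(tr$nets[[i]], b))$accuracy
    }, numeric(1))
    mean(accs)
  }
  grid_lo <- seq(0.48, 0.05, length.out = 20L)  # accuracy increases as nt drops
  grid_hi <- seq(0.95, 0.1, length.out = 20L)
  cal_lo <- calibrate_contrast(cal_fn(0.5), 0.75, grid_lo)
  cal_hi <- calibrate_contrast(cal_fn(1.0), 0.75, grid_hi)
  res <- pe_bias_v2(tr$nets, raw1, raw2, mu_nontarget_low = cal_lo$contrast,
                    mu_nontarget_high = cal_hi$contrast, sigma = sigma,
                    n_trials = cfg_get(cfg, "n_trials", 800L),
                    seed = cfg$seed)
  list(tables = list(per_net = res$summary),
       summary = list(balanced = res$balanced,
                      accuracy_diff = res$accuracy_diff,
                      confidence_diff = res$confidence_diff,
                      confidence_p = res$confidence_test$p.value,
                      nontarget_low = cal_lo$contrast,
                      nontarget_high = cal_hi$contrast))
}

exp_dissociation <- function(cfg) {
  tr <- train_synthetic_nets(cfg)
  res <- type1_type2_dissociation(
    tr$nets, tr$test_pool$raw, tr$test_pool$labels,
    xi = cfg_get(cfg, "xi", 1.2),
    n_trials = cfg_get(cfg, "n_trials", 2000L), seed = cfg$seed)
  list(tables = list(per_condition = res$per_condition,
                     condition_means = res$summary),
       summary = list(s1_rank_correlation = res$s1_rank_correlation,
                      xi = res$xi))
}

exp_grid <- function(cfg) {
  tr <- train_synthetic_nets(cfg)
  pool <- tr$test_pool
  raw1 <- pool$raw[, , pool$labels == 1L, drop = FALSE]
  raw2 <- pool$raw[, , pool$labels == 2L, drop = FALSE]
  mu_values <- seq(0.1, 1, length.out = cfg_get(cfg, "grid_size", 15L))
  grids <- lapply(seq_along(tr$nets), function(i)
    evidence_grid(tr$nets[[i]], raw1, raw2, mu_values,
                  n_per_cell = cfg_get(cfg, "n_per_cell", 6L),
                  seed = cfg$seed + i))
  reg <- confidence_regressions(grids)
  cells <- grids[[1]][, c("mu_s1", "mu_s2")]
  cells$accuracy <- rowMeans(sapply(grids, function(g) g$accuracy))
  cells$confidence <- rowMeans(sapply(grids, function(g) g$confidence))
  list(tables = list(cells = cells, r2 = reg$per_net),
       summary = as.list(reg$means))
}

exp_blindsight <- function(cfg) {
  tr <- train_synthetic_nets(cfg, sigma_range = c(3, 4))
  res <- run_blindsight(tr$nets, tr$test_pool$raw, tr$test_pool$labels,
                        n_trials = cfg_get(cfg, "n_trials", 800L),
                        seed = cfg$seed)
  agg <- stats::aggregate(res$per_cell[, c("d_prime", "meta_d", "confidence")],
                          by = list(arm = res$per_cell$arm), mean,
                          na.rm = TRUE)
  list(tables = list(per_cell = res$per_cell, overlap = res$overlap),
       summary = list(
         d_prime_lesion = agg$d_prime[agg$arm == "lesion"],
         meta_d_lesion = agg$meta_d[agg$arm == "lesion"],
         d_prime_control = agg$d_prime[agg$arm == "control"],
         meta_d_control = agg$meta_d[agg$arm == "control"],
         overlap_lesion = mean(res$overlap$overlap_lesion),
         overlap_control = mean(res$overlap$overlap_control)))
}

exp_tms <- function(cfg, layer) {
  tr <- train_synthetic_nets(cfg)
  mu <- if (layer == 1L) seq(0.1, 1, length.out = 5) else
    cfg_get(cfg, "mu", 0.55)
  tabs <- lapply(seq_along(tr$nets), function(i) {
    cbind(net = i,
          tms_sweep(tr$nets[[i]], tr$test_pool$raw, tr$test_pool$labels,
                    layer = layer, mu = mu,
                    n_trials = cfg_get(cfg, "n_trials", 600L),
                    seed = cfg$seed + i))
  })
  tab <- do.call(rbind, tabs)
  agg <- stats::aggregate(tab[, c("d_prime", "confidence", "meta_d")],
                          by = list(xi = tab$xi), mean, na.rm = TRUE)
  list(tables = list(sweep = tab, by_xi = agg),
       summary = list(
         d_prime_trend = stats::cor(agg$xi, agg$d_prime, method = "spearman"),
         confidence_trend = stats::cor(agg$xi, agg$confidence,
                                       method = "spearman"),
         meta_d_trend = stats::cor(agg$xi, agg$meta_d, method = "spearman")))
}

exp_single_unit <- function(cfg) {
  nets <- train_rl_nets(cfg)
  n_trials <- cfg_get(cfg, "n_trials", 3000L)
  rows <- list(); n_sig <- 0L
  for (i in seq_along(nets)) {
    batch <- gabor_batch(n_trials, seed = net_seed(cfg, i) + 5L)
    rec <- evaluate_trials(nets[[i]], batch, store_activations = TRUE)
    acts <- attr(rec, "activations")$encoder_out
    us <- single_unit_analysis(acts, rec)
    sig <- !is.null(us$tests$t_in_vs_t_s) &&
      us$tests$t_in_vs_t_s$p.value < 0.05 &&
      us$tests$t_s_vs_t_opp$p.value < 0.05 &&
      us$tests$t_in_vs_t_s$estimate > 0 && us$tests$t_s_vs_t_opp$estimate > 0
    n_sig <- n_sig + sig
    rows[[i]] <- data.frame(
      net = i, n_decision = us$n_decision, n_confidence = us$n_confidence,
      mean_t_in = mean(us$units$act_t_in[us$units$class == "decision"]),
      mean_t_s = mean(us$units$act_t_s[us$units$class == "decision"]),
      mean_t_opp = mean(us$units$act_t_opp[us$units$class == "decision"]),
      p_t_in_vs_t_s = if (is.null(us$tests$t_in_vs_t_s)) NA else
        us$tests$t_in_vs_t_s$p.value,
      p_t_s_vs_t_opp = if (is.null(us$tests$t_s_vs_t_opp)) NA else
        us$tests$t_s_vs_t_opp$p.value,
      significant_ordering = sig)
  }
  tab <- do.call(rbind, rows)
  list(tables = list(per_net = tab),
       summary = list(n_networks = length(nets), n_significant = n_sig,
                      proportion_significant = n_sig / length(nets)))
}

exp_decoding <- function(cfg) {
  tr <- train_synthetic_nets(cfg)
  pool <- tr$test_pool
  grid <- seq(0.05, 1, length.out = 30L)
  cal <- calibrate_contrast(mean_accuracy_fn(tr$nets, 2, 300L, cfg$seed,
                                             pool = pool), 0.75, grid)
  rows <- list()
  for (i in seq_along(tr$nets)) {
    trn <- condition_batch(pool$raw, pool$labels, cal$contrast, 2,
                           cfg_get(cfg, "probe_n", 800L),
                           seed = cfg$seed + 71L * i)
    for (scope in c("all_layers", "penultimate")) {
      probe <- train_probe_decoder(tr$nets[[i]], trn, scope,
                                   epochs = cfg_get(cfg, "epochs", 3L),
                                   seed = cfg$seed + i)
      tst <- condition_batch(pool$raw, pool$labels, cal$contrast, 2,
                             cfg_get(cfg, "n_trials", 800L),
                             seed = cfg$seed + 91L * i)
      rec <- evaluate_trials(tr$nets[[i]], tst, store_activations = TRUE)
      X <- if (scope == "penultimate") attr(rec, "activations")$encoder_out
        else do.call(cbind, attr(rec, "activations"))
      ev <- evidence_estimates(probe, X)
      da <- decoding_analyses(ev, rec)
      rows[[length(rows) + 1L]] <- cbind(net = i, scope = scope, da)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab$choice_probability,
                          by = list(scope = tab$scope,
                                    analysis = tab$analysis), mean,
                          na.rm = TRUE)
  names(agg)[3] <- "choice_probability"
  list(tables = list(per_net = tab, means = agg), summary = list())
}

experiment_registry <- function() {
  list(pe_bias_v1 = exp_pe_bias_v1,
       pe_bias_v1_rl = exp_pe_bias_v1_rl,
       pe_bias_v2 = exp_pe_bias_v2,
       dissociation = exp_dissociation,
       evidence_grid = exp_grid,
       blindsight = exp_blindsight,
       tms_v1 = function(cfg) exp_tms(cfg, 1L),
       tms_dlpfc = function(cfg) exp_tms(cfg, 6L),
       single_unit = exp_single_unit,
       decoding = exp_decoding)
}

#' Registered experiment names
#' @export
list_experiments <- function() names(experiment_registry())

#' Run a registered experiment end-to-end
#'
#' Trains the experiment's networks, runs its analysis, and writes an
#' archive directory containing tidy tables (CSV), a JSON summary, the
#' configuration and a state fingerprint.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir archive directory (created; default a tempdir subdir).
#' @return the archive path, invisibly; the result object (tables +
#'   summary) as attribute "result".
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  reg <- experiment_registry()
  if (!cfg$experiment %in% names(reg))
    stop("unknown experiment '", cfg$experiment, "'; registered: ",
         paste(names(reg), collapse = ", "))
  res <- reg[[cfg$experiment]](cfg)
  if (is.null(out_dir))
    out_dir <- file.path(tempfile("experiment_"), cfg$experiment)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$tables))
    utils::write.csv(res$tables[[nm]], file.path(out_dir,
                                                 paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(package = "metacognet",
                            version = as.character(
                              utils::packageVersion("metacognet")),
                            r_version = R.version.string,
                            seed = cfg$seed),
                       file.path(out_dir, "fingerprint.json"),
                       auto_unbox = TRUE)
  attr(out_dir, "result") <- res
  invisible(out_dir)
}

#' Load an experiment archive
#'
#' @param path archive directory written by [run_experiment()].
#' @export
load_experiment <- function(path) {
  if (!file.exists(file.path(path, "summary.json")))
    stop("not a valid experiment archive (missing summary.json): ", path)
  tabs <- list()
  for (f in list.files(path, pattern = "\\.csv$", full.names = TRUE))
    tabs[[sub("\\.csv$", "", basename(f))]] <- utils::read.csv(f)
  list(tables = tabs,
       summary = jsonlite::read_json(file.path(path, "summary.json"),
                                     simplifyVector = TRUE),
       config = jsonlite::read_json(file.path(path, "config.json"),
                                    simplifyVector = TRUE))
}

#' Human-readable report for an experiment archive
#'
#' Renders the stored summary (no recomputation: every number comes from a
#' table or summary cell in the archive) and flags any PE-bias comparison
#' whose accuracy-balance gate failed.
#'
#' @param path archive directory.
#' @return character vector of report lines (also printed).
#' @export
report_experiment <- function(path) {
  arc <- load_experiment(path)
  lines <- c(sprintf("Experiment: %s (n_networks = %s, seed = %s)",
                     arc$config$experiment, arc$config$n_networks,
                     arc$config$seed))
  if (length(arc$summary) == 0 && length(arc$tables) == 0) {
    lines <- c(lines, "no results")
  } else {
    for (nm in names(arc$summary)) {
      v <- arc$summary[[nm]]
      lines <- c(lines, sprintf("  %s: %s", nm,
                                paste(signif(unlist(v), 4), collapse = ", ")))
    }
    if (!is.null(arc$summary$balanced) && !isTRUE(arc$summary$balanced))
      lines <- c(lines, "  WARNING: accuracy-balance gate FAILED")
    lines <- c(lines, sprintf("  tables: %s",
                              paste(names(arc$tables), collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
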