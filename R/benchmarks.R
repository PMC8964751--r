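# Self-contained benchmark protocols on the spring simulator.  These are
# the package's study conditions for interaction recovery, pathway
# recovery and the ablation comparison; both the test suite and the
# reproduction script call them.

#' Edge-recovery benchmark on an ensemble of spring systems
#'
#' Simulates `n_systems` independent 5-node spring systems (edge
#' probability 0.5, spring constant 1, `dt` 0.01 with every 20th frame
#' kept), trains the relational-inference model with default
#' configuration on one window per system, and scores binary
#' edge/nonedge recovery per held-out system against its own
#' ground-truth graph.
#'
#' @param seed integer seed (simulation + training).
#' @param n_systems ensemble size (80/10/10 train/valid/test split).
#' @param epochs training epochs.
#' @param window_length steps per window.
#' @param subsample keep every `subsample`-th integration step.
#' @param batch_size,lr training hyperparameters.
#' @return list with `accuracy_mean`, `accuracy_median`, `accuracies`
#'   (per held-out window), `valid_mse_first`, `valid_mse_last`, `fit`.
#' @export
benchmark_edge_recovery <- function(seed, n_systems = 1250L, epochs = 20L,
                                    window_length = 30L, subsample = 20L,
                                    batch_size = 128L, lr = 2e-3) {
  cfg <- sim_config(n_nodes = 5L, edge_probability = 0.5, dt = 0.01,
                    n_steps = window_length * subsample, seed = seed)
  sims <- simulate_spring_ensemble(n_systems, cfg)
  splits <- ensemble_windows(sims, window_length = window_length,
                             seed = seed, normalize = FALSE)
  config <- nri_config()
  fit <- nri_train(splits, config, epochs = epochs, lr = lr, seed = seed,
                   batch_size = batch_size)
  accs <- recovery_accuracy_windows(fit, splits$test, splits$graphs$test,
                                    config)
  list(accuracy_mean = mean(accs), accuracy_median = stats::median(accs),
       accuracies = accs,
       valid_mse_first = fit$log$valid_mse[1L],
       valid_mse_last = fit$log$valid_mse[nrow(fit$log)],
       fit = fit)
}

#' Pathway-recovery benchmark on the driven chain
#'
#' Simulates an ensemble of 6-node driven chains (drive amplitude 0.5 at
#' random phase, initial-velocity jitter 0.1, every 40th frame kept),
#' trains the model, collapses the mean held-out posterior into an
#' interaction matrix, and extracts the least-cost undirected path from
#' the driven end to the free end.  Recovery means the path equals the
#' chain itself.
#'
#' @param seed integer seed.
#' @param n_chains ensemble size.
#' @param epochs training epochs.
#' @param n_nodes chain length.
#' @param retain_threshold edge retention threshold for the path graph.
#' @return list with `recovered` (logical), `path` (node sequence or
#'   NULL), `weights` (interaction matrix), `chain_weight`,
#'   `offchain_weight` (mean symmetrized weights on/off the chain).
#' @export
benchmark_pathway_recovery <- function(seed, n_chains = 300L,
                                       epochs = 15L, n_nodes = 6L,
                                       retain_threshold = 0.5) {
  win <- 30L
  sims <- lapply(seq_len(n_chains) - 1L, function(r) {
    cfg <- sim_config(n_nodes = n_nodes, dt = 0.01, n_steps = win * 40L,
                      seed = seed * 10000L + r)
    simulate_planted_pathway(n_nodes, drive_amplitude = 0.5, config = cfg,
                             v0_jitter = 0.1)
  })
  splits <- ensemble_windows(sims, window_length = win, seed = seed,
                             normalize = FALSE)
  config <- nri_config()
  fit <- nri_train(splits, config, epochs = epochs, lr = 2e-3,
                   seed = seed, batch_size = 128L)
  ev <- evaluate_nri(fit, splits$test, config)
  m <- edge_weight_matrix(ev$q_mean)
  g <- build_path_graph(m, retain_threshold = retain_threshold,
                        directed = FALSE)
  ps <- tryCatch(find_pathways(g, 1L, n_nodes, k = 1L),
                 error = function(e) NULL)
  path <- if (!is.null(ps) && length(ps$paths) > 0L) ps$paths[[1L]]$nodes
          else NULL
  ws <- pmax(m$w, t(m$w))
  chain_idx <- cbind(seq_len(n_nodes - 1L), seq_len(n_nodes - 1L) + 1L)
  off <- abs(row(ws) - col(ws)) > 1L
  list(recovered = identical(path, seq_len(n_nodes)),
       path = path, weights = m,
       chain_weight = mean(ws[chain_idx]),
       offchain_weight = mean(ws[off]))
}

#' Ablation benchmark: full model vs the VAE baseline without edges
#'
#' Dense spring systems (edge probability 0.8); both models trained for
#' the same number of epochs on the same windows; held-out reconstruction
#' MSE compared.
#'
#' @param seed integer seed.
#' @param n_systems ensemble size.
#' @param epochs training epochs for both models.
#' @param edge_probability coupling density (dense by default).
#' @return list with `mse_full`, `mse_baseline`.
#' @export
benchmark_ablation <- function(seed, n_systems = 600L, epochs = 8L,
                               edge_probability = 0.8) {
  win <- 30L
  cfg <- sim_config(n_nodes = 5L, edge_probability = edge_probability,
                    dt = 0.01, n_steps = win * 20L, seed = seed)
  sims <- simulate_spring_ensemble(n_systems, cfg)
  splits <- ensemble_windows(sims, window_length = win, seed = seed,
                             normalize = FALSE)
  config <- nri_config()
  fit <- nri_train(splits, config, epochs = epochs, lr = 2e-3,
                   seed = seed, batch_size = 128L)
  bfit <- train_vae_baseline(splits, config, epochs = epochs, lr = 2e-3,
                             seed = seed, batch_size = 128L)
  list(mse_full = evaluate_nri(fit, splits$test, config)$mse,
       mse_baseline = evaluate_baseline(bfit, splits$test, config))
}
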