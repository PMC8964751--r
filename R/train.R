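# Training loop, reconstruction evaluation (MSE, RMSF, VSD), the
# VAE-without-edge-latents ablation baseline and edge-recovery scoring.

# stack a list of [N, T, 6] window arrays into [B, N, T, 6]
windows_to_array <- function(windows) {
  d <- dim(windows[[1L]])
  out <- array(0, c(length(windows), d))
  for (b in seq_along(windows)) out[b, , , ] <- windows[[b]]
  out
}

log_prior_mat <- function(prior, nrow) {
  matrix(log(prior), nrow, length(prior), byrow = TRUE)
}

# forward pass + loss on one batch; returns list(loss node, tape, bound)
nri_batch_loss <- function(x_batch, params_num, config, gumbel_seeded) {
  B <- dim(x_batch)[1L]; n <- dim(x_batch)[2L]; tt <- dim(x_batch)[3L]
  tape <- ag_tape()
  bound <- bind_params(tape, params_num[c("enc", "dec")])
  bp <- batch_pairs(n, B)
  xin <- ag_const(tape, encoder_input(x_batch))
  logits <- encode_forward(tape, bound$enc, xin, bp, B * n)
  q <- ag_softmax_rows(tape, logits)
  # KL to the categorical prior
  lq <- ag_log(tape, q)
  kl <- ag_sum(tape, ag_mul(tape, q,
                            ag_add_const(tape, lq,
                                         -log_prior_mat(config$prior,
                                                        nrow(q$value)))))
  # Gumbel-softmax sample (reparameterized: gradient flows via logits)
  g <- -log(-log(matrix(stats::runif(length(logits$value)),
                        nrow(logits$value), ncol(logits$value))))
  z <- ag_softmax_rows(tape, ag_mul_const(tape,
                                          ag_add_const(tape, logits, g),
                                          1 / config$tau))
  mus <- decode_forward(tape, bound$dec, x_batch, z, bp, config,
                        teacher_period = config$prediction_steps)
  xsm <- batch_step_mats(x_batch)
  recon <- NULL
  for (t in seq_len(tt - 1L)) {
    target <- matrix(xsm[, t + 1L, ], B * n, 6L)
    d <- ag_add_const(tape, mus[[t]], -target)
    s <- ag_sum(tape, ag_mul(tape, d, d))
    recon <- if (is.null(recon)) s else ag_add(tape, recon, s)
  }
  recon <- ag_mul_const(tape, recon, 1 / (2 * config$sigma2))
  loss <- ag_mul_const(tape, ag_add(tape, recon, kl), 1 / B)
  list(loss = loss, tape = tape, bound = bound,
       recon = recon$value[1L] / B, kl = kl$value[1L] / B)
}

#' Train the relational-inference model on trajectory windows
#'
#' Per batch: encode the window, sample edge types with the
#' Gumbel-softmax relaxation, decode with periodic teacher forcing, and
#' take an Adam step on the negated ELBO (reconstruction NLL + KL to the
#' edge-type prior, averaged over the batch).  The checkpoint with the
#' lowest validation reconstruction MSE is returned (downstream use is
#' reconstruction quality, so MSE rather than the full ELBO selects it).
#'
#' @param splits a `data_splits` from [make_windows()].
#' @param config an [nri_config()].
#' @param epochs training epochs; 0 returns the initialization with an
#'   empty log.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling initialization, batch order and
#'   Gumbel noise.
#' @param batch_size windows per gradient step.
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param verbose print per-epoch losses.
#' @return an `nri_fit`: list with `params` (best checkpoint), `log`
#'   (one row per epoch), `config`, `best_epoch`.
#' @export
nri_train <- function(splits, config, epochs = 20L, lr = 2e-3, seed = 1L,
                      batch_size = 64L, lr_decay = 0.98, verbose = FALSE) {
  stopifnot(inherits(splits, "data_splits"), length(splits$train) > 0L)
  if (epochs > 0L && length(splits$valid) == 0L) {
    stop("validation split is empty; checkpoint selection needs at least ",
         "one validation window")
  }
  set.seed(seed)
  tt <- splits$window_length
  params <- nri_init_params(config, tt, seed = seed)
  params_num <- list(enc = params$enc, dec = params$dec)
  state <- adam_state(params_num)
  log <- data.frame(epoch = integer(), train_recon = numeric(),
                    train_kl = numeric(), valid_recon = numeric(),
                    valid_kl = numeric(), valid_mse = numeric(),
                    lr = numeric())
  best <- list(mse = Inf, params = params_num, epoch = 0L)
  ntr <- length(splits$train)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^(ep - 1L)
    ord <- sample.int(ntr)
    tr_recon <- 0; tr_kl <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, ntr)]
      xb <- windows_to_array(splits$train[idx])
      fwd <- nri_batch_loss(xb, params_num, config, TRUE)
      if (!is.finite(fwd$loss$value[1L])) {
        stop("training diverged (non-finite loss) at epoch ", ep)
      }
      ag_backward(fwd$tape, fwd$loss)
      grads <- collect_grads(fwd$bound)
      upd <- adam_step(params_num, grads, state, lr = lr_ep)
      params_num <- upd$params
      state <- upd$state
      tr_recon <- tr_recon + fwd$recon; tr_kl <- tr_kl + fwd$kl
      nb <- nb + 1L
    }
    val <- evaluate_nri(params_with(params, params_num), splits$valid,
                        config)
    log[ep, ] <- list(ep, tr_recon / nb, tr_kl / nb, val$recon, val$kl,
                      val$mse, lr_ep)
    if (verbose) {
      message(sprintf("epoch %d  train %.4g/%.4g  valid mse %.4g",
                      ep, tr_recon / nb, tr_kl / nb, val$mse))
    }
    if (val$mse < best$mse) {
      best <- list(mse = val$mse, params = params_num, epoch = ep)
    }
  }
  structure(list(params = params_with(params, best$params), log = log,
                 config = config, best_epoch = best$epoch,
                 seed = as.integer(seed),
                 normalization = splits$normalization,
                 dt = splits$dt, node_labels = splits$node_labels),
            class = "nri_fit")
}

params_with <- function(params, params_num) {
  params$enc <- params_num$enc
  params$dec <- params_num$dec
  params
}

#' Evaluate model reconstruction on a list of windows
#'
#' Encodes every window, decodes with the maximum-probability edge
#' assignment (no fresh Gumbel sample, so the result is deterministic)
#' and the training teacher-forcing period, and reports reconstruction
#' MSE plus the per-window-averaged loss components.
#'
#' @param params an `nri_params` (or `nri_fit`).
#' @param windows list of `[node, step, 6]` arrays.
#' @param config an [nri_config()].
#' @param batch_size evaluation batch size.
#' @return list with `mse`, `recon`, `kl`, and `q_mean` (posterior
#'   averaged over windows, an `edge_posterior`).
#' @export
evaluate_nri <- function(params, windows, config, batch_size = 128L) {
  if (inherits(params, "nri_fit")) params <- params$params
  stopifnot(length(windows) > 0L)
  n <- dim(windows[[1L]])[1L]
  e <- n * (n - 1L)
  sse <- 0; nobs <- 0; kl_tot <- 0
  q_sum <- matrix(0, e, config$K)
  for (start in seq(1L, length(windows), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(windows))
    xb <- windows_to_array(windows[idx])
    B <- dim(xb)[1L]; tt <- dim(xb)[3L]
    tape <- ag_tape()
    # constants only: no gradient work
    enc <- rapply(params$enc, function(v) ag_const(tape, v),
                  how = "replace", classes = "ANY")
    dec <- rapply(params$dec, function(v) ag_const(tape, v),
                  how = "replace", classes = "ANY")
    bp <- batch_pairs(n, B)
    xin <- ag_const(tape, encoder_input(xb))
    logits <- encode_forward(tape, enc, xin, bp, B * n)$value
    q <- exp(logits - apply(logits, 1L, max))
    q <- q / rowSums(q)
    for (b in seq_len(B)) q_sum <- q_sum + q[(b - 1L) * e + seq_len(e), ]
    z <- max_prob_edges(q)
    xsm <- batch_step_mats(xb)
    mus <- decode_forward(tape, dec, xb, ag_const(tape, z), bp, config,
                          teacher_period = config$prediction_steps)
    for (t in seq_len(tt - 1L)) {
      target <- matrix(xsm[, t + 1L, ], B * n, 6L)
      sse <- sse + sum((mus[[t]]$value - target)^2)
      nobs <- nobs + length(target)
    }
    kl_tot <- kl_tot + kl_divergence(q, config$prior)
  }
  q_mean <- q_sum / length(windows)
  list(mse = sse / nobs,
       recon = sse / (2 * config$sigma2) / length(windows),
       kl = kl_tot / length(windows),
       q_mean = structure(list(q = q_mean, pairs = ordered_pairs(n),
                               n_nodes = n), class = "edge_posterior"))
}

#' Reconstruct a trajectory with a trained model
#'
#' Full-horizon rollout from the first frame under the
#' maximum-probability edge assignment (deterministic: no Gumbel sample).
#' If the model was trained on normalized coordinates the reconstruction
#' is also returned denormalized to input units.
#'
#' @param fit an `nri_fit` (or an `nri_params` plus `config`).
#' @param x input [feature_tensor()] or array with `input_steps` steps.
#' @param config required if `fit` is a bare parameter set.
#' @return a `reconstruction` with `mu` (steps 2..T, same space as `x`),
#'   `mu_raw` (input units, if a normalization record is available) and
#'   the posterior used.
#' @export
nri_reconstruct <- function(fit, x, config = NULL) {
  if (inherits(fit, "nri_fit")) {
    params <- fit$params
    config <- fit$config
    norm <- fit$normalization
  } else {
    params <- fit
    stopifnot(!is.null(config))
    norm <- NULL
  }
  xa <- as_x_array(x)
  if (inherits(x, "feature_tensor") && !is.null(x$normalization)) {
    norm <- x$normalization
  }
  q <- nri_encode(xa, params, config)
  z <- max_prob_edges(q)
  recon <- nri_decode(xa, z, params, config,
                      prediction_steps = dim(xa)[2L])
  recon$posterior <- q
  if (!is.null(norm)) {
    fake <- list(normalization = norm)
    recon$mu_raw <- denormalize(fake, recon$mu)
  }
  recon
}

#' Root-mean-square fluctuation per node
#'
#' `RMSF_i = sqrt(mean_t ||pos_i^t - mean_t(pos_i)||^2)` over the position
#' features, in the tensor's length units.
#'
#' @param x a [feature_tensor()], a `[node, step, >=3]` array, or a
#'   `reconstruction` (its `mu` is used).
#' @return numeric vector of length N.
#' @export
rmsf <- function(x) {
  xa <- if (inherits(x, "reconstruction")) x$mu
        else if (inherits(x, "feature_tensor")) x$x
        else x
  stopifnot(length(dim(xa)) == 3L, dim(xa)[2L] >= 2L)
  pos <- xa[, , 1:3, drop = FALSE]
  n <- dim(pos)[1L]
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- pos[i, , ]
    dev <- sweep(p, 2L, colMeans(p))
    out[i] <- sqrt(mean(rowSums(dev^2)))
  }
  out
}

#' Reconstruction quality as RMSF-profile deviation (VSD)
#'
#' Default definition: mean over nodes of the squared difference between
#' the RMSF profiles of the two trajectories.  Symmetric in its
#' arguments; 0 for identical trajectories; lower is better.
#'
#' @param x_true,x_recon trajectories ([feature_tensor()], array, or
#'   `reconstruction`), same node count and units.
#' @return scalar (>= 0).
#' @export
vsd <- function(x_true, x_recon) {
  r1 <- rmsf(x_true)
  r2 <- rmsf(x_recon)
  if (length(r1) != length(r2)) {
    stop("trajectories have different node counts: ", length(r1), " vs ",
         length(r2))
  }
  mean((r1 - r2)^2)
}

#' Binary edge-recovery accuracy against a ground-truth graph
#'
#' Maps K edge types to edge/nonedge (type 1 = nonedge vs the rest) per
#' ordered pair and compares with the symmetrized ground-truth adjacency.
#' Latent types are unordered, so the better of the two binary label
#' permutations is reported.
#'
#' @param q an `edge_posterior` (e.g. `q_mean` from [evaluate_nri()]).
#' @param graph a [ground_truth_graph()].
#' @return accuracy in `[0.5, 1]`.
#' @export
edge_recovery_accuracy <- function(q, graph) {
  stopifnot(inherits(q, "edge_posterior"),
            q$n_nodes == graph$n_nodes)
  pred <- max.col(q$q, ties.method = "first") != 1L
  a <- adjacency(graph)
  truth <- a[cbind(q$pairs$i, q$pairs$j)]
  acc <- mean(pred == truth)
  max(acc, 1 - acc)
}

#' Per-window edge recovery over an ensemble
#'
#' Encodes each window and scores its inferred binary edge/nonedge map
#' against that window's own ground-truth graph.
#'
#' @param params an `nri_params` or `nri_fit`.
#' @param windows list of `[node, step, 6]` arrays.
#' @param graphs list of [ground_truth_graph()]s aligned with `windows`.
#' @param config an [nri_config()].
#' @param batch_size encoder batch size.
#' @return numeric vector of per-window accuracies.
#' @export
recovery_accuracy_windows <- function(params, windows, graphs, config,
                                      batch_size = 256L) {
  if (inherits(params, "nri_fit")) params <- params$params
  stopifnot(length(windows) == length(graphs), length(windows) > 0L)
  n <- dim(windows[[1L]])[1L]
  e <- n * (n - 1L)
  accs <- numeric(length(windows))
  for (start in seq(1L, length(windows), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(windows))
    xb <- windows_to_array(windows[idx])
    B <- dim(xb)[1L]
    tape <- ag_tape()
    enc <- rapply(params$enc, function(v) ag_const(tape, v),
                  how = "replace", classes = "ANY")
    bp <- batch_pairs(n, B)
    xin <- ag_const(tape, encoder_input(xb))
    logits <- encode_forward(tape, enc, xin, bp, B * n)$value
    qb <- exp(logits - apply(logits, 1L, max))
    qb <- qb / rowSums(qb)
    for (b in seq_len(B)) {
      qw <- structure(list(q = qb[(b - 1L) * e + seq_len(e), , drop = FALSE],
                           pairs = ordered_pairs(n), n_nodes = n),
                      class = "edge_posterior")
      accs[idx[b]] <- edge_recovery_accuracy(qw, graphs[[idx[b]]])
    }
  }
  accs
}

# ---- VAE ablation baseline ----------------------------------------------

#' Train the VAE baseline without latent variables over edges
#'
#' Ablation: the same recurrent graph decoder, but no encoder and no
#' per-pair categorical latent.  All ordered pairs share one fixed
#' interaction channel (a single message MLP applied to every pair), so
#' the model has strictly fewer latent degrees of freedom than the full
#' model's N(N-1) K-way posteriors.  Trained on reconstruction NLL only.
#'
#' @inheritParams nri_train
#' @return a `vae_baseline_fit` with `params`, `log`, `config`,
#'   `best_epoch`.
#' @export
train_vae_baseline <- function(splits, config, epochs = 20L, lr = 2e-3,
                               seed = 1L, batch_size = 64L,
                               lr_decay = 0.98, verbose = FALSE) {
  stopifnot(inherits(splits, "data_splits"), length(splits$train) > 0L)
  set.seed(seed)
  H <- config$hidden_dim
  msg_in <- if (config$msg_inputs == "hidden") 2L * H else 2L * (H + 6L)
  params_num <- list(dec = list(msg = list(mlp_params(msg_in, H, H)),
                                gru = gru_params(6L, H),
                                out = mlp_params(H, H, 6L)))
  state <- adam_state(params_num)
  n <- dim(splits$train[[1L]])[1L]
  log <- data.frame(epoch = integer(), train_recon = numeric(),
                    valid_mse = numeric(), lr = numeric())
  best <- list(mse = Inf, params = params_num, epoch = 0L)
  ntr <- length(splits$train)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^(ep - 1L)
    ord <- sample.int(ntr)
    tr <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, ntr)]
      xb <- windows_to_array(splits$train[idx])
      fwd <- baseline_batch_loss(xb, params_num, config)
      if (!is.finite(fwd$loss$value[1L])) {
        stop("baseline training diverged (non-finite loss) at epoch ", ep)
      }
      ag_backward(fwd$tape, fwd$loss)
      grads <- collect_grads(fwd$bound)
      upd <- adam_step(params_num, grads, state, lr = lr_ep)
      params_num <- upd$params
      state <- upd$state
      tr <- tr + fwd$recon; nb <- nb + 1L
    }
    val <- evaluate_baseline(params_num, splits$valid, config)
    log[ep, ] <- list(ep, tr / nb, val, lr_ep)
    if (verbose) message(sprintf("baseline epoch %d  valid mse %.4g", ep, val))
    if (val < best$mse) best <- list(mse = val, params = params_num,
                                     epoch = ep)
  }
  structure(list(params = best$params, log = log, config = config,
                 best_epoch = best$epoch, seed = as.integer(seed)),
            class = "vae_baseline_fit")
}

baseline_z <- function(n, B) {
  # every ordered pair uses the single shared channel (type 2 of 2)
  matrix(rep(c(0, 1), each = B * n * (n - 1L)), B * n * (n - 1L), 2L)
}

baseline_batch_loss <- function(x_batch, params_num, config) {
  B <- dim(x_batch)[1L]; n <- dim(x_batch)[2L]; tt <- dim(x_batch)[3L]
  tape <- ag_tape()
  bound <- bind_params(tape, params_num)
  bp <- batch_pairs(n, B)
  z <- ag_const(tape, baseline_z(n, B))
  mus <- decode_forward(tape, bound$dec, x_batch, z, bp, config,
                        teacher_period = config$prediction_steps)
  xsm <- batch_step_mats(x_batch)
  recon <- NULL
  for (t in seq_len(tt - 1L)) {
    target <- matrix(xsm[, t + 1L, ], B * n, 6L)
    d <- ag_add_const(tape, mus[[t]], -target)
    s <- ag_sum(tape, ag_mul(tape, d, d))
    recon <- if (is.null(recon)) s else ag_add(tape, recon, s)
  }
  loss <- ag_mul_const(tape, recon, 1 / (2 * config$sigma2 * B))
  list(loss = loss, tape = tape, bound = bound,
       recon = recon$value[1L] / (2 * config$sigma2 * B))
}

#' Held-out reconstruction MSE of the VAE baseline
#'
#' @param params baseline parameters (or a `vae_baseline_fit`).
#' @param windows list of window arrays.
#' @param config an [nri_config()].
#' @param batch_size evaluation batch size.
#' @return scalar MSE.
#' @export
evaluate_baseline <- function(params, windows, config, batch_size = 128L) {
  if (inherits(params, "vae_baseline_fit")) params <- params$params
  n <- dim(windows[[1L]])[1L]
  sse <- 0; nobs <- 0
  for (start in seq(1L, length(windows), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(windows))
    xb <- windows_to_array(windows[idx])
    B <- dim(xb)[1L]; tt <- dim(xb)[3L]
    tape <- ag_tape()
    dec <- rapply(params$dec, function(v) ag_const(tape, v),
                  how = "replace", classes = "ANY")
    bp <- batch_pairs(n, B)
    z <- ag_const(tape, baseline_z(n, B))
    xsm <- batch_step_mats(xb)
    mus <- decode_forward(tape, dec, xb, z, bp, config,
                          teacher_period = config$prediction_steps)
    for (t in seq_len(tt - 1L)) {
      target <- matrix(xsm[, t + 1L, ], B * n, 6L)
      sse <- sse + sum((mus[[t]]$value - target)^2)
      nobs <- nobs + length(target)
    }
  }
  sse / nobs
}
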