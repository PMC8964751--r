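#' Model configuration for neural relational inference
#'
#' The model is a variational autoencoder whose latent variables are K
#' categorical edge types per ordered node pair.  Edge type 1 is the
#' hard-coded "nonedge": the decoder has no message function for it, so
#' "no interaction" is structural rather than learned.
#'
#' @param K number of edge types (>= 2); default 4.
#' @param hidden_dim width of all embeddings and MLP hidden layers.
#' @param tau Gumbel-softmax temperature (> 0); default 0.5, no annealing.
#' @param prior length-K prior over edge types; default
#'   `(0.91, 0.03, 0.03, 0.03)` favouring sparse graphs.  Pass
#'   `rep(1/K, K)` for the uniform prior.
#' @param sigma2 fixed output variance of the Gaussian reconstruction
#'   likelihood; default 5e-5 (suited to coordinates normalized to
#'   `[-1, 1]`).
#' @param encoder_rounds rounds of node-to-edge passing in the encoder
#'   (the implemented architecture performs two, per the standard design).
#' @param mlp_layers layers per perceptron (2: hidden ELU layer + linear).
#' @param prediction_steps during training the recurrent decoder feeds
#'   back its own predictions for this many steps before resynchronizing
#'   with the ground-truth input; default 10.
#' @param msg_inputs what the decoder's edge-message perceptrons see per
#'   pair: the endpoints' recurrent hidden states concatenated with their
#'   current inputs (`"hidden_input"`, default) or hidden states alone
#'   (`"hidden"`).  Including the inputs lets a message represent the
#'   physical coupling (e.g. a spring force from the two positions)
#'   without first learning to embed positions into the hidden state.
#' @return an `nri_config`.
#' @export
nri_config <- function(K = 4L, hidden_dim = 32L, tau = 0.5,
                       prior = c(0.91, 0.03, 0.03, 0.03), sigma2 = 5e-5,
                       encoder_rounds = 2L, mlp_layers = 2L,
                       prediction_steps = 10L,
                       msg_inputs = c("hidden_input", "hidden")) {
  K <- as.integer(K)
  msg_inputs <- match.arg(msg_inputs)
  stopifnot(K >= 2L, length(prior) == K, all(prior >= 0),
            abs(sum(prior) - 1) < 1e-8, tau > 0, sigma2 > 0,
            hidden_dim >= 1L, prediction_steps >= 1L)
  structure(list(K = K, hidden_dim = as.integer(hidden_dim), tau = tau,
                 prior = prior, sigma2 = sigma2,
                 encoder_rounds = as.integer(encoder_rounds),
                 mlp_layers = as.integer(mlp_layers),
                 prediction_steps = as.integer(prediction_steps),
                 msg_inputs = msg_inputs),
            class = "nri_config")
}

# all ordered pairs (i, j), i != j, row-major; edge (i, j) sends i -> j
ordered_pairs <- function(n) {
  g <- expand.grid(j = seq_len(n), i = seq_len(n))
  g <- g[g$i != g$j, c("i", "j")]
  rownames(g) <- NULL
  g
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases.  Encoder: trajectory embedding,
#' two edge MLPs, one node MLP and a linear edge-type readout.  Decoder:
#' one message MLP per non-null edge type (types 2..K), a GRU cell on
#' `[aggregated message, input]`, and an output MLP whose result is added
#' to the current input (residual prediction).
#'
#' @param config an [nri_config()].
#' @param input_steps window length T the encoder embedding consumes
#'   (its input dimension is `6 * T`).
#' @param seed integer seed.
#' @return an `nri_params` list with elements `enc` and `dec`.
#' @export
nri_init_params <- function(config, input_steps, seed = 1L) {
  stopifnot(inherits(config, "nri_config"), input_steps >= 2L)
  set.seed(seed)
  H <- config$hidden_dim
  enc <- list(emb = mlp_bn_params(6L * input_steps, H, H),
              e1 = mlp_bn_params(2L * H, H, H),
              v1 = mlp_bn_params(H, H, H),
              e2 = mlp_bn_params(3L * H, H, H),
              out = list(W = glorot(H, config$K),
                         b = matrix(0, 1L, config$K)))
  msg_in <- if (config$msg_inputs == "hidden") 2L * H else 2L * (H + 6L)
  msg <- lapply(seq_len(config$K - 1L),
                function(k) mlp_params(msg_in, H, H))
  dec <- list(msg = msg,
              gru = gru_params(6L, H),
              out = mlp_params(H, H, 6L))
  structure(list(enc = enc, dec = dec, hidden_dim = H, K = config$K,
                 input_steps = as.integer(input_steps)),
            class = "nri_params")
}

# ---- forward passes on a tape -------------------------------------------

# x_batch: array [B, N, T, 6] -> encoder input matrix (B*N) x (T*6),
# node rows ordered batch-major: row (b-1)*N + i
encoder_input <- function(x_batch) {
  B <- dim(x_batch)[1L]; n <- dim(x_batch)[2L]
  tt <- dim(x_batch)[3L]
  out <- batch_step_mats(x_batch)
  dim(out) <- c(B * n, tt * 6L)
  out
}

# reshape [B, N, T, 6] -> [B*N, T, 6] with node index fastest
# (row (b-1)*N + i), so per-step matrices are cheap slices
batch_step_mats <- function(x_batch) {
  B <- dim(x_batch)[1L]; n <- dim(x_batch)[2L]
  xa <- aperm(x_batch, c(2L, 1L, 3L, 4L))
  dim(xa) <- c(n * B, dim(x_batch)[3L], 6L)
  xa
}

# batched pair index: send/recv row indices into the (B*N)-row node matrix
# and receiver groups for aggregation
batch_pairs <- function(n, B) {
  pr <- ordered_pairs(n)
  e <- nrow(pr)
  off <- rep((seq_len(B) - 1L) * n, each = e)
  list(send = rep(pr$i, B) + off,
       recv = rep(pr$j, B) + off,
       n_edges = e, pairs = pr)
}

# encoder: Eqs 3-6 then linear readout to K logits per ordered pair
encode_forward <- function(tape, enc, xin, bp, n_nodes_total) {
  h <- mlp_bn_forward(tape, enc$emb, xin)
  e1 <- mlp_bn_forward(tape, enc$e1,
                       ag_cbind(tape, ag_rows(tape, h, bp$send),
                                ag_rows(tape, h, bp$recv)))
  agg <- ag_rowsum(tape, e1, bp$recv, n_nodes_total)
  h2 <- mlp_bn_forward(tape, enc$v1, agg)
  # skip connection: the second edge round keeps the first round's
  # pair-specific embedding, which aggregation would otherwise wash out
  e2 <- mlp_bn_forward(tape, enc$e2,
                       ag_cbind(tape,
                                ag_cbind(tape,
                                         ag_rows(tape, h2, bp$send),
                                         ag_rows(tape, h2, bp$recv)),
                                e1))
  ag_add_bias(tape, ag_matmul(tape, e2, enc$out$W), enc$out$b)
}

# recurrent decoder rollout.
#   x_batch: [B, N, T, 6]; z: tape node (B*E x K) of edge-type weights.
#   Input at step t is the ground truth when (t-1) %% teacher_period == 0,
#   otherwise the model's own previous prediction (gradient flows through).
# Returns list of (B*N x 6) mean nodes for steps 2..T.
decode_forward <- function(tape, dec, x_batch, z, bp, config,
                           teacher_period) {
  B <- dim(x_batch)[1L]; n <- dim(x_batch)[2L]; tt <- dim(x_batch)[3L]
  nbn <- B * n
  H <- ncol(dec$gru$Wh$value) / 3L
  hid <- ag_const(tape, matrix(0, nbn, H))
  xsm <- batch_step_mats(x_batch)
  xt_mat <- function(t) matrix(xsm[, t, ], nbn, 6L)
  mus <- vector("list", tt - 1L)
  xin <- ag_const(tape, xt_mat(1L))
  input_aware <- !is.null(config$msg_inputs) &&
    config$msg_inputs == "hidden_input"
  for (t in seq_len(tt - 1L)) {
    hx <- if (input_aware) ag_cbind(tape, hid, xin) else hid
    ein <- ag_cbind(tape, ag_rows(tape, hx, bp$send),
                    ag_rows(tape, hx, bp$recv))
    msg <- typed_messages_forward(tape, dec$msg, z, ein)
    agg <- ag_mul_const(tape, ag_rowsum(tape, msg, bp$recv, nbn),
                        1 / (n - 1L))
    hid <- gru_msg_forward(tape, dec$gru, xin, agg, hid, H)
    mu <- ag_add(tape, xin, mlp_forward(tape, dec$out, hid))
    mus[[t]] <- mu
    if (t < tt - 1L) {
      xin <- if (t %% teacher_period == 0L) ag_const(tape, xt_mat(t + 1L))
             else mu
    }
  }
  mus
}

# ---- user-facing operations ---------------------------------------------

as_x_array <- function(x) {
  if (inherits(x, "feature_tensor")) x$x
  else { stopifnot(length(dim(x)) == 3L, dim(x)[3L] == 6L); x }
}

#' Infer the edge-type posterior for a trajectory
#'
#' Runs the graph-network encoder: each node's whole trajectory is
#' embedded, two rounds of node-to-edge message passing with one
#' edge-to-node aggregation in between produce an embedding per ordered
#' pair, and a softmax over K logits yields the categorical posterior
#' q(z_ij | x).
#'
#' @param x a [feature_tensor()] or `[node, step, 6]` array; the step
#'   count must equal `params$input_steps`.
#' @param params [nri_init_params()] output (possibly trained).
#' @param config the matching [nri_config()].
#' @return an `edge_posterior`: list with `q` (`N(N-1) x K` matrix of
#'   probabilities, rows summing to 1), `pairs` (data.frame `i`, `j`:
#'   ordered pair i -> j) and `n_nodes`.
#' @export
nri_encode <- function(x, params, config) {
  xa <- as_x_array(x)
  n <- dim(xa)[1L]
  if (n < 2L) stop("need at least 2 nodes to form pairs")
  if (dim(xa)[2L] != params$input_steps) {
    stop("trajectory has ", dim(xa)[2L], " steps but the encoder expects ",
         params$input_steps)
  }
  logits <- encode_logits(xa, params, config)
  q <- exp(logits - apply(logits, 1L, max))
  q <- q / rowSums(q)
  if (!all(is.finite(q))) stop("non-finite encoder activations")
  structure(list(q = q, pairs = ordered_pairs(n), n_nodes = n),
            class = "edge_posterior")
}

# numeric logits (E x K) for a single trajectory
encode_logits <- function(xa, params, config) {
  tape <- ag_tape()
  enc <- bind_params(tape, params$enc)
  xb <- array(xa, c(1L, dim(xa)))
  bp <- batch_pairs(dim(xa)[1L], 1L)
  xin <- ag_const(tape, encoder_input(xb))
  encode_forward(tape, enc, xin, bp, dim(xa)[1L])$value
}

#' Sample relaxed one-hot edge types (Gumbel-softmax)
#'
#' `z_ij = softmax((log q_ij + g) / tau)` with g i.i.d. standard Gumbel.
#' As `tau -> 0` samples approach one-hot vectors drawn from q.
#'
#' @param q an `edge_posterior` from [nri_encode()], or a bare
#'   probability matrix.
#' @param tau temperature (> 0).
#' @param seed integer seed for the Gumbel draws.
#' @return an `edge_sample`: list with `z` (rows sum to 1), `tau`, `seed`.
#' @export
nri_sample_edges <- function(q, tau = 0.5, seed = 1L) {
  if (tau <= 0) stop("tau must be > 0")
  qm <- if (inherits(q, "edge_posterior")) q$q else as.matrix(q)
  set.seed(seed)
  g <- -log(-log(matrix(stats::runif(length(qm)), nrow(qm), ncol(qm))))
  lg <- (log(pmax(qm, 1e-20)) + g) / tau
  z <- exp(lg - apply(lg, 1L, max))
  z <- z / rowSums(z)
  structure(list(z = z, tau = tau, seed = as.integer(seed)),
            class = "edge_sample")
}

# one-hot matrix from the maximum-probability edge type per pair
max_prob_edges <- function(q) {
  qm <- if (inherits(q, "edge_posterior")) q$q else q
  z <- matrix(0, nrow(qm), ncol(qm))
  z[cbind(seq_len(nrow(qm)), max.col(qm, ties.method = "first"))] <- 1
  z
}

#' Decode (reconstruct) a trajectory given sampled edges
#'
#' Recurrent graph decoder: per step, messages along each ordered pair are
#' a z-weighted sum over the non-null edge types' message MLPs (type 1
#' carries no message), aggregated per receiving node, fed with the
#' current input into a GRU, and the predicted mean is the current input
#' plus an output transform (residual prediction).  The decoder feeds back
#' its own predictions for `prediction_steps` steps before
#' resynchronizing with the ground-truth input; use
#' `prediction_steps >= T` for a full free rollout.
#'
#' @param x input [feature_tensor()] or array.
#' @param z an `edge_sample` (or bare `E x K` matrix, e.g. one-hot).
#' @param params,config model parameters and configuration.
#' @param prediction_steps steps between teacher-forcing
#'   resynchronizations; default from `config`.
#' @return a `reconstruction`: list with `mu` (`[node, step, 6]` array for
#'   steps 2..T) and `sigma2`.
#' @export
nri_decode <- function(x, z, params, config,
                       prediction_steps = config$prediction_steps) {
  xa <- as_x_array(x)
  n <- dim(xa)[1L]
  zm <- if (inherits(z, "edge_sample")) z$z else as.matrix(z)
  if (nrow(zm) != n * (n - 1L)) {
    stop("edge sample has ", nrow(zm), " rows; expected N(N-1) = ",
         n * (n - 1L))
  }
  tape <- ag_tape()
  dec <- bind_params(tape, params$dec)
  bp <- batch_pairs(n, 1L)
  mus <- decode_forward(tape, dec, array(xa, c(1L, dim(xa))),
                        ag_const(tape, zm), bp, config,
                        teacher_period = prediction_steps)
  tt <- dim(xa)[2L]
  mu <- array(0, c(n, tt - 1L, 6L))
  for (t in seq_len(tt - 1L)) mu[, t, ] <- mus[[t]]$value
  if (!all(is.finite(mu))) stop("non-finite decoder activations")
  structure(list(mu = mu, sigma2 = config$sigma2,
                 prediction_steps = prediction_steps),
            class = "reconstruction")
}

#' Gaussian reconstruction negative log-likelihood (constant dropped)
#'
#' `sum_j sum_{t=2..T} ||x_j^t - mu_j^t||^2 / (2 sigma2)`.
#'
#' @param x input [feature_tensor()] or array (steps 1..T).
#' @param recon a `reconstruction` from [nri_decode()] (means for steps
#'   2..T).
#' @param sigma2 fixed output variance (> 0).
#' @return scalar.
#' @export
reconstruction_nll <- function(x, recon, sigma2 = recon$sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  xa <- as_x_array(x)
  mu <- if (inherits(recon, "reconstruction")) recon$mu else recon
  target <- xa[, -1L, , drop = FALSE]
  stopifnot(all(dim(target) == dim(mu)))
  sum((target - mu)^2) / (2 * sigma2)
}

#' KL divergence from the edge-type posterior to the prior
#'
#' `sum_{i != j} sum_k q_ijk log(q_ijk / prior_k)` with `0 log 0 = 0`.
#' Under a uniform prior this equals `sum_{i != j} (log K - H(q_ij))`.
#'
#' @param q an `edge_posterior` or probability matrix.
#' @param prior length-K probability vector.
#' @return scalar (>= 0).
#' @export
kl_divergence <- function(q, prior) {
  qm <- if (inherits(q, "edge_posterior")) q$q else as.matrix(q)
  stopifnot(length(prior) == ncol(qm), abs(sum(prior) - 1) < 1e-8)
  if (any(prior == 0 & colSums(qm) > 0)) {
    stop("prior has zero mass on an edge type with posterior support ",
         "(infinite KL)")
  }
  terms <- qm * (log(qm / rep(prior, each = nrow(qm))))
  terms[qm == 0] <- 0
  sum(terms)
}

#' Negated evidence lower bound (training loss)
#'
#' Reconstruction NLL plus KL divergence to the edge-type prior; equals
#' the negative ELBO up to an additive constant.
#'
#' @param x input trajectory.
#' @param recon a `reconstruction`.
#' @param q an `edge_posterior`.
#' @param config an [nri_config()] supplying `sigma2` and `prior`.
#' @return scalar.
#' @export
elbo_loss <- function(x, recon, q, config) {
  reconstruction_nll(x, recon, config$sigma2) +
    kl_divergence(q, config$prior)
}
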