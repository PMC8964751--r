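# Neural building blocks on top of the autograd tape: two-layer ELU
# perceptrons, a GRU cell, Glorot initialization and an Adam optimizer.
# Parameters live as flat named lists of numeric matrices; each forward
# pass binds them onto a fresh tape as trainable leaves.

# add a row-vector bias node to a matrix, memoizing the expanded bias on
# the node (same dimensions recur every decoder step within a batch)
add_bias_fast <- function(m, bnode) {
  nr <- nrow(m)
  bm <- bnode$bias_cache
  if (is.null(bm) || nrow(bm) != nr) {
    bm <- matrix(bnode$value, nr, ncol(m), byrow = TRUE)
    bnode$bias_cache <- bm
  }
  m + bm
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# parameter set for a 2-layer perceptron in -> hidden -> out
mlp_params <- function(nin, nhidden, nout) {
  list(W1 = glorot(nin, nhidden), b1 = matrix(0, 1L, nhidden),
       W2 = glorot(nhidden, nout), b2 = matrix(0, 1L, nout))
}

# forward pass; p is a list of tape nodes named as in mlp_params.
# Fused into a single tape node (hand-written backward) to keep the tape
# short: elu(x W1 + b1) W2 + b2.
mlp_forward <- function(tape, p, x) {
  xv <- x$value
  h1 <- add_bias_fast(xv %*% p$W1$value, p$b1)
  epm <- exp(pmin(h1, 0))              # elu slope; 1 where h1 > 0
  a1 <- pmax(h1, 0) + epm - 1
  out <- add_bias_fast(a1 %*% p$W2$value, p$b2)
  ag_node(tape, out, list(p$W1, p$b1, p$W2, p$b2, x), function(g) {
    ga1 <- g %*% t(p$W2$value)
    gh1 <- ga1 * epm
    list(if (isTRUE(p$W1$track)) crossprod(xv, gh1) else NULL,
         if (isTRUE(p$b1$track)) matrix(colSums(gh1), 1L) else NULL,
         if (isTRUE(p$W2$track)) crossprod(a1, g) else NULL,
         if (isTRUE(p$b2$track)) matrix(colSums(g), 1L) else NULL,
         if (isTRUE(x$track)) gh1 %*% t(p$W1$value) else NULL)
  })
}

# Encoder perceptron with batch normalization:
#   out = gamma * standardize(elu(elu(x W1 + b1) W2 + b2)) + beta
# standardized per feature over the batch (batch statistics, no running
# averages).  Normalizing the edge/node embeddings keeps the edge-type
# logits well-scaled, which protects the discrete latent from collapsing
# to a single type early in training.
mlp_bn_params <- function(nin, nhidden, nout) {
  c(mlp_params(nin, nhidden, nout),
    list(gamma = matrix(1, 1L, nout), beta = matrix(0, 1L, nout)))
}

mlp_bn_forward <- function(tape, p, x, eps = 1e-5) {
  xv <- x$value
  nr <- nrow(xv)
  h1 <- add_bias_fast(xv %*% p$W1$value, p$b1)
  epm1 <- exp(pmin(h1, 0))
  a1 <- pmax(h1, 0) + epm1 - 1
  h2 <- add_bias_fast(a1 %*% p$W2$value, p$b2)
  epm2 <- exp(pmin(h2, 0))
  a2 <- pmax(h2, 0) + epm2 - 1
  mu <- colMeans(a2)
  va <- colMeans(a2 * a2) - mu^2
  sd <- sqrt(va + eps)
  xh <- (a2 - rep(mu, each = nr)) / rep(sd, each = nr)
  gam <- as.vector(p$gamma$value)
  out <- xh * rep(gam, each = nr) + rep(as.vector(p$beta$value), each = nr)
  ag_node(tape, out, list(p$W1, p$b1, p$W2, p$b2, p$gamma, p$beta, x),
          function(g) {
    dxh <- g * rep(gam, each = nr)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xh)
    da2 <- (dxh - rep(m1, each = nr) - xh * rep(m2, each = nr)) /
      rep(sd, each = nr)
    dh2 <- da2 * epm2
    da1 <- dh2 %*% t(p$W2$value)
    dh1 <- da1 * epm1
    list(if (isTRUE(p$W1$track)) crossprod(xv, dh1) else NULL,
         if (isTRUE(p$b1$track)) matrix(colSums(dh1), 1L) else NULL,
         if (isTRUE(p$W2$track)) crossprod(a1, dh2) else NULL,
         if (isTRUE(p$b2$track)) matrix(colSums(dh2), 1L) else NULL,
         if (isTRUE(p$gamma$track)) matrix(colSums(g * xh), 1L) else NULL,
         if (isTRUE(p$beta$track)) matrix(colSums(g), 1L) else NULL,
         if (isTRUE(x$track)) dh1 %*% t(p$W1$value) else NULL)
  })
}

# GRU cell parameters: fused input/hidden weights for the r,u,n gates
gru_params <- function(nin, nhidden) {
  list(Wi = glorot(nin, 3L * nhidden), bi = matrix(0, 1L, 3L * nhidden),
       Wh = glorot(nhidden, 3L * nhidden), bh = matrix(0, 1L, 3L * nhidden))
}

# One GRU step (single fused tape node).  x: (n x nin) node, h: (n x H).
#   r = sigmoid(W_ir x + b_ir + W_hr h + b_hr)
#   u = sigmoid(W_iu x + b_iu + W_hu h + b_hu)
#   c = tanh(W_in x + b_in + r * (W_hn h + b_hn))
#   h' = u * h + (1 - u) * c
gru_forward <- function(tape, p, x, h, nhidden) {
  xv <- x$value; hv <- h$value
  gi <- add_bias_fast(xv %*% p$Wi$value, p$bi)
  gh <- add_bias_fast(hv %*% p$Wh$value, p$bh)
  ir <- seq_len(nhidden); iu <- ir + nhidden; ic <- iu + nhidden
  r <- 1 / (1 + exp(-(gi[, ir, drop = FALSE] + gh[, ir, drop = FALSE])))
  u <- 1 / (1 + exp(-(gi[, iu, drop = FALSE] + gh[, iu, drop = FALSE])))
  chn <- gh[, ic, drop = FALSE]
  cc <- tanh(gi[, ic, drop = FALSE] + r * chn)
  out <- u * hv + (1 - u) * cc
  ag_node(tape, out, list(p$Wi, p$bi, p$Wh, p$bh, x, h), function(g) {
    dc <- g * (1 - u) * (1 - cc * cc)       # preactivation of c
    du <- g * (hv - cc) * u * (1 - u)       # preactivation of u
    dr <- dc * chn * r * (1 - r)            # preactivation of r
    dgi <- cbind(dr, du, dc)
    dgh <- cbind(dr, du, dc * r)
    gx <- if (isTRUE(x$track)) dgi %*% t(p$Wi$value) else NULL
    gh_ <- if (isTRUE(h$track)) dgh %*% t(p$Wh$value) + g * u else NULL
    list(if (isTRUE(p$Wi$track)) crossprod(xv, dgi) else NULL,
         if (isTRUE(p$bi$track)) matrix(colSums(dgi), 1L) else NULL,
         if (isTRUE(p$Wh$track)) crossprod(hv, dgh) else NULL,
         if (isTRUE(p$bh$track)) matrix(colSums(dgh), 1L) else NULL,
         gx, gh_)
  })
}

# All non-null edge-type messages in one fused tape node:
#   out = sum_k z[, k+1] * mlp_k(ein)
# msgs: list of bound mlp_params nodes (types 2..K); z: (rows x K) node;
# ein: (rows x d) node.  The first layers of all K-1 perceptrons are
# evaluated as one matrix product.
typed_messages_forward <- function(tape, msgs, z, ein) {
  nk <- length(msgs)
  ev <- ein$value
  nr <- nrow(ev)
  H <- ncol(msgs[[1L]]$W2$value)
  W1cat <- do.call(cbind, lapply(msgs, function(p) p$W1$value))
  b1cat <- do.call(cbind, lapply(msgs, function(p) p$b1$value))
  h1 <- ev %*% W1cat
  h1 <- h1 + rep(b1cat, each = nr)
  epm <- exp(pmin(h1, 0))
  a1 <- pmax(h1, 0) + epm - 1
  hh <- ncol(msgs[[1L]]$W1$value)
  outk <- vector("list", nk)
  out <- matrix(0, nr, H)
  zv <- z$value
  for (k in seq_len(nk)) {
    cols <- (k - 1L) * hh + seq_len(hh)
    ok <- a1[, cols, drop = FALSE] %*% msgs[[k]]$W2$value
    ok <- ok + rep(msgs[[k]]$b2$value, each = nr)
    outk[[k]] <- ok
    out <- out + ok * zv[, k + 1L]
  }
  parents <- c(unlist(lapply(msgs, function(p)
    list(p$W1, p$b1, p$W2, p$b2))), list(z, ein))
  ag_node(tape, out, parents, function(g) {
    grads <- vector("list", 4L * nk + 2L)
    dh1 <- matrix(0, nr, hh * nk)
    gz <- if (isTRUE(z$track)) matrix(0, nr, ncol(zv)) else NULL
    for (k in seq_len(nk)) {
      cols <- (k - 1L) * hh + seq_len(hh)
      gk <- g * zv[, k + 1L]
      a1k <- a1[, cols, drop = FALSE]
      p <- msgs[[k]]
      grads[[4L * (k - 1L) + 1L]] <- NULL   # filled below
      if (isTRUE(p$W2$track)) {
        grads[[4L * (k - 1L) + 3L]] <- crossprod(a1k, gk)
      }
      if (isTRUE(p$b2$track)) {
        grads[[4L * (k - 1L) + 4L]] <- matrix(colSums(gk), 1L)
      }
      dh1[, cols] <- (gk %*% t(p$W2$value)) * epm[, cols, drop = FALSE]
      if (!is.null(gz)) gz[, k + 1L] <- rowSums(g * outk[[k]])
    }
    for (k in seq_len(nk)) {
      cols <- (k - 1L) * hh + seq_len(hh)
      p <- msgs[[k]]
      if (isTRUE(p$W1$track)) {
        grads[[4L * (k - 1L) + 1L]] <- crossprod(ev, dh1[, cols,
                                                         drop = FALSE])
      }
      if (isTRUE(p$b1$track)) {
        grads[[4L * (k - 1L) + 2L]] <- matrix(colSums(dh1[, cols,
                                                          drop = FALSE]),
                                              1L)
      }
    }
    grads[[4L * nk + 1L]] <- gz
    grads[[4L * nk + 2L]] <- if (isTRUE(ein$track)) dh1 %*% t(W1cat)
                             else NULL
    grads
  })
}

# Message-gated recurrent unit (single fused tape node), the recurrence
# used by the reference implementation of this model family: the
# hidden-path contribution of every gate is computed from the aggregated
# incoming messages rather than from the hidden state, so interaction
# messages modulate the recurrence directly.
#   r = sigmoid(W_ir x + b_ir + W_hr m + b_hr)
#   i = sigmoid(W_ii x + b_ii + W_hi m + b_hi)
#   n = tanh(W_in x + b_in + r * (W_hn m + b_hn))
#   h' = (1 - i) * n + i * h
# x: (rows x nin) input node, m: (rows x H) message node, h: (rows x H).
gru_msg_forward <- function(tape, p, x, m, h, nhidden) {
  xv <- x$value; mv <- m$value; hv <- h$value
  gi <- add_bias_fast(xv %*% p$Wi$value, p$bi)
  gh <- add_bias_fast(mv %*% p$Wh$value, p$bh)
  ir <- seq_len(nhidden); iu <- ir + nhidden; ic <- iu + nhidden
  r <- 1 / (1 + exp(-(gi[, ir, drop = FALSE] + gh[, ir, drop = FALSE])))
  u <- 1 / (1 + exp(-(gi[, iu, drop = FALSE] + gh[, iu, drop = FALSE])))
  chn <- gh[, ic, drop = FALSE]
  cc <- tanh(gi[, ic, drop = FALSE] + r * chn)
  out <- (1 - u) * cc + u * hv
  ag_node(tape, out, list(p$Wi, p$bi, p$Wh, p$bh, x, m, h), function(g) {
    dc <- g * (1 - u) * (1 - cc * cc)
    du <- g * (hv - cc) * u * (1 - u)
    dr <- dc * chn * r * (1 - r)
    dgi <- cbind(dr, du, dc)
    dgh <- cbind(dr, du, dc * r)
    list(if (isTRUE(p$Wi$track)) crossprod(xv, dgi) else NULL,
         if (isTRUE(p$bi$track)) matrix(colSums(dgi), 1L) else NULL,
         if (isTRUE(p$Wh$track)) crossprod(mv, dgh) else NULL,
         if (isTRUE(p$bh$track)) matrix(colSums(dgh), 1L) else NULL,
         if (isTRUE(x$track)) dgi %*% t(p$Wi$value) else NULL,
         if (isTRUE(m$track)) dgh %*% t(p$Wh$value) else NULL,
         if (isTRUE(h$track)) g * u else NULL)
  })
}

# Bind a (possibly nested) list of numeric matrices onto a tape as
# trainable leaves, preserving structure.
bind_params <- function(tape, params) {
  rapply(params, function(v) ag_param(tape, v), how = "replace",
         classes = "ANY")
}

# Collect gradients from bound nodes back into the flat structure of the
# numeric parameter list (zero where a parameter was unused).
collect_grads <- function(bound) {
  rapply(bound, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value))
    else nd$grad
  }, how = "replace", classes = "ANY")
}

adam_state <- function(params) {
  flat <- unlist_mats(params)
  list(m = lapply(flat, function(v) v * 0),
       v = lapply(flat, function(v) v * 0),
       t = 0L)
}

unlist_mats <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      for (k in seq_along(x)) walk(x[[k]], paste0(prefix, ".", nms[k]))
    } else out[[substring(prefix, 2L)]] <<- x
  }
  walk(params, "")
  out
}

relist_mats <- function(flat, skeleton) {
  idx <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else { idx <<- idx + 1L; flat[[idx]] }
  }
  walk(skeleton)
}

# One Adam update; returns list(params, state)
adam_step <- function(params, grads, state, lr = 5e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  pf <- unlist_mats(params)
  gf <- unlist_mats(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(pf)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gf[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gf[[i]]^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    pf[[i]] <- pf[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = relist_mats(pf, params), state = state)
}
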