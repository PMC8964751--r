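# Encoder, Gumbel-softmax sampler, decoder and loss terms against
# straight-line hand computations and sampling oracles.

test_that("posterior has N(N-1) rows, each summing to 1", {
  tm <- tiny_model()
  x <- rand_features(n = 2, tt = 6)
  q <- nri_encode(x, tm$params, tm$config)
  expect_equal(nrow(q$q), 2)
  expect_equal(rowSums(q$q), rep(1, 2), tolerance = 1e-9)
  x5 <- rand_features(n = 5, tt = 6)
  q5 <- nri_encode(x5, tm$params, tm$config)
  expect_equal(nrow(q5$q), 20)
  expect_equal(rowSums(q5$q), rep(1, 20), tolerance = 1e-9)
  expect_error(nri_encode(rand_features(n = 2, tt = 5), tm$params,
                          tm$config), "expects")
})

test_that("encoder logits match a hand computation of the message rounds", {
  # independent straight-line replication with hidden width 1: each block
  # is  bn(elu(elu(x.W1 + b1) W2 + b2))  with batch statistics over its
  # rows; rounds are node embedding -> node-to-edge -> edge-to-node sum
  # over incoming edges -> second node-to-edge with the first round's
  # edge value appended (skip) -> linear readout over K types
  K <- 4; tt <- 2; n <- 3
  config <- nri_config(K = K, hidden_dim = 1)
  params <- nri_init_params(config, tt, seed = 1)
  blk <- function(w1, b1, w2, b2, gamma, beta) {
    list(W1 = w1, b1 = matrix(b1, 1, 1), W2 = matrix(w2, 1, 1),
         b2 = matrix(b2, 1, 1), gamma = matrix(gamma, 1, 1),
         beta = matrix(beta, 1, 1))
  }
  params$enc$emb <- blk(matrix(0.05, 12, 1), 1, 1, 0.2, 1.5, 0.2)
  params$enc$e1 <- blk(matrix(c(0.3, -0.4), 2, 1), 0.5, -1, 0, 0.8, -0.1)
  params$enc$v1 <- blk(matrix(0.25, 1, 1), 0.1, 1, 0.3, 1.2, 0)
  params$enc$e2 <- blk(matrix(c(0.2, 0.6, -0.5), 3, 1), 0.4, 1, 0, 1, 0.3)
  params$enc$out <- list(W = matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4),
                         b = matrix(0.05, 1, 4))
  set.seed(2)
  xa <- array(runif(n * tt * 6, 0.1, 1), c(n, tt, 6))

  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  blk_apply <- function(p, rows) {    # rows: list of input vectors
    a2 <- vapply(rows, function(x) {
      elu(elu(sum(x * p$W1) + p$b1[1]) * p$W2[1] + p$b2[1])
    }, 0)
    mu <- mean(a2)
    sd <- sqrt(mean(a2^2) - mu^2 + 1e-5)
    (a2 - mu) / sd * p$gamma[1] + p$beta[1]
  }
  h <- blk_apply(params$enc$emb,
                 lapply(1:n, function(i) as.vector(xa[i, , ])))
  pairs <- expand.grid(j = 1:n, i = 1:n)
  pairs <- pairs[pairs$i != pairs$j, c("i", "j")]
  e1 <- blk_apply(params$enc$e1,
                  Map(function(i, j) c(h[i], h[j]), pairs$i, pairs$j))
  agg <- vapply(1:n, function(j) sum(e1[pairs$j == j]), 0)
  h2 <- blk_apply(params$enc$v1, as.list(agg))
  e2 <- blk_apply(params$enc$e2,
                  Map(function(k) c(h2[pairs$i[k]], h2[pairs$j[k]], e1[k]),
                      seq_len(nrow(pairs))))
  logits_hand <- outer(e2, as.vector(params$enc$out$W)) +
    rep(params$enc$out$b[1], each = length(e2))
  q_hand <- exp(logits_hand) / rowSums(exp(logits_hand))

  q <- nri_encode(xa, params, config)
  expect_equal(q$q, q_hand, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("permuting node order permutes the posterior (fixed weights)", {
  tm <- tiny_model(n_steps = 8, hidden = 6, seed = 4)
  x <- rand_features(n = 4, tt = 8, seed = 5)
  perm <- c(3, 1, 4, 2)                 # new node k is old node perm[k]
  q1 <- nri_encode(x, tm$params, tm$config)
  q2 <- nri_encode(x$x[perm, , , drop = FALSE], tm$params, tm$config)
  # new pair (a, b) corresponds to old pair (perm[a], perm[b])
  map <- match(paste(perm[q1$pairs$i], perm[q1$pairs$j]),
               paste(q1$pairs$i, q1$pairs$j))
  expect_equal(q2$q, q1$q[map, ], tolerance = 1e-10)
})

test_that("gumbel-softmax samples are normalized and sharpen as tau -> 0", {
  q <- rand_posterior(n = 3, K = 4, seed = 6)
  z <- nri_sample_edges(q, tau = 0.7, seed = 1)
  expect_equal(rowSums(z$z), rep(1, 6), tolerance = 1e-9)
  expect_true(all(z$z > 0 & z$z < 1))
  z0 <- nri_sample_edges(q, tau = 1e-6, seed = 2)
  expect_true(all(apply(z0$z, 1, max) > 0.999))
  expect_error(nri_sample_edges(q, tau = 0), "tau")
})

test_that("gumbel argmax frequencies match direct categorical sampling", {
  p <- c(0.7, 0.1, 0.1, 0.1)
  q <- matrix(p, 1, 4)
  n_draw <- 10000
  counts <- integer(4)
  for (s in seq_len(n_draw)) {
    z <- nri_sample_edges(q, tau = 0.1, seed = s)
    k <- which.max(z$z[1, ])
    counts[k] <- counts[k] + 1
  }
  freq <- counts / n_draw
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-9))
})

test_that("all-nonedge decoding is insensitive to other nodes", {
  tm <- tiny_model(n_steps = 6, hidden = 5, seed = 7)
  x <- rand_features(n = 3, tt = 6, seed = 8)
  z <- matrix(0, 6, 4); z[, 1] <- 1
  r1 <- nri_decode(x, z, tm$params, tm$config)
  x2 <- x$x
  x2[2, , ] <- x2[2, , ] + 5            # perturb a different node
  r2 <- nri_decode(x2, z, tm$params, tm$config)
  expect_equal(r2$mu[1, , ], r1$mu[1, , ], tolerance = 1e-12)
  expect_equal(r2$mu[3, , ], r1$mu[3, , ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r2$mu[2, , ], r1$mu[2, , ])))
})

test_that("zero output transform makes the decoder purely residual", {
  tm <- tiny_model(n_steps = 5, hidden = 4, seed = 9)
  tm$params$dec$out$W1[] <- 0
  tm$params$dec$out$b1[] <- 0
  tm$params$dec$out$W2[] <- 0
  tm$params$dec$out$b2[] <- 0
  x <- rand_features(n = 3, tt = 5, seed = 10)
  z <- matrix(0.25, 6, 4)
  r <- nri_decode(x, z, tm$params, tm$config, prediction_steps = 1)
  for (t in 1:4) expect_equal(r$mu[, t, ], x$x[, , , drop = FALSE][, t, ],
                              tolerance = 1e-12)
})

test_that("single decoder step matches a hand-evaluated recurrence", {
  # message-gated recurrence: every gate's hidden-path term is computed
  # from the aggregated incoming messages
  #   r = sig(W_ir x + b_ir + W_hr m + b_hr)
  #   u = sig(W_iu x + b_iu + W_hu m + b_hu)
  #   c = tanh(W_in x + b_in + r * (W_hn m + b_hn))
  #   h' = (1 - u) c + u h;  mu = x + f_out(h')
  config <- nri_config(hidden_dim = 2)
  params <- nri_init_params(config, 2, seed = 11)
  x <- rand_features(n = 2, tt = 2, seed = 12)
  z <- matrix(0, 2, 4); z[, 1] <- 1     # nonedge: aggregated message = 0
  r <- nri_decode(x, z, params, config, prediction_steps = 1)

  sig <- function(v) 1 / (1 + exp(-v))
  elu <- function(v) pmax(v, 0) + exp(pmin(v, 0)) - 1
  p <- params$dec$gru
  H <- 2
  for (node in 1:2) {
    xin <- x$x[node, 1, ]
    m0 <- rep(0, H)                     # no messages
    h0 <- rep(0, H)
    gi <- as.vector(xin %*% p$Wi) + as.vector(p$bi)
    gh <- as.vector(m0 %*% p$Wh) + as.vector(p$bh)
    rr <- sig(gi[1:H] + gh[1:H])
    uu <- sig(gi[(H + 1):(2 * H)] + gh[(H + 1):(2 * H)])
    cc <- tanh(gi[(2 * H + 1):(3 * H)] + rr * gh[(2 * H + 1):(3 * H)])
    h1 <- (1 - uu) * cc + uu * h0
    fo <- params$dec$out
    a1 <- elu(h1 %*% fo$W1 + as.vector(fo$b1))
    mu_hand <- xin + as.vector(a1 %*% fo$W2) + as.vector(fo$b2)
    expect_equal(r$mu[node, 1, ], mu_hand, tolerance = 1e-10)
  }
})

test_that("decode is permutation-equivariant (fixed weights)", {
  tm <- tiny_model(n_steps = 5, hidden = 4, seed = 13)
  x <- rand_features(n = 4, tt = 5, seed = 14)
  set.seed(15)
  q <- rand_posterior(n = 4, K = 4, seed = 15)
  z <- nri_sample_edges(q, tau = 0.5, seed = 16)$z
  perm <- c(2, 4, 3, 1)                 # new node k is old node perm[k]
  pairs <- ns$ordered_pairs(4)
  map <- match(paste(perm[pairs$i], perm[pairs$j]),
               paste(pairs$i, pairs$j))
  zp <- z[map, , drop = FALSE]          # new pair (a,b) = old (perm a, perm b)
  r1 <- nri_decode(x, z, tm$params, tm$config)
  r2 <- nri_decode(x$x[perm, , , drop = FALSE], zp, tm$params, tm$config)
  expect_equal(r2$mu, r1$mu[perm, , , drop = FALSE], tolerance = 1e-10)
})

test_that("reconstruction NLL equals the brute-force double loop", {
  x <- rand_features(n = 3, tt = 6, seed = 17)
  mu <- array(rnorm(3 * 5 * 6), c(3, 5, 6))
  recon <- structure(list(mu = mu, sigma2 = 0.3), class = "reconstruction")
  expect_equal(reconstruction_nll(x, recon, 0.3),
               sum(vapply(1:3, function(j) {
                 sum(vapply(2:6, function(t) {
                   sum((x$x[j, t, ] - mu[j, t - 1, ])^2)
                 }, 0))
               }, 0)) / (2 * 0.3), tolerance = 1e-10)
  # mu = x -> 0
  recon0 <- structure(list(mu = x$x[, -1, , drop = FALSE], sigma2 = 1),
                      class = "reconstruction")
  expect_equal(reconstruction_nll(x, recon0), 0)
  # single node, single step, scalar difference 1, sigma2 = 0.5 -> 1
  x1 <- array(0, c(1, 2, 6))
  mu1 <- array(0, c(1, 1, 6)); mu1[1, 1, 1] <- 1
  expect_equal(reconstruction_nll(x1,
                                  structure(list(mu = mu1, sigma2 = 0.5),
                                            class = "reconstruction")), 1)
  expect_error(reconstruction_nll(x, recon, -1), "sigma2")
})

test_that("KL divergence: closed forms and brute-force oracle", {
  prior <- c(0.91, 0.03, 0.03, 0.03)
  q <- rand_posterior(n = 4, K = 4, seed = 18)
  brute <- 0
  for (r in seq_len(nrow(q$q))) {
    for (k in 1:4) {
      if (q$q[r, k] > 0) brute <- brute + q$q[r, k] *
          log(q$q[r, k] / prior[k])
    }
  }
  expect_equal(kl_divergence(q, prior), brute, tolerance = 1e-10)
  # q = prior -> 0
  qp <- q; qp$q <- matrix(prior, nrow(q$q), 4, byrow = TRUE)
  expect_equal(kl_divergence(qp, prior), 0, tolerance = 1e-12)
  # one-hot under uniform prior, one pair -> log 4
  q1 <- structure(list(q = matrix(c(1, 0, 0, 0), 1, 4),
                       pairs = data.frame(i = 1, j = 2), n_nodes = 2),
                  class = "edge_posterior")
  expect_equal(kl_divergence(q1, rep(0.25, 4)), log(4), tolerance = 1e-12)
  # uniform prior equals sum(log K - H(q))
  H <- -rowSums(q$q * log(q$q))
  expect_equal(kl_divergence(q, rep(0.25, 4)), sum(log(4) - H),
               tolerance = 1e-10)
  expect_error(kl_divergence(q, c(1, 0, 0, 0)), "zero mass")
})

test_that("elbo loss is the sum of its two components", {
  tm <- tiny_model(n_steps = 5, hidden = 4, seed = 19)
  x <- rand_features(n = 3, tt = 5, seed = 20)
  q <- nri_encode(x, tm$params, tm$config)
  z <- nri_sample_edges(q, 0.5, seed = 21)
  recon <- nri_decode(x, z, tm$params, tm$config)
  expect_equal(elbo_loss(x, recon, q, tm$config),
               reconstruction_nll(x, recon, tm$config$sigma2) +
                 kl_divergence(q, tm$config$prior), tolerance = 1e-12)
  # changing only q leaves the reconstruction term unchanged
  q2 <- q; q2$q <- matrix(0.25, nrow(q$q), 4)
  expect_equal(elbo_loss(x, recon, q2, tm$config) -
                 kl_divergence(q2, tm$config$prior),
               elbo_loss(x, recon, q, tm$config) -
                 kl_divergence(q, tm$config$prior), tolerance = 1e-10)
  # perfect reconstruction and q = prior -> 0
  recon0 <- structure(list(mu = x$x[, -1, , drop = FALSE],
                           sigma2 = tm$config$sigma2),
                      class = "reconstruction")
  qp <- q; qp$q <- matrix(tm$config$prior, nrow(q$q), 4, byrow = TRUE)
  expect_equal(elbo_loss(x, recon0, qp, tm$config), 0, tolerance = 1e-10)
})

test_that("loss gradient reaches encoder weights through the Gumbel path", {
  config <- nri_config(hidden_dim = 4)
  params <- nri_init_params(config, 6, seed = 22)
  pn <- list(enc = params$enc, dec = params$dec)
  set.seed(23)
  xb <- array(rnorm(2 * 3 * 6 * 6, sd = 0.5), c(2, 3, 6, 6))
  set.seed(24)
  fwd <- ns$nri_batch_loss(xb, pn, config, TRUE)
  ns$ag_backward(fwd$tape, fwd$loss)
  g <- ns$unlist_mats(ns$collect_grads(fwd$bound))
  enc_norm <- sum(vapply(g[grep("^enc", names(g))],
                         function(m) sum(abs(m)), 0))
  expect_gt(enc_norm, 0)
})

test_that("checkpoint round-trips parameters, config and normalization", {
  tm <- tiny_model(n_steps = 5, hidden = 3, seed = 25)
  fit <- structure(list(params = tm$params, log = NULL,
                        config = tm$config, best_epoch = 3L, seed = 1L,
                        normalization = list(center = c(1, 2, 3),
                                             scale = 4.5),
                        dt = 0.1, node_labels = c("A", "B", "C")),
                   class = "nri_fit")
  path <- tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$params$enc, tm$params$enc, tolerance = 1e-12)
  expect_equal(back$params$dec, tm$params$dec, tolerance = 1e-12)
  expect_equal(back$config$prior, tm$config$prior)
  expect_equal(back$normalization$scale, 4.5)
  x <- rand_features(n = 3, tt = 5, seed = 26)
  expect_equal(nri_encode(x, back$params, back$config)$q,
               nri_encode(x, tm$params, tm$config)$q, tolerance = 1e-12)
})
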