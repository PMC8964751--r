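# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in forward order; ag_backward() walks the tape in
# reverse, accumulating gradients.  Every value is a numeric matrix (scalars
# are 1x1).  Nodes track whether any ancestor is a trainable parameter so
# that gradient work is skipped for pure-data subgraphs.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = list(), backward = NULL,
                    track = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (is.null(track)) {
    track <- FALSE
    for (p in parents) if (isTRUE(p$track)) { track <- TRUE; break }
  }
  nd$track <- track
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

# Trainable leaf: gradients are accumulated into it.
ag_param <- function(tape, value) {
  ag_node(tape, as.matrix(value), track = TRUE)
}

# Data leaf: no gradient is ever requested for it.
ag_const <- function(tape, value) {
  ag_node(tape, as.matrix(value), track = FALSE)
}

ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || !isTRUE(nd$track)) next
    if (is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!isTRUE(p$track) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    # free intermediate gradients (keep leaves for the optimizer)
    if (length(ps) > 0L) nd$grad <- NULL
  }
  invisible(NULL)
}

ag_matmul <- function(tape, a, b) {
  ag_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(if (isTRUE(a$track)) g %*% t(b$value) else NULL,
         if (isTRUE(b$track)) crossprod(a$value, g) else NULL)
  })
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ag_sub <- function(tape, a, b) {
  ag_node(tape, a$value - b$value, list(a, b),
          function(g) list(g, -g))
}

ag_mul <- function(tape, a, b) {
  ag_node(tape, a$value * b$value, list(a, b), function(g) {
    list(if (isTRUE(a$track)) g * b$value else NULL,
         if (isTRUE(b$track)) g * a$value else NULL)
  })
}

# matrix + row vector (bias) broadcast over rows
ag_add_bias <- function(tape, a, bias) {
  v <- a$value
  v <- sweep(v, 2L, as.vector(bias$value), "+")
  ag_node(tape, v, list(a, bias), function(g) {
    list(g,
         if (isTRUE(bias$track)) matrix(colSums(g), 1L) else NULL)
  })
}

ag_add_const <- function(tape, a, k) {
  ag_node(tape, a$value + k, list(a), function(g) list(g))
}

ag_mul_const <- function(tape, a, k) {
  ag_node(tape, a$value * k, list(a), function(g) list(g * k))
}

# value = k - a
ag_rsub_const <- function(tape, a, k) {
  ag_node(tape, k - a$value, list(a), function(g) list(-g))
}

# scale each row of a (n x m) by the matching entry of s (n x 1)
ag_scale_rows <- function(tape, a, s) {
  sv <- as.vector(s$value)
  ag_node(tape, a$value * sv, list(a, s), function(g) {
    list(if (isTRUE(a$track)) g * sv else NULL,
         if (isTRUE(s$track)) matrix(rowSums(g * a$value), ncol = 1L)
         else NULL)
  })
}

ag_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ag_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ag_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ag_node(tape, v, list(a), function(g) list(g * (1 - v * v)))
}

ag_elu <- function(tape, a) {
  x <- a$value
  epm <- exp(pmin(x, 0))               # slope; 1 where x > 0
  v <- pmax(x, 0) + epm - 1
  ag_node(tape, v, list(a), function(g) list(g * epm))
}

# natural log with clamping away from zero (inputs are probabilities)
ag_log <- function(tape, a, eps = 1e-12) {
  x <- pmax(a$value, eps)
  ag_node(tape, log(x), list(a), function(g) list(g / x))
}

# select rows (gather); backward scatter-adds
ag_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  nr <- nrow(a$value)
  ag_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nr, ncol(g))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# sum rows of a by integer group 1..ngroups (scatter-add); backward gathers
ag_rowsum <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  rs <- rowsum(a$value, group = group)
  v <- matrix(0, ngroups, ncol(a$value))
  v[as.integer(rownames(rs)), ] <- rs
  ag_node(tape, v, list(a), function(g) {
    list(g[group, , drop = FALSE])
  })
}

ag_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ag_node(tape, cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

# select columns; backward scatters into zero matrix
ag_cols <- function(tape, a, idx) {
  idx <- as.integer(idx)
  nc <- ncol(a$value)
  ag_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- g
    list(out)
  })
}

# row-wise softmax
ag_softmax_rows <- function(tape, a) {
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  v <- e / rowSums(e)
  ag_node(tape, v, list(a), function(g) {
    list(v * (g - rowSums(g * v)))
  })
}

ag_sum <- function(tape, a) {
  dims <- dim(a$value)
  ag_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}
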