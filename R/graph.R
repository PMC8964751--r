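#' Collapse an edge-type posterior into a directed interaction matrix
#'
#' The default rule `prob_any_edge` sets `w_ij = 1 - q_ij(nonedge)`, i.e.
#' the posterior probability that any non-null interaction type connects
#' i to j; this is additive over the non-null types and keeps weights in
#' `[0, 1]`.  `max_type` keeps the probability of the most likely type
#' when it is not the nonedge (0 otherwise); `per_type` extracts one
#' type's probability.
#'
#' @param q an `edge_posterior` from [nri_encode()] or [evaluate_nri()].
#' @param rule weight rule.
#' @param type edge type (2..K) for `rule = "per_type"`.
#' @return an `interaction_matrix`: list with `w` (N x N, zero diagonal,
#'   directed: `w[i, j]` is the weight of i -> j), `n_nodes`, `rule`.
#' @export
edge_weight_matrix <- function(q, rule = c("prob_any_edge", "max_type",
                                           "per_type"), type = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(q, "edge_posterior"))
  n <- q$n_nodes
  wvec <- switch(rule,
    prob_any_edge = 1 - q$q[, 1L],
    max_type = {
      mx <- max.col(q$q, ties.method = "first")
      ifelse(mx == 1L, 0, q$q[cbind(seq_len(nrow(q$q)), mx)])
    },
    per_type = {
      if (is.null(type) || type < 2L || type > ncol(q$q)) {
        stop("per_type rule needs a non-null edge type in 2..K")
      }
      q$q[, type]
    })
  w <- matrix(0, n, n)
  w[cbind(q$pairs$i, q$pairs$j)] <- wvec
  interaction_matrix(w, rule = rule)
}

#' Interaction-matrix container
#'
#' @param w N x N numeric matrix of directed pair weights (diagonal
#'   forced to zero).
#' @param rule provenance string.
#' @return an `interaction_matrix`.
#' @export
interaction_matrix <- function(w, rule = "manual") {
  w <- as.matrix(w)
  stopifnot(nrow(w) == ncol(w), all(is.finite(w)))
  diag(w) <- 0
  structure(list(w = w, n_nodes = nrow(w), rule = rule),
            class = "interaction_matrix")
}

#' Residue-to-domain (block) assignment
#'
#' @param blocks vector of block labels, one per node (e.g. "WW",
#'   "Cat. loop", "PPIase core").
#' @return a `domain_map`.
#' @export
domain_map <- function(blocks) {
  stopifnot(length(blocks) >= 1L, !anyNA(blocks))
  structure(list(blocks = as.character(blocks),
                 levels = unique(as.character(blocks))),
            class = "domain_map")
}

#' Aggregate an interaction matrix over domain blocks
#'
#' Block weight = sum (default) or mean of member-pair weights, for every
#' ordered block pair including within-block.  With `stat = "sum"` the
#' total weight is conserved.
#'
#' @param m an [interaction_matrix()].
#' @param dm a [domain_map()] covering all nodes.
#' @param stat `"sum"` or `"mean"`.
#' @return a `block_matrix`: list with `b` (directed block x block
#'   matrix), `levels`, `sizes`, `stat`.
#' @export
aggregate_blocks <- function(m, dm, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(m, "interaction_matrix"), inherits(dm, "domain_map"))
  if (length(dm$blocks) != m$n_nodes) {
    missing <- if (length(dm$blocks) < m$n_nodes) {
      (length(dm$blocks) + 1L):m$n_nodes
    } else integer()
    stop("domain map covers ", length(dm$blocks), " nodes but the matrix ",
         "has ", m$n_nodes,
         if (length(missing)) paste0("; node(s) without a block: ",
                                     paste(missing, collapse = ", ")))
  }
  lev <- dm$levels
  idx <- match(dm$blocks, lev)
  nb <- length(lev)
  b <- matrix(0, nb, nb, dimnames = list(lev, lev))
  cnt <- matrix(0, nb, nb)
  for (i in seq_len(m$n_nodes)) {
    for (j in seq_len(m$n_nodes)) {
      if (i == j) next
      b[idx[i], idx[j]] <- b[idx[i], idx[j]] + m$w[i, j]
      cnt[idx[i], idx[j]] <- cnt[idx[i], idx[j]] + 1
    }
  }
  if (stat == "mean") b <- ifelse(cnt > 0, b / cnt, 0)
  structure(list(b = b, levels = lev, sizes = as.vector(table(idx)),
                 stat = stat),
            class = "block_matrix")
}

#' Per-node degree and summed incident weight
#'
#' Degree counts incident edges (incoming + outgoing) with weight at or
#' above the threshold; strength sums all incident weights.  This is the
#' quantity drawn as node size in interaction-graph figures.
#'
#' @param m an [interaction_matrix()].
#' @param threshold weight threshold in `[0, 1]` for degree counting.
#' @return data.frame with columns `node`, `degree`, `strength`.
#' @export
node_weights <- function(m, threshold = 0.5) {
  stopifnot(inherits(m, "interaction_matrix"),
            threshold >= 0, threshold <= 1)
  w <- m$w
  keep <- w >= threshold
  diag(keep) <- FALSE
  data.frame(node = seq_len(m$n_nodes),
             degree = rowSums(keep) + colSums(keep),
             strength = rowSums(w) + colSums(w))
}

#' Write an interaction matrix as a TSV edge list
#'
#' Columns `i  j  weight`, one row per ordered pair with nonzero weight.
#'
#' @param m an [interaction_matrix()].
#' @param path output file.
#' @param all write zero-weight pairs too.
#' @export
write_interaction_matrix <- function(m, path, all = FALSE) {
  pr <- ordered_pairs(m$n_nodes)
  df <- data.frame(i = pr$i, j = pr$j, weight = m$w[cbind(pr$i, pr$j)])
  if (!all) df <- df[df$weight > 0, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
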