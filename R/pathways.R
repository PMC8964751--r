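#' Build a weighted path graph from an interaction matrix
#'
#' Edges with weight at or above the retention threshold become graph
#' edges with traversal cost `-log(w)` (default) or `1/w`, so stronger
#' interactions are cheaper to traverse.  Under `neg_log` a path's total
#' cost is the negative log of the product of its edge weights, i.e. the
#' minimum-cost path is the most probable interaction chain.
#'
#' @param m an [interaction_matrix()].
#' @param retain_threshold minimum weight for an edge to be kept, in
#'   (0, 1).
#' @param cost_transform `"neg_log"` or `"reciprocal"`.
#' @param directed traverse ordered edges as stored (default); if FALSE
#'   the matrix is symmetrized first with `max(w_ij, w_ji)`.
#' @return a `path_graph`: list with the igraph `graph` (edge attribute
#'   `cost`, vertex count = N), `cost_transform`, `retain_threshold`,
#'   `directed`.
#' @export
build_path_graph <- function(m, retain_threshold = 0.5,
                             cost_transform = c("neg_log", "reciprocal"),
                             directed = TRUE) {
  cost_transform <- match.arg(cost_transform)
  stopifnot(inherits(m, "interaction_matrix"),
            retain_threshold > 0, retain_threshold < 1)
  w <- m$w
  if (!directed) {
    w <- pmax(w, t(w))
  }
  keep <- which(w >= retain_threshold & row(w) != col(w), arr.ind = TRUE)
  if (!directed) keep <- keep[keep[, 1L] < keep[, 2L], , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("retention threshold ", retain_threshold,
            " removed every edge; path graph is empty")
  }
  ww <- w[keep]
  cost <- switch(cost_transform, neg_log = -log(ww), reciprocal = 1 / ww)
  g <- igraph::make_empty_graph(n = m$n_nodes, directed = directed)
  if (nrow(keep) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(keep)))
    igraph::E(g)$cost <- cost
    igraph::E(g)$weight <- ww
  }
  structure(list(graph = g, cost_transform = cost_transform,
                 retain_threshold = retain_threshold,
                 directed = directed, n_nodes = m$n_nodes),
            class = "path_graph")
}

#' Shortest and suboptimal source-to-sink pathways
#'
#' For every source-sink pair, the k lowest-cost loopless (simple) paths
#' over the path graph (k = 1 is the classic shortest path); Yen-style
#' semantics via igraph.  Equal-cost paths are ordered lexicographically
#' by node sequence for reproducibility.  Pairs with no path yield an
#' empty entry.
#'
#' @param g a [build_path_graph()] result.
#' @param sources,sinks node index vectors (non-empty, disjoint).
#' @param k paths per source-sink pair.
#' @return a `path_set`: list with `paths` (list of lists with `nodes`,
#'   `cost`, `source`, `sink`), `sources`, `sinks`, `k`.
#' @export
find_pathways <- function(g, sources, sinks, k = 1L) {
  stopifnot(inherits(g, "path_graph"), length(sources) > 0L,
            length(sinks) > 0L, k >= 1L)
  sources <- as.integer(sources); sinks <- as.integer(sinks)
  bad <- setdiff(c(sources, sinks), seq_len(g$n_nodes))
  if (length(bad) > 0L) {
    stop("unknown node(s) in sources/sinks: ", paste(bad, collapse = ", "))
  }
  if (length(intersect(sources, sinks)) > 0L) {
    stop("sources and sinks must be disjoint")
  }
  paths <- list()
  for (s in sources) {
    for (t in sinks) {
      res <- tryCatch(
        igraph::k_shortest_paths(g$graph, from = s, to = t, k = k,
                                 weights = igraph::E(g$graph)$cost),
        error = function(e) list(vpaths = list()))
      for (vp in res$vpaths) {
        nodes <- as.integer(vp)
        cost <- path_cost(g, nodes)
        paths[[length(paths) + 1L]] <- list(nodes = nodes, cost = cost,
                                            source = s, sink = t)
      }
    }
  }
  # within each pair: order by cost, ties broken lexicographically
  if (length(paths) > 0L) {
    key <- vapply(paths, function(p) paste(p$source, p$sink), "")
    ord <- order(key,
                 vapply(paths, function(p) p$cost, 0),
                 vapply(paths, function(p)
                   paste(formatC(p$nodes, width = 6, flag = "0"),
                         collapse = "-"), ""))
    paths <- paths[ord]
  }
  structure(list(paths = paths, sources = sources, sinks = sinks,
                 k = as.integer(k)),
            class = "path_set")
}

# total cost of a node sequence over the path graph
path_cost <- function(g, nodes) {
  if (length(nodes) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(nodes) - 1L)) {
    eid <- igraph::get_edge_ids(g$graph, c(nodes[i], nodes[i + 1L]))
    if (eid == 0) stop("path traverses a non-existent edge ",
                       nodes[i], " -> ", nodes[i + 1L])
    total <- total + igraph::E(g$graph)$cost[eid]
  }
  total
}

#' How often each node appears on the extracted pathways
#'
#' The per-residue path frequency is a simple importance measure: nodes
#' that sit on many source-to-sink routes mediate more of the
#' communication.
#'
#' @param ps a `path_set` from [find_pathways()].
#' @param n_nodes total node count (defaults to the largest node seen).
#' @param include_endpoints count sources/sinks too (default TRUE).
#' @return integer vector: number of paths containing each node.
#' @export
path_residue_frequency <- function(ps, n_nodes = NULL,
                                   include_endpoints = TRUE) {
  stopifnot(inherits(ps, "path_set"))
  if (is.null(n_nodes)) {
    n_nodes <- max(c(1L, unlist(lapply(ps$paths, `[[`, "nodes")),
                     ps$sources, ps$sinks))
  }
  counts <- integer(n_nodes)
  for (p in ps$paths) {
    nodes <- p$nodes
    if (!include_endpoints && length(nodes) > 2L) {
      nodes <- nodes[-c(1L, length(nodes))]
    } else if (!include_endpoints) {
      nodes <- integer()
    }
    counts[unique(nodes)] <- counts[unique(nodes)] + 1L
  }
  counts
}

#' Betweenness centrality of nodes on the path graph
#'
#' Fraction of all-pairs shortest paths (by traversal cost) passing
#' through each node, normalized to `[0, 1]`.
#'
#' @param g a [build_path_graph()] result with at least one edge.
#' @return numeric vector of length N.
#' @export
node_centrality <- function(g) {
  stopifnot(inherits(g, "path_graph"))
  if (igraph::ecount(g$graph) == 0L) stop("path graph has no edges")
  igraph::betweenness(g$graph, directed = g$directed,
                      weights = igraph::E(g$graph)$cost,
                      normalized = TRUE)
}

#' Write a path set as JSON
#'
#' Paths as node arrays with their costs, plus sources/sinks/k.
#'
#' @param ps a `path_set`.
#' @param path output file.
#' @export
write_path_set <- function(ps, path) {
  out <- list(sources = ps$sources, sinks = ps$sinks, k = ps$k,
              paths = lapply(ps$paths, function(p) {
                list(nodes = p$nodes, cost = p$cost,
                     source = p$source, sink = p$sink)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
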