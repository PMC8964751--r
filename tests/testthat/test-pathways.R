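# Path graph construction, k-shortest pathways, frequencies, centrality —
# all pinned to brute-force enumeration on small graphs.

test_that("cost transforms are correct and monotone", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 1; w[2, 3] <- 0.5; w[1, 3] <- 0.25
  g <- build_path_graph(interaction_matrix(w), retain_threshold = 0.2)
  costs <- igraph::E(g$graph)$cost
  ww <- igraph::E(g$graph)$weight
  expect_equal(costs[ww == 1], 0)
  expect_equal(costs[ww == 0.5], log(2), tolerance = 1e-12)
  grec <- build_path_graph(interaction_matrix(w), 0.2, "reciprocal")
  expect_equal(igraph::E(grec$graph)$cost,
               1 / igraph::E(grec$graph)$weight)
  # monotone: stronger edge -> cheaper, over random matrices
  set.seed(1)
  for (rep in 1:5) {
    m <- rand_interaction(n = 5, seed = rep)
    g <- build_path_graph(m, retain_threshold = 0.3)
    ord <- order(igraph::E(g$graph)$weight)
    expect_true(all(diff(igraph::E(g$graph)$cost[ord]) <= 1e-12))
  }
  expect_warning(build_path_graph(interaction_matrix(matrix(0, 3, 3)),
                                  0.5), "every edge")
})

test_that("simple chains and disconnected sinks behave", {
  w <- matrix(0, 3, 3); w[1, 2] <- 0.9; w[2, 3] <- 0.8
  g <- build_path_graph(interaction_matrix(w), 0.5)
  ps <- find_pathways(g, sources = 1, sinks = 3, k = 1)
  expect_length(ps$paths, 1)
  expect_equal(ps$paths[[1]]$nodes, c(1, 2, 3))
  # disconnected sink -> empty
  w4 <- matrix(0, 4, 4); w4[1, 2] <- 0.9
  g4 <- build_path_graph(interaction_matrix(w4), 0.5)
  expect_length(find_pathways(g4, 1, 4, k = 2)$paths, 0)
  expect_error(find_pathways(g, sources = 1, sinks = 9), "unknown node")
  expect_error(find_pathways(g, sources = 1, sinks = 1), "disjoint")
})

test_that("k shortest loopless paths match exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    w <- matrix(runif(n * n), n, n); diag(w) <- 0
    w[w < 0.35] <- 0                   # sparsify
    m <- interaction_matrix(w)
    g <- build_path_graph(m, retain_threshold = 0.35)
    cost <- ifelse(w >= 0.35, -log(w), NA)
    from <- 1; to <- n
    brute <- enumerate_paths(cost, from, to)
    for (k in c(1, 3)) {
      ps <- find_pathways(g, from, to, k = k)
      expect_length(ps$paths, min(k, length(brute)))
      for (i in seq_along(ps$paths)) {
        expect_equal(ps$paths[[i]]$cost, brute[[i]]$cost,
                     tolerance = 1e-9,
                     label = sprintf("rep %d k %d path %d", rep, k, i))
      }
      if (length(ps$paths) > 0) {
        expect_equal(ps$paths[[1]]$nodes, brute[[1]]$nodes)
      }
    }
    # k = 1 cost lower-bounds every k > 1 cost
    ps3 <- find_pathways(g, from, to, k = 3)
    if (length(ps3$paths) > 1) {
      costs <- vapply(ps3$paths, `[[`, 0, "cost")
      expect_true(all(diff(costs) >= -1e-12))
    }
  }
})

test_that("adding an edge never increases a shortest-path cost", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 5
    w <- matrix(runif(n * n, 0.4, 0.9), n, n); diag(w) <- 0
    drop <- sample(which(row(w) != col(w)), 10)
    w2 <- w; w2[drop] <- 0
    g_less <- build_path_graph(interaction_matrix(w2), 0.3)
    g_more <- build_path_graph(interaction_matrix(w), 0.3)
    for (s in 1:2) for (t in (n - 1):n) {
      if (s == t) next
      p1 <- find_pathways(g_less, s, t, 1)$paths
      p2 <- find_pathways(g_more, s, t, 1)$paths
      if (length(p1) > 0) {
        expect_true(length(p2) > 0)
        expect_lte(p2[[1]]$cost, p1[[1]]$cost + 1e-12)
      }
    }
  }
})

test_that("residue path frequency matches naive membership counting", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[2, 3] <- 0.9; w[1, 3] <- 0.6; w[3, 4] <- 0.9
  g <- build_path_graph(interaction_matrix(w), 0.5)
  ps <- find_pathways(g, 1, 4, k = 3)
  freq <- path_residue_frequency(ps, n_nodes = 4)
  brute <- integer(4)
  for (p in ps$paths) brute[p$nodes] <- brute[p$nodes] + 1L
  expect_equal(freq, brute)
  # single path (1,2,3): all count once, absent node zero
  ps1 <- find_pathways(build_path_graph(interaction_matrix(
    matrix(c(0, 0.9, 0, 0, 0, 0.9, 0, 0, 0), 3, 3, byrow = TRUE)), 0.5),
    1, 3, 1)
  expect_equal(path_residue_frequency(ps1, n_nodes = 3), c(1L, 1L, 1L))
  # endpoints excluded on request
  expect_equal(path_residue_frequency(ps1, n_nodes = 3,
                                      include_endpoints = FALSE),
               c(0L, 1L, 0L))
})

test_that("betweenness equals the brute-force all-pairs count", {
  # middle of a 3-chain is the only nonzero centrality
  w <- matrix(0, 3, 3); w[1, 2] <- 0.9; w[2, 3] <- 0.9
  g <- build_path_graph(interaction_matrix(w), 0.5)
  cen <- node_centrality(g)
  expect_gt(cen[2], 0)
  expect_equal(cen[c(1, 3)], c(0, 0))
  # complete graph with equal costs: all equal
  we <- matrix(0.8, 4, 4); diag(we) <- 0
  ge <- build_path_graph(interaction_matrix(we), 0.5)
  cene <- node_centrality(ge)
  expect_equal(max(cene) - min(cene), 0, tolerance = 1e-12)
  # random graphs against a naive Brandes-free oracle
  set.seed(13)
  for (rep in 1:4) {
    n <- 5
    w <- matrix(runif(n * n), n, n); diag(w) <- 0
    w[w < 0.4] <- 0
    g <- build_path_graph(interaction_matrix(w), 0.4)
    cost <- ifelse(w >= 0.4, -log(w), NA)
    brute <- numeric(n)
    for (s in 1:n) for (t in 1:n) {
      if (s == t) next
      paths <- enumerate_paths(cost, s, t)
      if (length(paths) == 0) next
      best <- min(vapply(paths, `[[`, 0, "cost"))
      shortest <- Filter(function(p) p$cost <= best + 1e-9, paths)
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p$nodes, TRUE))
        brute[v] <- brute[v] + through / length(shortest)
      }
    }
    brute <- brute / ((n - 1) * (n - 2))   # directed normalization
    expect_equal(node_centrality(g), brute, tolerance = 1e-9,
                 label = paste("rep", rep))
  }
})

test_that("path sets serialize to JSON with costs", {
  w <- matrix(0, 3, 3); w[1, 2] <- 0.9; w[2, 3] <- 0.9
  g <- build_path_graph(interaction_matrix(w), 0.5)
  ps <- find_pathways(g, 1, 3, 1)
  tf <- tempfile(fileext = ".json")
  write_path_set(ps, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$paths$nodes[[1]], c(1, 2, 3))
  expect_equal(back$paths$cost, -log(0.9) * 2, tolerance = 1e-9)
})
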