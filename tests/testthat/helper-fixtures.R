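# Shared fixtures, all built in code.

ns <- asNamespace("nridyn")

# a tiny random feature tensor
rand_features <- function(n = 3, tt = 8, seed = 1, dt = 0.5) {
  set.seed(seed)
  feature_tensor(array(rnorm(n * tt * 6), c(n, tt, 6)), dt = dt)
}

# a random edge posterior over n nodes with K types
rand_posterior <- function(n = 4, K = 4, seed = 1) {
  set.seed(seed)
  e <- n * (n - 1)
  q <- matrix(rexp(e * K), e, K)
  q <- q / rowSums(q)
  structure(list(q = q, pairs = ns$ordered_pairs(n), n_nodes = n),
            class = "edge_posterior")
}

# a random interaction matrix with weights in [0, 1]
rand_interaction <- function(n = 5, seed = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  diag(w) <- 0
  interaction_matrix(w)
}

# minimal multi-model PDB text for a poly-GLY peptide
write_test_pdb <- function(path, n_res = 3, n_models = 2,
                           drop_ca = NULL) {
  # drop_ca: optional list(residue =, model =) to omit one C-alpha
  lines <- character()
  atom_line <- function(serial, name, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, resno, x, y, z, substr(name, 1, 1))
  }
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0
    for (r in seq_len(n_res)) {
      skip_ca <- !is.null(drop_ca) && drop_ca$residue == r &&
        drop_ca$model == m
      serial <- serial + 1
      lines <- c(lines, atom_line(serial, "N", r, r * 3, m, 0))
      if (!skip_ca) {
        serial <- serial + 1
        lines <- c(lines, atom_line(serial, "CA", r, r * 3 + 1, m, 0.5))
      }
      serial <- serial + 1
      lines <- c(lines, atom_line(serial, "C", r, r * 3 + 2, m, 1))
    }
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

# small trained-ish parameter set (random init is fine for shape tests)
tiny_model <- function(n_steps = 6, hidden = 4, seed = 2) {
  config <- nri_config(hidden_dim = hidden)
  list(config = config,
       params = nri_init_params(config, n_steps, seed = seed))
}

# brute-force enumeration of all simple paths between two nodes on a
# small directed cost matrix (NA = no edge); returns list(nodes, cost)
enumerate_paths <- function(cost, from, to) {
  n <- nrow(cost)
  out <- list()
  recurse <- function(path, total) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- list(nodes = path, cost = total)
      return()
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% path || is.na(cost[last, nxt])) next
      recurse(c(path, nxt), total + cost[last, nxt])
    }
  }
  recurse(from, 0)
  out[order(vapply(out, `[[`, 0, "cost"),
            vapply(out, function(p) paste(formatC(p$nodes, width = 6,
                                                  flag = "0"),
                                          collapse = "-"), ""))]
}
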