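#' Simulation configuration for the spring-system generator
#'
#' Defines a toy interacting-particle system: point masses coupled by
#' Hookean springs on a random undirected graph, integrated with the
#' velocity-Verlet (leapfrog) scheme.  Units are abstract (length, time
#' and mass all default to 1), so MD-style units (Angstrom, ns) map onto
#' them directly.
#'
#' @param n_nodes number of particles (>= 2).
#' @param edge_probability probability that an unordered pair is coupled.
#' @param spring_constant coupling constant k for every sampled spring.
#' @param mass particle mass.
#' @param dt integration time step (> 0).
#' @param n_steps number of stored frames (>= 2).
#' @param noise_scale standard deviation of additive Gaussian observation
#'   noise applied to stored positions after integration (0 = noiseless).
#' @param seed integer seed; fully determines the output.
#' @param box_half_width half-width of the uniform box initial positions
#'   are drawn from.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_nodes = 5L, edge_probability = 0.5,
                       spring_constant = 1, mass = 1, dt = 0.01,
                       n_steps = 1000L, noise_scale = 0, seed = 1L,
                       box_half_width = 1) {
  stopifnot(n_nodes >= 2L, dt > 0, n_steps >= 2L,
            edge_probability >= 0, edge_probability <= 1,
            spring_constant >= 0, mass > 0, noise_scale >= 0,
            box_half_width > 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 edge_probability = edge_probability,
                 spring_constant = spring_constant, mass = mass,
                 dt = dt, n_steps = as.integer(n_steps),
                 noise_scale = noise_scale, seed = as.integer(seed),
                 box_half_width = box_half_width),
            class = "sim_config")
}

#' Ground-truth interaction graph
#'
#' @param n_nodes node count.
#' @param edges data.frame with columns `i`, `j` (1-based node indices,
#'   i != j) and `k` (coupling constant >= 0).  Undirected: each coupled
#'   pair appears once with i < j.
#' @return a `ground_truth_graph`.
#' @export
ground_truth_graph <- function(n_nodes, edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(i = integer(), j = integer(), k = numeric())
  }
  stopifnot(all(c("i", "j", "k") %in% names(edges)),
            all(edges$i != edges$j),
            all(edges$i >= 1L), all(edges$j >= 1L),
            all(edges$i <= n_nodes), all(edges$j <= n_nodes),
            all(is.finite(edges$k)), all(edges$k >= 0))
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "ground_truth_graph")
}

# logical adjacency matrix of a ground-truth graph (symmetric)
adjacency <- function(graph) {
  a <- matrix(FALSE, graph$n_nodes, graph$n_nodes)
  if (nrow(graph$edges) > 0L) {
    a[cbind(graph$edges$i, graph$edges$j)] <- TRUE
    a[cbind(graph$edges$j, graph$edges$i)] <- TRUE
  }
  a
}

# Spring force field: F_i = -sum_j k_ij * f(x_i - x_j) with either zero
# rest length (linear) or rest length r0 (radial).
spring_forces <- function(pos, kmat, rest_length = 0) {
  n <- nrow(pos)
  if (rest_length == 0) {
    # linear springs: F_i = sum_j k_ij (x_j - x_i)
    return(kmat %*% pos - pos * rowSums(kmat))
  }
  # radial springs with rest length r0: the effective coupling of pair
  # (i, j) is k_ij (|d| - r0) / |d|, applied along d = x_j - x_i
  dd <- as.matrix(stats::dist(pos))
  s <- matrix(0, n, n)
  nz <- kmat > 0 & dd > 1e-12
  s[nz] <- kmat[nz] * (dd[nz] - rest_length) / dd[nz]
  s %*% pos - pos * rowSums(s)
}

# Velocity-Verlet integration of n_steps frames (including the initial
# state).  driven: optional list(node, fun) prescribing one node's
# position as a function of time.
integrate_springs <- function(x0, v0, kmat, config, rest_length = 0,
                              driven = NULL) {
  n <- nrow(x0)
  n_steps <- config$n_steps
  dt <- config$dt
  m <- config$mass
  pos <- array(0, c(n, n_steps, 3L))
  vel <- array(0, c(n, n_steps, 3L))
  x <- x0; v <- v0
  if (!is.null(driven)) {
    x[driven$node, ] <- driven$fun(0)
    v[driven$node, ] <- 0
  }
  pos[, 1L, ] <- x; vel[, 1L, ] <- v
  a <- spring_forces(x, kmat, rest_length) / m
  for (t in seq_len(n_steps - 1L)) {
    x <- x + v * dt + 0.5 * a * dt^2
    if (!is.null(driven)) {
      xd <- driven$fun(t * dt)
      x[driven$node, ] <- xd
    }
    a_new <- spring_forces(x, kmat, rest_length) / m
    v <- v + 0.5 * (a + a_new) * dt
    if (!is.null(driven)) {
      # finite-difference velocity of the prescribed node
      v[driven$node, ] <- (xd - pos[driven$node, t, ]) / dt
    }
    a <- a_new
    if (!all(is.finite(x))) {
      stop("integration failure: non-finite coordinates at step ", t + 1L,
           " (time step dt too large for the stiffest spring)")
    }
    pos[, t + 1L, ] <- x
    vel[, t + 1L, ] <- v
  }
  list(pos = pos, vel = vel)
}

sim_output <- function(res, graph, config) {
  pos_obs <- res$pos
  if (config$noise_scale > 0) {
    pos_obs <- pos_obs + array(stats::rnorm(length(pos_obs), 0,
                                            config$noise_scale),
                               dim = dim(pos_obs))
  }
  x <- array(0, c(dim(res$pos)[1L], config$n_steps, 6L))
  x[, , 1:3] <- pos_obs
  x[, , 4:6] <- res$vel
  features <- feature_tensor(x, dt = config$dt)
  trajectory <- raw_trajectory(pos_obs, frame_interval = config$dt)
  list(features = features, trajectory = trajectory, graph = graph)
}

#' Simulate spring-coupled particles on a random graph
#'
#' Draws an undirected Erdos-Renyi graph over `n_nodes` particles, couples
#' every sampled pair with a zero-rest-length Hookean spring of constant
#' `spring_constant`, and integrates Newtonian dynamics with
#' velocity-Verlet.  The ground-truth graph is returned alongside the
#' trajectory so that interaction-recovery can be scored exactly.
#'
#' @param config a [sim_config()].
#' @return list with `features` (a [feature_tensor()] holding positions and
#'   the integrator's true velocities), `trajectory` (a [raw_trajectory()]
#'   of positions only), and `graph` (the generating
#'   [ground_truth_graph()]).
#' @export
simulate_springs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on <- stats::runif(nrow(pairs)) < config$edge_probability
  edges <- data.frame(i = pairs[on, 1L], j = pairs[on, 2L],
                      k = rep(config$spring_constant, sum(on)))
  graph <- ground_truth_graph(n, edges)
  x0 <- matrix(stats::runif(n * 3L, -config$box_half_width,
                            config$box_half_width), n, 3L)
  v0 <- matrix(stats::rnorm(n * 3L, 0, 0.5), n, 3L)
  simulate_spring_system(graph, x0, v0, config)
}

#' Simulate a given spring system from a given initial state
#'
#' Deterministic core of [simulate_springs()]: no graph sampling and no
#' initial-condition sampling, so node relabeling commutes with
#' simulation.  Observation noise (if any) is still drawn from the current
#' RNG state.
#'
#' @param graph a [ground_truth_graph()].
#' @param x0,v0 n x 3 matrices of initial positions and velocities.
#' @param config a [sim_config()] (its `n_nodes` must match the graph).
#' @return as [simulate_springs()].
#' @export
simulate_spring_system <- function(graph, x0, v0, config) {
  stopifnot(graph$n_nodes == config$n_nodes,
            nrow(x0) == config$n_nodes, nrow(v0) == config$n_nodes)
  kmat <- matrix(0, graph$n_nodes, graph$n_nodes)
  if (nrow(graph$edges) > 0L) {
    kmat[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$k
    kmat[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$k
  }
  res <- integrate_springs(x0, v0, kmat, config)
  sim_output(res, graph, config)
}

#' Simulate a driven linear chain with a planted pathway
#'
#' Builds a chain 1-2-...-n of particles coupled by springs with rest
#' length 1, placed at their equilibrium positions along the x axis, and
#' drives node 1 sinusoidally along x with the given amplitude.  The
#' perturbation propagates down the chain, so the ground-truth
#' signalling pathway is the chain itself.
#'
#' @param n_nodes chain length (>= 3).
#' @param drive_amplitude displacement amplitude of node 1 (length units);
#'   0 leaves the chain at rest.
#' @param config a [sim_config()]; `n_nodes` must match, and
#'   `edge_probability`/`box_half_width` are ignored.
#' @param drive_frequency angular frequency of the drive; default
#'   0.5 * sqrt(k/m), below the chain's resonances.
#' @param drive_phase phase offset of the drive; `NULL` (default) draws it
#'   uniformly from `[0, 2*pi)` under the config seed, so an ensemble of
#'   seeds probes the chain at varied phases.
#' @param v0_jitter standard deviation of Gaussian noise added to initial
#'   velocities (0 = start exactly at rest).
#' @return as [simulate_springs()].
#' @export
simulate_planted_pathway <- function(n_nodes, drive_amplitude, config,
                                     drive_frequency = NULL,
                                     drive_phase = NULL, v0_jitter = 0) {
  stopifnot(n_nodes >= 3L, config$n_nodes == n_nodes, v0_jitter >= 0)
  set.seed(config$seed)
  if (is.null(drive_frequency)) {
    drive_frequency <- 0.5 * sqrt(config$spring_constant / config$mass)
  }
  if (is.null(drive_phase)) drive_phase <- stats::runif(1, 0, 2 * pi)
  edges <- data.frame(i = seq_len(n_nodes - 1L), j = seq_len(n_nodes - 1L) + 1L,
                      k = rep(config$spring_constant, n_nodes - 1L))
  graph <- ground_truth_graph(n_nodes, edges)
  kmat <- matrix(0, n_nodes, n_nodes)
  kmat[cbind(edges$i, edges$j)] <- edges$k
  kmat[cbind(edges$j, edges$i)] <- edges$k
  x0 <- cbind(seq_len(n_nodes) - 1, 0, 0)    # equilibrium spacing = rest length
  v0 <- matrix(0, n_nodes, 3L)
  if (v0_jitter > 0) {
    v0 <- v0 + matrix(stats::rnorm(n_nodes * 3L, 0, v0_jitter), n_nodes, 3L)
  }
  base <- x0[1L, ]
  driven <- list(node = 1L,
                 fun = function(time) {
                   base + c(drive_amplitude *
                              sin(drive_frequency * time + drive_phase) -
                              drive_amplitude * sin(drive_phase), 0, 0)
                 })
  res <- integrate_springs(x0, v0, kmat, config, rest_length = 1,
                           driven = driven)
  sim_output(res, graph, config)
}

#' Simulate an ensemble of independent spring systems
#'
#' Draws `n_systems` spring systems, each with its own random graph and
#' initial conditions (seeds `config$seed`, `config$seed + 1`, ...).
#' Interaction recovery is only identifiable across systems whose graphs
#' differ: a single linear spring trajectory is a fixed superposition of
#' normal modes, so one node's own history already predicts its future
#' and edges carry no extra information.  Training on an ensemble with
#' varying graphs forces the model to read the interactions out of the
#' data, which is the standard validation design for relational
#' inference.
#'
#' @param n_systems number of independent systems.
#' @param config a [sim_config()]; `seed` seeds the first system.
#' @return list of [simulate_springs()] outputs.
#' @export
simulate_spring_ensemble <- function(n_systems, config) {
  stopifnot(n_systems >= 1L)
  lapply(seq_len(n_systems) - 1L, function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    simulate_springs(cfg)
  })
}

#' Total mechanical energy of a simulated spring system per frame
#'
#' Kinetic plus spring potential energy (zero rest length), evaluated
#' directly from the stored positions and velocities.  Useful as an
#' integration-quality diagnostic: the symplectic integrator keeps this
#' bounded.
#'
#' @param sim output of [simulate_springs()] or
#'   [simulate_spring_system()].
#' @param config the [sim_config()] used.
#' @return numeric vector, one energy per frame.
#' @export
mechanical_energy <- function(sim, config) {
  x <- sim$features$x
  n_steps <- dim(x)[2L]
  e <- numeric(n_steps)
  ed <- sim$graph$edges
  for (t in seq_len(n_steps)) {
    v <- x[, t, 4:6, drop = TRUE]
    ke <- 0.5 * config$mass * sum(v^2)
    pe <- 0
    if (nrow(ed) > 0L) {
      d <- x[ed$i, t, 1:3, drop = FALSE] - x[ed$j, t, 1:3, drop = FALSE]
      pe <- 0.5 * sum(ed$k * rowSums(matrix(d, nrow(ed), 3L)^2))
    }
    e[t] <- ke + pe
  }
  e
}

#' Write a trajectory as a per-frame coordinate table
#'
#' TSV with header `frame  node  x  y  z`; frames and nodes are 1-based.
#' This is the same dialect [load_coordinates()] reads back.
#'
#' @param trajectory a [raw_trajectory()].
#' @param path output file.
#' @export
write_coordinate_table <- function(trajectory, path) {
  pos <- trajectory$positions
  n <- dim(pos)[1L]; tt <- dim(pos)[2L]
  df <- data.frame(frame = rep(seq_len(tt), each = n),
                   node = rep(seq_len(n), times = tt),
                   x = as.vector(pos[, , 1L]),
                   y = as.vector(pos[, , 2L]),
                   z = as.vector(pos[, , 3L]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth edge list
#'
#' TSV with header `i  j  k_ij` (1-based node indices).
#'
#' @param graph a [ground_truth_graph()].
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  df <- graph$edges
  names(df) <- c("i", "j", "k_ij")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
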