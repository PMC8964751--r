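#' Raw trajectory container
#'
#' One representative point per residue (the C-alpha for PDB input) per
#' frame, before featurization.
#'
#' @param positions array `[node, frame, 3]` of coordinates (length units;
#'   Angstrom for MD input).
#' @param frame_interval time per stored frame (e.g. ns); defaults to 1.
#' @param node_labels optional character vector of residue identifiers.
#' @return a `raw_trajectory`.
#' @export
raw_trajectory <- function(positions, frame_interval = 1,
                           node_labels = NULL) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3L] == 3L,
            dim(positions)[2L] >= 2L, all(is.finite(positions)),
            frame_interval > 0)
  if (is.null(node_labels)) {
    node_labels <- as.character(seq_len(dim(positions)[1L]))
  }
  stopifnot(length(node_labels) == dim(positions)[1L])
  structure(list(positions = positions,
                 n_nodes = dim(positions)[1L],
                 n_frames = dim(positions)[2L],
                 frame_interval = frame_interval,
                 node_labels = node_labels),
            class = "raw_trajectory")
}

#' Feature tensor consumed by the relational-inference model
#'
#' Per node and time step a 6-vector: position (x, y, z) then velocity
#' (x, y, z).
#'
#' @param x array `[node, step, 6]`.
#' @param dt time between consecutive steps.
#' @param normalization `NULL`, or the record of the affine transform
#'   applied to positions (list with `center` length-3 and `scale`
#'   scalar); velocities are scaled by `1/scale` as well.
#' @param node_labels optional residue identifiers.
#' @return a `feature_tensor`.
#' @export
feature_tensor <- function(x, dt = 1, normalization = NULL,
                           node_labels = NULL) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3L] == 6L, dim(x)[2L] >= 2L,
            all(is.finite(x)), dt > 0)
  if (is.null(node_labels)) node_labels <- as.character(seq_len(dim(x)[1L]))
  structure(list(x = x, n_nodes = dim(x)[1L], n_steps = dim(x)[2L],
                 dt = dt, normalization = normalization,
                 node_labels = node_labels),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("feature_tensor:", x$n_nodes, "nodes x", x$n_steps,
      "steps x 6 features (pos xyz, vel xyz); dt =", x$dt, "\n")
  if (!is.null(x$normalization)) cat("  positions normalized to [-1, 1]\n")
  invisible(x)
}

#' Load a trajectory from a multi-model PDB or a coordinate table
#'
#' For PDB input every MODEL is one frame and every residue is reduced to
#' its C-alpha atom; residue sets must be identical across models.  The
#' coordinate-table dialect is TSV with header `frame node x y z`, as
#' written by [write_coordinate_table()].
#'
#' @param path input file.
#' @param format `"pdb_multimodel"` or `"coordinate_table"`.
#' @param frame_interval time per frame (passed through).
#' @return a [raw_trajectory()].
#' @export
load_coordinates <- function(path, format = c("coordinate_table",
                                              "pdb_multimodel"),
                             frame_interval = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         coordinate_table = load_coordinate_table(path, frame_interval),
         pdb_multimodel = load_pdb_multimodel(path, frame_interval))
}

load_coordinate_table <- function(path, frame_interval) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("frame", "node", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("coordinate table must have columns: ", paste(need, collapse = " "))
  }
  frames <- sort(unique(df$frame))
  nodes <- sort(unique(df$node))
  n <- length(nodes); tt <- length(frames)
  pos <- array(NA_real_, c(n, tt, 3L))
  fi <- match(df$frame, frames); ni <- match(df$node, nodes)
  for (d in 1:3) pos[cbind(ni, fi, d)] <- df[[c("x", "y", "z")[d]]]
  if (anyNA(pos)) stop("coordinate table is missing node/frame entries")
  raw_trajectory(pos, frame_interval, node_labels = as.character(nodes))
}

load_pdb_multimodel <- function(path, frame_interval) {
  # validation pass over MODEL blocks: every residue must carry a C-alpha
  # in every model, and the residue set must not change across models
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) < 2L || length(ends) != length(starts)) {
    stop("PDB has fewer than 2 MODEL records; not a multi-model trajectory")
  }
  res_sets <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[(starts[m] + 1L):(ends[m] - 1L)]
    blk <- blk[startsWith(blk, "ATOM")]
    resno <- trimws(substr(blk, 23L, 26L))
    chain <- substr(blk, 22L, 22L)
    aname <- trimws(substr(blk, 13L, 16L))
    res <- unique(paste0(chain, resno))
    has_ca <- unique(paste0(chain, resno)[aname == "CA"])
    missing <- setdiff(res, has_ca)
    if (length(missing) > 0L) {
      stop("residue ", trimws(sub("^.", "", missing[1L])),
           " has no C-alpha atom in model ", m)
    }
    res_sets[[m]] <- res
  }
  for (m in seq_along(res_sets)[-1L]) {
    if (!identical(res_sets[[m]], res_sets[[1L]])) {
      stop("residue set in model ", m, " differs from model 1")
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[ca$atom, , drop = FALSE]
  labels <- paste0(at$resid, at$resno)
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]      # frames x (3*n)
  n <- length(ca$atom)
  tt <- nrow(xyz)
  pos <- array(NA_real_, c(n, tt, 3L))
  for (t in seq_len(tt)) {
    pos[, t, ] <- matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
  }
  raw_trajectory(pos, frame_interval, node_labels = labels)
}

#' Subsample a trajectory to a chosen number of steps
#'
#' Retains `n_steps` frames at (as near as possible) uniform spacing,
#' always including the first frame: frame indices
#' `floor((0:(n_steps-1)) * n_frames / n_steps) + 1`.  For 5000 frames and
#' 50 steps this keeps every 100th frame; 20 steps gives a 250-frame
#' interval.
#'
#' @param raw a [raw_trajectory()].
#' @param n_steps number of frames to keep (2 <= n_steps <= n_frames).
#' @return a [raw_trajectory()] whose `frame_interval` reflects the new
#'   spacing and which carries the retained indices as
#'   `attr(, "frame_indices")`.
#' @export
subsample_trajectory <- function(raw, n_steps) {
  stopifnot(inherits(raw, "raw_trajectory"))
  n_steps <- as.integer(n_steps)
  if (n_steps > raw$n_frames) {
    stop("n_steps (", n_steps, ") exceeds available frames (",
         raw$n_frames, ")")
  }
  stopifnot(n_steps >= 2L)
  idx <- floor(seq(0L, n_steps - 1L) * raw$n_frames / n_steps) + 1L
  out <- raw_trajectory(raw$positions[, idx, , drop = FALSE],
                        frame_interval = raw$frame_interval *
                          raw$n_frames / n_steps,
                        node_labels = raw$node_labels)
  attr(out, "frame_indices") <- idx
  out
}

#' Build the 6-feature tensor (position + velocity) from a trajectory
#'
#' Velocity at step t (t >= 2) is the backward finite difference
#' `(pos_t - pos_{t-1}) / dt`; the first step copies the second step's
#' velocity so no spurious rest frame is introduced.  With
#' `normalize = TRUE` positions are centered per axis and scaled by one
#' common factor into `[-1, 1]` (velocities share the scale factor), and
#' the transform is recorded for exact inversion.
#'
#' @param raw a [raw_trajectory()].
#' @param normalize logical; default TRUE.
#' @return a [feature_tensor()].
#' @export
featurize <- function(raw, normalize = TRUE) {
  stopifnot(inherits(raw, "raw_trajectory"))
  dt <- raw$frame_interval
  if (dt <= 0) stop("frame interval must be positive")
  pos <- raw$positions
  n <- dim(pos)[1L]; tt <- dim(pos)[2L]
  norm <- NULL
  if (normalize) {
    center <- apply(pos, 3L, mean)
    for (d in 1:3) pos[, , d] <- pos[, , d] - center[d]
    scale <- max(abs(pos))
    if (scale == 0) scale <- 1
    pos <- pos / scale
    norm <- list(center = center, scale = scale)
  }
  vel <- array(0, c(n, tt, 3L))
  vel[, 2:tt, ] <- (pos[, 2:tt, , drop = FALSE] -
                      pos[, 1:(tt - 1L), , drop = FALSE]) / dt
  vel[, 1L, ] <- vel[, 2L, ]
  x <- array(0, c(n, tt, 6L))
  x[, , 1:3] <- pos
  x[, , 4:6] <- vel
  feature_tensor(x, dt = dt, normalization = norm,
                 node_labels = raw$node_labels)
}

#' Invert the normalization recorded on a feature tensor
#'
#' @param features a [feature_tensor()] (or a bare `[node, step, >=3]`
#'   array via `x`).
#' @param x optional array to denormalize with `features`' record instead
#'   of `features$x`.
#' @return array in the original coordinate units.
#' @export
denormalize <- function(features, x = NULL) {
  if (is.null(x)) x <- features$x
  norm <- features$normalization
  if (is.null(norm)) return(x)
  nd <- dim(x)[3L]
  for (d in 1:3) x[, , d] <- x[, , d] * norm$scale + norm$center[d]
  if (nd >= 6L) for (d in 4:6) x[, , d] <- x[, , d] * norm$scale
  x
}

#' Build train/validation/test windows from an ensemble of simulations
#'
#' One window per simulated system: each trajectory is subsampled to
#' `window_length` steps, featurized (normalized per system) and assigned
#' wholly to one split, so no system leaks across splits.  The matching
#' ground-truth graphs are carried alongside each split for
#' recovery scoring.
#'
#' @param sims list from [simulate_spring_ensemble()].
#' @param window_length steps per window.
#' @param fractions length-3 positive split fractions summing to 1.
#' @param seed shuffle seed (train order only; assignment is by position).
#' @param normalize normalize each system's coordinates to `[-1, 1]`.
#' @return a `data_splits` with additional `graphs` element (list with
#'   `train`, `valid`, `test` graph lists aligned with the windows).
#' @export
ensemble_windows <- function(sims, window_length, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L, normalize = TRUE) {
  stopifnot(length(sims) >= 3L, length(fractions) == 3L,
            all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  wins <- lapply(sims, function(s) {
    raw <- subsample_trajectory(s$trajectory, window_length)
    featurize(raw, normalize = normalize)$x
  })
  graphs <- lapply(sims, `[[`, "graph")
  nsys <- length(sims)
  bounds <- c(0L, floor(cumsum(fractions)[1:2] * nsys), nsys)
  names <- c("train", "valid", "test")
  out <- list(); gout <- list()
  for (s in 1:3) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    if (bounds[s + 1L] <= bounds[s]) {
      stop("split '", names[s], "' received zero systems")
    }
    out[[names[s]]] <- wins[idx]
    gout[[names[s]]] <- graphs[idx]
  }
  set.seed(seed)
  ord <- sample.int(length(out$train))
  out$train <- out$train[ord]
  gout$train <- gout$train[ord]
  structure(c(out, list(graphs = gout,
                        window_length = as.integer(window_length),
                        stride = NA_integer_, fractions = fractions,
                        seed = as.integer(seed),
                        dt = sims[[1L]]$trajectory$frame_interval *
                          sims[[1L]]$trajectory$n_frames / window_length,
                        normalization = NULL,
                        node_labels = sims[[1L]]$trajectory$node_labels)),
            class = "data_splits")
}

#' Cut a trajectory into train/validation/test windows
#'
#' The step axis is first partitioned chronologically into contiguous
#' train, validation and test ranges by `fractions` (frames are
#' autocorrelated, so a random split would leak), then fixed-length
#' windows are cut within each range with the given stride.  Only the
#' order of training windows is shuffled, under `seed`.
#'
#' @param features a [feature_tensor()].
#' @param window_length steps per window.
#' @param stride step between window starts.
#' @param fractions length-3 positive vector summing to 1
#'   (train, validation, test).
#' @param seed integer seed for the training-window shuffle.
#' @return a `data_splits` list with elements `train`, `valid`, `test`
#'   (lists of `[node, window_length, 6]` arrays), plus the cutting
#'   parameters.
#' @export
make_windows <- function(features, window_length, stride = 1L,
                         fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(features, "feature_tensor"),
            window_length >= 2L, window_length <= features$n_steps,
            stride >= 1L, length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  tt <- features$n_steps
  bounds <- c(0L, floor(cumsum(fractions)[1:2] * tt), tt)
  names <- c("train", "valid", "test")
  out <- list()
  for (s in 1:3) {
    lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
    len <- hi - lo + 1L
    if (len < window_length) {
      if (s == 1L) {
        stop("split 'train' has ", len,
             " steps, fewer than window_length = ", window_length)
      }
      warning("split '", names[s], "' has ", len,
              " steps, fewer than window_length = ", window_length,
              "; it receives zero windows")
      out[[names[s]]] <- list()
      next
    }
    starts <- seq(lo, hi - window_length + 1L, by = stride)
    out[[names[s]]] <- lapply(starts, function(st) {
      features$x[, st:(st + window_length - 1L), , drop = FALSE]
    })
  }
  set.seed(seed)
  out$train <- out$train[sample.int(length(out$train))]
  structure(c(out, list(window_length = as.integer(window_length),
                        stride = as.integer(stride),
                        fractions = fractions, seed = as.integer(seed),
                        dt = features$dt,
                        normalization = features$normalization,
                        node_labels = features$node_labels)),
            class = "data_splits")
}
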