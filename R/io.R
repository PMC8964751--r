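# Model checkpoint serialization: one JSON archive holding parameters,
# configuration and the normalization record, so a trained model can be
# reloaded for inference without any binary format.

#' Write a trained model checkpoint
#'
#' @param fit an `nri_fit` from [nri_train()].
#' @param path output file (JSON).
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "nri_fit"))
  ser_mats <- function(x) {
    if (is.list(x)) lapply(x, ser_mats)
    else list(dim = dim(x), data = as.vector(x))
  }
  out <- list(config = unclass(fit$config),
              input_steps = fit$params$input_steps,
              hidden_dim = fit$params$hidden_dim,
              K = fit$params$K,
              enc = ser_mats(fit$params$enc),
              dec = ser_mats(fit$params$dec),
              normalization = fit$normalization,
              dt = fit$dt,
              node_labels = fit$node_labels,
              best_epoch = fit$best_epoch,
              seed = fit$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint written by [write_checkpoint()]
#'
#' @param path JSON checkpoint file.
#' @return an `nri_fit` (without the training log).
#' @export
read_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  deser <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      d <- as.integer(unlist(x$dim))
      matrix(as.numeric(unlist(x$data)), d[1L], d[2L])
    } else lapply(x, deser)
  }
  cfg <- lapply(raw$config, function(v)
    if (length(v) > 1L || is.list(v)) unlist(v) else v)
  config <- nri_config(K = cfg$K, hidden_dim = cfg$hidden_dim,
                       tau = cfg$tau, prior = as.numeric(cfg$prior),
                       sigma2 = cfg$sigma2,
                       encoder_rounds = cfg$encoder_rounds,
                       mlp_layers = cfg$mlp_layers,
                       prediction_steps = cfg$prediction_steps,
                       msg_inputs = if (is.null(cfg$msg_inputs)) "hidden_input"
                                    else cfg$msg_inputs)
  params <- structure(list(enc = deser(raw$enc), dec = deser(raw$dec),
                           hidden_dim = as.integer(raw$hidden_dim),
                           K = as.integer(raw$K),
                           input_steps = as.integer(raw$input_steps)),
                      class = "nri_params")
  norm <- raw$normalization
  if (!is.null(norm)) {
    norm <- list(center = as.numeric(unlist(norm$center)),
                 scale = as.numeric(norm$scale))
  }
  structure(list(params = params, log = NULL, config = config,
                 best_epoch = as.integer(raw$best_epoch),
                 seed = as.integer(raw$seed),
                 normalization = norm, dt = as.numeric(raw$dt),
                 node_labels = as.character(unlist(raw$node_labels))),
            class = "nri_fit")
}

#' Export an edge posterior as TSV
#'
#' Columns `i  j  type  probability`, one row per ordered pair and edge
#' type.
#'
#' @param q an `edge_posterior`.
#' @param path output file.
#' @export
write_edge_posterior <- function(q, path) {
  stopifnot(inherits(q, "edge_posterior"))
  K <- ncol(q$q)
  df <- data.frame(i = rep(q$pairs$i, K), j = rep(q$pairs$j, K),
                   type = rep(seq_len(K), each = nrow(q$q)),
                   probability = as.vector(q$q))
  df <- df[order(df$i, df$j, df$type), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
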