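#' Reference C-alpha coordinates for distance thresholding
#'
#' Pairwise residue distances are computed once from a single reference
#' structure (never per frame) and used to restrict the stability score
#' to spatially proximal pairs.
#'
#' @param x an N x 3 coordinate matrix, a [raw_trajectory()] (its first
#'   frame is used), or a path to a PDB file (C-alpha coordinates of the
#'   first model).
#' @return a `distance_reference`: list with `coords` (N x 3) and `dist`
#'   (N x N symmetric matrix, zero diagonal).
#' @export
distance_reference <- function(x) {
  coords <- if (is.character(x)) {
    pdb <- suppressWarnings(bio3d::read.pdb(x))
    ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
    matrix(pdb$xyz[1L, ca$xyz], ncol = 3L, byrow = TRUE)
  } else if (inherits(x, "raw_trajectory")) {
    x$positions[, 1L, ]
  } else {
    as.matrix(x)
  }
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  structure(list(coords = coords, dist = d, n_nodes = nrow(coords)),
            class = "distance_reference")
}

#' Pairwise free-energy score of a learned interaction matrix
#'
#' `E_z` = sum of learned-edge weights over pairs whose reference
#' C-alpha distance is at or below the threshold (e.g. 12 or 15
#' Angstrom).  Ordered pairs by default; the unordered option halves the
#' sum for symmetric matrices, a factor that cancels in any downstream
#' correlation.
#'
#' @param m an [interaction_matrix()].
#' @param ref a [distance_reference()] covering all nodes.
#' @param threshold distance threshold (> 0, length units of `ref`).
#' @param pairs `"ordered"` (default) or `"unordered"`.
#' @return scalar E_z.
#' @export
pairwise_energy_score <- function(m, ref, threshold,
                                  pairs = c("ordered", "unordered")) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(m, "interaction_matrix"),
            inherits(ref, "distance_reference"), threshold > 0)
  if (ref$n_nodes < m$n_nodes) {
    stop("node ", ref$n_nodes + 1L, " has no reference coordinates")
  }
  d <- ref$dist[seq_len(m$n_nodes), seq_len(m$n_nodes)]
  sel <- d <= threshold & row(d) != col(d)
  if (pairs == "unordered") sel <- sel & upper.tri(d)
  sum(m$w[sel])
}

#' Mutant-versus-wild-type stability scores
#'
#' `Delta G_Z = E_z(variant) - E_z(WT)` per variant under a common
#' distance threshold.
#'
#' @param variants named list of [interaction_matrix()] objects.
#' @param wt wild-type [interaction_matrix()].
#' @param ref a [distance_reference()].
#' @param threshold distance threshold (Angstrom).
#' @param pairs passed to [pairwise_energy_score()].
#' @return a `stability_report` (partial): data.frame with `variant`,
#'   `E_z`, `delta_gz`, plus attributes `E_z_wt` and `threshold`.
#' @export
delta_g_scores <- function(variants, wt, ref, threshold,
                           pairs = c("ordered", "unordered")) {
  pairs <- match.arg(pairs)
  stopifnot(length(variants) > 0L, !is.null(names(variants)))
  n <- wt$n_nodes
  for (nm in names(variants)) {
    if (variants[[nm]]$n_nodes != n) {
      stop("variant '", nm, "' has ", variants[[nm]]$n_nodes,
           " nodes; wild type has ", n)
    }
  }
  e_wt <- pairwise_energy_score(wt, ref, threshold, pairs)
  e <- vapply(variants, pairwise_energy_score, 0, ref = ref,
              threshold = threshold, pairs = pairs)
  out <- data.frame(variant = names(variants), E_z = as.numeric(e),
                    delta_gz = as.numeric(e) - e_wt,
                    row.names = NULL)
  attr(out, "E_z_wt") <- e_wt
  attr(out, "threshold") <- threshold
  class(out) <- c("stability_report", class(out))
  out
}

#' Correlate computed stability scores with experimental ddG
#'
#' Pearson correlation between `Delta G_Z` and experimental unfolding
#' free-energy changes (kcal/mol), with a two-sided t-test on
#' `df = n - 2` and a Fisher-z 95% confidence interval.  `R2` carries the
#' sign of r (signed `r * |r|` convention, so anticorrelation is visible
#' as a negative value); the unsigned square is also returned.
#'
#' @param delta_gz numeric vector of computed scores.
#' @param ddg_exp numeric vector of experimental ddG values (kcal/mol),
#'   same length (n >= 3), no missing values.
#' @return list with `r`, `R2` (signed), `R2_unsigned`, `p`, `ci95`
#'   (signed-R2 scale), `ci95_r`, `df`, `n`.
#' @export
correlate_with_experiment <- function(delta_gz, ddg_exp) {
  stopifnot(length(delta_gz) == length(ddg_exp), length(delta_gz) >= 3L)
  if (anyNA(delta_gz) || anyNA(ddg_exp)) {
    stop("missing values must be dropped upstream (see read_ddg)")
  }
  if (stats::sd(delta_gz) == 0 || stats::sd(ddg_exp) == 0) {
    stop("zero variance in one of the score vectors")
  }
  ct <- stats::cor.test(delta_gz, ddg_exp, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  ci_r <- as.numeric(ct$conf.int)
  signed_sq <- function(x) sign(x) * x^2
  list(r = r, R2 = signed_sq(r), R2_unsigned = r^2,
       p = ct$p.value, ci95 = signed_sq(ci_r), ci95_r = ci_r,
       df = unname(ct$parameter), n = length(delta_gz))
}

#' Read experimental ddG values from a TSV
#'
#' Expects columns `variant` and `ddG_kcal_per_mol`; entries marked `ND`
#' (not determined) are dropped with a warning.
#'
#' @param path TSV file.
#' @return data.frame with `variant`, `ddG` (numeric, kcal/mol).
#' @export
read_ddg <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stopifnot(all(c("variant", "ddG_kcal_per_mol") %in% names(df)))
  nd <- toupper(trimws(df$ddG_kcal_per_mol)) %in% c("ND", "N.D.", "NA")
  if (any(nd)) {
    warning("dropping ", sum(nd), " variant(s) with undetermined ddG: ",
            paste(df$variant[nd], collapse = ", "))
    df <- df[!nd, , drop = FALSE]
  }
  data.frame(variant = df$variant,
             ddG = as.numeric(df$ddG_kcal_per_mol))
}
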