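#' Fit a structure-based phylogeny from an all-versus-all alignment table
#'
#' The main entry point: compiles pairwise structural-alignment scores into
#' a similarity matrix ([hits_to_similarity()]), transforms it to
#' evolutionary distances ([correct_similarity()]), infers an unrooted
#' neighbor-joining tree ([neighbor_joining()]) and roots it by minimal
#' ancestor deviation ([mad_root()]). The default configuration —
#' corrected Fident distances — is the combination that performs best in
#' taxonomic-congruence benchmarks of structure-based trees.
#'
#' If structures are supplied together with `plddt_threshold`, predicted
#' models with mean pLDDT below the threshold are dropped (and their hits
#' with them) before the matrix is assembled. If lineages are supplied the
#' Taxonomic Congruence Score is computed on the rooted tree. The whole fit
#' is deterministic: identical inputs and options give identical output.
#'
#' @param hits alignment hit table (data frame from [read_alignment_tsv()]
#'   or [similarity_table_from_tree()]), or a path to such a TSV.
#' @param metric score used for distances: `"fident"` (default), `"lddt"`
#'   or `"tm"`.
#' @param mode `"corrected"` (default) or `"raw"`; see
#'   [correct_similarity()].
#' @param structures optional named list of [structure_record()]s.
#' @param plddt_threshold optional mean-pLDDT cutoff (e.g. 40); only
#'   applied when structures are given.
#' @param lineages optional lineage map (list or data frame) for TCS.
#' @param external_tree optional unrooted [ape::phylo] tree (or Newick
#'   path) built by an external distance program from the exported matrix;
#'   replaces the internal NJ step, the rest of the pipeline is unchanged.
#' @param eps,transform passed to [correct_similarity()].
#' @param impute_missing passed to [hits_to_similarity()].
#' @return object of class `foldtree`; see [print.foldtree()],
#'   [summary.foldtree()], [residuals.foldtree()], [simulate.foldtree()].
#' @examples
#' truth <- simulate_tree(12, "yule", seed = 1)
#' hits <- similarity_table_from_tree(truth, noise_sd = 0, seed = 1)
#' fit <- foldtree(hits, lineages = simulate_taxonomy(truth))
#' fit
#' robinson_foulds(fit$tree, truth)
#' @export
foldtree <- function(hits, metric = c("fident", "lddt", "tm"),
                     mode = c("corrected", "raw"), structures = NULL,
                     plddt_threshold = NULL, lineages = NULL,
                     external_tree = NULL, eps = 1e-4, transform = NULL,
                     impute_missing = FALSE) {
  cl <- match.call()
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (is.character(hits)) hits <- read_alignment_tsv(hits)

  filtered <- NULL
  if (!is.null(structures) && !is.null(plddt_threshold)) {
    filtered <- filter_by_plddt(structures, plddt_threshold)
    if (length(filtered$removed) > 0L) {
      hits <- hits[!(hits$query %in% filtered$removed |
                       hits$target %in% filtered$removed), , drop = FALSE]
    }
  }

  S <- hits_to_similarity(hits, metric, impute_missing = impute_missing)
  D <- correct_similarity(S, mode, eps = eps, transform = transform)
  if (!is.null(external_tree)) {
    unrooted <- if (is.character(external_tree)) read_newick(external_tree)
      else external_tree
    if (!setequal(unrooted$tip.label, rownames(D))) {
      stop("external tree leaf set does not match the hit table", call. = FALSE)
    }
    unrooted <- ape::unroot(unrooted)
  } else {
    unrooted <- neighbor_joining(D)
  }
  mad <- mad_root(unrooted)
  rooted <- mad$tree

  tcs_res <- if (!is.null(lineages)) tcs(rooted, lineages)
  structure(
    list(tree = rooted, unrooted = unrooted, mad = mad,
         similarity = S, distances = D,
         metric = metric, mode = mode,
         rtt_variance = rtt_variance(rooted), tcs = tcs_res,
         filtered = filtered, call = cl),
    class = "foldtree"
  )
}

#' @describeIn foldtree compact description of the fitted tree.
#' @param x,object a `foldtree` fit.
#' @param ... unused.
#' @export
print.foldtree <- function(x, ...) {
  cat("Structure-based phylogeny (", x$metric, ", ", x$mode, " distances)\n",
      sep = "")
  cat("  leaves:      ", length(x$tree$tip.label), "\n", sep = "")
  b <- x$mad$best
  cat(sprintf("  MAD root:    branch %d->%d, deviation %.4g\n",
              x$mad$scores$parent[b], x$mad$scores$child[b],
              x$mad$scores$score[b]))
  cat(sprintf("  rtt variance: %.4g\n", x$rtt_variance))
  if (!is.null(x$tcs)) {
    cat(sprintf("  TCS:         %.4g\n", x$tcs$tree_score))
  }
  if (!is.null(x$filtered) && length(x$filtered$removed) > 0L) {
    cat("  pLDDT-filtered out: ", paste(x$filtered$removed, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn foldtree fit configuration plus distance and score summaries.
#' @export
summary.foldtree <- function(object, ...) {
  D <- object$distances
  off <- D[upper.tri(D)]
  out <- list(
    n_leaves = length(object$tree$tip.label),
    metric = object$metric, mode = object$mode,
    distance_range = range(off),
    mean_distance = mean(off),
    rtt_variance = object$rtt_variance,
    tcs = if (!is.null(object$tcs)) object$tcs$tree_score,
    mad_deviation = object$mad$scores$score[object$mad$best],
    n_removed = if (is.null(object$filtered)) 0L
      else length(object$filtered$removed)
  )
  class(out) <- "summary.foldtree"
  out
}

#' @export
print.summary.foldtree <- function(x, ...) {
  cat(sprintf(
    "foldtree fit: %d leaves, %s/%s\n  distances %.4g..%.4g (mean %.4g)\n",
    x$n_leaves, x$metric, x$mode, x$distance_range[1L], x$distance_range[2L],
    x$mean_distance))
  cat(sprintf("  MAD deviation %.4g, rtt variance %.4g\n",
              x$mad_deviation, x$rtt_variance))
  if (!is.null(x$tcs)) cat(sprintf("  TCS %.4g\n", x$tcs))
  if (x$n_removed > 0L) cat("  structures removed by pLDDT filter:",
                            x$n_removed, "\n")
  invisible(x)
}

#' @describeIn foldtree plot the rooted tree (thin wrapper over
#'   [ape::plot.phylo()]).
#' @export
plot.foldtree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}

#' @describeIn foldtree matrix of input distances minus the tree's
#'   patristic distances — how far the fitted tree is from exactly
#'   explaining the corrected distances (all zero on additive input).
#' @export
residuals.foldtree <- function(object, ...) {
  P <- patristic_matrix(object$unrooted)
  D <- object$distances[rownames(P), colnames(P)]
  D - P
}

#' @describeIn foldtree simulate new alignment tables from the fitted tree
#'   (parametric bootstrap); returns a list of `nsim` hit tables.
#' @param nsim number of tables to simulate.
#' @param seed integer seed.
#' @param noise_sd score noise for the simulated tables.
#' @export
simulate.foldtree <- function(object, nsim = 1, seed = 1, noise_sd = 0, ...) {
  lapply(seq_len(nsim), function(i) {
    similarity_table_from_tree(object$tree, noise_sd = noise_sd,
                               seed = seed + i - 1L)
  })
}
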