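#' Taxonomic Congruence Score (TCS) of a rooted tree
#'
#' Scores how well a rooted gene-tree topology agrees with the taxonomic
#' classification of its leaves. Working bottom-up, each leaf carries the
#' set of taxa in its lineage; each internal node (including the root)
#' carries the intersection of its children's sets, and its score is the
#' cardinality of that set. Each leaf's score is the sum of internal-node
#' scores along its root-to-leaf path, so congruence near the root — where
#' intersections span many leaves — is weighted most heavily. The tree
#' score is the mean leaf score.
#'
#' The score depends only on topology, never on branch lengths, and is
#' invariant to child ordering. Because it reflects the density of
#' taxonomic information in the leaf set, TCS values are only comparable
#' between trees over the same leaves (e.g. alternative reconstructions of
#' one family), never across families.
#'
#' Unknown (empty) ranks are absent from a leaf's set rather than matching
#' anything, so missing annotation never inflates intersections. Taxa are
#' compared as (rank, name) pairs, so identical names at different ranks do
#' not collide. Multifurcations intersect over all children.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param lineages named list (leaf id -> named character vector of
#'   rank = taxon, broadest first) as from [read_lineages()] or
#'   [simulate_taxonomy()]; a lineage data frame is also accepted.
#' @param node_score function mapping an internal node's taxon set to its
#'   score; the default is the set cardinality. Replaceable to, e.g.,
#'   normalise by lineage depth.
#' @return object of class `tcs_result`: list with `node_scores` (named by
#'   internal node id), `leaf_scores` (named by leaf label) and
#'   `tree_score` (mean leaf score).
#' @export
tcs <- function(tree, lineages, node_score = length) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  lineages <- .as_lineage_list(lineages)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(lineages))
  if (length(missing) > 0L) {
    stop("no lineage for leaf: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  empty <- tips[vapply(lineages[tips], length, integer(1L)) == 0L]
  if (length(empty) > 0L) {
    stop("empty lineage for leaf: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  ntip <- length(tips)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  E <- ape::reorder.phylo(tree, "postorder")$edge

  sets <- vector("list", ntot)
  for (i in seq_len(ntip)) {
    lin <- lineages[[tips[i]]]
    sets[[i]] <- paste(names(lin), lin, sep = "|")
  }
  # postorder guarantees children precede parents
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1L]; ch <- E[k, 2L]
    sets[[p]] <- if (is.null(sets[[p]])) sets[[ch]] else
      intersect(sets[[p]], sets[[ch]])
  }
  node_scores <- vapply((ntip + 1L):ntot, function(v) {
    as.numeric(node_score(sets[[v]]))
  }, numeric(1L))
  names(node_scores) <- as.character((ntip + 1L):ntot)

  # accumulate internal-node scores from the root down
  acc <- numeric(ntot)
  acc[root] <- node_scores[[as.character(root)]]
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    acc[ch] <- acc[p] + if (ch > ntip) node_scores[[as.character(ch)]] else 0
  }
  leaf_scores <- acc[seq_len(ntip)]
  names(leaf_scores) <- tips
  structure(
    list(node_scores = node_scores, leaf_scores = leaf_scores,
         tree_score = mean(leaf_scores)),
    class = "tcs_result"
  )
}

#' @export
print.tcs_result <- function(x, ...) {
  cat(sprintf("TCS tree score: %.4g over %d leaves (leaf scores %g..%g)\n",
              x$tree_score, length(x$leaf_scores), min(x$leaf_scores),
              max(x$leaf_scores)))
  invisible(x)
}

#' Variance of normalised root-to-tip distances
#'
#' Root-to-tip path lengths are divided by their mean and the population
#' variance of the normalised values is returned — the squared coefficient
#' of variation of root-to-tip distances. It is 0 exactly when the tree is
#' ultrametric (a strict molecular clock) and invariant to rescaling all
#' branch lengths, so trees of different depths are comparable.
#'
#' @param tree rooted [ape::phylo] tree with at least 2 leaves.
#' @return non-negative scalar.
#' @export
rtt_variance <- function(tree) {
  x <- root_to_tip(tree)
  if (length(x) < 2L) stop("need at least 2 leaves", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("mean root-to-tip distance is zero", call. = FALSE)
  z <- x / m
  mean((z - mean(z))^2)
}

#' Winner proportions with multinomial error bars
#'
#' Benchmark tabulation: for a table of per-family scores (rows = protein
#' families, columns = tree-building methods), find the winning method per
#' family, and report each method's proportion of wins with the standard
#' error of a multinomial proportion, `sqrt(p (1 - p) / n)`. A k-way tie
#' within a family awards 1/k of a win to each tied method, so proportions
#' always sum to 1. Scores are only ever compared within a family (one
#' row), never across rows.
#'
#' @param table numeric matrix or data frame, families x methods; each row
#'   must contain at least one finite score. `NA` cells (method not run on
#'   that family) never win.
#' @return data frame with columns `method`, `wins`, `proportion`, `se`.
#' @export
winner_proportions <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty score table", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  bad <- which(!apply(m, 1L, function(r) any(is.finite(r))))
  if (length(bad) > 0L) {
    stop("row ", bad[1L], " has no finite score", call. = FALSE)
  }
  n <- nrow(m)
  wins <- numeric(ncol(m))
  for (i in seq_len(n)) {
    r <- m[i, ]
    best <- max(r, na.rm = TRUE)
    tied <- which(is.finite(r) & r == best)
    wins[tied] <- wins[tied] + 1 / length(tied)
  }
  p <- wins / n
  data.frame(method = colnames(m), wins = wins, proportion = p,
             se = sqrt(p * (1 - p) / n), row.names = NULL,
             stringsAsFactors = FALSE)
}
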