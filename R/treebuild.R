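#' Infer an unrooted tree by neighbor joining
#'
#' Canonical Saitou–Nei neighbor joining (via [ape::nj()]) on a corrected
#' distance matrix. NJ is consistent: on an additive matrix it recovers the
#' generating topology and branch lengths exactly. Because
#' [hits_to_similarity()] orders labels lexicographically, the output is
#' deterministic for a given hit table. Negative estimated branch lengths
#' (which arise under noise) are clamped to 0 with a message; no length is
#' transferred to neighbouring branches.
#'
#' @param D labelled symmetric non-negative distance matrix with zero
#'   diagonal; n >= 2 taxa. With n = 2 the single pairwise distance is
#'   returned as a two-branch cherry splitting it evenly.
#' @return unrooted [ape::phylo] tree over all labels.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix must be labelled", call. = FALSE)
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    # two taxa: the split distance is all there is (no unrooted topology)
    return(ape::read.tree(text = sprintf("(%s:%.9g,%s:%.9g);",
                                         rownames(D)[1L], D[1L, 2L] / 2,
                                         rownames(D)[2L], D[1L, 2L] / 2)))
  }
  tree <- ape::nj(as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Robinson–Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies (symmetric difference); 0 iff the unrooted
#' topologies are identical. Branch lengths are ignored.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
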