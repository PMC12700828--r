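#' Re-root a tree at a point along an edge
#'
#' Places a new root node on edge `edge_idx` at distance `x` from the
#' child end, then re-orients the whole tree away from it. Used by
#' [mad_root()]; exported because it is occasionally useful for placing a
#' root found by other means.
#'
#' @param tree [ape::phylo] tree (rooted input is unrooted first).
#' @param edge_idx row index into `tree$edge`.
#' @param x distance from the child node of the edge, in `[0, edge length]`.
#' @return rooted [ape::phylo] tree with a binary root.
#' @export
reroot_at_edge <- function(tree, edge_idx, x) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  E <- tree$edge
  L <- tree$edge.length
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  len <- L[edge_idx]
  if (x < 0 || x > len + 1e-12) stop("x outside the edge", call. = FALSE)
  x <- min(max(x, 0), len)

  adj <- vector("list", ntot)
  for (k in seq_len(nrow(E))) {
    if (k == edge_idx) next
    a <- E[k, 1L]; b <- E[k, 2L]
    adj[[a]] <- c(adj[[a]], list(c(b, L[k])))
    adj[[b]] <- c(adj[[b]], list(c(a, L[k])))
  }
  pnode <- E[edge_idx, 1L]; cnode <- E[edge_idx, 2L]

  root_new <- ntip + 1L
  next_internal <- ntip + 2L
  n_edges <- nrow(E) + 1L
  new_edge <- matrix(0L, n_edges, 2L)
  new_len <- numeric(n_edges)
  filled <- 0L
  visited <- logical(ntot)
  visited[c(pnode, cnode)] <- TRUE
  # stack entries: (old node id, new parent id, incoming edge length)
  stack <- list(list(pnode, root_new, len - x), list(cnode, root_new, x))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    old <- top[[1L]]
    if (old <= ntip) {
      new_id <- old
    } else {
      new_id <- next_internal
      next_internal <- next_internal + 1L
    }
    filled <- filled + 1L
    new_edge[filled, ] <- c(top[[2L]], new_id)
    new_len[filled] <- top[[3L]]
    for (nb in adj[[old]]) {
      if (!visited[nb[1L]]) {
        visited[nb[1L]] <- TRUE
        stack[[length(stack) + 1L]] <- list(as.integer(nb[1L]), new_id, nb[2L])
      }
    }
  }
  out <- list(edge = new_edge, edge.length = new_len,
              tip.label = tree$tip.label, Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Root a tree by minimal ancestor deviation (MAD)
#'
#' For every branch and candidate root position rho on it, MAD measures how
#' far the tree departs from a molecular clock when rooted there: the
#' root-mean-square, over all leaf pairs (b, c) on opposite sides of rho, of
#' the relative deviation `|2 d(rho, b) / d(b, c) - 1|` of the induced
#' ancestor from the pair midpoint. The root is placed at the global
#' minimiser. The deviation is a ratio of path lengths, so the placement is
#' invariant to rescaling all branch lengths; on a perfectly ultrametric
#' tree the minimal deviation is exactly 0 at the true root.
#'
#' The optimal position on each branch is found in closed form (the
#' objective is a convex quadratic in rho, clamped to the branch), not by
#' grid search. Leaf pairs with zero inter-leaf distance are skipped with a
#' warning. Ties between branches are broken toward the most balanced leaf
#' split, then lexicographically, so output is deterministic.
#'
#' @param tree [ape::phylo] tree with n >= 3 leaves and non-negative branch
#'   lengths, not all zero. A rooted input is unrooted first.
#' @return object of class `foldtree_mad`: list with `tree` (the rooted
#'   tree), `scores` (data frame of per-branch minimal deviation and
#'   optimal position — ambiguity diagnostics), and `best` (row index of
#'   the chosen branch).
#' @export
mad_root <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("MAD rooting needs at least 3 leaves", call. = FALSE)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (sum(tree$edge.length) == 0) {
    stop("all branch lengths are zero; deviation undefined", call. = FALSE)
  }
  E <- tree$edge
  L <- tree$edge.length
  D <- ape::dist.nodes(tree)
  desc <- phangorn::Descendants(tree, type = "tips")
  warned_zero <- FALSE

  n_edge <- nrow(E)
  pos <- numeric(n_edge)
  score <- numeric(n_edge)
  balance <- integer(n_edge)
  side_key <- character(n_edge)
  for (e in seq_len(n_edge)) {
    cnode <- E[e, 2L]
    in_tips <- desc[[cnode]]
    out_tips <- setdiff(seq_len(ntip), in_tips)
    db <- D[cnode, in_tips]
    dbc <- D[in_tips, out_tips, drop = FALSE]
    ok <- dbc > 0
    if (!all(ok) && !warned_zero) {
      warning("leaf pairs with zero inter-leaf distance skipped in MAD",
              call. = FALSE)
      warned_zero <- TRUE
    }
    A <- ifelse(ok, 1 / dbc, 0)
    dB <- matrix(db, nrow = length(in_tips), ncol = length(out_tips))
    sA <- sum(A[ok])
    sA2 <- sum(A[ok]^2)
    sBA2 <- sum((dB * A^2)[ok])
    if (sA2 == 0) { # every straddling pair degenerate
      pos[e] <- 0; score[e] <- Inf
    } else {
      xs <- (sA - 2 * sBA2) / (2 * sA2)
      xs <- min(max(xs, 0), L[e])
      dev <- (2 * (dB + xs) * A - 1)[ok]
      pos[e] <- xs
      score[e] <- sqrt(mean(dev^2))
    }
    balance[e] <- abs(length(in_tips) - length(out_tips))
    small <- if (length(in_tips) <= length(out_tips)) in_tips else out_tips
    side_key[e] <- paste(sort(tree$tip.label[small]), collapse = "|")
  }

  best_score <- min(score)
  cand <- which(score <= best_score + 1e-12)
  if (length(cand) > 1L) {
    cand <- cand[balance[cand] == min(balance[cand])]
    cand <- cand[order(side_key[cand])]
  }
  best <- cand[1L]
  rooted <- reroot_at_edge(tree, best, pos[best])
  structure(
    list(tree = rooted,
         scores = data.frame(parent = E[, 1L], child = E[, 2L], length = L,
                             position = pos, score = score),
         best = best),
    class = "foldtree_mad"
  )
}

#' @export
print.foldtree_mad <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "MAD rooting: root on branch %d->%d at %.4g from the child end (deviation %.4g)\n",
    x$scores$parent[b], x$scores$child[b], x$scores$position[b],
    x$scores$score[b]))
  invisible(x)
}

#' Root-to-tip path lengths
#'
#' Sum of branch lengths from the root to each leaf, the quantity whose
#' spread measures departure from a strict molecular clock.
#'
#' @param tree rooted [ape::phylo] tree.
#' @return named numeric vector, one non-negative length per leaf, in the
#'   tree's leaf order.
#' @seealso [rtt_variance()]
#' @export
root_to_tip <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)
  out <- depths[seq_along(tree$tip.label)]
  names(out) <- tree$tip.label
  out
}
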