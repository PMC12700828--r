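# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and where possible the
# libraries) used by the package functions they verify.

# --- tree plumbing ---------------------------------------------------------

# parent vector and root of an ape tree as stored
.orc_parents <- function(tree) {
  ntot <- length(tree$tip.label) + tree$Nnode
  parent <- integer(ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

# depth (path length from stored root) of every node, by walking parents
.orc_depths <- function(tree) {
  parent <- .orc_parents(tree)
  elen <- numeric(length(parent))
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- length(tree$tip.label) + 1L
  depths <- rep(NA_real_, length(parent))
  depths[root] <- 0
  depth_of <- function(v) {
    if (!is.na(depths[v])) return(depths[v])
    d <- depth_of(parent[v]) + elen[v]
    depths[v] <<- d
    d
  }
  for (v in seq_along(parent)) depth_of(v)
  depths
}

# ancestor chain of a node up to the stored root
.orc_ancestors <- function(tree, v) {
  parent <- .orc_parents(tree)
  root <- length(tree$tip.label) + 1L
  out <- v
  while (v != root) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}

# patristic distance between two nodes via depths and the MRCA
oracle_node_dist <- function(tree, a, b) {
  depths <- .orc_depths(tree)
  anc_a <- .orc_ancestors(tree, a)
  anc_b <- .orc_ancestors(tree, b)
  mrca <- anc_a[anc_a %in% anc_b][1L]
  depths[a] + depths[b] - 2 * depths[mrca]
}

# full leaf-by-leaf patristic matrix by pairwise walks
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  D <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      D[i, j] <- D[j, i] <- oracle_node_dist(tree, i, j)
    }
  }
  ord <- order(rownames(D))
  D[ord, ord]
}

# tips below each node, by recursion over a children list
oracle_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  children <- vector("list", ntot)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    children[[p]] <- c(children[[p]], tree$edge[k, 2L])
  }
  sets <- vector("list", ntot)
  rec <- function(v) {
    if (v <= ntip) {
      sets[[v]] <<- v
    } else {
      sets[[v]] <<- unlist(lapply(children[[v]], rec))
    }
    sets[[v]]
  }
  rec(ntip + 1L)
  sets
}

# canonical non-trivial bipartitions of an unrooted topology, as strings
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  sets <- oracle_tip_sets(tree)
  all_labels <- sort(tree$tip.label)
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    if (ch <= ntip) next
    side <- sort(tree$tip.label[sets[[ch]]])
    other <- setdiff(all_labels, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (all_labels[1L] %in% side) other else side
    keys <- c(keys, paste(canon, collapse = ","))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- MAD grid-search oracle -----------------------------------------------

# exhaustive grid search of the straddling-pair RMS deviation objective;
# rel_step is the grid step as a fraction of each branch length
oracle_mad_grid <- function(tree, rel_step = 1e-4) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  depths <- .orc_depths(tree)
  P <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      P[i, j] <- P[j, i] <- oracle_node_dist(tree, i, j)
    }
  }
  sets <- oracle_tip_sets(tree)
  best <- list(score = Inf, edge = NA_integer_, x = NA_real_)
  for (e in seq_len(nrow(tree$edge))) {
    cnode <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    in_tips <- sets[[cnode]]
    out_tips <- setdiff(seq_len(ntip), in_tips)
    pairs <- expand.grid(b = in_tips, cc = out_tips)
    dcb <- depths[pairs$b] - depths[cnode]
    dbc <- P[cbind(pairs$b, pairs$cc)]
    keep <- dbc > 0
    if (!any(keep)) next
    A <- 1 / dbc[keep]
    B <- dcb[keep]
    xs <- seq(0, len, by = max(len * rel_step, 1e-12))
    dev <- (2 * A * B - 1) + (2 * A) %o% xs
    rms <- sqrt(colMeans(dev^2))
    g <- which.min(rms)
    if (rms[g] < best$score) {
      best <- list(score = rms[g], edge = e, x = xs[g])
    }
  }
  best
}

# --- TCS recursion oracle --------------------------------------------------

# independent recursive set-intersection scoring of a rooted tree
oracle_tcs <- function(tree, lineages) {
  if (is.data.frame(lineages)) {
    ids <- as.character(lineages[[1L]])
    ranks <- names(lineages)[-1L]
    lineages <- setNames(lapply(seq_along(ids), function(i) {
      v <- as.character(unlist(lineages[i, -1L]))
      names(v) <- ranks
      v[nzchar(v)]
    }), ids)
  }
  ntip <- length(tree$tip.label)
  children <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    children[[p]] <- c(children[[p]], tree$edge[k, 2L])
  }
  leaf_scores <- numeric(0)
  rec <- function(v, acc) {
    if (v <= ntip) {
      lin <- lineages[[tree$tip.label[v]]]
      leaf_scores[tree$tip.label[v]] <<- NA # placeholder until second pass
      return(list(set = paste(names(lin), lin, sep = "|"), leaves = v))
    }
    subs <- lapply(children[[v]], rec, acc = acc)
    set <- Reduce(intersect, lapply(subs, `[[`, "set"))
    list(set = set, leaves = unlist(lapply(subs, `[[`, "leaves")),
         children = subs, score = length(set))
  }
  top <- rec(ntip + 1L, 0)
  # second pass: accumulate internal-node scores down each path
  walk <- function(node, acc) {
    if (is.null(node$children)) {
      leaf_scores[tree$tip.label[node$leaves]] <<- acc
      return(invisible())
    }
    for (ch in node$children) walk(ch, acc + if (is.null(ch$children)) 0 else ch$score)
  }
  walk(top, top$score)
  list(leaf_scores = leaf_scores, tree_score = mean(leaf_scores))
}

# --- corecut oracles -------------------------------------------------------

# per-residue membership count by explicit loops
oracle_coverage <- function(hits, protein_id, n_total, len) {
  cov <- numeric(len)
  for (r in seq_len(len)) {
    partners <- character(0)
    for (k in seq_len(nrow(hits))) {
      if (hits$query[k] == protein_id && hits$target[k] != protein_id &&
          hits$qstart[k] <= r && r <= hits$qend[k]) {
        partners <- c(partners, hits$target[k])
      }
      if (hits$target[k] == protein_id && hits$query[k] != protein_id &&
          hits$tstart[k] <= r && r <= hits$tend[k]) {
        partners <- c(partners, hits$query[k])
      }
    }
    cov[r] <- length(unique(partners)) / n_total
  }
  cov
}

oracle_find_core <- function(coverage, threshold) {
  first <- NA_integer_
  last <- NA_integer_
  for (r in seq_along(coverage)) {
    if (coverage[r] > threshold) {
      if (is.na(first)) first <- r
      last <- r
    }
  }
  if (is.na(first)) return(NULL)
  c(first, last)
}
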