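#' Per-residue alignment coverage of one protein
#'
#' Maps the family's pairwise alignments onto one protein: for each residue,
#' the fraction of the *other* proteins in the set that have at least one
#' alignment whose span on this protein contains the residue. Distinct
#' partner proteins are counted, not alignment rows, so reciprocal
#' duplicate hits never double-count.
#'
#' @param hits alignment hit table (rows where the protein appears on
#'   either side are used; others are ignored).
#' @param protein_id the protein whose profile is computed.
#' @param n_total number of other proteins in the set (the denominator);
#'   defaults to the number of distinct partners appearing in `hits`.
#' @param length protein length; defaults to the qlen/tlen recorded for it.
#' @return object of class `coverage_profile`: list with `protein_id` and
#'   numeric `coverage` in \[0, 1\], one value per residue.
#' @export
coverage_profile <- function(hits, protein_id, n_total = NULL, length = NULL) {
  as_q <- hits$query == protein_id & hits$target != protein_id
  as_t <- hits$target == protein_id & hits$query != protein_id
  partners <- c(hits$target[as_q], hits$query[as_t])
  starts <- c(hits$qstart[as_q], hits$tstart[as_t])
  ends <- c(hits$qend[as_q], hits$tend[as_t])
  if (is.null(length)) {
    lens <- c(hits$qlen[as_q], hits$tlen[as_t],
              hits$tlen[hits$target == protein_id],
              hits$qlen[hits$query == protein_id])
    if (base::length(lens) == 0L) {
      stop("protein '", protein_id, "' absent from hit table", call. = FALSE)
    }
    length <- max(lens)
  }
  if (is.null(n_total)) n_total <- base::length(unique(partners))
  if (n_total < 1L) stop("n_total must be at least 1", call. = FALSE)

  counts <- integer(length)
  for (p in unique(partners)) {
    sel <- partners == p
    covered <- logical(length)
    for (k in which(sel)) {
      covered[starts[k]:ends[k]] <- TRUE
    }
    counts <- counts + covered
  }
  structure(
    list(protein_id = protein_id, coverage = counts / n_total),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d residues, coverage %.2f..%.2f\n",
              x$protein_id, length(x$coverage), min(x$coverage),
              max(x$coverage)))
  invisible(x)
}

#' A consensus-core span on one protein
#'
#' @param protein_id protein identifier.
#' @param start,end 1-based inclusive residue positions.
#' @return object of class `core_region`.
#' @export
core_region <- function(protein_id, start, end) {
  if (start < 1L || start > end) stop("invalid core region", call. = FALSE)
  structure(list(protein_id = protein_id, start = as.integer(start),
                 end = as.integer(end)),
            class = "core_region")
}

#' Locate the consensus core from a coverage profile
#'
#' The core is the continuous region between the first and the last residue
#' whose coverage strictly exceeds the threshold. Interior residues that
#' dip below the threshold are retained: the core is a single span, not the
#' union of high-coverage islands.
#'
#' @param profile a [coverage_profile()].
#' @param threshold coverage fraction in (0, 1); default 0.8, i.e. over 80%
#'   of the dataset must map to the boundary residues.
#' @return a [core_region()].
#' @export
find_core <- function(profile, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  idx <- which(profile$coverage > threshold)
  if (length(idx) == 0L) {
    stop("no residue of '", profile$protein_id, "' exceeds coverage ",
         threshold, "; no core", call. = FALSE)
  }
  core_region(profile$protein_id, min(idx), max(idx))
}

#' Trim a homolog set to its consensus structural core
#'
#' Runs [coverage_profile()] and [find_core()] for every structure and
#' splits each protein into three pieces: the core (used for tree
#' building), and the N- and C-terminal fragments outside it (candidate
#' variable domains, later clustered for tree annotation). Proteins in
#' which no residue reaches the coverage threshold are excluded with a
#' warning. Empty fragments are dropped.
#'
#' After trimming, similarities must be recomputed on the cores (a fresh
#' all-versus-all table, or [similarity_table_from_tree()] in synthetic
#' work) before building the core tree.
#'
#' @param structures named list of [structure_record()] objects (names =
#'   protein ids) — or a named integer vector of protein lengths, in which
#'   case only regions are computed and no records are sliced.
#' @param hits alignment hit table over those proteins.
#' @param threshold coverage threshold passed to [find_core()].
#' @return list with `cores`, `n_fragments`, `c_fragments` (named lists of
#'   trimmed records, or of `core_region` spans if lengths were supplied),
#'   `regions` (named list of [core_region()]) and `excluded` (ids).
#' @export
trim_set <- function(structures, hits, threshold = 0.8) {
  lengths_only <- !is.list(structures)
  ids <- names(structures)
  if (is.null(ids)) stop("structures must be named by protein id", call. = FALSE)
  n_total <- length(structures) - 1L
  if (n_total < 1L) stop("need at least 2 proteins", call. = FALSE)

  cores <- list(); nfr <- list(); cfr <- list()
  regions <- list(); excluded <- character(0)
  for (id in ids) {
    len <- if (lengths_only) structures[[id]] else length(structures[[id]])
    prof <- coverage_profile(hits, id, n_total = n_total, length = len)
    reg <- tryCatch(find_core(prof, threshold), error = function(e) NULL)
    if (is.null(reg)) {
      warning("no core found for ", id, "; excluded", call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    regions[[id]] <- reg
    if (lengths_only) {
      cores[[id]] <- reg
      if (reg$start > 1L) nfr[[id]] <- core_region(id, 1L, reg$start - 1L)
      if (reg$end < len) cfr[[id]] <- core_region(id, reg$end + 1L, len)
    } else {
      s <- structures[[id]]
      cores[[id]] <- .subset_record(s, reg$start:reg$end)
      if (reg$start > 1L) {
        nfr[[id]] <- .subset_record(s, 1:(reg$start - 1L),
                                    id = paste0(id, "_N"))
      }
      if (reg$end < len) {
        cfr[[id]] <- .subset_record(s, (reg$end + 1L):len,
                                    id = paste0(id, "_C"))
      }
    }
  }
  list(cores = cores, n_fragments = nfr, c_fragments = cfr,
       regions = regions, excluded = excluded)
}

#' Cluster trimmed terminal fragments
#'
#' Single-linkage clustering of the N-/C-terminal fragments cut off by
#' [trim_set()], from pairwise structural-alignment scores among the
#' fragments: two fragments join the same cluster when connected by a chain
#' of alignments at or above the similarity threshold. Cluster labels are
#' deterministic — each cluster is named after its lexicographically
#' smallest member. Fragments shorter than `min_length` are labelled
#' `"none"` and take no part in clustering. Singletons are allowed.
#'
#' @param fragments named list of fragment records (or named integer vector
#'   of fragment lengths); names are fragment ids.
#' @param pairwise_scores alignment hit table among the fragments (same
#'   tabular dialect as [read_alignment_tsv()]).
#' @param metric score column used for the threshold; default `"fident"`.
#' @param threshold minimum similarity for an edge; default 0.3.
#' @param min_length fragments shorter than this are labelled `"none"`;
#'   default 10 residues.
#' @return named character vector: fragment id -> cluster label.
#' @export
cluster_termini <- function(fragments, pairwise_scores = NULL,
                            metric = c("fident", "lddt", "tm"),
                            threshold = 0.3, min_length = 10L) {
  metric <- match.arg(metric)
  ids <- names(fragments)
  lens <- if (is.list(fragments)) {
    vapply(fragments, length, integer(1L))
  } else {
    as.integer(fragments)
  }
  labels <- setNames(rep(NA_character_, length(ids)), ids)
  labels[lens < min_length] <- "none"
  active <- ids[lens >= min_length]

  # union-find over active fragments
  parent <- setNames(seq_along(active), active)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (!is.null(pairwise_scores) && nrow(pairwise_scores) > 0L) {
    col <- .metric_column(metric)
    sel <- pairwise_scores$query %in% active &
      pairwise_scores$target %in% active &
      pairwise_scores$query != pairwise_scores$target &
      pairwise_scores[[col]] >= threshold
    qi <- match(pairwise_scores$query[sel], active)
    ti <- match(pairwise_scores$target[sel], active)
    for (k in seq_along(qi)) {
      ri <- find(qi[k]); rj <- find(ti[k])
      if (ri != rj) parent[[rj]] <- ri
    }
  }
  roots <- vapply(seq_along(active), find, integer(1L))
  for (r in unique(roots)) {
    members <- active[roots == r]
    labels[members] <- min(members)
  }
  labels
}
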