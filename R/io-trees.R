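#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that additionally rejects duplicate
#' leaf labels, which the rest of the pipeline requires to be unique.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in '", path, "'", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in '", path, "'", call. = FALSE)
  }
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 9 significant digits so that a
#' write-then-read round trip preserves them to well below 1e-9 relative.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 9)
  invisible(path)
}

#' Read / write a PHYLIP square distance matrix
#'
#' The square (lower+upper) PHYLIP distance format: a first line holding n,
#' then one line per taxon with its label and n distances. Used to exchange
#' corrected distance matrices with external distance-tree programs.
#'
#' @param path file path.
#' @return `read_phylip_dist`: a labelled symmetric numeric matrix.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop("'", path, "' is not a square PHYLIP distance matrix", call. = FALSE)
  }
  labels <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(fields) != n + 1L) {
      stop("line ", i + 1L, " of '", path, "': expected ", n + 1L,
           " fields, found ", length(fields), call. = FALSE)
    }
    labels[i] <- fields[1L]
    m[i, ] <- as.numeric(fields[-1L])
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' @rdname read_phylip_dist
#' @param D labelled symmetric numeric matrix.
#' @export
write_phylip_dist <- function(D, path) {
  labels <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(labels[i], formatC(D[i, ], format = "g", digits = 9)),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' Read leaf lineages from a TSV table
#'
#' First column: leaf identifier; remaining columns: taxonomic ranks in a
#' fixed broad-to-narrow order (e.g. kingdom ... species). Empty cells mark
#' unknown ranks and are dropped from that leaf's lineage rather than being
#' treated as wildcard matches.
#'
#' @param path path to the lineage TSV (with header).
#' @return named list mapping leaf id to a named character vector of
#'   rank = taxon entries (unknown ranks absent).
#' @seealso [tcs()], [simulate_taxonomy()]
#' @export
read_lineages <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) {
    stop("lineage table needs an id column plus at least one rank", call. = FALSE)
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate leaf id in lineage table: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  ranks <- names(tab)[-1L]
  out <- lapply(seq_along(ids), function(i) {
    v <- unlist(tab[i, -1L], use.names = FALSE)
    names(v) <- ranks
    v[!is.na(v) & nzchar(v)]
  })
  names(out) <- ids
  out
}

#' Write leaf lineages as a TSV table
#'
#' @param lineages named list as returned by [read_lineages()] or
#'   [simulate_taxonomy()], or a data frame whose first column is the leaf id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  if (is.data.frame(lineages)) {
    tab <- lineages
  } else {
    ranks <- unique(unlist(lapply(lineages, names)))
    tab <- data.frame(id = names(lineages), stringsAsFactors = FALSE)
    for (r in ranks) {
      tab[[r]] <- vapply(lineages, function(v) {
        if (r %in% names(v)) v[[r]] else ""
      }, character(1L))
    }
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coerce lineage input (list or data frame) to the internal list form
#' @noRd
.as_lineage_list <- function(lineages) {
  if (is.data.frame(lineages)) {
    ids <- as.character(lineages[[1L]])
    ranks <- names(lineages)[-1L]
    out <- lapply(seq_along(ids), function(i) {
      v <- as.character(unlist(lineages[i, -1L], use.names = FALSE))
      names(v) <- ranks
      v[!is.na(v) & nzchar(v)]
    })
    names(out) <- ids
    out
  } else {
    lineages
  }
}
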