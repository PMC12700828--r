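#' Required columns of the tabular alignment dialect
#'
#' The named-column TSV dialect produced by structural aligners in
#' exhaustive all-versus-all mode. Extra columns are ignored on read.
#' @noRd
.alignment_columns <- c(
  "query", "target", "fident", "lddt", "alntmscore",
  "qstart", "qend", "tstart", "tend", "qlen", "tlen"
)

.score_columns <- c("fident", "lddt", "alntmscore")

#' Map a metric name to its TSV column
#' @noRd
.metric_column <- function(metric) {
  metric <- match.arg(metric, c("fident", "lddt", "tm"))
  switch(metric, fident = "fident", lddt = "lddt", tm = "alntmscore")
}

#' Validate an alignment hits table
#'
#' Checks the invariants of the tabular dialect: all score fields in
#' \[0, 1\] and 1 <= start <= end <= length on both query and target sides.
#'
#' @param hits data frame of alignment hits.
#' @return `hits`, invisibly, if valid. Otherwise an error naming the first
#'   offending row.
#' @export
validate_hits <- function(hits) {
  missing <- setdiff(.alignment_columns, names(hits))
  if (length(missing) > 0L) {
    stop("alignment table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in .score_columns) {
    v <- hits[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad) > 0L) {
      stop(sprintf("row %d: column '%s' = %s is outside [0, 1]",
                   bad[1L], col, format(v[bad[1L]])), call. = FALSE)
    }
  }
  bad <- which(!(hits$qstart >= 1 & hits$qstart <= hits$qend &
                   hits$qend <= hits$qlen))
  if (length(bad) > 0L) {
    stop(sprintf("row %d: query span violates 1 <= qstart <= qend <= qlen",
                 bad[1L]), call. = FALSE)
  }
  bad <- which(!(hits$tstart >= 1 & hits$tstart <= hits$tend &
                   hits$tend <= hits$tlen))
  if (length(bad) > 0L) {
    stop(sprintf("row %d: target span violates 1 <= tstart <= tend <= tlen",
                 bad[1L]), call. = FALSE)
  }
  invisible(hits)
}

#' Read an all-versus-all structural alignment table
#'
#' Reads the tab-separated, named-column dialect of structural aligner
#' output (one row per directed pairwise comparison). The header must name
#' at least `query`, `target`, `fident`, `lddt`, `alntmscore`, `qstart`,
#' `qend`, `tstart`, `tend`, `qlen` and `tlen`; any extra columns are
#' silently dropped. Row order is preserved and no deduplication is
#' performed: n proteins compared exhaustively yield n^2 rows.
#'
#' @param path path to a TSV file with a header line.
#' @return data frame with the required columns, one row per hit.
#' @seealso [write_alignment_tsv()], [hits_to_similarity()]
#' @export
read_alignment_tsv <- function(path) {
  hits <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.alignment_columns, names(hits))
  if (length(missing) > 0L) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hits <- hits[, .alignment_columns]
  hits$query <- as.character(hits$query)
  hits$target <- as.character(hits$target)
  validate_hits(hits)
  hits
}

#' Write an alignment table in the tabular dialect
#'
#' @param hits data frame as returned by [read_alignment_tsv()] or
#'   [similarity_table_from_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[, .alignment_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
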