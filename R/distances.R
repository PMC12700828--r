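#' Assemble a similarity matrix from alignment hits
#'
#' Compiles the all-versus-all hit table into a labelled symmetric
#' similarity matrix. Each off-diagonal entry is the mean of the selected
#' score over all hits between the two proteins in either direction
#' (exhaustive searches report both directions; averaging them is symmetric
#' and unbiased). The diagonal is forced to 1 and labels are sorted
#' lexicographically, which also makes downstream tree inference
#' deterministic.
#'
#' @param hits data frame of alignment hits (see [read_alignment_tsv()]).
#' @param metric which score to use: `"fident"` (fraction identical in the
#'   structural-alphabet + amino-acid alignment), `"lddt"` or `"tm"`
#'   (alignment-length-normalised TM score).
#' @param impute_missing under the exhaustive-search contract every
#'   unordered pair must have at least one hit; if `FALSE` (default) a
#'   missing pair is an error listing the pairs, if `TRUE` missing entries
#'   are imputed with the minimum observed off-diagonal similarity.
#' @return symmetric numeric matrix with unit diagonal, labels as dimnames.
#' @export
hits_to_similarity <- function(hits, metric = c("fident", "lddt", "tm"),
                               impute_missing = FALSE) {
  metric <- match.arg(metric)
  validate_hits(hits)
  col <- .metric_column(metric)
  labels <- sort(unique(c(hits$query, hits$target)))
  n <- length(labels)
  if (n < 2L) stop("need at least 2 proteins, got ", n, call. = FALSE)

  off <- hits$query != hits$target
  qi <- match(hits$query[off], labels)
  ti <- match(hits$target[off], labels)
  lo <- pmin(qi, ti)
  hi <- pmax(qi, ti)
  key <- (lo - 1L) * n + hi
  sums <- tapply(hits[[col]][off], key, sum)
  counts <- tapply(rep(1L, sum(off)), key, sum)
  means <- sums / counts

  S <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  ki <- as.integer(names(means))
  i <- (ki - 1L) %/% n + 1L
  j <- (ki - 1L) %% n + 1L
  S[cbind(i, j)] <- means
  S[cbind(j, i)] <- means
  diag(S) <- 1

  if (anyNA(S)) {
    miss <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)
    if (impute_missing) {
      fill <- min(S[upper.tri(S)], na.rm = TRUE)
      S[is.na(S)] <- fill
    } else {
      pairs <- apply(miss, 1L, function(r) {
        paste(labels[r[1L]], labels[r[2L]], sep = "~")
      })
      stop("no alignment hit for ", length(pairs), " pair(s): ",
           paste(utils::head(pairs, 10L), collapse = ", "),
           if (length(pairs) > 10L) ", ...",
           " (set impute_missing = TRUE to impute with the matrix minimum)",
           call. = FALSE)
    }
  }
  S
}

#' Transform similarities into evolutionary distances
#'
#' Converts a similarity matrix to a distance matrix either as the raw
#' complement `d = 1 - s` or with a saturation-inverting correction so that
#' pairwise distances grow linearly with divergence time instead of
#' flattening as scores saturate. The default corrected transform is
#' `d = -ln(max(s, eps))`; a fitted per-metric correction can be supplied
#' through `transform`.
#'
#' Both transforms satisfy d(1) = 0 and are strictly decreasing in s, so
#' monotone orderings of similarity are preserved as distance orderings.
#'
#' @param S symmetric similarity matrix in \[0, 1\] with unit diagonal
#'   (see [hits_to_similarity()]).
#' @param mode `"corrected"` (default) or `"raw"`.
#' @param eps clipping floor for the logarithm; similarities at or below
#'   `eps` are clipped (with a warning), bounding the maximum corrected
#'   distance at `-ln(eps)` (about 9.2 at the default 1e-4) and keeping
#'   neighbor joining numerically stable.
#' @param transform optional function `s -> d` replacing the default
#'   corrected transform (must map 1 to 0 and be strictly decreasing).
#' @return non-negative symmetric distance matrix with zero diagonal.
#' @export
correct_similarity <- function(S, mode = c("corrected", "raw"),
                               eps = 1e-4, transform = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1)) {
    stop("similarity values must be finite and in [0, 1]", call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-12) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (mode == "raw") {
    D <- 1 - S
  } else if (!is.null(transform)) {
    D <- transform(S)
    if (any(!is.finite(D)) || any(D < -1e-12)) {
      stop("supplied transform produced non-finite or negative distances",
           call. = FALSE)
    }
    D[D < 0] <- 0
  } else {
    if (any(S < eps & row(S) != col(S))) {
      warning("similarities below eps = ", format(eps),
              " clipped before log transform", call. = FALSE)
    }
    D <- -log(pmax(S, eps))
  }
  D <- (D + t(D)) / 2 + 0 # + 0 normalises IEEE negative zeros
  diag(D) <- 0
  D
}

#' Filter structures by mean pLDDT confidence
#'
#' Predicted models with an average per-residue pLDDT below the threshold
#' are removed before the similarity matrix is assembled, so the label set
#' shrinks consistently across the pipeline. Structures without pLDDT
#' (experimental models) are kept with a warning.
#'
#' @param structures list of [structure_record()] objects.
#' @param threshold minimum mean pLDDT in \[0, 100\]; default 40.
#' @return list with character vectors `kept` and `removed` (protein ids).
#' @export
filter_by_plddt <- function(structures, threshold = 40) {
  if (threshold < 0 || threshold > 100) {
    stop("threshold must be in [0, 100]", call. = FALSE)
  }
  ids <- unname(vapply(structures, function(s) s$protein_id, character(1L)))
  keep <- vapply(structures, function(s) {
    if (is.null(s$plddt)) {
      warning("structure ", s$protein_id,
              " has no pLDDT; kept (experimental structures are not filtered)",
              call. = FALSE)
      return(TRUE)
    }
    mean(s$plddt) >= threshold
  }, logical(1L))
  list(kept = ids[keep], removed = ids[!keep])
}
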