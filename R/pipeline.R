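#' Run the full pipeline on files and write its outputs
#'
#' File-level wrapper around [foldtree()] for scripted use: reads the hit
#' table (and optional structures and lineages), fits the tree, and writes
#' the rooted Newick, the corrected distance matrix in PHYLIP square
#' format, a JSON metrics report and a JSON manifest of every parameter of
#' the run. Rerunning with the same inputs and config reproduces the
#' outputs byte for byte.
#'
#' @param hits_tsv path to the alignment hit TSV.
#' @param out_dir output directory (created if needed).
#' @param structures_dir optional directory of PDB files (one per protein).
#' @param lineages_tsv optional lineage TSV for TCS.
#' @param metric,mode,plddt_threshold,impute_missing,external_tree passed
#'   to [foldtree()] (`plddt_threshold` only takes effect with
#'   `structures_dir`).
#' @return the `foldtree` fit, invisibly; side effect: files
#'   `rooted.nwk`, `distances.phylip`, `mad_scores.tsv`, `report.json`,
#'   `manifest.json` in `out_dir`.
#' @export
run_foldtree <- function(hits_tsv, out_dir, structures_dir = NULL,
                         lineages_tsv = NULL, metric = "fident",
                         mode = "corrected", plddt_threshold = NULL,
                         impute_missing = FALSE, external_tree = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- read_alignment_tsv(hits_tsv)
  message("stage io: ", nrow(hits), " hits read from ", hits_tsv)

  structures <- NULL
  if (!is.null(structures_dir)) {
    files <- sort(list.files(structures_dir, pattern = "\\.pdb$",
                             full.names = TRUE))
    structures <- lapply(files, read_pdb_ca)
    names(structures) <- vapply(structures, function(s) s$protein_id,
                                character(1L))
    message("stage io: ", length(structures), " structures read")
  }
  lineages <- if (!is.null(lineages_tsv)) read_lineages(lineages_tsv)

  fit <- foldtree(hits, metric = metric, mode = mode,
                  structures = structures,
                  plddt_threshold = plddt_threshold, lineages = lineages,
                  external_tree = external_tree,
                  impute_missing = impute_missing)
  message("stage fit: ", length(fit$tree$tip.label), " leaves",
          if (!is.null(fit$filtered)) {
            paste0(", ", length(fit$filtered$removed), " removed by pLDDT filter")
          })

  write_newick(fit$tree, file.path(out_dir, "rooted.nwk"))
  write_phylip_dist(fit$distances, file.path(out_dir, "distances.phylip"))
  utils::write.table(fit$mad$scores, file.path(out_dir, "mad_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    n_leaves = length(fit$tree$tip.label),
    metric = metric, mode = mode,
    rtt_variance = fit$rtt_variance,
    mad_deviation = fit$mad$scores$score[fit$mad$best],
    n_structures_removed = if (is.null(fit$filtered)) 0L
      else length(fit$filtered$removed)
  )
  if (!is.null(fit$tcs)) report$tcs <- fit$tcs$tree_score
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    hits_tsv = hits_tsv, structures_dir = structures_dir,
    lineages_tsv = lineages_tsv, metric = metric, mode = mode,
    plddt_threshold = plddt_threshold, impute_missing = impute_missing,
    external_tree = if (is.character(external_tree)) external_tree,
    package_version = as.character(utils::packageVersion("foldtree"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(fit)
}
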