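#' Construct a CA-trace structure record
#'
#' Minimal per-protein container: ordered C-alpha coordinates, the
#' amino-acid sequence, original residue numbering, and (for predicted
#' models) the per-residue pLDDT confidence read from the B-factor column.
#'
#' @param protein_id protein identifier.
#' @param ca_coords numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param sequence one-letter amino-acid string of length n.
#' @param plddt optional numeric vector of length n in \[0, 100\];
#'   `NULL` for experimental structures.
#' @param resno optional original residue numbers (defaults to `1:n`).
#' @return object of class `structure_record`.
#' @export
structure_record <- function(protein_id, ca_coords, sequence,
                             plddt = NULL, resno = NULL) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  seq_chars <- strsplit(sequence, "")[[1L]]
  if (length(seq_chars) != n) {
    stop("sequence length (", length(seq_chars),
         ") does not match number of CA coordinates (", n, ")", call. = FALSE)
  }
  if (!is.null(plddt) && length(plddt) != n) {
    stop("plddt length does not match number of residues", call. = FALSE)
  }
  if (is.null(resno)) resno <- seq_len(n)
  structure(
    list(protein_id = as.character(protein_id), ca_coords = ca_coords,
         sequence = sequence, plddt = plddt, resno = as.integer(resno)),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record> ", x$protein_id, ": ", nrow(x$ca_coords),
      " residues", sep = "")
  if (!is.null(x$plddt)) {
    cat(sprintf(", mean pLDDT %.1f", mean(x$plddt)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.structure_record <- function(x) nrow(x$ca_coords)

#' Subset a structure record to a residue index range
#' @noRd
.subset_record <- function(s, idx, id = s$protein_id) {
  structure_record(
    protein_id = id,
    ca_coords = s$ca_coords[idx, , drop = FALSE],
    sequence = paste(strsplit(s$sequence, "")[[1L]][idx], collapse = ""),
    plddt = if (!is.null(s$plddt)) s$plddt[idx],
    resno = s$resno[idx]
  )
}

#' Read the C-alpha trace of a PDB file
#'
#' Parses a single-model PDB file (via bio3d), keeping only CA atoms of one
#' chain, in residue order. The first model and first alternate location are
#' used; HETATM records are ignored. The B-factor column is mapped to the
#' `plddt` slot, the convention used by structure-prediction models.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default takes the first chain present.
#' @param protein_id identifier for the record; defaults to the file name
#'   without extension.
#' @return a [structure_record()].
#' @export
read_pdb_ca <- function(path, chain = NULL, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("'", path, "' contains no CA atoms", call. = FALSE)
  }
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("'", path, "' has no CA atoms in chain ", chain, call. = FALSE)
  }
  key <- paste(atoms$resno, atoms$insert)
  if (anyDuplicated(key)) {
    stop("'", path, "' has duplicate residue numbers in chain ", chain,
         call. = FALSE)
  }
  structure_record(
    protein_id = protein_id,
    ca_coords = as.matrix(atoms[, c("x", "y", "z")]),
    sequence = paste(bio3d::aa321(atoms$resid), collapse = ""),
    plddt = atoms$b,
    resno = atoms$resno
  )
}

#' Write the core region of a structure as a trimmed PDB file
#'
#' Writes a CA-only PDB containing exactly the residues of `region`.
#' Original residue numbering is kept by default so trimmed files remain
#' comparable with the untrimmed models.
#'
#' @param s a [structure_record()].
#' @param region a [core_region()] (or any list with `start` and `end`
#'   residue indices, 1-based inclusive into `s`).
#' @param path output path.
#' @param renumber if `TRUE`, residues are renumbered from 1.
#' @return `path`, invisibly.
#' @export
write_trimmed_pdb <- function(s, region, path, renumber = FALSE) {
  n <- length(s)
  if (region$start < 1L || region$end > n || region$start > region$end) {
    stop("core region [", region$start, ", ", region$end,
         "] out of bounds for ", s$protein_id, " (", n, " residues)",
         call. = FALSE)
  }
  idx <- seq.int(region$start, region$end)
  trimmed <- .subset_record(s, idx)
  resno <- if (renumber) seq_along(idx) else trimmed$resno
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(trimmed$ca_coords)),
    resno = resno,
    resid = bio3d::aa123(strsplit(trimmed$sequence, "")[[1L]]),
    elety = rep("CA", length(idx)),
    chain = rep("A", length(idx)),
    b = if (is.null(trimmed$plddt)) rep(0, length(idx)) else trimmed$plddt
  )
  invisible(path)
}
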