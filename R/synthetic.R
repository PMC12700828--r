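#' Simulate a rooted tree under a Yule process
#'
#' Pure-birth (Yule) trees with exponential waiting times, ultrametric by
#' construction; the `clock_noise` model additionally multiplies every
#' branch by independent lognormal(0, sigma) noise, breaking the clock
#' while keeping the topology. Leaves are labelled `t01`, `t02`, ... with
#' zero-padding so lexicographic and numeric orders coincide. Deterministic
#' given the seed.
#'
#' @param n_leaves number of leaves, >= 2.
#' @param model `"yule"` (ultrametric) or `"clock_noise"`.
#' @param birth birth rate of the Yule process; default 1.
#' @param sigma lognormal sdlog of the branch-length noise (clock_noise
#'   model only); `sigma = 0` leaves the tree ultrametric. Default 0.3.
#' @param seed integer seed (mandatory — every fixture must be
#'   reproducible).
#' @return rooted [ape::phylo] tree with branch lengths.
#' @export
simulate_tree <- function(n_leaves, model = c("yule", "clock_noise"),
                          birth = 1, sigma = 0.3, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_leaves < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (birth <= 0) stop("birth rate must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_leaves, birth = birth, death = 0)
  width <- nchar(as.character(n_leaves))
  tree$tip.label <- sprintf(paste0("t%0", width, "d"), seq_len(n_leaves))
  if (model == "clock_noise" && sigma > 0) {
    tree$edge.length <- tree$edge.length *
      stats::rlnorm(length(tree$edge.length), 0, sigma)
  }
  tree
}

#' Patristic distance matrix of a tree
#'
#' Pairwise sums of branch lengths along leaf-to-leaf paths, with rows and
#' columns in lexicographic label order (the order the rest of the pipeline
#' uses). On any tree the result is additive, so neighbor joining recovers
#' the tree exactly.
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @return labelled symmetric matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(D))
  D[ord, ord, drop = FALSE]
}

#' Describe a simulated core/terminal domain architecture
#'
#' Layout used by [similarity_table_from_tree()] to emit alignment spans:
#' every protein shares a structural core; members listed in `n_members`
#' carry the N-terminal stretch preceding the core (residues
#' `1..core[1]-1` in their local numbering, so their core sits at `core`),
#' while other members start directly at the core (local core
#' `1..core[2]-core[1]+1`). Members in `c_members` carry an extra
#' C-terminal domain of `c_len` residues after the core. Alignments only
#' ever span core residues.
#'
#' @param core integer pair `c(start, end)`: the core span in the local
#'   coordinates of a member carrying the N-terminal stretch.
#' @param n_members leaf labels carrying the N-terminal stretch; `NULL`
#'   (default) means all of them.
#' @param c_len length of the optional C-terminal domain; default 0.
#' @param c_members leaf labels carrying the C-terminal domain.
#' @return object of class `domain_architecture`.
#' @export
domain_architecture <- function(core = c(50L, 200L), n_members = NULL,
                                c_len = 0L, c_members = character(0)) {
  if (length(core) != 2L || core[1L] < 1L || core[1L] > core[2L]) {
    stop("core must be c(start, end) with 1 <= start <= end", call. = FALSE)
  }
  structure(list(core = as.integer(core), n_members = n_members,
                 c_len = as.integer(c_len),
                 c_members = as.character(c_members)),
            class = "domain_architecture")
}

#' Per-leaf layout (local core span + length) under an architecture
#' @noRd
.arch_layout <- function(arch, label) {
  has_n <- is.null(arch$n_members) || label %in% arch$n_members
  core_len <- arch$core[2L] - arch$core[1L] + 1L
  start <- if (has_n) arch$core[1L] else 1L
  end <- start + core_len - 1L
  len <- end + if (label %in% arch$c_members) arch$c_len else 0L
  list(start = start, end = end, len = len)
}

#' Simulate an exhaustive all-versus-all alignment table from a tree
#'
#' Emulates the tabular output of an exhaustive structural aligner for the
#' leaves of a tree: for every ordered pair the fident/lddt/tm scores are
#' `clip(exp(-d) + N(0, noise_sd), 0, 1)` where d is the patristic
#' distance, and self-hits score 1 over the full span. The `exp(-d)` decay
#' pairs with the `-ln` corrected transform of [correct_similarity()], so
#' at `noise_sd = 0` the pipeline is exactly invertible — a test
#' convention, not a claim about the real score–time relation. Alignment
#' spans cover exactly the shared core of the optional
#' [domain_architecture()] (default: full-length proteins of 100 residues),
#' which is what makes the corecut stage exercisable on synthetic data.
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @param noise_sd standard deviation of the additive Gaussian score noise;
#'   default 0.
#' @param architecture optional [domain_architecture()].
#' @param seed integer seed (mandatory).
#' @param base_length protein length when no architecture is given.
#' @return alignment hit table (data frame in the dialect of
#'   [read_alignment_tsv()]), with the seed recorded in
#'   `attr(, "seed")`.
#' @export
similarity_table_from_tree <- function(tree, noise_sd = 0,
                                       architecture = NULL, seed,
                                       base_length = 100L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  D <- patristic_matrix(tree)
  labels <- rownames(D)
  n <- length(labels)
  layout <- lapply(labels, function(l) {
    if (is.null(architecture)) {
      list(start = 1L, end = as.integer(base_length),
           len = as.integer(base_length))
    } else {
      .arch_layout(architecture, l)
    }
  })
  names(layout) <- labels

  qs <- rep(labels, each = n)
  ts <- rep(labels, times = n)
  d <- D[cbind(match(qs, labels), match(ts, labels))]
  base <- exp(-d)
  noisy <- function() pmin(pmax(base + stats::rnorm(n * n, 0, noise_sd), 0), 1)
  fident <- noisy(); lddt <- noisy(); tm <- noisy()
  self <- qs == ts
  fident[self] <- 1; lddt[self] <- 1; tm[self] <- 1

  ql <- vapply(layout[qs], `[[`, integer(1L), "len")
  tl <- vapply(layout[ts], `[[`, integer(1L), "len")
  qstart <- vapply(layout[qs], `[[`, integer(1L), "start")
  qend <- vapply(layout[qs], `[[`, integer(1L), "end")
  tstart <- vapply(layout[ts], `[[`, integer(1L), "start")
  tend <- vapply(layout[ts], `[[`, integer(1L), "end")
  qstart[self] <- 1L; qend[self] <- ql[self]
  tstart[self] <- 1L; tend[self] <- tl[self]

  hits <- data.frame(query = qs, target = ts, fident = fident, lddt = lddt,
                     alntmscore = tm, qstart = qstart, qend = qend,
                     tstart = tstart, tend = tend, qlen = ql, tlen = tl,
                     stringsAsFactors = FALSE)
  attr(hits, "seed") <- seed
  hits
}

#' Simulated structure records for the leaves of a tree
#'
#' Companion to [similarity_table_from_tree()]: one CA-trace record per
#' leaf with lengths given by the architecture, straight-line placeholder
#' coordinates (no attempt at real fold geometry) and a constant
#' per-residue pLDDT.
#'
#' @param tree [ape::phylo] tree.
#' @param architecture optional [domain_architecture()].
#' @param plddt mean pLDDT assigned to every residue; may be a named vector
#'   (per leaf) to simulate low-confidence models. Default 90.
#' @param base_length protein length when no architecture is given.
#' @return named list of [structure_record()] objects.
#' @export
simulate_structures <- function(tree, architecture = NULL, plddt = 90,
                                base_length = 100L) {
  labels <- sort(tree$tip.label)
  out <- lapply(labels, function(l) {
    len <- if (is.null(architecture)) as.integer(base_length) else
      .arch_layout(architecture, l)$len
    p <- if (!is.null(names(plddt))) plddt[[l]] else plddt
    structure_record(
      protein_id = l,
      ca_coords = cbind(3.8 * seq_len(len), 0, 0),
      sequence = paste(rep("A", len), collapse = ""),
      plddt = rep(p, len)
    )
  })
  names(out) <- labels
  out
}

#' Simulate a taxonomy congruent with a species tree
#'
#' Assigns 7-rank lineages (kingdom ... species) by cutting the rooted tree
#' at a series of increasing depths from the root: leaves descending
#' through the same lineage at a cut share that rank's taxon. The
#' resulting lineages are fully congruent with the tree, so the tree's TCS
#' is maximal among trees on those leaves. Deterministic given the tree
#' and cut depths; the seed argument is accepted for interface symmetry.
#'
#' @param species_tree rooted [ape::phylo] tree (ideally ultrametric).
#' @param rank_depths increasing depths (from the root) at which the 7
#'   ranks are cut; default: fractions
#'   `(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.95)` of the maximum leaf
#'   depth.
#' @param seed unused; present so all simulators share a signature.
#' @return data frame with columns `id`, `kingdom`, ..., `species`
#'   (writable with [write_lineages()], consumable by [tcs()]).
#' @export
simulate_taxonomy <- function(species_tree, rank_depths = NULL, seed = NULL) {
  if (!ape::is.rooted(species_tree)) {
    stop("species tree must be rooted", call. = FALSE)
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  depths <- ape::node.depth.edgelength(species_tree)
  if (is.null(rank_depths)) {
    rank_depths <- max(depths) * c(0.05, 0.20, 0.35, 0.50, 0.65, 0.80, 0.95)
  }
  if (length(rank_depths) != 7L || is.unsorted(rank_depths)) {
    stop("rank_depths must be 7 non-decreasing depths", call. = FALSE)
  }
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  E <- species_tree$edge
  parent <- integer(ntip + species_tree$Nnode)
  parent[E[, 2L]] <- E[, 1L]

  taxon <- function(leaf, h) {
    # shallowest node on the root->leaf path whose depth >= h
    node <- leaf
    while (node != root && depths[parent[node]] >= h) node <- parent[node]
    if (h <= 0) root else node
  }
  tab <- data.frame(id = species_tree$tip.label, stringsAsFactors = FALSE)
  for (r in seq_along(ranks)) {
    tab[[ranks[r]]] <- vapply(seq_len(ntip), function(leaf) {
      sprintf("%s_n%d", substr(ranks[r], 1L, 1L),
              taxon(leaf, rank_depths[r]))
    }, character(1L))
  }
  tab
}

#' Randomly swap leaf labels (TCS negative control)
#'
#' Performs `k_swaps` random transpositions of tip labels, leaving the
#' topology and branch lengths untouched. Used as a negative control:
#' shuffled labels break the congruence between tree and taxonomy.
#'
#' @param tree [ape::phylo] tree.
#' @param k_swaps number of transpositions; 0 returns the tree unchanged.
#' @param seed integer seed (mandatory).
#' @return tree with permuted tip labels.
#' @export
permute_leaves <- function(tree, k_swaps, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (k_swaps < 0) stop("k_swaps must be non-negative", call. = FALSE)
  set.seed(seed)
  labels <- tree$tip.label
  n <- length(labels)
  for (k in seq_len(k_swaps)) {
    ij <- sample.int(n, 2L)
    labels[ij] <- labels[rev(ij)]
  }
  tree$tip.label <- labels
  tree
}
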