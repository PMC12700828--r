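# hand-built hit rows with arbitrary spans on protein P
span_hits <- function(spans, plen = 20L, partner_len = 30L) {
  # spans: data.frame(partner, start, end); one row per alignment, P as query
  data.frame(query = "P", target = spans$partner, fident = 0.5, lddt = 0.5,
             alntmscore = 0.5, qstart = spans$start, qend = spans$end,
             tstart = 1L, tend = partner_len, qlen = plen,
             tlen = partner_len, stringsAsFactors = FALSE)
}

test_that("coverage_profile counts distinct partners, not rows", {
  hits <- span_hits(data.frame(partner = "Q", start = 1L, end = 20L))
  prof <- coverage_profile(hits, "P", n_total = 1L)
  expect_equal(prof$coverage, rep(1, 20))

  # duplicated reciprocal hit must not double-count
  recip <- hits
  recip[, c("query", "target")] <- recip[, c("target", "query")]
  recip[, c("qstart", "qend", "qlen")] <- hits[, c("tstart", "tend", "tlen")]
  recip[, c("tstart", "tend", "tlen")] <- hits[, c("qstart", "qend", "qlen")]
  prof <- coverage_profile(rbind(hits, recip), "P", n_total = 1L,
                           length = 20L)
  expect_equal(prof$coverage, rep(1, 20))

  # 10 partners, a residue covered by 8 of them -> 0.8
  spans <- data.frame(partner = paste0("Q", 1:10),
                      start = c(rep(1L, 8), 11L, 11L),
                      end = rep(20L, 10))
  prof <- coverage_profile(span_hits(spans), "P", n_total = 10L)
  expect_equal(prof$coverage[5L], 0.8)
  expect_equal(prof$coverage[15L], 1)
  expect_error(coverage_profile(hits, "P", n_total = 0L), "n_total")
})

test_that("coverage_profile equals the interval-stabbing oracle on random spans", {
  set.seed(7)
  for (rep in 1:10) {
    n_partner <- sample(3:8, 1L)
    plen <- sample(15:40, 1L)
    spans <- do.call(rbind, lapply(seq_len(n_partner), function(p) {
      k <- sample(1:3, 1L) # several alignments per partner
      s <- sample.int(plen, k, replace = TRUE)
      e <- pmin(plen, s + sample(0:10, k, replace = TRUE))
      data.frame(partner = paste0("Q", p), start = s, end = e)
    }))
    hits <- span_hits(spans, plen = plen)
    prof <- coverage_profile(hits, "P", n_total = n_partner, length = plen)
    expect_equal(prof$coverage,
                 oracle_coverage(hits, "P", n_partner, plen))
    # permuting rows changes nothing
    prof2 <- coverage_profile(hits[sample(nrow(hits)), ], "P",
                              n_total = n_partner, length = plen)
    expect_equal(prof2$coverage, prof$coverage)
  }
})

test_that("find_core keeps the span between first and last high-coverage residues", {
  full <- structure(list(protein_id = "P", coverage = rep(1, 10)),
                    class = "coverage_profile")
  reg <- find_core(full)
  expect_equal(c(reg$start, reg$end), c(1L, 10L))

  # interior dips below threshold stay inside the core
  dip <- structure(list(protein_id = "P",
                        coverage = c(0.2, 0.9, 0.5, 0.9, 0.1)),
                   class = "coverage_profile")
  reg <- find_core(dip, threshold = 0.8)
  expect_equal(c(reg$start, reg$end), c(2L, 4L))

  # the comparison is strictly greater-than
  at_thr <- structure(list(protein_id = "P", coverage = c(0.8, 0.9, 0.8)),
                      class = "coverage_profile")
  reg <- find_core(at_thr, threshold = 0.8)
  expect_equal(c(reg$start, reg$end), c(2L, 2L))

  none <- structure(list(protein_id = "P", coverage = rep(0.5, 5)),
                    class = "coverage_profile")
  expect_error(find_core(none, threshold = 0.8), "no core")

  set.seed(12)
  for (rep in 1:50) {
    cov <- round(runif(sample(5:50, 1L)), 2)
    prof <- structure(list(protein_id = "P", coverage = cov),
                      class = "coverage_profile")
    orc <- oracle_find_core(cov, 0.8)
    if (is.null(orc)) {
      expect_error(find_core(prof, 0.8), "no core")
    } else {
      reg <- find_core(prof, 0.8)
      expect_equal(c(reg$start, reg$end), orc)
    }
  }
})

test_that("trim_set splits proteins into core and terminal fragments", {
  truth <- simulate_tree(8, "yule", seed = 31)
  labs <- sort(truth$tip.label)
  arch <- domain_architecture(core = c(21, 90), n_members = labs,
                              c_len = 10, c_members = labs)
  hits <- similarity_table_from_tree(truth, 0, arch, seed = 31)
  structures <- simulate_structures(truth, arch)
  expect_equal(length(structures[[1L]]), 100L)

  tr <- trim_set(structures, hits)
  expect_equal(length(tr$cores[[1L]]), 70L)
  expect_equal(length(tr$n_fragments[[1L]]), 20L)
  expect_equal(length(tr$c_fragments[[1L]]), 10L)
  expect_length(tr$excluded, 0L)

  # core covering the whole protein leaves no fragments
  arch_full <- domain_architecture(core = c(1, 100), n_members = labs)
  hits_full <- similarity_table_from_tree(truth, 0, arch_full, seed = 31)
  tr_full <- trim_set(simulate_structures(truth, arch_full), hits_full)
  expect_length(tr_full$n_fragments, 0L)
  expect_length(tr_full$c_fragments, 0L)
  expect_equal(length(tr_full$cores[[1L]]), 100L)
})

test_that("corecut is idempotent: re-trimming cores reproduces them", {
  truth <- simulate_tree(8, "yule", seed = 32)
  labs <- sort(truth$tip.label)
  arch <- domain_architecture(core = c(50, 200), n_members = labs)
  hits <- similarity_table_from_tree(truth, 0, arch, seed = 32)
  tr <- trim_set(simulate_structures(truth, arch), hits)
  core_len <- length(tr$cores[[1L]])

  # hits among the cores: full-span alignments (the simulator's core-only
  # contract after trimming)
  core_arch <- domain_architecture(core = c(1, core_len), n_members = labs)
  core_hits <- similarity_table_from_tree(truth, 0, core_arch, seed = 32)
  tr2 <- trim_set(tr$cores, core_hits)
  expect_equal(vapply(tr2$cores, length, integer(1L)),
               vapply(tr$cores, length, integer(1L)))
  expect_length(tr2$n_fragments, 0L)
})

test_that("cluster_termini is single linkage with deterministic labels", {
  lens <- c(f1 = 40L, f2 = 40L, f3 = 40L, f4 = 5L)
  mk_scores <- function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(query = r[[1L]], target = r[[2L]],
                 fident = as.numeric(r[[3L]]), lddt = 0.5, alntmscore = 0.5,
                 qstart = 1L, qend = 40L, tstart = 1L, tend = 40L,
                 qlen = 40L, tlen = 40L, stringsAsFactors = FALSE)
    }))
  }
  # identical pair joins, below-threshold pair stays apart
  scores <- mk_scores(list(list("f1", "f2", 0.9), list("f2", "f3", 0.1)))
  lab <- cluster_termini(lens, scores)
  expect_equal(lab[["f1"]], "f1")
  expect_equal(lab[["f2"]], "f1")
  expect_equal(lab[["f3"]], "f3") # singleton
  expect_equal(lab[["f4"]], "none") # below min_length

  # all below threshold: all singletons
  scores <- mk_scores(list(list("f1", "f2", 0.1), list("f2", "f3", 0.1)))
  lab <- cluster_termini(lens[1:3], scores)
  expect_equal(unname(lab), c("f1", "f2", "f3"))

  # chaining: f1-f2 and f2-f3 edges merge all three (single linkage)
  scores <- mk_scores(list(list("f1", "f2", 0.5), list("f2", "f3", 0.5)))
  lab <- cluster_termini(lens[1:3], scores)
  expect_equal(unname(lab), c("f1", "f1", "f1"))
})

test_that("planted two-cluster fragment sets are recovered exactly", {
  set.seed(5)
  ids <- paste0("g", 1:8)
  lens <- setNames(rep(30L, 8), ids)
  pairs <- t(combn(ids, 2L))
  same <- (pairs[, 1L] %in% ids[1:4]) == (pairs[, 2L] %in% ids[1:4])
  scores <- data.frame(query = pairs[, 1L], target = pairs[, 2L],
                       fident = ifelse(same, 0.8, 0.05), lddt = 0.5,
                       alntmscore = 0.5, qstart = 1L, qend = 30L,
                       tstart = 1L, tend = 30L, qlen = 30L, tlen = 30L,
                       stringsAsFactors = FALSE)
  lab <- cluster_termini(lens, scores)
  expect_equal(unname(lab[ids[1:4]]), rep("g1", 4))
  expect_equal(unname(lab[ids[5:8]]), rep("g5", 4))
})
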