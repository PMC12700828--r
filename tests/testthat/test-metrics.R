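ranks7 <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

lineage_of <- function(taxa) setNames(taxa, ranks7[seq_along(taxa)])

test_that("TCS scores shared-lineage cherries per the set recursion", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  full <- list(A = lineage_of(paste0("x", 1:7)),
               B = lineage_of(paste0("x", 1:7)))
  res <- tcs(cherry, full)
  expect_equal(unname(res$node_scores), 7L)
  expect_equal(res$leaf_scores, c(A = 7, B = 7))
  expect_equal(res$tree_score, 7)

  # only the kingdom shared
  partial <- list(A = lineage_of(paste0("x", 1:7)),
                  B = lineage_of(c("x1", paste0("y", 2:7))))
  expect_equal(tcs(cherry, partial)$tree_score, 1)
})

test_that("TCS matches the worked 4-leaf example and the recursion oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  shared3 <- paste0("s", 1:3)
  lin <- list(
    A = lineage_of(c(shared3, "oA", "fAB", "gAB", "spA")),
    B = lineage_of(c(shared3, "oA", "fAB", "gAB", "spB")),
    C = lineage_of(c(shared3, "oA", "fCD", "gC", "spC")),
    D = lineage_of(c(shared3, "oA", "fCD", "gD", "spD"))
  )
  # A,B share 6 ranks; C,D share 5; all four share 3... except 'oA' is shared
  # by all, so rebuild: all share exactly ranks 1-3
  lin$C["order"] <- "oCD"
  lin$D["order"] <- "oCD"
  res <- tcs(tree, lin)
  expect_setequal(unname(res$node_scores), c(3L, 6L, 5L))
  expect_equal(sort(unname(res$leaf_scores)), c(8, 8, 9, 9))
  expect_equal(res$tree_score, 8.5)

  orc <- oracle_tcs(tree, lin)
  expect_equal(res$leaf_scores[names(orc$leaf_scores)], orc$leaf_scores)
  expect_equal(res$tree_score, orc$tree_score)
})

test_that("TCS equals the oracle on random trees and ignores branch lengths", {
  for (seed in 1:20) {
    tree <- simulate_tree(8, "yule", seed = seed)
    tax <- simulate_taxonomy(tree)
    res <- tcs(tree, tax)
    orc <- oracle_tcs(tree, tax)
    expect_equal(res$tree_score, orc$tree_score)
    expect_equal(res$leaf_scores[names(orc$leaf_scores)], orc$leaf_scores)

    # branch lengths are irrelevant
    scaled <- tree
    scaled$edge.length <- runif(length(scaled$edge.length))
    expect_equal(tcs(scaled, tax)$tree_score, res$tree_score)

    # child order / rotation is irrelevant
    rot <- ape::rotateConstr(tree, rev(tree$tip.label))
    expect_equal(tcs(rot, tax)$tree_score, res$tree_score)
  }
})

test_that("TCS handles multifurcations by intersecting over all children", {
  tree <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:1);")
  lin <- list(A = lineage_of(c("k", "p", "c1")),
              B = lineage_of(c("k", "p", "c2")),
              C = lineage_of(c("k", "q", "c3")),
              D = lineage_of(c("k", "p", "c4")))
  res <- tcs(tree, lin)
  # A ^ B ^ C = {k} (p not shared by C); root = {k}
  expect_setequal(unname(res$node_scores), 1L)
  expect_equal(res$leaf_scores, c(A = 2, B = 2, C = 2, D = 1))
  expect_equal(res$tree_score, 1.75)
})

test_that("TCS validates its inputs", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_error(tcs(cherry, list(A = lineage_of("k"))), "no lineage.*B")
  expect_error(tcs(cherry, list(A = lineage_of("k"), B = character(0))),
               "empty lineage")
  expect_error(tcs(ape::unroot(simulate_tree(5, "yule", seed = 1)),
                   list()), "rooted")
})

test_that("rtt_variance: clock limit, two-point value, scale invariance", {
  ultra <- simulate_tree(12, "yule", seed = 6)
  expect_equal(rtt_variance(ultra), 0, tolerance = 1e-18)

  two <- ape::read.tree(text = "(A:2,B:3);")
  expect_equal(rtt_variance(two), 0.04)

  noisy <- simulate_tree(12, "clock_noise", sigma = 0.4, seed = 6)
  v <- rtt_variance(noisy)
  expect_gt(v, 0)
  scaled <- noisy
  scaled$edge.length <- scaled$edge.length * 10
  expect_equal(rtt_variance(scaled), v, tolerance = 1e-12)

  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(rtt_variance(zero), "zero")
})

test_that("winner_proportions: formula cases, ties and bootstrap agreement", {
  # one method always wins
  tab <- cbind(m1 = rep(2, 10), m2 = rep(1, 10))
  wp <- winner_proportions(tab)
  expect_equal(wp$proportion, c(1, 0))
  expect_equal(wp$se, c(0, 0))

  # 50/50 over n = 100: p = 0.5 +- 0.05
  tab <- cbind(m1 = rep(c(2, 0), 50), m2 = rep(1, 100))
  wp <- winner_proportions(tab)
  expect_equal(wp$proportion, c(0.5, 0.5))
  expect_equal(wp$se, c(0.05, 0.05))

  # ties split fractionally, proportions sum to one
  tab <- cbind(m1 = c(1, 1), m2 = c(1, 0), m3 = c(1, 2))
  wp <- winner_proportions(tab)
  expect_equal(sum(wp$proportion), 1)
  expect_equal(wp$proportion, c(1 / 6 + 0, 1 / 6, 1 / 6 + 1 / 2))

  # bootstrap oracle: multinomial SE agrees with resampled winner counts
  set.seed(314)
  scores <- matrix(rnorm(80 * 3), 80, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  wp <- winner_proportions(scores)
  credit <- t(apply(scores, 1L, function(r) {
    w <- r == max(r)
    w / sum(w)
  }))
  boots <- replicate(10000, colMeans(credit[sample(80, replace = TRUE), ]))
  boot_se <- apply(boots, 1L, sd)
  expect_true(all(abs(wp$proportion - rowMeans(boots)) <= 3 * boot_se))
  expect_equal(wp$se, unname(boot_se), tolerance = 0.25)

  expect_error(winner_proportions(matrix(numeric(0), 0, 2)), "empty")
  expect_error(winner_proportions(rbind(c(1, NA), c(NA, NA))), "row 2")
})
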