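# Parsimony scoring and tree search, checked against assignment-enumeration
# oracles, full topology enumeration in R, and phangorn as an independent
# implementation of Fitch counting.

test_that("tree lengths match the assignment-enumeration oracle on worked cases", {
  tr_bal <- ape::read.tree(text = "((A,B),(C,D));")
  # character 1100: one change; 1010: two changes
  for (case in list(list(ch = c(A = 1, B = 1, C = 0, D = 0), exp = 1),
                    list(ch = c(A = 1, B = 0, C = 1, D = 0), exp = 2))) {
    pol <- polarity_from_binary(rbind(c1 = case$ch))
    expect_equal(oracle_char_length(tr_bal, case$ch, "wagner"), case$exp)
    expect_equal(tree_length(tr_bal, pol, "wagner"), case$exp)
  }
  # A1 B0 C1 D1 on (((A,B),C),D) with all-zero root: wagner 2, camin-sokal 3
  tr_cat <- ape::read.tree(text = "(((A,B),C),D);")
  ch <- c(A = 1, B = 0, C = 1, D = 1)
  pol <- polarity_from_binary(rbind(c1 = ch))
  expect_equal(oracle_char_length(tr_cat, ch, "wagner"), 2)
  expect_equal(oracle_char_length(tr_cat, ch, "camin_sokal"), 3)
  expect_equal(tree_length(tr_cat, pol, "wagner"), 2L)
  expect_equal(tree_length(tr_cat, pol, "camin_sokal"), 3L)
  # constant characters contribute 0 (all-ancestral) or a single root gain
  pol0 <- polarity_from_binary(rbind(c1 = c(A = 0, B = 0, C = 0, D = 0)))
  expect_equal(tree_length(tr_cat, pol0, "wagner"), 0L)
  expect_equal(tree_length(tr_cat, pol0, "camin_sokal"), 0L)
})

test_that("tree_length equals the oracle and phangorn on random instances", {
  set.seed(31)
  for (rep in 1:12) {
    nt <- sample(4:6, 1)
    labels <- LETTERS[1:nt]
    tr <- random_rooted_tree(labels)
    nc <- sample(3:8, 1)
    m <- matrix(rbinom(nt * nc, 1, 0.5), nrow = nc,
                dimnames = list(sprintf("c%d", 1:nc), labels))
    pol <- polarity_from_binary(m)
    lw <- tree_length(tr, pol, "wagner")
    lc <- tree_length(tr, pol, "camin_sokal")
    expect_equal(lw, oracle_length(tr, m, "wagner"))
    expect_equal(lc, oracle_length(tr, m, "camin_sokal"))
    expect_gte(lc, lw)  # irreversibility can only cost steps

    # independent implementation: Fitch length of the unrooted tree with an
    # explicit all-zero ancestor leaf equals the rooted all-ancestral score
    nw <- ape::write.tree(tr)
    tr0 <- ape::read.tree(text = paste0("(", sub(";$", "", nw), ",ROOT0);"))
    m0 <- cbind(m, ROOT0 = 0L)
    dat <- phangorn::phyDat(t(m0), type = "USER", levels = c(0, 1))
    expect_equal(lw, as.integer(phangorn::parsimony(tr0, dat)))
  }
})

test_that("tree_length names a leaf absent from the polarity matrix", {
  pol <- polarity_from_binary(rbind(c1 = c(A = 1, B = 0, C = 0)))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(tree_length(tr, pol), "D")
})

test_that("exhaustive search reproduces full R-level topology enumeration", {
  set.seed(17)
  for (nt in 4:5) {
    labels <- LETTERS[1:nt]
    all_nw <- all_rooted_newicks(labels)
    expect_length(all_nw, prod(seq(3, 2 * nt - 3, by = 2)))  # (2n-3)!!
    for (rep in 1:3) {
      nc <- sample(4:10, 1)
      m <- matrix(rbinom(nt * nc, 1, 0.5), nrow = nc,
                  dimnames = list(sprintf("c%d", 1:nc), labels))
      pol <- polarity_from_binary(m)
      for (model in c("wagner", "camin_sokal")) {
        lens <- vapply(all_nw, function(s)
          oracle_length(ape::read.tree(text = s), m, model), 0)
        ts <- exhaustive_search(pol, model)
        expect_equal(ts$length, as.integer(min(lens)))
        oracle_best <- sort(unique(vapply(
          all_nw[lens == min(lens)],
          function(s) canonical_topology(ape::read.tree(text = s)), "")))
        got <- sort(vapply(ts$trees, canonical_topology, ""))
        expect_identical(got, oracle_best)
      }
    }
  }
})

test_that("the worked toy matrix yields the two unrooted MP trees and a star consensus", {
  m <- rbind(c1 = c(A = 1, B = 1, C = 0, D = 0),
             c2 = c(A = 1, B = 0, C = 1, D = 0))
  pol <- polarity_from_binary(m)
  ts <- exhaustive_search(pol, "wagner")
  expect_equal(ts$length, 3L)
  keys <- unique(vapply(ts$trees, unrooted_key, ""))
  ab_cd <- unrooted_key(ape::read.tree(text = "((A,B),(C,D));"))
  ac_bd <- unrooted_key(ape::read.tree(text = "((A,C),(B,D));"))
  ad_bc <- unrooted_key(ape::read.tree(text = "((A,D),(B,C));"))
  expect_setequal(keys, c(ab_cd, ac_bd))
  expect_false(ad_bc %in% keys)
  # the excluded grouping costs one extra step
  expect_equal(tree_length(ape::read.tree(text = "((A,D),(B,C));"), pol), 4L)
  cons <- strict_consensus(ts)
  expect_equal(cons$Nnode, 1L)  # fully unresolved star
  expect_setequal(cons$tip.label, c("A", "B", "C", "D"))
})

test_that("a perfectly compatible (nested) matrix has one MP tree of minimal length", {
  # nested 1-blocks: {A,B,C,D} chain
  m <- rbind(c1 = c(A = 1, B = 1, C = 1, D = 0),
             c2 = c(A = 1, B = 1, C = 0, D = 0),
             c3 = c(A = 1, B = 0, C = 0, D = 0))
  pol <- polarity_from_binary(m)
  ts <- exhaustive_search(pol, "wagner")
  expect_equal(ts$length, 3L)  # = number of variable characters
  expect_equal(ts$n_opt, 1)
  expect_identical(canonical_topology(ts$trees[[1]]),
                   canonical_topology(ape::read.tree(text = "(((A,B),C),D);")))
})

test_that("three taxa collapse to the single unrooted topology", {
  m <- rbind(c1 = c(A = 1, B = 1, C = 0))
  ts <- exhaustive_search(polarity_from_binary(m))
  keys <- unique(vapply(ts$trees, function(t)
    paste(sort(t$tip.label), collapse = ","), ""))
  expect_identical(keys, "A,B,C")
  # every returned rooted optimum is a rooting of the same unrooted star
  expect_true(all(vapply(ts$trees, function(t) t$Nnode <= 2, TRUE)))
})

test_that("exhaustive search refuses oversized problems and points to the heuristic", {
  pol <- random_binary_polarity(12, 5)
  expect_error(exhaustive_search(pol), "heuristic_search")
})

test_that("heuristic search matches the exhaustive optimum on random instances", {
  set.seed(23)
  for (rep in 1:10) {
    nt <- sample(4:7, 1)
    pol <- random_binary_polarity(nt, sample(5:30, 1))
    for (model in c("wagner", "camin_sokal")) {
      ex <- exhaustive_search(pol, model)
      he <- heuristic_search(pol, model, seed = rep)
      expect_equal(he$length, ex$length)
      # every heuristic tree is a genuine optimum
      expect_true(all(vapply(he$trees, canonical_topology, "") %in%
                        vapply(ex$trees, canonical_topology, "")))
    }
  }
})

test_that("heuristic search is deterministic given the seed and improves with starts", {
  set.seed(5)
  pol <- random_binary_polarity(8, 40)
  a <- heuristic_search(pol, seed = 99, n_starts = 5)
  b <- heuristic_search(pol, seed = 99, n_starts = 5)
  expect_identical(lapply(a$trees, ape::write.tree),
                   lapply(b$trees, ape::write.tree))
  expect_identical(a$length, b$length)
  one <- heuristic_search(pol, seed = 1, n_starts = 1)
  many <- heuristic_search(pol, seed = 1, n_starts = 30)
  expect_lte(many$length, one$length)
})

test_that("rooting on the all-zero ancestor leaf prunes it and is idempotent", {
  tr <- ape::read.tree(text = "((ROOT0,A),(B,C));")
  rooted <- root_cladogram(tr)
  expect_identical(canonical_topology(rooted),
                   canonical_topology(ape::read.tree(text = "(A,(B,C));")))
  expect_identical(canonical_topology(root_cladogram(rooted)),
                   canonical_topology(rooted))
  unrooted <- ape::unroot(ape::read.tree(text = "((A,B),(C,D),E);"))
  expect_error(root_cladogram(unrooted), "ROOT0")
})

test_that("strict consensus keeps exactly the clades common to all trees", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  # single tree and k copies are identity
  expect_identical(canonical_topology(strict_consensus(list(t1))),
                   canonical_topology(t1))
  expect_identical(canonical_topology(strict_consensus(list(t1, t1, t1))),
                   canonical_topology(t1))
  star <- strict_consensus(list(t1, t2))
  expect_equal(star$Nnode, 1L)
  # shared nested clade survives
  t3 <- ape::read.tree(text = "(((A,B),C),D);")
  t4 <- ape::read.tree(text = "(((A,B),D),C);")
  cons <- strict_consensus(list(t3, t4))
  keys <- vapply(expclad:::node_members(cons), paste, "", collapse = ",")
  expect_true("A,B" %in% keys)
  expect_error(strict_consensus(list(t1, ape::read.tree(text = "((A,B),(C,E));"))),
               "leaf sets")
})

test_that("strict consensus agrees with ape's consensus on random tree sets", {
  set.seed(41)
  for (rep in 1:5) {
    labels <- LETTERS[1:6]
    trees <- lapply(1:3, function(i) random_rooted_tree(labels))
    mine <- strict_consensus(trees)
    apes <- ape::consensus(trees, p = 1, rooted = TRUE)
    key <- function(t) sort(vapply(expclad:::node_members(t)[
      (length(t$tip.label) + 1):(length(t$tip.label) + t$Nnode)],
      paste, "", collapse = ","))
    expect_identical(key(mine), key(apes))
  }
})
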