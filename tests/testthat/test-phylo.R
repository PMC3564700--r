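# Neighbor joining, Robinson-Foulds distance, and MRe consensus.

test_that("3-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # the unique unrooted 3-leaf tree: terminal branch per tip
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ recovers topology and branch lengths from additive matrices", {
  withr::local_seed(31)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d[true$tip.label, true$tip.label])
    expect_identical(rf_distance(est, true), 0)
    # additivity: the NJ tree induces exactly the input distances
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("degenerate all-equal matrix still yields a valid tree", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, letters[1:5])
  # deterministic: same input, same tree
  expect_identical(ape::write.tree(tr), ape::write.tree(nj_tree(d)))
})

test_that("NJ rejects malformed matrices", {
  d <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  d2 <- matrix(0, 2, 2)
  expect_error(nj_tree(d2), ">= 3")
  d3 <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_error(nj_tree(rbind(cbind(d3, 1), 1)), "finite|symmetric")
})

test_that("negative NJ branch lengths are kept, or clamped on request", {
  # non-additive matrix engineered to force a negative internal estimate
  d <- matrix(c(0, 1, 9, 9,
                1, 0, 9, 9,
                9, 9, 0, 0.5,
                9, 9, 0.5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d[1, 3] <- 2; d[3, 1] <- 2
  tr <- nj_tree(d)
  if (any(tr$edge.length < 0)) {
    tot <- sum(tr$edge.length)
    trc <- nj_tree(d, clamp_negative = TRUE)
    expect_true(all(trc$edge.length >= 0))
    expect_equal(sum(trc$edge.length), tot, tolerance = 1e-9)
  }
  succeed()
})

test_that("RF distance matches brute-force bipartition enumeration", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(rf_distance(t1, t1), 0)
  expect_identical(rf_distance(t1, t2), 2)
  withr::local_seed(32)
  for (i in 1:60) {
    a <- random_topology(6)
    b <- random_topology(6)
    expect_identical(rf_distance(a, b), as.numeric(oracle_rf(a, b)))
  }
})

test_that("RF is a bounded metric on resolved trees", {
  withr::local_seed(33)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- random_topology(n); b <- random_topology(n); c <- random_topology(n)
    dab <- rf_distance(a, b); dbc <- rf_distance(b, c)
    dac <- rf_distance(a, c)
    expect_lte(dab, 2 * (n - 3))
    expect_identical(dab, rf_distance(b, a))
    expect_lte(dac, dab + dbc)  # triangle inequality
    expect_identical(rf_distance(a, a), 0)
  }
  expect_equal(rf_distance(random_topology(10), random_topology(10),
                           normalized = TRUE) <= 1, TRUE)
})

test_that("RF refuses mismatched leaf sets, naming the difference", {
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(a, b), "only in first: \\[D\\]")
})

test_that("consensus of identical trees is that tree at full support", {
  t0 <- random_topology(8)
  cons <- consensus_mre(rep(list(t0), 1000))
  expect_identical(rf_distance(cons, t0), 0)
  expect_true(all(setdiff(cons$node.label, "") == "1000"))
})

test_that("majority splits are retained with their occurrence counts", {
  # 3 trees; the split AB|rest appears in 2 of them
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),((C,D),E));")
  t3 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  cons <- consensus_mre(list(t1, t2, t3))
  sp <- attr(cons, "splits")
  # the A,B-vs-rest split canonicalizes to the side without leaf A
  ab <- sp[sp$key == "C|D|E", ]
  expect_identical(ab$count, 2L)
  expect_true(ab$retained)
  de <- sp[sp$key == "D|E", ]
  expect_identical(de$count, 2L)
  expect_true(de$retained)
})

test_that("extended rule admits a sub-majority split that strict majority drops", {
  # 10 trees on 6 leaves: majority split {A,B}; a 40% split {D,E} is
  # compatible with it and with everything retained, so MRe keeps it
  maj <- ape::read.tree(text = "(((A,B),(D,E)),C,F);")
  alt1 <- ape::read.tree(text = "(((A,B),(C,E)),D,F);")
  alt2 <- ape::read.tree(text = "(((A,B),(C,D)),E,F);")
  trees <- c(rep(list(maj), 4), rep(list(alt1), 3), rep(list(alt2), 3))
  cons <- consensus_mre(trees)
  sp <- attr(cons, "splits")
  expect_identical(sp$count[sp$key == "C|D|E|F"], 10L)
  expect_identical(sp$count[sp$key == "D|E"], 4L)
  expect_true(sp$retained[sp$key == "D|E"])  # 40% < majority, still kept
  # strict majority consensus would keep only A|B
  counts <- oracle_split_counts(trees)
  expect_identical(sort(names(counts[counts > 5])), "C|D|E|F")
  # occurrence counts agree with the independent enumeration
  for (k in sp$key)
    expect_identical(sp$count[sp$key == k], as.integer(counts[[k]]))
})

test_that("consensus output splits are pairwise compatible and well supported", {
  withr::local_seed(34)
  trees <- lapply(1:15, function(i) random_topology(9))
  cons <- consensus_mre(trees)
  sp <- attr(cons, "splits")
  kept <- sp$tips[sp$retained]
  if (length(kept) > 1) {
    for (i in seq_len(length(kept) - 1)) for (j in seq(i + 1, length(kept))) {
      a <- kept[[i]]; b <- kept[[j]]
      ninter <- length(intersect(a, b))
      expect_true(ninter == 0 || ninter == length(a) || ninter == length(b))
    }
  }
  # node labels carry the counts of the retained splits
  expect_setequal(as.integer(setdiff(cons$node.label, "")),
                  sp$count[sp$retained])
  expect_error(consensus_mre(list(random_topology(5), random_topology(6))),
               "differing leaf sets")
})

test_that("newick output round-trips topology, labels and branch lengths", {
  withr::local_seed(35)
  tr <- ape::rtree(12)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_identical(rf_distance(back, tr), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
})
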