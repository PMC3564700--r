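# Substitution models and the sequence-family simulator.

test_that("transition matrices are stochastic, stationary and reversible", {
  for (m in list(subst_model("K2P", tstv = 2),
                 subst_model("F84", tstv = 2, c(0.3, 0.2, 0.2, 0.3)),
                 subst_model("F84", tstv = 1.4, c(0.4, 0.15, 0.15, 0.3)))) {
    expect_equal(unname(transition_probs(m, 0)), diag(4), tolerance = 1e-12)
    for (t in c(0.01, 0.1, 0.5, 3)) {
      P <- transition_probs(m, t)
      expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(P >= 0))
      # stationarity: pi P = pi
      expect_equal(as.numeric(m$freq %*% P), m$freq, tolerance = 1e-12)
      # detailed balance: pi_i P_ij = pi_j P_ji
      Fl <- unname(diag(m$freq) %*% P)
      expect_equal(Fl, t(Fl), tolerance = 1e-10)
    }
    # very long branch forgets the starting base
    Pinf <- transition_probs(m, 50)
    for (i in 1:4) expect_equal(unname(Pinf[i, ]), m$freq, tolerance = 1e-8)
  }
})

test_that("K2P with ts/tv 0.5 behaves as Jukes-Cantor", {
  m <- subst_model("K2P", tstv = 0.5)
  # all off-diagonal instantaneous rates equal
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(off, rep(off[1], 12), tolerance = 1e-12)
  # observed changes on a long branch split 1:2 between transitions and
  # transversions (one transition partner vs two transversion partners)
  P <- transition_probs(m, 0.8)
  withr::local_seed(41)
  n <- 1e5
  from <- rep(1L, n)  # all A
  to <- sample.int(4, n, TRUE, prob = P[1, ])
  changed <- to != 1L
  ti <- sum(to == 3L)             # A -> G
  tv <- sum(changed) - ti
  p_hat <- ti / sum(changed)
  se <- sqrt(p_hat * (1 - p_hat) / sum(changed))
  expect_lt(abs(p_hat - 1 / 3), 3 * se + 1e-3)
})

test_that("single-branch divergence matches the closed-form p-distance", {
  m <- subst_model("K2P", tstv = 2)
  P <- transition_probs(m, 0.1)
  p_expected <- 1 - sum(0.25 * diag(P))
  tr <- ape::read.tree(text = "(a:0.1,b:0,c:0);")
  fam <- evolve_family(tr, m, root_length = 1e5, seed = 42)
  a <- strsplit(fam$sequences$seq[fam$sequences$id == "a"], "")[[1]]
  b <- strsplit(fam$sequences$seq[fam$sequences$id == "b"], "")[[1]]
  p_obs <- mean(a != b)
  se <- sqrt(p_expected * (1 - p_expected) / 1e5)
  expect_lt(abs(p_obs - p_expected), 3 * se)
})

test_that("zero-length branches copy the root everywhere, gap-free", {
  tr <- balanced_tree(8, branch_length = 0)
  fam <- evolve_family(tr, subst_model("K2P"), root_length = 200,
                       indel_rate = 0, seed = 9)
  expect_identical(unique(fam$sequences$seq), fam$sequences$seq[1])
  expect_identical(ncol(fam$alignment), 200L)
  expect_false(any(fam$alignment == "-"))
})

test_that("simulation at stationarity keeps base composition in check", {
  m <- subst_model("F84", tstv = 2, base_freq = c(0.4, 0.1, 0.2, 0.3))
  tr <- ape::read.tree(text = "(a:2,b:2,c:2);")
  fam <- evolve_family(tr, m, root_length = 2e4, seed = 17)
  for (s in fam$sequences$seq) {
    obs <- table(factor(strsplit(s, "")[[1]], levels = c("A","C","G","T")))
    p <- as.numeric(obs) / sum(obs)
    se <- sqrt(m$freq * (1 - m$freq) / sum(obs))
    expect_true(all(abs(p - m$freq) < 4 * se))
  }
})

test_that("the logged true alignment is consistent with the leaf sequences", {
  fam <- evolve_family(balanced_tree(), subst_model("K2P"),
                       root_length = 300, indel_rate = 0.02, seed = 30)
  for (i in seq_len(nrow(fam$sequences))) {
    row <- fam$alignment[fam$sequences$id[i], ]
    expect_identical(paste(row[row != "-"], collapse = ""),
                     fam$sequences$seq[i])
  }
  # indels present: lengths vary and gaps exist
  expect_gt(length(unique(nchar(fam$sequences$seq))), 1)
  expect_true(any(fam$alignment == "-"))
})

test_that("simulation and benchmark are reproducible from the seed", {
  a <- evolve_family(balanced_tree(), subst_model("K2P"), seed = 77,
                     root_length = 100, indel_rate = 0.01)
  b <- evolve_family(balanced_tree(), subst_model("K2P"), seed = 77,
                     root_length = 100, indel_rate = 0.01)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$alignment, b$alignment)
  s1 <- glance(benchmark_rcm(3, subst_model("K2P"), root_length = 200,
                             seed = 5))
  s2 <- glance(benchmark_rcm(3, subst_model("K2P"), root_length = 200,
                             seed = 5))
  expect_identical(s1, s2)
})

test_that("zero families give an empty benchmark without error", {
  bk <- benchmark_rcm(0, subst_model("K2P"))
  expect_identical(nrow(tidy(bk)), 0L)
  expect_identical(nrow(glance(bk)), 0L)
})

test_that("long weakly-diverged sequences are reconstructed near-perfectly", {
  bk <- benchmark_rcm(5, subst_model("K2P"), tree = balanced_tree(8, 0.03),
                      root_length = 2000, indel_rate = 0, seed = 21)
  expect_lt(glance(bk)$mean_rf_normalized, 0.1)
})

test_that("reconstruction accuracy improves with sequence length", {
  # harder regime (short sequences, more divergence) so errors exist at
  # the small end; mean normalized RF should not increase with length
  lens <- c(125, 500)
  tr <- balanced_tree(16, 0.12)
  means <- vapply(lens, function(L) {
    glance(benchmark_rcm(10, subst_model("K2P"), tree = tr,
                         root_length = L, indel_rate = 0,
                         seed = 31))$mean_rf_normalized
  }, numeric(1))
  expect_gte(means[1], means[2])
})

test_that("invalid model parameters are rejected", {
  expect_error(subst_model("HKY"), "arg")
  expect_error(subst_model("K2P", tstv = -1))
  expect_error(subst_model("F84", tstv = 0.1,
                           base_freq = c(0.25, 0.25, 0.25, 0.25)),
               "minimum")
  expect_error(subst_model("F84", base_freq = c(0.5, 0.5, 0.2, 0.2)))
})
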