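test_that("pairwise identity follows the shorter-sequence convention", {
  s <- randomSeqs(1, 80, 80, seed = 4)[[1]]
  expect_equal(pairwiseIdentity(s, s), 1)
  expect_equal(pairwiseIdentity(strrep("A", 4), strrep("C", 4)), 0)
  # 100-mers differing at exactly one position
  a <- randomSeqs(1, 100, 100, seed = 5)[[1]]
  b <- a; substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "C" else "A"
  expect_equal(pairwiseIdentity(a, b), 0.99)
  expect_equal(pairwiseIdentity(b, a), pairwiseIdentity(a, b))
})

test_that("greedy clustering merges by threshold and keeps longest representatives", {
  a <- randomSeqs(1, 100, 100, seed = 6)[[1]]
  b <- a; substr(b, 10, 10) <- if (substr(a, 10, 10) == "A") "C" else "A"
  x <- c(a = a, b = b)
  for (th in c(0.95, 0.99))
    expect_length(greedyCluster(x, th)@clusters, 1)
  expect_length(greedyCluster(x, 1.0)@clusters, 2)

  # duplicates at threshold 1: one representative per distinct sequence
  y <- c(p = a, q = a, r = b)
  cl <- greedyCluster(y, 1.0)
  expect_equal(length(cl@clusters), 2)
  expect_setequal(clusterMembers(cl)$member_id, names(y))
  # representative is the longest member, ties broken by input order
  z <- c(short = substr(a, 1, 60), long = a)
  cl2 <- greedyCluster(z, 0.9)
  expect_equal(names(cl2@clusters), "long")
})

test_that("clustering is idempotent and monotone in the threshold", {
  s <- makeDuplicates(Biostrings::AAStringSet(randomSeqs(15, 60, 80, seed = 7)),
                      k = 2, mutations = 1, seed = 8)
  counts <- vapply(c(0.9, 0.95, 0.99, 1.0), function(th)
    length(greedyCluster(s, th)@clusters), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # re-clustering the retained set changes nothing
  cl <- greedyCluster(s, 0.95)
  again <- greedyCluster(retainedSequences(cl), 0.95)
  expect_equal(names(again@clusters), names(cl@clusters))
})

test_that("duplicate construction gives exact expected cluster counts", {
  base <- Biostrings::AAStringSet(randomSeqs(10, 100, 100, seed = 9))
  # k = 2 copies with 1 mutation: identity 0.99 merges at 0.99, not at 1.00
  dup <- makeDuplicates(base, k = 2, mutations = 1, seed = 10)
  expect_length(greedyCluster(dup, 0.99)@clusters, 10)
  expect_length(greedyCluster(dup, 1.0)@clusters, 30)
  # mutation-free copies collapse at threshold 1
  dup0 <- makeDuplicates(base, k = 1, mutations = 0, seed = 11)
  expect_length(greedyCluster(dup0, 1.0)@clusters, 10)
})
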