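test_that("correlation matrix is symmetric, affine-invariant and flags zero variance", {
  set.seed(1)
  x <- rnorm(20)
  m <- cbind(x = x, y = 2 * x + 1, z = rnorm(20), const = rep(3, 20))
  rownames(m) <- sprintf("r%02d", 1:20)
  r <- correlationMatrix(m)
  expect_equal(r, t(r), ignore_attr = TRUE)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["x", "y"], 1)
  expect_equal(unname(r["const", c("x", "y", "z")]), rep(0, 3))
  expect_equal(attr(r, "zeroVariance"), "const")
  # 4-point textbook evaluation of the Pearson formula
  a <- c(1, 2, 4, 5); b <- c(1, 3, 2, 6)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  m2 <- cbind(a = a, b = b, c = c(2, 1, 0, 4))
  rownames(m2) <- paste0("p", 1:4)
  expect_equal(correlationMatrix(m2)["a", "b"], hand)
})

test_that("pruning removes the higher-mean-correlation member and audits clean", {
  set.seed(2)
  x <- rnorm(50)
  # A correlates with B (r ~ 0.95) and somewhat with C, so A has the
  # larger mean absolute correlation and must be the one removed
  A <- x
  B <- x + rnorm(50, sd = 0.3)
  C <- 0.5 * x + rnorm(50, sd = 1)
  m <- cbind(A = A, B = B, C = C)
  rownames(m) <- sprintf("r%02d", 1:50)
  r <- correlationMatrix(m)
  stopifnot(abs(r["A", "B"]) > 0.7, abs(r["A", "C"]) < 0.7)
  pr <- pruneCorrelated(m, 0.7)
  expect_equal(removedFeatures(pr), "A")
  expect_setequal(keptFeatures(pr), c("B", "C"))

  # identical columns: exactly one goes
  m3 <- cbind(u = x, v = x, w = rnorm(50))
  rownames(m3) <- rownames(m)
  pr3 <- pruneCorrelated(m3, 0.7)
  expect_length(removedFeatures(pr3), 1)

  # nothing exceeds the cutoff: nothing removed
  set.seed(3)
  ind <- matrix(rnorm(50 * 5), 50,
                dimnames = list(sprintf("r%02d", 1:50), letters[1:5]))
  expect_length(removedFeatures(pruneCorrelated(ind, 0.99)), 0)

  expect_error(pruneCorrelated(m, 1.5), "cutoff")
})

test_that("pruned set passes the post-condition audit and matches caret's", {
  skip_if_not_installed("caret")
  set.seed(4)
  z <- matrix(rnorm(60 * 8), 60, 8)
  m <- z %*% matrix(rnorm(8 * 30), 8) + matrix(rnorm(60 * 30, sd = 0.6), 60)
  dimnames(m) <- list(sprintf("r%02d", 1:60), sprintf("f%02d", 1:30))
  pr <- pruneCorrelated(m, 0.7)
  audit <- function(keep) {
    r <- abs(cor(m[, keep])); diag(r) <- 0
    max(r)
  }
  expect_lte(audit(keptFeatures(pr)), 0.7)
  # caret's exact removal is an independent solver of the same task;
  # its kept set must satisfy the identical audit
  drop <- caret::findCorrelation(cor(m), cutoff = 0.7, exact = TRUE)
  expect_lte(audit(setdiff(colnames(m), colnames(m)[drop])), 0.7)

  # determinism: identical input order gives identical result
  pr2 <- pruneCorrelated(m, 0.7)
  expect_identical(keptFeatures(pr), keptFeatures(pr2))
})
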