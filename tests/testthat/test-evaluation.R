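test_that("metrics match the hand-worked confusion example and boundaries", {
  m <- classMetrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
  expect_equal(round(unname(m[c("Ac", "Sn", "Sp")]), 2),
               c(71.43, 75.00, 66.67))
  expect_equal(unname(m[["MCC"]]), 5 / 12, tolerance = 1e-9)

  perfect <- classMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 1))
  worst <- classMetrics(c(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(unname(worst[["MCC"]]), -1)
  # degenerate denominator: all predictions one class -> MCC 0
  onesided <- classMetrics(c(TP = 5, TN = 0, FP = 5, FN = 0))
  expect_equal(unname(onesided[["MCC"]]), 0)
  expect_error(classMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "no evaluated")
})

test_that("metric identities: Ac swap invariance and MCC sign flip", {
  set.seed(1)
  for (k in 1:10) {
    c4 <- as.numeric(sample(0:20, 4, replace = TRUE))
    names(c4) <- c("TP", "TN", "FP", "FN")
    if (sum(c4) == 0) next
    swapped <- c(TP = c4[["TN"]], TN = c4[["TP"]],
                 FP = c4[["FN"]], FN = c4[["FP"]])
    expect_equal(classMetrics(c4)[["Ac"]], classMetrics(swapped)[["Ac"]])
    inverted <- c(TP = c4[["FN"]], TN = c4[["FP"]],
                  FP = c4[["TN"]], FN = c4[["TP"]])
    expect_equal(classMetrics(inverted)[["MCC"]],
                 -classMetrics(c4)[["MCC"]], tolerance = 1e-12)
  }
})

test_that("80/20 split is stratified, sized by largest remainder and seeded", {
  lab <- factor(rep(c("monomer", "oligomer"), c(60, 40)))
  names(lab) <- sprintf("s%03d", 1:100)
  sp <- splitTrainExternal(lab, seed = 5)
  expect_length(sp$external, 20)
  expect_length(sp$internal, 80)
  expect_length(intersect(sp$internal, sp$external), 0)
  expect_identical(splitTrainExternal(lab, seed = 5), sp)
  expect_false(identical(splitTrainExternal(lab, seed = 6), sp))
  # class proportions preserved within rounding across many seeds
  for (seed in 1:50) {
    spk <- splitTrainExternal(lab, seed)
    tab <- table(lab[spk$external])
    expect_equal(unname(tab[["monomer"]]), 12)
    expect_equal(unname(tab[["oligomer"]]), 8)
  }
  tiny <- factor(c("monomer", "oligomer", "oligomer", "oligomer",
                   "oligomer"))
  names(tiny) <- letters[1:5]
  expect_error(splitTrainExternal(tiny, 1), "at least 2 members")
})

test_that("tenfold CV pools counts over balanced stratified folds", {
  sim <- simulateProteins(nPerClass = 30, signal = "motif_insertion",
                          strength = 1, seed = 31)
  ft <- computeSelectedFeatures(sim$sequences, "RMY")
  cv <- crossValidate(ft, sim$labels, k = 10, seed = 3)
  expect_equal(unname(sum(cv$counts)), 60)        # bookkeeping
  expect_equal(unname(cv$metrics[["Ac"]]), 100)   # separable by construction
  folds <- oligoFP:::.stratifiedFolds(sim$labels, 10, 3)
  expect_lte(diff(range(table(folds))), 1)
  expect_error(crossValidate(ft[1:8, ], sim$labels[1:8], k = 10),
               "at least 10")
})

test_that("benchmark aggregates are reproducible and SD-zero at one iteration", {
  sim <- simulateProteins(nPerClass = 20, signal = "motif_insertion",
                          strength = 1, seed = 41)
  run <- function() benchmarkDescriptors(
    sim$sequences, sim$labels, features = c("RMY", "LI"),
    nIterations = 2, seed = 17, prune = FALSE)
  b1 <- run(); b2 <- run()
  expect_identical(reportMetrics(b1$report), reportMetrics(b2$report))
  b3 <- benchmarkDescriptors(sim$sequences, sim$labels,
                             features = c("RMY", "LI"),
                             nIterations = 1, seed = 17, prune = FALSE)
  expect_true(all(reportMetrics(b3$report)$sd == 0))
})

test_that("external labels never influence fitting", {
  sim <- simulateProteins(nPerClass = 20, signal = "motif_insertion",
                          strength = 1, seed = 51)
  ft <- computeSelectedFeatures(sim$sequences, c("RMY", "LI"))
  sp <- splitTrainExternal(sim$labels, seed = 9)
  fit1 <- fitTree(ft[sp$internal, ], sim$labels[sp$internal])
  mutated <- sim$labels
  mutated[sp$external] <- rev(mutated[sp$external])  # perturb external only
  fit2 <- fitTree(ft[sp$internal, ], mutated[sp$internal])
  expect_identical(treeToList(fit1), treeToList(fit2))
})
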