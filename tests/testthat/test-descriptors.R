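test_that("composition descriptors match hand-evaluated values", {
  a <- computeAAC("AAA")
  expect_equal(unname(a[["AAC.A"]]), 1)
  expect_equal(sum(a), 1)
  expect_equal(unname(computeAAC("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  m <- computeAAC("MKV")
  expect_equal(unname(m[c("AAC.M", "AAC.K", "AAC.V")]), rep(1 / 3, 3))

  expect_equal(unname(computeDPC("AC")[["DPC.AC"]]), 1)
  expect_equal(unname(computeDPC("AAA")[["DPC.AA"]]), 1)
  d <- computeDPC("ACAC")
  expect_equal(unname(d[["DPC.AC"]]), 2 / 3)
  expect_equal(unname(d[["DPC.CA"]]), 1 / 3)

  expect_equal(unname(computeTPC("ACD")[["TPC.ACD"]]), 1)
  expect_equal(unname(computeTPC("AAAA")[["TPC.AAA"]]), 1)
  expect_length(computeTPC("ACD"), 8000)

  expect_error(computeDPC("A"), "too short")
  expect_error(computeTPC("AC"), "too short")
})

test_that("autocorrelation kinds match hand evaluation on a toy profile", {
  # P = (1, 2, 3), d = 1
  expect_equal(oligoFP:::.autocorr(c(1, 2, 3), 1, "moreau_broto"), 4)
  expect_equal(oligoFP:::.autocorr(c(1, 2, 3), 1, "moran"), 0)
  expect_equal(oligoFP:::.autocorr(c(1, 2, 3), 1, "geary"), 0.5)
  s <- randomSeqs(1, 40, 40, seed = 5)[[1]]
  for (kind in c("moreau_broto", "moran", "geary"))
    expect_length(computeAutocorrelation(s, kind), 240)
  expect_error(computeAutocorrelation(strrep("A", 10), "moran", lag = 30),
               "lag.*exceeds")
  # zero-variance convention: homopolymer yields 0 with a warning
  expect_warning(v <- computeAutocorrelation(strrep("A", 40), "moran"),
                 "zero property variance")
  expect_true(all(v == 0))
  expect_warning(g <- computeAutocorrelation(strrep("A", 40), "geary"))
  expect_true(all(g == 0))
})

test_that("CTD composition, transition and distribution follow the stated conventions", {
  v <- computeCTD(strrep("R", 10))  # R is hydrophobicity group 1
  expect_equal(unname(v[["CTD.C.hydrophobicity.1"]]), 1)
  expect_equal(unname(v[["CTD.C.hydrophobicity.2"]]), 0)
  expect_true(all(v[grep("CTD.T.hydrophobicity", names(v))] == 0))
  expect_equal(
    unname(v[paste0("CTD.D.hydrophobicity.1.",
                    c("first", "25", "50", "75", "100"))]),
    c(10, 30, 50, 80, 100))
  # RGRG encodes 1212 under hydrophobicity: T12 = (2 + 1)/3
  t12 <- computeCTD("RGRG")[["CTD.T.hydrophobicity.12"]]
  expect_equal(unname(t12), 1)
  expect_length(v, 147)
  # per-property composition blocks sum to 1
  s <- randomSeqs(1, 50, 50, seed = 9)[[1]]
  w <- computeCTD(s)
  for (p in names(ctdGroups()))
    expect_equal(sum(w[paste0("CTD.C.", p, ".", 1:3)]), 1)
})

test_that("conjoint triads map residues through the class table", {
  v <- computeCTriad("AAA")
  expect_length(v, 343)
  expect_equal(unname(v[["CTriad.111"]]), 1)
  expect_equal(sum(v != 0), 1)
  # A, G, V share class 1
  expect_equal(unname(computeCTriad("AGV")[["CTriad.111"]]), 1)
  expect_error(computeCTriad("AC"), "too short")
})

test_that("QSO coupling numbers match a hand-evaluated toy distance matrix", {
  toy <- matrix(0, 20, 20, dimnames = list(AA, AA))
  toy["A", "C"] <- 1; toy["C", "A"] <- 1
  v <- computeQSO("ACA", lag = 2, matrices = list(toy = toy))
  expect_equal(unname(v[["SOCN.toy.1"]]), 2)  # 1^2 + 1^2
  expect_equal(unname(v[["SOCN.toy.2"]]), 0)
  expect_length(computeQSO(randomSeqs(1, 40, 40, seed = 2)[[1]]), 160)
  expect_error(computeQSO(strrep("A", 10), lag = 30), "lag.*exceeds")
})

test_that("PseAAC vectors have the stated widths and sum to 1", {
  s <- randomSeqs(1, 45, 45, seed = 3)[[1]]
  p <- computePseAAC(s); ap <- computeAPseAAC(s)
  expect_length(p, 50)
  expect_length(ap, 80)
  expect_equal(sum(p), 1)
  expect_equal(sum(ap), 1)
  # homopolymer: all order factors of the type-1 form vanish
  hp <- computePseAAC(strrep("A", 40))
  expect_true(all(hp[paste0("PAAC.lambda.", 1:30)] == 0))
  expect_equal(unname(hp[["PAAC.A"]]), 1)
  expect_error(computePseAAC(strrep("A", 20), lambda = 30), "lambda")
})

test_that("descriptors are invariant to sequence id and deterministic", {
  s <- randomSeqs(1, 50, 50, seed = 11)
  ft1 <- computeDescriptors(setNames(s, "one"), "ctd")
  ft2 <- computeDescriptors(setNames(s, "two"), "ctd")
  expect_equal(unname(featureMatrix(ft1)), unname(featureMatrix(ft2)))
  ft3 <- computeDescriptors(setNames(s, "one"), "ctd")
  expect_identical(featureMatrix(ft1), featureMatrix(ft3))
})

test_that("class tables have the published widths and name offending sequences", {
  s <- Biostrings::AAStringSet(c(ok = randomSeqs(1, 50, 50, seed = 1)[[1]],
                                 tiny = "MKVL"))
  expect_error(computeDescriptors(s, "ac"), "tiny")
  widths <- c(aac_dpc_tpc = 8420, ac = 720, ctd = 147, ctriad = 343,
              qso = 160, pseaac = 130)
  sim <- simulateProteins(nPerClass = 2, seed = 21)
  for (cl in names(widths))
    expect_equal(ncol(computeDescriptors(sim$sequences, cl)),
                 unname(widths[[cl]]), label = cl)
})

test_that("selected-feature mode equals projecting the full table", {
  s <- Biostrings::AAStringSet(randomSeqs(20, 35, 60, seed = 13))
  sel <- computeSelectedFeatures(s, c("RMY", "LI", "T"))
  expect_equal(featureNames(sel), c("TPC.RMY", "DPC.LI", "AAC.T"))
  full <- computeDescriptors(s, "aac_dpc_tpc")
  expect_equal(featureMatrix(sel),
               featureMatrix(full)[, c("TPC.RMY", "DPC.LI", "AAC.T")],
               tolerance = 1e-12)
  # hand case: RMY and LI on "RMYLI"
  one <- computeSelectedFeatures(c(q = "RMYLI"), c("RMY", "LI"))
  expect_equal(unname(featureMatrix(one)[1, ]), c(1 / 3, 1 / 4))
  expect_error(computeSelectedFeatures(s, "ZZZ"), "unknown feature")
  # non-composition classes are projectable too
  selq <- computeSelectedFeatures(s, "QSO.grantham.A")
  expect_equal(featureMatrix(selq)[, 1],
               featureMatrix(computeDescriptors(s, "qso"))[, "QSO.grantham.A"])
})
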