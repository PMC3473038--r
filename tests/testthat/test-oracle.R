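test_that("enumeration matches known counts and the counting recursion", {
  expect_length(enumerateStructures("AAAAA", tmParams), 1)
  expect_length(enumerateStructures("GAAAC", tmParams), 2)
  expect_length(enumerateStructures("GGAAACC", tmParams), 6)
  expect_error(enumerateStructures(strrep("A", 25), tmParams), "limit")
  set.seed(31)
  for (rep in 1:25) {
    seq <- randomSeq(sample(8:16, 1))
    structs <- enumerateStructures(seq, tmParams, limit = 16)
    expect_equal(length(structs), countStructures(seq, tmParams))
    # each exactly once
    keys <- vapply(structs, function(s) paste(pairTable(s), collapse = ","),
      character(1))
    expect_false(anyDuplicated(keys) > 0)
    # structure-space constraints hold for every enumerated structure
    for (s in structs) {
      bp <- basePairs(s)
      if (nrow(bp)) expect_true(all(bp[, 2] - bp[, 1] > tmParams@theta))
    }
  }
})

test_that("brute-force ensemble is a probability distribution", {
  set.seed(32)
  inst <- randomInstance()
  or <- bruteForceEnsemble(inst$seq, inst$q, 1.1, tmParams)
  expect_equal(sum(or$probs), 1, tolerance = 1e-12)
  expect_true(all(or$probs > 0))
  # beta = 0 is the classic Boltzmann ensemble
  or0 <- bruteForceEnsemble(inst$seq, inst$q, 0, tmParams)
  expect_equal(or0$probs,
    exp(-or0$energies / tmParams@RT) / sum(exp(-or0$energies / tmParams@RT)),
    tolerance = 1e-12)
  # GAAAC closed form: two Boltzmann terms
  eh <- hairpinEnergy("GAAAC", 1, 5, tmParams)
  org <- bruteForceEnsemble("GAAAC", NULL, 0, tmParams)
  expect_equal(org$Z, 1 + exp(-eh / tmParams@RT), tolerance = 1e-12)
})

test_that("accuracy counts exact pairs with NA for 0/0 ratios", {
  ref <- secondaryStructure({
    pt <- integer(10); pt[c(1, 2, 3)] <- c(10L, 9L, 7L)
    pt[c(10, 9, 7)] <- c(1L, 2L, 3L); pt
  })
  pred <- secondaryStructure({
    pt <- integer(10); pt[c(1, 2, 4)] <- c(10L, 9L, 8L)
    pt[c(10, 9, 8)] <- c(1L, 2L, 4L); pt
  })
  acc <- structureAccuracy(pred, ref)
  expect_equal(acc$tp, 2); expect_equal(acc$fp, 1); expect_equal(acc$fn, 1)
  expect_equal(acc$sensitivity, 2 / 3)
  expect_equal(acc$ppv, 2 / 3)
  perfect <- structureAccuracy(ref, ref)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$ppv, 1)
  none <- structureAccuracy(emptyStructure(10), ref)
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$ppv))
  expect_error(structureAccuracy(emptyStructure(3), ref), "lengths")
})

test_that("accuracy is symmetric with sensitivity and ppv exchanged", {
  set.seed(33)
  for (rep in 1:10) {
    a <- randomStructure()
    structs <- enumerateStructures(a$seq, tmParams)
    b <- structs[[sample(length(structs), 1)]]
    f <- structureAccuracy(a$structure, b)
    r <- structureAccuracy(b, a$structure)
    expect_equal(f$sensitivity, r$ppv)
    expect_equal(f$ppv, r$sensitivity)
  }
})

test_that("discrepancy positions use |q - x| > threshold, excluding missing", {
  ref <- secondaryStructure(c(6L, 0L, 0L, 0L, 0L, 1L))
  q <- c(0.9, 0.2, NA, 0.5, 0.8, 0.1)
  # pos 1 paired with q=0.9 -> |0.9-0| > 0.5 flagged
  # pos 2 unpaired q=0.2 -> |0.2-1| > 0.5 flagged
  # pos 3 missing -> excluded; pos 4 q=0.5 -> |0.5-1| = 0.5 not > 0.5
  d <- discrepancyPositions(q, ref)
  expect_equal(d$positions, c(1L, 2L))
  expect_equal(d$assessable, 5)
  expect_equal(d$rate, 2 / 5)
})

test_that("beta search recovers a data-supported alternative structure", {
  p <- tmParams
  expect_error(betaGridSearch("GAAAC", rep(0.5, 5), emptyStructure(5), p,
    grid = numeric(0)), "empty")
  # single-point grid returns that value
  g1 <- betaGridSearch("GAAAC", rep(0.5, 5), emptyStructure(5), p, grid = 2)
  expect_equal(g1$beta, 2)
  # data agreeing with the plain MFE: flat profile, smallest beta returned
  seq <- "GGGAAAACCC"
  mfe0 <- weightedMFE(seq, NULL, 0, p)$structure
  q0 <- unpairedIndicator(mfe0)
  gs <- betaGridSearch(seq, q0, mfe0, p, grid = seq(0, 2, 0.5))
  expect_equal(gs$beta, 0)
  expect_true(all(gs$profile$objective == 2))
  # bistable toy: the 5' G-run can pair with either C-run; the short-loop
  # helix wins on energy, the probing data favor the long-range helix
  seq2 <- "GGGGAAAACCCCAAAACCCC"
  alt <- parseDotBracket("((((............))))")
  qa <- unpairedIndicator(alt)
  plainAcc <- structureAccuracy(weightedMFE(seq2, NULL, 0, p)$structure, alt)
  gs2 <- betaGridSearch(seq2, qa, alt, p, grid = seq(0, 3, 0.5))
  bestAcc <- structureAccuracy(
    weightedMFE(seq2, qa, gs2$beta, p)$structure, alt)
  expect_true(bestAcc$sensitivity == 1 && bestAcc$ppv == 1)
  expect_true(is.na(plainAcc$sensitivity) || plainAcc$sensitivity < 1 ||
    plainAcc$ppv < 1)
})
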