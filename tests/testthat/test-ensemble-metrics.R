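test_that("structure distance is the L1 sum over positions", {
  empty <- emptyStructure(5)
  expect_equal(structureDistance(empty, rep(1, 5)), 0)
  expect_equal(structureDistance(empty, rep(0, 5)), 5)
  s <- secondaryStructure(c(5L, 0L, 0L, 0L, 1L))
  expect_equal(structureDistance(s, c(0.1, 0.9, 0.5, 0.9, 0.1)), 0.9)
  expect_error(structureDistance(s, c(0.1, 0.9)), "length")
})

test_that("quadratic-time ED equals the ensemble-sum definition", {
  set.seed(21)
  for (rep in 1:15) {
    inst <- randomInstance()
    beta <- runif(1, 0, 3)
    or <- bruteForceEnsemble(inst$seq, inst$q, beta, tmParams)
    ed <- expectedDistance(or$unpaired, inst$q)
    expect_equal(ed, or$ED, tolerance = 1e-9)
    # matrix input accepted too
    expect_equal(expectedDistance(or$bpp, inst$q), or$ED, tolerance = 1e-9)
  }
  # degenerate single-structure ensemble: ED = d(S, q)
  q <- runif(4)
  or1 <- bruteForceEnsemble("AAAA", q, 1, tmParams)
  expect_equal(or1$ED, structureDistance(emptyStructure(4), q))
  # q = 0.5 everywhere: ED = n/2 for any ensemble
  inst <- randomInstance()
  or5 <- bruteForceEnsemble(inst$seq, rep(0.5, inst$n), 0.8, tmParams)
  expect_equal(expectedDistance(or5$unpaired, rep(0.5, inst$n)), inst$n / 2)
})

test_that("critical distance separates gainers from losers", {
  set.seed(22)
  for (rep in 1:10) {
    inst <- randomInstance()
    beta <- runif(1, 0.3, 2.5)
    or0 <- bruteForceEnsemble(inst$seq, inst$q, 0, tmParams)
    orb <- bruteForceEnsemble(inst$seq, inst$q, beta, tmParams)
    dstar <- criticalDistance(or0$logZ, orb$logZ, beta, tmParams@RT)
    gain <- orb$probs > or0$probs
    below <- orb$distances < dstar
    # P'(S) > P(S)  <=>  d(S, q) < d*
    expect_equal(gain, below)
  }
  # AAAA: single structure forces d* = d(empty, q)
  q <- runif(4)
  or0 <- bruteForceEnsemble("AAAA", q, 0, tmParams)
  orb <- bruteForceEnsemble("AAAA", q, 1, tmParams)
  expect_equal(criticalDistance(or0$logZ, orb$logZ, 1, tmParams@RT),
    sum(1 - q), tolerance = 1e-9)
  # beta = 0 needs the documented limit
  expect_error(criticalDistance(1, 1, 0, tmParams@RT), "ed0")
  expect_equal(criticalDistance(1, 1, 0, tmParams@RT, ed0 = 3.2), 3.2)
})

test_that("pointwise entropies vanish for deterministic ensembles", {
  bpp <- matrix(0, 4, 4)
  ent <- pointwiseEntropy(bpp, "full")
  expect_equal(ent$H, rep(0, 4))
  expect_equal(pointwiseEntropy(bpp, "binary")$H, rep(0, 4))
  # u = 0.5 -> binary entropy ln 2
  b2 <- matrix(0, 2, 2); b2[1, 2] <- b2[2, 1] <- 0.5
  expect_equal(pointwiseEntropy(b2, "binary")$H, rep(log(2), 2))
  # two equally likely partners, never unpaired -> full entropy ln 2
  b3 <- matrix(0, 3, 3)
  b3[1, 2] <- b3[2, 1] <- 0.5
  b3[1, 3] <- b3[3, 1] <- 0.5
  expect_equal(pointwiseEntropy(b3, "full")$H[1], log(2))
})

test_that("Morgan-Higgs diversity is the expected pair distance", {
  certain <- matrix(0, 3, 3); certain[1, 3] <- certain[3, 1] <- 1
  expect_equal(morganHiggsDiversity(certain), 0)
  half <- matrix(0, 2, 2); half[1, 2] <- half[2, 1] <- 0.5
  expect_equal(morganHiggsDiversity(half), 0.5)
  # exhaustive double-sum over the enumerated ensemble
  set.seed(23)
  for (rep in 1:8) {
    inst <- randomInstance(8, 12)
    or <- bruteForceEnsemble(inst$seq, inst$q, runif(1, 0, 2), tmParams)
    keys <- lapply(or$structures, function(s) {
      bp <- basePairs(s); paste(bp[, 1], bp[, 2])
    })
    m <- length(keys)
    exp_dist <- 0
    for (a in seq_len(m)) for (b in seq_len(m))
      exp_dist <- exp_dist + or$probs[a] * or$probs[b] *
        (length(setdiff(keys[[a]], keys[[b]])) +
         length(setdiff(keys[[b]], keys[[a]])))
    expect_equal(morganHiggsDiversity(or$bpp), exp_dist, tolerance = 1e-9)
  }
})
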