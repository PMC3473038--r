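test_that("Boltzmann position weights follow exp(-beta|x-q|/RT)", {
  RT <- tmParams@RT
  w <- buildWeights(c(0, 0.5, 1), 0, RT)
  expect_equal(w$w0, rep(1, 3))
  expect_equal(w$w1, rep(1, 3))
  w2 <- buildWeights(c(0, 0.5, 1), 1.2, RT)
  expect_equal(w2$w1[3], 1)                     # zero discrepancy
  expect_equal(w2$w0[1], 1)
  expect_equal(w2$w0[2], w2$w1[2])              # q = 0.5 symmetric
  expect_equal(w2$w0[2], exp(-0.5 * 1.2 / RT))
  expect_error(buildWeights(c(0.5), -1, RT), "beta")
  expect_error(buildWeights(c(NA_real_), 1, RT), "missing")
})

test_that("loop weight is the product of unpaired weights", {
  w <- list(w0 = rep(1, 5), w1 = c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(loopWeight(w, 3, 2), 1)          # empty interval
  expect_equal(loopWeight(w, 2, 4), 0.8 * 0.7 * 0.6)
  expect_equal(loopWeight(w, 1, 4), loopWeight(w, 1, 3) * w$w1[4])
})

test_that("single-structure and two-structure sequences have closed forms", {
  p <- tmParams
  RT <- p@RT
  # AAAA: only the empty structure
  set.seed(11)
  q <- runif(4)
  w <- buildWeights(q, 1.3, RT)
  tb <- insidePartition("AAAA", w, p)
  expect_equal(tb$Z[1, 4], prod(w$w1), tolerance = 1e-12)
  pp <- pairProbabilities(tb)
  expect_equal(pp$bpp, matrix(0, 4, 4))
  expect_equal(pp$unpaired, rep(1, 4))
  # GAAAC with unit weights: Z = 1 + exp(-Eh/RT), p(1,5) closed form
  eh <- hairpinEnergy("GAAAC", 1, 5, p)
  tb2 <- insidePartition("GAAAC", unitWeights(5), p)
  expect_equal(tb2$Z[1, 5], 1 + exp(-eh / RT), tolerance = 1e-12)
  pp2 <- pairProbabilities(tb2)
  expect_equal(pp2$bpp[1, 5], exp(-eh / RT) / (1 + exp(-eh / RT)),
    tolerance = 1e-12)
  # GGAAACC: sum over the 6 enumerated structures
  or <- bruteForceEnsemble("GGAAACC", NULL, 0, p)
  expect_length(or$structures, 6)
  tb3 <- insidePartition("GGAAACC", unitWeights(7), p)
  expect_equal(tb3$Z[1, 7], or$Z, tolerance = 1e-12)
})

test_that("per-structure factorization: position weights give exp(-beta d/RT)", {
  set.seed(12)
  for (rep in 1:20) {
    inst <- randomStructure()
    n <- nchar(inst$seq)
    q <- runif(n)
    beta <- runif(1, 0.1, 3)
    w <- buildWeights(q, beta, tmParams@RT)
    x <- unpairedIndicator(inst$structure)
    fac <- prod(ifelse(x == 1, w$w1, w$w0))
    d <- structureDistance(inst$structure, q)
    expect_equal(fac, exp(-beta * d / tmParams@RT), tolerance = 1e-12)
  }
})

test_that("beta = 0 reduces bitwise to the plain fold", {
  set.seed(13)
  seq <- randomSeq(12)
  q <- runif(12)
  plain <- foldRna(seq, mode = "plain")
  soft0 <- foldRna(seq, q = q, beta = 0, mode = "soft")
  expect_identical(pairProbs(soft0), pairProbs(plain))
  expect_identical(soft0@logZWeighted, plain@logZWeighted)
  expect_identical(pairTable(mfeStructure(soft0)),
    pairTable(mfeStructure(plain)))
  expect_identical(soft0@mfeScore, plain@mfeScore)
})

test_that("weighted MFE minimizes E + beta*d and reduces at beta = 0", {
  p <- tmParams
  set.seed(14)
  # AAAA: empty structure, score = beta * sum(1 - q)
  q4 <- runif(4)
  m <- weightedMFE("AAAA", q4, 2, p)
  expect_equal(pairTable(m$structure), rep(0L, 4))
  expect_equal(m$score, 2 * sum(1 - q4))
  for (rep in 1:15) {
    inst <- randomInstance()
    beta <- sample(c(0, 0.7, 1.5, 3), 1)
    or <- bruteForceEnsemble(inst$seq, inst$q, beta, p)
    mfe <- weightedMFE(inst$seq, inst$q, beta, p)
    expect_equal(mfe$score, or$mfeScore, tolerance = 1e-9)
    # returned structure attains the reported score
    expect_equal(energyOfStructure(inst$seq, mfe$structure, p) +
      beta * structureDistance(mfe$structure, inst$q), mfe$score,
      tolerance = 1e-9)
  }
})

test_that("inside/outside normalization: u + sum_j p = 1 at every position", {
  set.seed(15)
  for (rep in 1:10) {
    inst <- randomInstance()
    w <- buildWeights(inst$q, runif(1, 0, 3), tmParams@RT)
    pp <- pairProbabilities(insidePartition(inst$seq, w, tmParams))
    expect_equal(rowSums(pp$bpp) + pp$unpaired, rep(1, inst$n),
      tolerance = 1e-9)
    expect_true(all(pp$bpp >= -1e-12 & pp$bpp <= 1 + 1e-12))
  }
})

test_that("Deigan pseudo-energy term follows m ln(s+1) + b", {
  expect_equal(deiganPseudoEnergy(0), -0.8)
  expect_equal(deiganPseudoEnergy(exp(1) - 1), 2.6 - 0.8)
  expect_equal(deiganPseudoEnergy(NA), 0)
  expect_equal(deiganPseudoEnergy(c(0, NA, exp(1) - 1)), c(-0.8, 0, 1.8))
})

test_that("Deigan mode: missing data reduces to plain; isolated pairs free", {
  p <- tmParams
  seq <- "GGGCAAAAGCCC"
  allNA <- rep(NA_real_, nchar(seq))
  fd <- foldDeigan(seq, allNA, p)
  plain <- weightedMFE(seq, NULL, 0, p)
  expect_identical(pairTable(fd$structure), pairTable(plain$structure))
  expect_equal(fd$energy, plain$energy)
  # isolated pair: no stacked context, so pseudo-energy contributes nothing
  s <- parseDotBracket("(....)", validate = "none")
  pseudo <- deiganPseudoEnergy(rep(2, 6))
  expect_equal(energyOfStructure("GAAAAC", s, p, pseudo = pseudo),
    energyOfStructure("GAAAAC", s, p))
})

test_that("Deigan stacking rule counts interior helix positions twice", {
  p <- tmParams
  # 3-stack helix on GGGAAAACCC: pairs (1,10),(2,9),(3,8)
  seq <- "GGGAAAACCC"
  s <- parseDotBracket("(((....)))")
  pseudo <- seq(0.1, 1.0, by = 0.1)
  expected <- sum(pseudo[c(1, 10, 2, 9)]) + sum(pseudo[c(2, 9, 3, 8)])
  expect_equal(
    energyOfStructure(seq, s, p, pseudo = pseudo) -
      energyOfStructure(seq, s, p),
    expected)
})

test_that("rescaled long-sequence fold stays finite and normalized", {
  set.seed(16)
  seq <- randomSeq(120)
  q <- runif(120)
  r <- foldRna(seq, q = q, beta = 1)
  expect_true(is.finite(r@logZ) && is.finite(r@logZWeighted))
  expect_true(all(r@unpaired >= -1e-9 & r@unpaired <= 1 + 1e-9))
  expect_equal(rowSums(pairProbs(r)) + r@unpaired, rep(1, 120),
    tolerance = 1e-9)
})
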