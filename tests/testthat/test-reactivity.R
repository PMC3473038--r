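test_that("SHAPE map hits its breakpoints, caps and clamps", {
  cfg <- defaultNormalizationConfig()
  expect_equal(normalizeShape(0), 0)
  expect_equal(normalizeShape(cfg$shapeCap), 1)
  expect_equal(normalizeShape(5), 1)            # above cap
  expect_equal(normalizeShape(-0.3), 0)         # negative clamps to 0 first
  # interior breakpoints map to their configured targets
  expect_equal(normalizeShape(cfg$shapeBreaksRaw), cfg$shapeBreaksTarget)
  # midpoint of a segment maps linearly
  mid <- (0.3 + 0.7) / 2
  expect_equal(normalizeShape(mid), (0.55 + 0.85) / 2)
  # missing propagates
  expect_equal(normalizeShape(c(0.1, NA)), c(normalizeShape(0.1), NA))
})

test_that("SHAPE map rejects malformed configs", {
  bad <- defaultNormalizationConfig()
  bad$shapeBreaksRaw <- c(0, 0.3, 0.25, 0.7, 2.2)
  expect_error(normalizeShape(0.5, bad), "strictly increasing")
  bad2 <- defaultNormalizationConfig()
  bad2$shapeBreaksTarget <- c(0, 0.35, 0.55, 0.85, 0.9)
  expect_error(normalizeShape(0.5, bad2), "end at 1")
})

test_that("in-line quantile map clamps outliers and centers the midpoint", {
  set.seed(3)
  raw <- runif(200, 0, 10)
  q <- normalizeInline(raw)
  expect_true(all(q >= 0 & q <= 1))
  expect_equal(q[which.min(raw)], 0)   # min is below the 2.5% quantile
  expect_equal(q[which.max(raw)], 1)
  # on 0..100 the clip limits are exactly (2.5, 97.5), so 50 maps to 0.5
  qmid <- normalizeInline(as.numeric(0:100))
  expect_equal(qmid[51], 0.5)
  expect_warning(qc <- normalizeInline(rep(2, 10)), "degenerate")
  expect_equal(qc, rep(0.5, 10))
  expect_error(normalizeInline(c(1, NA)), "at least 2")
})

test_that("both normalizations are monotone with range [0,1]", {
  set.seed(4)
  for (rep in 1:20) {
    raw <- sort(c(rnorm(30, 0.5, 0.6), rexp(10)))
    qs <- normalizeShape(raw)
    qi <- normalizeInline(raw)
    expect_true(all(diff(qs) >= 0))
    expect_true(all(diff(qi) >= 0))
    expect_true(all(qs >= 0 & qs <= 1))
    expect_true(all(qi >= 0 & qi <= 1))
  }
})

test_that("resolveMissing fills, validates and is idempotent", {
  expect_equal(resolveMissing(c(0.1, NA, 0.9)), c(0.1, 0.5, 0.9))
  expect_equal(resolveMissing(rep(NA_real_, 4)), rep(0.5, 4))
  expect_error(resolveMissing(c(0.1, NA), fill = 1.2), "probability")
  complete <- c(0.2, 0.8)
  expect_identical(resolveMissing(complete), complete)
})

test_that("normalizeProfile dispatches on probing chemistry", {
  prof <- new("ReactivityProfile", raw = c(0, 1, NA, 2.5), kind = "shape")
  np <- normalizeProfile(prof)
  expect_equal(unpairedProbs(np)[1], 0)
  expect_equal(unpairedProbs(np)[4], 1)
  expect_true(is.na(unpairedProbs(np)[3]))
  prof2 <- new("ReactivityProfile", raw = c(1, 2, 3, 4, 5), kind = "inline")
  expect_true(all(diff(unpairedProbs(normalizeProfile(prof2))) >= 0))
})
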