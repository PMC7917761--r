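# Regression-tree fitting, stage boosting, cascade training and prediction.

test_that("a single-sample tree stores nu times its residual in the leaf", {
  feat <- matrix(runif(6), 1, 6)
  resid <- matrix(c(2, -1, 0.5), 1, 3)
  tr <- fitTree(feat, resid, depth = 3L, nCandidates = 10L, shrinkage = 0.1,
                seed = 1L)
  populated <- which(rowSums(tr$leaves != 0) > 0)
  expect_length(populated, 1L)
  expect_equal(tr$leaves[populated, ], 0.1 * as.numeric(resid),
               tolerance = 1e-12)
})

test_that("two separable samples split into +/- nu r leaves", {
  feat <- cbind(c(0, 1), c(0, 0))    # probe 1 separates, probe 2 constant
  r <- c(3, -4)
  resid <- rbind(r, -r)
  tr <- fitTree(feat, resid, depth = 1L, nCandidates = 200L, shrinkage = 0.5,
                seed = 2L)
  expect_equal(sort(tr$leafIndex), c(1L, 2L))
  expect_equal(tr$leaves[tr$leafIndex[1], ], 0.5 * r, tolerance = 1e-12)
  expect_equal(tr$leaves[tr$leafIndex[2], ], -0.5 * r, tolerance = 1e-12)
})

test_that("exhaustive split search matches an independent brute-force oracle", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(4:20, 1)
    P <- sample(3:6, 1)
    depth <- sample(1:2, 1)
    feat <- matrix(round(runif(n * P), 2), n, P)
    resid <- matrix(rnorm(n * 4), n, 4)
    tr <- fitTree(feat, resid, depth = depth, shrinkage = 1,
                  exhaustive = TRUE)
    got <- fittedTreeSSE(tr, feat, resid, shrinkage = 1)
    want <- bruteForceTreeSSE(feat, resid, depth)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("tree fitting is deterministic under a fixed seed", {
  set.seed(29)
  feat <- matrix(runif(60 * 12), 60, 12)
  resid <- matrix(rnorm(60 * 8), 60, 8)
  t1 <- fitTree(feat, resid, depth = 3L, nCandidates = 40L, seed = 77L)
  t2 <- fitTree(feat, resid, depth = 3L, nCandidates = 40L, seed = 77L)
  expect_identical(t1, t2)
  t3 <- fitTree(feat, resid, depth = 3L, nCandidates = 40L, seed = 78L)
  expect_false(identical(t1$theta, t3$theta))
})

test_that("stage boosting decreases training loss monotonically", {
  st <- tinyStudy(2L, 8L)
  cfg <- csrConfig(T = 1L, K = 50L, F = 3L, P = 60L, nCandidates = 50L,
                   seed = 3L)
  m <- trainCSR(augmentFlips(st), cfg)
  loss <- m@lossTrace[[1]]
  expect_length(loss, 51L)
  expect_true(all(diff(loss) <= 1e-9))
  expect_lt(loss[51], loss[2])
  expect_lt(loss[2], loss[1])

  # reproducible loss sequence under the same master seed
  m2 <- trainCSR(augmentFlips(st), cfg)
  expect_identical(m@lossTrace, m2@lossTrace)
})

test_that("zero-residual training is a fixed point", {
  st <- tinyStudy(1L, 4L)
  # replace every ground truth by its own initialization
  mean <- meanShape(lapply(st, function(s) s@shape),
                    lapply(st, function(s) bbox(s)))
  fixed <- lapply(st, function(s)
    annotatedSample(s@image, initShape(bbox(s), mean), bbox(s),
                    subjectId(s), s@distance, s@section))
  cfg <- csrConfig(T = 2L, K = 10L, F = 2L, P = 30L, nCandidates = 20L,
                   seed = 4L)
  m <- trainCSR(fixed, cfg)
  expect_true(all(unlist(m@lossTrace) < 1e-18))
  for (s in fixed) {
    pred <- predictShape(m, s@image, bbox(s))
    expect_equal(coords(pred), coords(initShape(bbox(s), faceShape(m@meanShape))),
                 tolerance = 1e-9)
  }
})

test_that("the default configuration carries the study settings", {
  cfg <- csrConfig()
  expect_identical(cfg$T, 10L)
  expect_identical(cfg$F, 4L)
  expect_identical(cfg$K, 500L)
  expect_identical(cfg$P, 400L)
  expect_error(csrConfig(bogusKey = 1), "unused argument")
  expect_error(csrConfig(T = 0L), "config error")
  expect_error(csrConfig(shrinkage = 1.5), "config error")
})

test_that("prediction is deterministic and traced stage by stage", {
  st <- tinyStudy(2L, 5L)
  cfg <- csrConfig(T = 3L, K = 10L, F = 2L, P = 40L, nCandidates = 30L,
                   seed = 6L)
  m <- trainCSR(augmentFlips(st), cfg)
  s <- st[[1]]
  p1 <- predictShape(m, s@image, bbox(s))
  p2 <- predictShape(m, s@image, bbox(s))
  expect_identical(coords(p1), coords(p2))

  tr <- predictTrace(m, s@image, bbox(s))
  expect_length(tr, 4L)
  expect_equal(coords(tr[[1]]),
               coords(initShape(bbox(s), faceShape(m@meanShape))),
               tolerance = 1e-12)
  expect_identical(coords(tr[[4]]), coords(p1))

  # per-stage training NPPE is non-increasing
  expect_true(all(diff(m@trainLog$trainNPPE) <= 1e-9))
})

test_that("full training is byte-reproducible under one master seed", {
  st <- tinyStudy(2L, 4L)
  cfg <- csrConfig(T = 2L, K = 6L, F = 2L, P = 25L, nCandidates = 20L,
                   seed = 101L)
  m1 <- trainCSR(augmentFlips(st), cfg)
  m2 <- trainCSR(augmentFlips(st), cfg)
  expect_identical(m1@stages, m2@stages)
  expect_identical(m1@meanShape, m2@meanShape)
})
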