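# Shape arithmetic: mean shape, initialization, similarity alignment,
# flip augmentation.

test_that("mean shape removes bbox translation and scale", {
  shp <- testShape(8L)
  bb <- bBox(10, 20, 50, 40)
  one <- meanShape(list(shp), list(bb))
  expect_equal(coords(one),
               cbind((coords(shp)[, 1] - 10) / 50, (coords(shp)[, 2] - 20) / 40),
               ignore_attr = TRUE)

  # a pure translate with an equally translated bbox averages to itself
  shift <- faceShape(coords(shp) + matrix(c(30, -5), 8, 2, byrow = TRUE))
  bb2 <- bBox(40, 15, 50, 40)
  two <- meanShape(list(shp, shift), list(bb, bb2))
  expect_equal(coords(two), coords(one), tolerance = 1e-12)

  expect_error(meanShape(list(), list()), "no shapes")
  expect_error(meanShape(list(shp, testShape(5L)), list(bb, bb)), "mixed|dimension")
})

test_that("empirical mean shape concentrates at the template (CLT bound)", {
  set.seed(11)
  template <- coords(testShape(20L, seed = 2L))
  sigma <- 2
  bb <- bBox(0, 0, 100, 100)
  shapes <- lapply(1:10, function(i)
    faceShape(template + matrix(rnorm(40, 0, sigma), 20, 2)))
  mu <- coords(meanShape(shapes, rep(list(bb), 10)))
  # per-coordinate deviation below 3*sigma/sqrt(10), in bbox units
  expect_lt(max(abs(mu - template / 100)), 3 * sigma / sqrt(10) / 100)
})

test_that("initShape is deterministic and bbox-equivariant", {
  mean <- meanShape(list(testShape(12L)), list(bBox(0, 0, 100, 100)))
  s1 <- initShape(bBox(0, 0, 100, 100), mean)
  expect_equal(coords(s1), coords(mean) * 100, ignore_attr = TRUE)
  expect_identical(coords(initShape(bBox(10, 20, 50, 50), mean)),
                   coords(initShape(bBox(10, 20, 50, 50), mean)))
  a <- coords(initShape(bBox(10, 20, 50, 50), mean))
  b <- coords(initShape(bBox(15, 20, 50, 50), mean))
  expect_equal(b - a, matrix(c(5, 0), 12, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(initShape(bBox(0, 0, -1, 5), mean))
})

test_that("similarity alignment recovers composed transforms", {
  src <- testShape(10L)
  idt <- alignSimilarity(src, src)
  expect_equal(idt$scale, 1, tolerance = 1e-12)
  expect_equal(idt$rotation, 0, tolerance = 1e-12)

  tr <- alignSimilarity(src, faceShape(coords(src) +
                                         matrix(c(5, -3), 10, 2, byrow = TRUE)))
  expect_equal(c(tr$scale, tr$rotation, tr$tx, tr$ty), c(1, 0, 5, -3),
               tolerance = 1e-9)

  tf0 <- list(scale = 1.7, rotation = 30 * pi / 180, tx = 4, ty = 9)
  dst <- applyTransform(tf0, coords(src))
  tf <- alignSimilarity(coords(src), dst)
  expect_equal(tf[c("scale", "rotation", "tx", "ty")],
               tf0[c("scale", "rotation", "tx", "ty")], tolerance = 1e-8)

  expect_error(alignSimilarity(matrix(1, 5, 2), matrix(2, 5, 2)),
               "degenerate")
})

test_that("alignment recovers random similarities over random shapes", {
  set.seed(13)
  for (i in 1:25) {
    src <- matrix(runif(2 * sample(3:30, 1), -100, 100), ncol = 2)
    tf0 <- randomSimilarity()
    tf <- alignSimilarity(src, applyTransform(tf0, src))
    expect_equal(tf$scale, tf0$scale, tolerance = 1e-6)
    expect_equal(sin(tf$rotation - tf0$rotation), 0, tolerance = 1e-6)
    expect_equal(c(tf$tx, tf$ty), c(tf0$tx, tf0$ty), tolerance = 1e-4)
    inv <- thermalign::invertTransform(tf0)
    back <- applyTransform(inv, applyTransform(tf0, src))
    expect_equal(back, src, tolerance = 1e-9)
  }
})

test_that("the 68-point mirror map is an involution fixing the midline", {
  perm <- defaultMirrorMap68()
  expect_identical(perm[perm], seq_len(68L))
  fixed <- which(perm == seq_len(68L))
  # chin, nose bridge + tip, under-nose center, lip centers (1-based)
  expect_identical(fixed, c(9L, 28L, 29L, 30L, 31L, 34L, 52L, 58L, 63L, 67L))
})

test_that("flipping is an involution and follows the pixel-center rule", {
  st <- tinyStudy(1L, 3L)
  s <- st[[2]]
  f <- flipSample(s)
  expect_true(f@flipped)
  expect_identical(subjectId(f), subjectId(s))
  W <- ncol(pixels(s@image))
  perm <- defaultMirrorMap68()
  expect_equal(coords(f@shape)[perm, 1], W - 1 - coords(s@shape)[, 1],
               tolerance = 1e-12)
  ff <- flipSample(f)
  expect_false(ff@flipped)
  expect_identical(pixels(ff@image), pixels(s@image))
  expect_equal(coords(ff@shape), coords(s@shape), tolerance = 1e-9)
  expect_equal(c(bbox(ff)@x, bbox(ff)@y, bbox(ff)@w, bbox(ff)@h),
               c(bbox(s)@x, bbox(s)@y, bbox(s)@w, bbox(s)@h),
               tolerance = 1e-9)

  # landmark at x = 0 in a 640-wide frame maps to x = 639
  img <- thermalImage(matrix(24, 4, 640))
  cc <- coords(canonicalTemplate68()) * 3
  cc[1, ] <- c(0, 1)
  smp <- annotatedSample(img, faceShape(cc), bBox(0, 0, 4, 3.2), "S1")
  flp <- flipSample(smp)
  expect_equal(unname(coords(flp@shape)[defaultMirrorMap68()[1], 1]), 639)

  badPerm <- c(2L, 3L, 1L, 4:68)
  expect_error(flipSample(s, mirror = badPerm), "involution")
})

test_that("flip augmentation doubles the dataset", {
  st <- tinyStudy(2L, 4L)
  aug <- augmentFlips(st)
  expect_length(aug, 16L)
  expect_identical(vapply(aug, function(s) s@flipped, logical(1)),
                   rep(c(FALSE, TRUE), each = 8L))
})
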