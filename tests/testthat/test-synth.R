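# Synthetic thermal-face generator: template, renderer, protocol.

test_that("the canonical template is a constant symmetric 68-point layout", {
  tpl <- canonicalTemplate68()
  expect_equal(nLandmarks(tpl), 68L)
  expect_identical(coords(tpl), coords(canonicalTemplate68()))
  perm <- defaultMirrorMap68()
  mir <- cbind(1 - coords(tpl)[, 1], coords(tpl)[, 2])[perm, ]
  expect_equal(mir, coords(tpl), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(coords(tpl) >= 0 & coords(tpl) <= 1))
})

test_that("identity-pose rendering reproduces the stored layout exactly", {
  spec <- protocolSpec(imageSize = c(320L, 240L))
  prof <- subjectProfiles(spec)[[1]]
  s <- renderFace(prof, pose = c(0, 0, 0), distance = 60, spec = spec,
                  seed = 91L)
  meta <- s@image@meta
  # ground truth is the deformed template under the recorded scale/shift
  expect_equal(coords(s@shape),
               meta$shape0 * meta$scale +
                 matrix(c(meta$tx, meta$ty), 68, 2, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
  # identity pose: layout is similar to the deformed template
  tf <- alignSimilarity(meta$shape0, coords(s@shape))
  expect_equal(tf$rotation, 0, tolerance = 1e-9)
  resid <- applyTransform(tf, meta$shape0) - coords(s@shape)
  expect_lt(max(abs(resid)), 1e-6)
  expect_error(renderFace(prof, pose = c(70, 0, 0), spec = spec),
               "value error")
})

test_that("rendered face temperatures honor the subject profile", {
  spec <- protocolSpec(imageSize = c(320L, 240L))
  profs <- subjectProfiles(spec)
  for (i in c(1L, 5L)) {
    s <- renderFace(profs[[i]], pose = c(20, -20, 0), distance = 90,
                    spec = spec, seed = 100L + i, subject = sprintf("S%d", i))
    st <- faceTemperatureStats(s@image, s@shape)
    slack <- 3 * spec$noiseSd
    expect_gte(st[["tMin"]], profs[[i]]$tMin - slack)
    expect_lte(st[["tMax"]], profs[[i]]$tMax + slack)
    expect_equal(st[["tMean"]], profs[[i]]$tMean, tolerance = 0.05)
  }
})

test_that("study-mode temperature statistics stay in the observed envelope", {
  st <- tinyStudy(3L, 6L, imageSize = c(320L, 240L), seed = 7L)
  slack <- 3 * 0.05
  for (s in st) {
    v <- faceTemperatureStats(s@image, s@shape)
    expect_gte(v[["tMin"]], 29.2 - slack)
    expect_lte(v[["tMin"]], 31.4 + slack)
    expect_gte(v[["tMax"]], 33.7 - slack)
    expect_lte(v[["tMax"]], 34.3 + slack)
    expect_gte(v[["tMean"]], 31.85 - slack)
    expect_lte(v[["tMean"]], 33.0 + slack)
  }
})

test_that("face widths track the distance condition targets", {
  spec <- protocolSpec(imageSize = c(400L, 300L))
  prof <- subjectProfiles(spec)[[2]]
  widths <- vapply(1:50, function(i) {
    s <- renderFace(prof, pose = c(0, 0, 0), distance = 120, spec = spec,
                    seed = 200L + i)
    pixelsPerFaceWidth(s)
  }, numeric(1))
  expect_lt(abs(mean(widths) - 97) / 97, 0.10)
})

test_that("the study allocation is deterministic and correctly labelled", {
  spec <- protocolSpec(nSubjects = 2L, imagesPerSubject = 29L,
                       imageSize = c(320L, 240L), seed = 5L)
  st <- generateStudy(spec)
  expect_length(st, 58L)
  subj <- vapply(st, subjectId, character(1))
  expect_equal(as.numeric(table(subj)), c(29, 29))
  one <- st[subj == "S1"]
  dist <- vapply(one, function(s) s@distance, numeric(1))
  expect_equal(sort(unique(dist)), c(60, 90, 120))
  sect <- vapply(one, function(s) s@section, character(1))
  # 29 images at one distance would split 9/9/11; here 29 over 3 distances
  expect_true(all(c("Small", "Large", "Random") %in% sect))
  # determinism: same spec, same dataset
  st2 <- generateStudy(spec)
  expect_identical(pixels(st2[[10]]@image), pixels(st[[10]]@image))
  expect_identical(coords(st2[[10]]@shape), coords(st[[10]]@shape))
  # a different seed changes the rendering
  st3 <- generateStudy(protocolSpec(nSubjects = 2L, imagesPerSubject = 29L,
                                    imageSize = c(320L, 240L), seed = 6L))
  expect_false(identical(pixels(st3[[10]]@image), pixels(st[[10]]@image)))
})

test_that("the per-subject section split reproduces the 9/9/11 allocation", {
  counts <- thermalign:::sectionCounts(29L)
  expect_equal(unname(counts), c(9L, 9L, 11L))
  expect_equal(sum(thermalign:::sectionCounts(10L)), 10L)
})

test_that("bounding boxes pad the landmark extent by 10 percent", {
  st <- tinyStudy(1L, 3L)
  s <- st[[1]]
  cc <- coords(s@shape)
  expect_equal(bbox(s)@w, diff(range(cc[, 1])) * 1.2, tolerance = 1e-9)
  expect_equal(bbox(s)@x, min(cc[, 1]) - 0.1 * diff(range(cc[, 1])),
               tolerance = 1e-9)
})
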