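# Image, landmark, manifest and model I/O: round trips and error contracts.

test_that("CSV thermal images round-trip and validate", {
  img <- constImage(24, 3, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeThermalImage(img, path)
  back <- readThermalImage(path)
  expect_s4_class(back, "ThermalImage")
  expect_equal(dim(pixels(back)), c(3L, 3L))
  expect_true(all(pixels(back) == 24))
  expect_equal(imageUnit(back), "celsius")

  set.seed(1)
  img2 <- thermalImage(matrix(runif(64 * 48, 22, 35), 48, 64))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeThermalImage(img2, path2, digits = 6L)
  expect_lt(max(abs(pixels(readThermalImage(path2)) - pixels(img2))), 1e-6)
})

test_that("ragged and non-numeric CSV rows are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "1,2"), path)
  expect_error(readThermalImage(path), "ragged")
  writeLines(c("1,2", "3,x"), path)
  expect_error(readThermalImage(path), "row 2.*col 2")
  expect_error(readThermalImage(tempfile(fileext = ".csv")), "not found")
})

test_that("tiff16 carrier stays within its quantization bound", {
  set.seed(2)
  img <- thermalImage(matrix(runif(64 * 48, 20, 40), 48, 64))
  path <- withr::local_tempfile(fileext = ".tif")
  writeThermalImage(img, path, scale = 0.01, offset = 0)
  back <- readThermalImage(path, scale = 0.01, offset = 0)
  # half-count quantization: scale / 2
  expect_lte(max(abs(pixels(back) - pixels(img))), 0.005)
})

test_that("png8 carries 8-bit intensity frames", {
  img <- thermalImage(matrix(rep(0:255, length.out = 32 * 32), 32, 32),
                      unit = "intensity")
  path <- withr::local_tempfile(fileext = ".png")
  writeThermalImage(img, path)
  back <- readThermalImage(path)
  expect_equal(imageUnit(back), "intensity")
  expect_equal(pixels(back), pixels(img), ignore_attr = TRUE)
})

test_that("pts files round-trip exactly and enforce their header", {
  set.seed(3)
  shp <- faceShape(cbind(runif(68, 0, 640), runif(68, 0, 480)))
  path <- withr::local_tempfile(fileext = ".pts")
  writeLandmarks(shp, path)
  back <- readLandmarks(path)
  expect_equal(nLandmarks(back), 68L)
  expect_equal(coords(back), coords(shp), tolerance = 1e-6)
  # on-disk coordinates are 1-based
  body <- readLines(path)
  first <- as.numeric(strsplit(body[4], " ")[[1]])
  expect_equal(first, coords(shp)[1, ] + 1, tolerance = 1e-6,
               ignore_attr = TRUE)

  lines <- readLines(path)
  writeLines(lines[-5], path)  # drop one coordinate line
  expect_error(readLandmarks(path), "declares 68 points but file has 67")
  writeLines(c("version: 1", "n_points: 2", "{", "1 2", "3 a", "}"), path)
  expect_error(readLandmarks(path), "non-numeric")
})

test_that("manifests load in order and name the failing record", {
  st <- tinyStudy(2L, 4L)
  dir <- withr::local_tempdir()
  writeStudy(st, dir, format = "csv")
  man <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8L)
  ds <- loadDataset(man)
  expect_length(ds, 8L)
  expect_equal(vapply(ds, subjectId, character(1)),
               vapply(st, subjectId, character(1)))
  expect_equal(coords(ds[[3]]@shape), coords(st[[3]]@shape),
               tolerance = 1e-5, ignore_attr = TRUE)

  man$image[5] <- "missing.csv"
  expect_error(loadDataset(man), "record 5")
  expect_length(loadDataset(man[0, ]), 0L)
})

test_that("model archives round-trip with identical predictions", {
  st <- tinyStudy(2L, 5L)
  cfg <- csrConfig(T = 2L, K = 8L, F = 2L, P = 30L, nCandidates = 25L,
                   seed = 9L)
  model <- trainCSR(augmentFlips(st), cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_equal(length(back@stages), 2L)
  expect_equal(length(back@stages[[1]]$trees), 8L)
  for (s in st[1:5]) {
    expect_identical(coords(predictShape(back, s@image, bbox(s))),
                     coords(predictShape(model, s@image, bbox(s))))
  }
})

test_that("model loading rejects truncated and foreign files", {
  path <- withr::local_tempfile(fileext = ".rds")
  writeBin(as.raw(1:32), path)
  expect_error(loadModel(path), "I/O error")
  saveRDS(list(format = "something-else", version = 1L), path)
  expect_error(loadModel(path), "incompatibility")
  saveRDS(list(format = "thermalign-csr", version = 99L), path)
  expect_error(loadModel(path), "version")
})
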