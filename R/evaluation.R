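## NPPE metric, CED curves, subject-wise cross-validation, stratified
## summaries and throughput benchmarking.

#' Normalized point-to-point error
#'
#' The mean Euclidean distance between predicted and ground-truth landmarks,
#' divided by the mean of the face's width and height:
#' `NPPE = (1/N) * sum_n ||p_n - g_n|| / ((w + h) / 2)`.
#' 0.05 is the conventional acceptable-accuracy level. The metric is
#' invariant under joint translation of both shapes and under joint
#' rescaling of shapes and face extents.
#'
#' @param pred,gt [FaceShape-class] objects (or M x 2 matrices) with equal
#'   landmark counts.
#' @param faceW,faceH face width and height in pixels (> 0); by convention
#'   the ground-truth landmark extent.
#' @return a non-negative scalar (fraction of face size; multiply by 100 for
#'   the percent convention).
#' @export
nppe <- function(pred, gt, faceW, faceH) {
  p <- if (is(pred, "FaceShape")) pred@coords else pred
  g <- if (is(gt, "FaceShape")) gt@coords else gt
  if (nrow(p) != nrow(g)) stop("dimension error: landmark counts differ")
  if (faceW <= 0 || faceH <= 0) stop("value error: face extents must be > 0")
  d <- sqrt(rowSums((p - g)^2))
  mean(d) / ((faceW + faceH) / 2)
}

# Face extent (w, h) from ground-truth landmarks (annotation-tool
# independent); set useBBox = TRUE to normalize by the manifest box instead.
faceExtent <- function(sample, useBBox = FALSE) {
  if (useBBox) return(c(sample@bbox@w, sample@bbox@h))
  cc <- sample@shape@coords
  c(diff(range(cc[, 1])), diff(range(cc[, 2])))
}

#' NPPE of a prediction against a sample's annotation
#'
#' @param pred predicted [FaceShape-class].
#' @param sample the [AnnotatedSample-class] holding ground truth.
#' @param useBBox normalize by the manifest bbox instead of the landmark
#'   extent.
#' @export
nppeSample <- function(pred, sample, useBBox = FALSE) {
  ext <- faceExtent(sample, useBBox)
  nppe(pred, sample@shape, ext[1], ext[2])
}

#' Cumulative error distribution curve
#'
#' Fraction of images whose error is at or below each threshold -- a
#' non-decreasing step function reaching 1.
#'
#' @param errors non-empty numeric vector of per-image errors.
#' @param thresholds ascending thresholds (default: 0 to 0.15 in steps of
#'   0.005, the usual NPPE plotting range).
#' @return data.frame with columns `threshold` and `fraction`.
#' @export
ced <- function(errors, thresholds = seq(0, 0.15, by = 0.005)) {
  if (!length(errors)) stop("value error: no errors given")
  if (is.unsorted(thresholds)) stop("value error: thresholds must be ascending")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(errors <= t), numeric(1)))
}

#' Pixels per face width
#'
#' Ground-truth landmark x-extent (max - min), rounded to the nearest
#' integer -- the resolution covariate used to stratify accuracy by camera
#' distance.
#'
#' @param sample an [AnnotatedSample-class] (or a [FaceShape-class]).
#' @export
pixelsPerFaceWidth <- function(sample) {
  cc <- if (is(sample, "AnnotatedSample")) sample@shape@coords else
    sample@coords
  round(diff(range(cc[, 1])))
}

#' Subject-wise k-fold cross-validation plan
#'
#' One fold per subject: the fold's test set is all of that subject's
#' original images (mirror-augmented copies are excluded from testing by
#' default, to avoid scoring duplicates) and the training set is every other
#' subject's images including flips. Because flipped copies keep their
#' subject id, train and test are subject-disjoint in every fold.
#'
#' @param samples list of [AnnotatedSample-class].
#' @param includeFlippedTest also evaluate on mirrored copies.
#' @return list of folds; each has `subject`, `trainIdx`, `testIdx` (indices
#'   into `samples`).
#' @export
subjectKFold <- function(samples, includeFlippedTest = FALSE) {
  subj <- vapply(samples, subjectId, character(1))
  flip <- vapply(samples, function(s) s@flipped, logical(1))
  ids <- unique(subj)
  if (length(ids) < 2L)
    stop("value error: cross-validation needs at least 2 subjects")
  lapply(ids, function(id) {
    testIdx <- which(subj == id & (includeFlippedTest | !flip))
    list(subject = id, trainIdx = which(subj != id), testIdx = testIdx)
  })
}

nppeReport <- function(perImage) {
  s <- if (nrow(perImage))
    list(mean = mean(perImage$nppe), sd = stats::sd(perImage$nppe))
  else list(mean = NA_real_, sd = NA_real_)
  byD <- if (nrow(perImage) && any(!is.na(perImage$distance))) {
    sp <- split(perImage$nppe, perImage$distance)
    data.frame(distance = as.numeric(names(sp)),
               mean = vapply(sp, mean, numeric(1)),
               sd = vapply(sp, stats::sd, numeric(1)),
               n = lengths(sp), row.names = NULL)
  } else data.frame(distance = numeric(), mean = numeric(), sd = numeric(),
                    n = integer())
  new("NPPEReport", perImage = perImage, summary = s, byDistance = byD)
}

#' Subject-wise cross-validated evaluation
#'
#' Trains one cascade per fold (each fold's seed derives from the master
#' seed) and scores that fold's held-out subject, concatenating per-image
#' NPPE across folds into an [NPPEReport-class] with overall and
#' per-distance summaries. Training sets are flip-augmented unless `flip =
#' FALSE`; test sets contain original images only by default.
#'
#' @param samples list of original (unflipped) [AnnotatedSample-class].
#' @param config a [csrConfig()] configuration.
#' @param flip augment each fold's training set with mirrored copies.
#' @param includeFlippedTest also score mirrored test copies.
#' @param perStage also record mean test NPPE after every cascade stage.
#' @param predictor optional override `function(model, sample) -> FaceShape`
#'   replacing [predictShape()] (e.g. an oracle for harness checks; when
#'   given, training is skipped and `model` is NULL).
#' @param verbose print fold progress.
#' @return list with `report` ([NPPEReport-class]), `models` (per-fold
#'   [CSRModel-class] or NULL), `perStage` (data.frame fold/stage/meanNPPE
#'   when requested), `ced` (the pooled CED curve).
#' @export
evaluateCV <- function(samples, config = csrConfig(), flip = TRUE,
                       includeFlippedTest = FALSE, perStage = FALSE,
                       predictor = NULL, verbose = FALSE) {
  if (!inherits(config, "csr_config")) config <- do.call(csrConfig, config)
  aug <- if (flip) augmentFlips(samples) else samples
  folds <- subjectKFold(aug, includeFlippedTest)
  rows <- list(); models <- list(); stageRows <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    model <- NULL
    if (is.null(predictor)) {
      cfgF <- config
      cfgF$seed <- deriveSeed(config$seed, 50L, f)
      if (verbose) message("fold ", f, "/", length(folds),
                           ": training on ", length(fold$trainIdx),
                           " images")
      model <- trainCSR(aug[fold$trainIdx], cfgF)
    }
    pred <- predictor %||% function(m, s) predictShape(m, s@image, s@bbox)
    errs <- numeric(length(fold$testIdx))
    for (j in seq_along(fold$testIdx)) {
      s <- aug[[fold$testIdx[j]]]
      errs[j] <- nppeSample(pred(model, s), s)
      if (perStage && !is.null(model)) {
        tr <- predictTrace(model, s@image, s@bbox)
        stageRows[[length(stageRows) + 1L]] <- data.frame(
          fold = f, stage = seq_along(tr) - 1L,
          nppe = vapply(tr, nppeSample, numeric(1), sample = s))
      }
    }
    rows[[f]] <- data.frame(
      id = fold$testIdx, nppe = errs,
      subject = vapply(aug[fold$testIdx], subjectId, character(1)),
      distance = vapply(aug[fold$testIdx], function(s) s@distance, numeric(1)),
      faceWidthPx = vapply(aug[fold$testIdx], pixelsPerFaceWidth, numeric(1)),
      fold = f)
    models[[f]] <- model
  }
  perImage <- do.call(rbind, rows)
  perStageDf <- if (length(stageRows)) {
    all <- do.call(rbind, stageRows)
    agg <- stats::aggregate(nppe ~ fold + stage, all, mean)
    names(agg)[3] <- "meanNPPE"
    agg[order(agg$fold, agg$stage), ]
  } else NULL
  list(report = nppeReport(perImage), models = models,
       perStage = perStageDf, ced = ced(perImage$nppe))
}

#' Prediction throughput (frames per second)
#'
#' Wall-clock throughput of [predictShape()] over in-memory samples; model
#' loading and dataset I/O are outside the timed region. Hardware-dependent
#' and reported for information only -- never a pass/fail quantity.
#'
#' @param model a trained [CSRModel-class].
#' @param samples list of [AnnotatedSample-class].
#' @param repetitions passes over the sample list.
#' @return list with `fps`, `elapsedSec`, `nPredictions` and `platform`.
#' @export
benchmarkFPS <- function(model, samples, repetitions = 3L) {
  if (!length(samples)) stop("value error: no samples to benchmark")
  n <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(repetitions)) {
    for (s in samples) {
      predictShape(model, s@image, s@bbox)
      n <- n + 1L
    }
  }
  el <- proc.time()[["elapsed"]] - t0
  list(fps = n / max(el, 1e-9), elapsedSec = el, nPredictions = n,
       platform = R.version$platform)
}
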