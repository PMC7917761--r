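## Gradient-boosted ensemble-of-regression-trees cascade.
##
## Residuals are boosted in a per-sample normalized frame: shape differences
## are divided by s_i = (bbox width + bbox height) / 2 before tree fitting and
## leaf updates are multiplied back by s_i on application, so one leaf vector
## transfers across camera distances (face sizes). The boosting objective --
## the summed squared difference between ground truth and current estimate --
## is unchanged up to that fixed per-sample weighting.

nInternalNodes <- function(depth) bitwShiftL(1L, depth) - 1L

# Draw candidate probe pairs: uniform when lambda == 0, otherwise weighted by
# exp(-lambda * distance between probes) via a precomputed pair CDF.
drawCandidatePairs <- function(P, n, pairCDF = NULL) {
  u <- sample.int(P, n, replace = TRUE)
  if (is.null(pairCDF)) {
    v <- sample.int(P - 1L, n, replace = TRUE)
    v <- v + (v >= u)
  } else {
    r <- stats::runif(n) * pairCDF[cbind(u, P)]
    v <- vapply(seq_len(n), function(i) {
      findInterval(r[i], pairCDF[u[i], ], left.open = TRUE) + 1L
    }, integer(1))
    v <- pmin(v, P)
  }
  list(u = u, v = v)
}

pairSelectionCDF <- function(positions, lambda) {
  if (lambda <= 0) return(NULL)
  d <- as.matrix(stats::dist(positions))
  w <- exp(-lambda * d)
  diag(w) <- 0
  t(apply(w, 1L, cumsum))
}

#' Fit one regression tree on pixel-difference features
#'
#' Greedy top-down fitting of a complete depth-F binary tree. At each node,
#' `nCandidates` random (u, v, theta) triples are scored by the squared-error
#' reduction of the residuals (equivalently, maximal between-child
#' sum-of-squares); the threshold of each candidate is drawn uniformly
#' between the observed min and max of that feature difference at the node.
#' Leaves store `shrinkage` times the mean residual of the samples reaching
#' them; empty leaves store zeros. Ties between candidates are broken by
#' first-seen order under the seeded stream, so fitting is fully
#' deterministic given `seed`.
#'
#' @param featureValues n x P matrix of probe intensities per sample.
#' @param residuals n x D matrix of regression targets (D = 2M).
#' @param depth tree depth F.
#' @param nCandidates candidate triples scored per split node.
#' @param shrinkage learning rate applied to the leaf vectors.
#' @param seed substream seed for candidate draws.
#' @param exhaustive if TRUE, ignore the random candidates and search all
#'   probe pairs x all midpoint thresholds (reference mode for small
#'   instances).
#' @param minLeaf minimum child size for a split to be admissible (1 = grow
#'   complete trees, empty leaves allowed).
#' @param pairCDF optional pair-selection CDF from the closeness prior.
#' @return a `csr_tree` list: `u`, `v`, `theta` per internal node, `leaves`
#'   (2^F x D, shrinkage applied), `leafIndex` (training-sample leaf
#'   assignment), `depth`.
#' @export
fitTree <- function(featureValues, residuals, depth = 4L, nCandidates = 400L,
                    shrinkage = 0.1, seed = 1L, exhaustive = FALSE,
                    minLeaf = 1L, pairCDF = NULL) {
  if (nrow(featureValues) < 1L) stop("value error: no samples")
  if (nrow(featureValues) != nrow(residuals))
    stop("dimension error: feature and residual row counts differ")
  if (depth < 1L) stop("config error: depth must be >= 1")
  P <- ncol(featureValues)
  nNodes <- nInternalNodes(depth)
  if (exhaustive) {
    cu <- cv <- matrix(1L, nNodes, 1L)
    cr <- matrix(0, nNodes, 1L)
  } else {
    cand <- withSeed(seed, {
      pairs <- drawCandidatePairs(P, nNodes * nCandidates, pairCDF)
      list(u = pairs$u, v = pairs$v,
           r = stats::runif(nNodes * nCandidates))
    })
    cu <- matrix(cand$u, nNodes, nCandidates, byrow = TRUE)
    cv <- matrix(cand$v, nNodes, nCandidates, byrow = TRUE)
    cr <- matrix(cand$r, nNodes, nCandidates, byrow = TRUE)
  }
  fit <- .fitTreeCpp(featureValues, t(residuals), as.integer(depth),
                     cu, cv, cr, exhaustive, as.integer(minLeaf))
  structure(list(u = fit$u, v = fit$v, theta = fit$theta,
                 leaves = fit$leaves * shrinkage,
                 leafIndex = fit$leafIndex, depth = as.integer(depth)),
            class = "csr_tree")
}

# Route one feature vector through a fitted tree; returns the leaf row.
treeLeafIndex <- function(tree, featVec) {
  nNodes <- nInternalNodes(tree$depth)
  node <- 1L
  while (node <= nNodes) {
    f <- featVec[tree$u[node]] - featVec[tree$v[node]]
    node <- 2L * node + (f > tree$theta[node])
  }
  node - nNodes
}

treePredict <- function(tree, featVec) {
  tree$leaves[treeLeafIndex(tree, featVec), ]
}

#' Fit one cascade stage by gradient boosting
#'
#' Probe features are extracted once per sample at the stage-entry shapes;
#' K trees are then fitted sequentially, each on the boosted residual
#' (ground truth minus current estimate, in the normalized frame), with the
#' current estimates updated by every tree's output. The training loss is
#' non-increasing over trees by construction.
#'
#' @param intensities list of intensity [ThermalImage-class]s.
#' @param gtMat,curMat n x 2M matrices of ground-truth and stage-entry shape
#'   vectors (image pixels).
#' @param scales per-sample normalization s_i = (bbox w + bbox h) / 2.
#' @param pool the stage [FeaturePool-class].
#' @param mean unit-frame mean [FaceShape-class].
#' @param config a [csrConfig()] list.
#' @param seed stage substream seed.
#' @return list with `stage` (pool + trees + nu), `shapes` (updated n x 2M
#'   matrix), `loss` (length K + 1 vector of normalized squared loss, entry
#'   1 = loss at stage entry).
#' @export
fitStage <- function(intensities, gtMat, curMat, scales, pool, mean, config,
                     seed = 1L) {
  n <- nrow(gtMat)
  if (n < 1L) stop("value error: empty training set")
  P <- length(pool@anchor)
  feat <- matrix(0, n, P)
  for (i in seq_len(n)) {
    pos <- warpPoints(pool, mean, fromShapeVector(curMat[i, ]))
    feat[i, ] <- extractFeatures(intensities[[i]], pos)
  }
  resid <- (gtMat - curMat) / scales
  pairCDF <- pairSelectionCDF(pool@offset + mean@coords[pool@anchor, ],
                              config$lambdaPrior)
  K <- config$K
  loss <- numeric(K + 1L)
  loss[1L] <- sum(resid^2)
  trees <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- fitTree(feat, resid, depth = config$F,
                  nCandidates = config$nCandidates,
                  shrinkage = config$shrinkage,
                  seed = deriveSeed(seed, 2L, k),
                  minLeaf = config$minLeaf, pairCDF = pairCDF)
    pred <- tr$leaves[tr$leafIndex, , drop = FALSE]
    resid <- resid - pred
    loss[k + 1L] <- sum(resid^2)
    tr$leafIndex <- NULL
    trees[[k]] <- tr
  }
  list(stage = list(pool = pool, trees = trees, nu = config$shrinkage),
       shapes = gtMat - resid * scales, loss = loss)
}

#' Train a cascaded shape regressor
#'
#' Computes the bbox-normalized mean shape, initializes every training image
#' from its bounding box, then for t = 1..T draws a fresh feature pool and
#' fits a boosted stage so that S(t) = S(t-1) + dS(t) with dS(t) predicted
#' from the image and the stage-entry shape. Per-stage mean training NPPE is
#' recorded in the model's `trainLog`.
#'
#' @param samples list of [AnnotatedSample-class] (typically flip-augmented).
#' @param config a [csrConfig()] configuration; defaults are the study
#'   settings T=10, F=4, K=500, P=400.
#' @param verbose print per-stage progress.
#' @return a trained [CSRModel-class].
#' @export
trainCSR <- function(samples, config = csrConfig(), verbose = FALSE) {
  if (!inherits(config, "csr_config")) config <- do.call(csrConfig, config)
  if (!length(samples)) stop("value error: empty training set")
  Ms <- vapply(samples, function(s) nLandmarks(s@shape), integer(1))
  if (length(unique(Ms)) != 1L)
    stop("dimension error: inconsistent landmark counts")
  M <- Ms[1]

  shapes <- lapply(samples, function(s) s@shape)
  bboxes <- lapply(samples, function(s) s@bbox)
  mean <- meanShape(shapes, bboxes)

  intens <- lapply(samples, function(s)
    normalizeToIntensity(s@image, config$normalization, config$fixedRange))
  gtMat <- t(vapply(shapes, asShapeVector, numeric(2L * M)))
  curMat <- t(vapply(bboxes, function(b) asShapeVector(initShape(b, mean)),
                     numeric(2L * M)))
  scales <- vapply(bboxes, function(b) (b@w + b@h) / 2, numeric(1))

  if (config$oversampleInits > 0L) {
    # extra initializations: another training face's normalized ground truth
    extra <- withSeed(deriveSeed(config$seed, 7L), {
      n0 <- length(samples)
      idx <- rep(seq_len(n0), config$oversampleInits)
      src <- vapply(idx, function(i) {
        j <- sample.int(n0, 1L)
        while (j == i && n0 > 1L) j <- sample.int(n0, 1L)
        j
      }, integer(1))
      list(idx = idx, src = src)
    })
    addCur <- t(vapply(seq_along(extra$idx), function(k) {
      i <- extra$idx[k]; j <- extra$src[k]
      asShapeVector(bboxDenormalize(
        bboxNormalize(shapes[[j]]@coords, bboxes[[j]]), bboxes[[i]]))
    }, numeric(2L * M)))
    intens <- c(intens, intens[extra$idx])
    gtMat <- rbind(gtMat, gtMat[extra$idx, , drop = FALSE])
    scales <- c(scales, scales[extra$idx])
    curMat <- rbind(curMat, addCur)
  }

  # ground-truth face extents for the training NPPE diagnostic
  exts <- t(vapply(seq_len(nrow(gtMat)), function(i) {
    cc <- fromShapeVector(gtMat[i, ])
    c(diff(range(cc[, 1])), diff(range(cc[, 2])))
  }, numeric(2)))
  meanTrainNPPE <- function(cur) {
    mean(vapply(seq_len(nrow(cur)), function(i)
      nppe(fromShapeVector(cur[i, ]), fromShapeVector(gtMat[i, ]),
           exts[i, 1], exts[i, 2]), numeric(1)))
  }

  stages <- vector("list", config$T)
  lossTrace <- vector("list", config$T)
  log <- data.frame(stage = 0L, trainNPPE = meanTrainNPPE(curMat),
                    loss = sum(((gtMat - curMat) / scales)^2))
  for (t in seq_len(config$T)) {
    pool <- sampleFeaturePool(mean, P = config$P, spread = config$spread,
                              seed = deriveSeed(config$seed, 1L, t),
                              stage = t)
    fit <- fitStage(intens, gtMat, curMat, scales, pool, mean, config,
                    seed = deriveSeed(config$seed, 3L, t))
    stages[[t]] <- fit$stage
    lossTrace[[t]] <- fit$loss
    curMat <- fit$shapes
    log <- rbind(log, data.frame(stage = t, trainNPPE = meanTrainNPPE(curMat),
                                 loss = fit$loss[length(fit$loss)]))
    if (verbose)
      message(sprintf("stage %d/%d: train NPPE %.4f", t, config$T,
                      log$trainNPPE[nrow(log)]))
  }
  new("CSRModel", meanShape = mean@coords, stages = stages, M = as.integer(M),
      config = unclass(config), trainLog = log, lossTrace = lossTrace)
}

#' Predict landmarks with a trained cascade
#'
#' Normalizes the image, initializes the mean shape from the bounding box and
#' applies the T stages; deterministic for a fixed model and input.
#' `predictTrace` additionally returns every intermediate estimate
#' S(0)..S(T); its last element equals the `predictShape` output exactly.
#'
#' @param model a trained [CSRModel-class].
#' @param img a [ThermalImage-class].
#' @param box the face [BBox-class].
#' @return `predictShape`: the final [FaceShape-class].
#' @export
predictShape <- function(model, img, box) {
  trace <- predictTrace(model, img, box)
  trace[[length(trace)]]
}

#' @rdname predictShape
#' @return `predictTrace`: list of T + 1 [FaceShape-class] estimates.
#' @export
predictTrace <- function(model, img, box) {
  cfg <- model@config
  intens <- if (identical(img@unit, "intensity")) img else
    normalizeToIntensity(img, cfg$normalization %||% "minmax",
                         cfg$fixedRange %||% c(20, 40))
  mean <- faceShape(model@meanShape)
  s <- (box@w + box@h) / 2
  cur <- initShape(box, mean)@coords
  trace <- vector("list", length(model@stages) + 1L)
  trace[[1L]] <- faceShape(cur)
  D <- 2L * model@M
  for (t in seq_along(model@stages)) {
    st <- model@stages[[t]]
    pos <- warpPoints(st$pool, mean, cur)
    feat <- extractFeatures(intens, pos)
    upd <- numeric(D)
    for (tr in st$trees) upd <- upd + treePredict(tr, feat)
    cur <- cur + s * fromShapeVector(upd)
    trace[[t + 1L]] <- faceShape(cur)
  }
  trace
}
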