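# Small in-code fixtures shared across test files.

# Compact synthetic study: few subjects, small frames, fast to render.
tinyStudy <- function(nSubjects = 2L, imagesPerSubject = 6L,
                      imageSize = c(200L, 160L), seed = 42L, ...) {
  generateStudy(protocolSpec(nSubjects = nSubjects,
                             imagesPerSubject = imagesPerSubject,
                             imageSize = imageSize, seed = seed, ...))
}

constImage <- function(value = 24, h = 3L, w = 3L) {
  thermalImage(matrix(value, h, w))
}

# A deterministic non-degenerate shape for geometry tests.
testShape <- function(M = 10L, seed = 7L) {
  set.seed(seed)
  faceShape(cbind(runif(M, 0, 100), runif(M, 0, 100)))
}

randomSimilarity <- function() {
  list(scale = runif(1, 0.3, 3), rotation = runif(1, -pi, pi),
       tx = runif(1, -50, 50), ty = runif(1, -50, 50))
}

# Independent brute-force regression-tree oracle: recursive exhaustive
# search over all probe pairs and all midpoint thresholds, minimizing the
# summed squared error of child means. Returns the achieved training SSE.
bruteForceTreeSSE <- function(feat, resid, depth) {
  sse <- function(rows) {
    if (!length(rows)) return(0)
    r <- resid[rows, , drop = FALSE]
    mu <- colMeans(r)
    sum(sweep(r, 2, mu)^2)
  }
  fitNode <- function(rows, d) {
    if (d == 0L || length(rows) < 2L) return(sse(rows))
    best <- NULL; bestScore <- Inf
    P <- ncol(feat)
    for (u in seq_len(P - 1L)) for (v in (u + 1L):P) {
      f <- feat[rows, u] - feat[rows, v]
      vals <- sort(unique(f))
      if (length(vals) < 2L) next
      for (k in seq_len(length(vals) - 1L)) {
        th <- (vals[k] + vals[k + 1L]) / 2
        left <- rows[f <= th]
        right <- rows[f > th]
        sc <- sse(left) + sse(right)
        if (sc < bestScore) {
          bestScore <- sc
          best <- list(left = left, right = right)
        }
      }
    }
    if (is.null(best)) return(sse(rows))
    fitNode(best$left, d - 1L) + fitNode(best$right, d - 1L)
  }
  fitNode(seq_len(nrow(feat)), depth)
}

# SSE actually achieved on the training set by a fitted (unshrunk) tree.
fittedTreeSSE <- function(tree, feat, resid, shrinkage) {
  leaves <- tree$leaves / shrinkage
  pred <- t(vapply(seq_len(nrow(feat)), function(i)
    leaves[thermalign:::treeLeafIndex(tree, feat[i, ]), ],
    numeric(ncol(resid))))
  sum((resid - pred)^2)
}
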