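## Shape-indexed two-pixel difference features: intensity normalization,
## per-stage probe pools in the mean-shape frame, similarity warping to the
## current shape estimate, and nearest-pixel extraction.

#' Normalize a thermal frame to [0, 1] intensity
#'
#' `"minmax"` maps the per-image min/max linearly onto 0..1 (a constant
#' image maps to all zeros); `"fixed"` maps a configured Celsius window
#' (default 20..40) with clipping. Both mappings are monotone
#' non-decreasing, so the two-pixel difference features built on them keep
#' their sign structure.
#'
#' @param img a [ThermalImage-class].
#' @param mode `"minmax"` or `"fixed"`.
#' @param fixedRange length-2 Celsius window for `"fixed"`.
#' @return a [ThermalImage-class] with `unit = "intensity"` and pixels in
#'   [0, 1]; normalization provenance in `meta`.
#' @export
normalizeToIntensity <- function(img, mode = c("minmax", "fixed"),
                                 fixedRange = c(20, 40)) {
  mode <- match.arg(mode)
  p <- img@pixels
  if (mode == "minmax") {
    lo <- min(p); hi <- max(p)
    v <- if (hi > lo) (p - lo) / (hi - lo) else p * 0
    prov <- list(normalization = "minmax", lo = lo, hi = hi)
  } else {
    lo <- fixedRange[1]; hi <- fixedRange[2]
    if (lo >= hi) stop("config error: fixed range must satisfy lo < hi")
    v <- pmin(pmax((p - lo) / (hi - lo), 0), 1)
    prov <- list(normalization = "fixed", lo = lo, hi = hi)
  }
  thermalImage(v, unit = "intensity", meta = c(img@meta, prov))
}

#' Draw a stage feature pool in the mean-shape frame
#'
#' Each of the P probes is a uniformly chosen anchor landmark plus an offset
#' drawn uniformly in the square [-spread, +spread]^2, both in mean-shape
#' reference units (the unit bbox frame). A fresh pool is drawn for every
#' cascade stage; draws are deterministic under a fixed seed.
#'
#' @param mean unit-frame mean [FaceShape-class].
#' @param P number of probes (study setting: 400).
#' @param spread half-width of the offset window, reference units.
#' @param seed integer seed for this pool's substream.
#' @param stage stage index stored with the pool.
#' @return a [FeaturePool-class].
#' @export
sampleFeaturePool <- function(mean, P = 400L, spread = 0.15, seed = 1L,
                              stage = 1L) {
  if (P < 2L) stop("config error: P must be >= 2")
  if (spread <= 0) stop("config error: spread must be > 0")
  M <- nLandmarks(mean)
  withSeed(seed, {
    anchor <- sample.int(M, P, replace = TRUE)
    offset <- matrix(stats::runif(2L * P, -spread, spread), ncol = 2L)
  })
  new("FeaturePool", anchor = as.integer(anchor), offset = offset,
      stage = as.integer(stage))
}

#' Warp pool probes to the current shape estimate
#'
#' The similarity transform from the mean shape to the current estimate is
#' fitted by [alignSimilarity()]; each probe then maps to
#' `current[anchor] + s * R %*% offset` -- the offset is rotated and scaled
#' but anchored at the probe's landmark in the current shape, which is what
#' makes the features pose-covariant.
#'
#' @param pool a [FeaturePool-class].
#' @param mean unit-frame mean [FaceShape-class].
#' @param current current shape estimate in image pixels.
#' @return P x 2 matrix of probe positions, image pixels.
#' @export
warpPoints <- function(pool, mean, current) {
  tf <- alignSimilarity(mean, current)
  R <- matrix(c(cos(tf$rotation), sin(tf$rotation),
                -sin(tf$rotation), cos(tf$rotation)), 2L, 2L)
  rot <- tf$scale * pool@offset %*% t(R)
  cur <- if (is(current, "FaceShape")) current@coords else current
  cur[pool@anchor, , drop = FALSE] + rot
}

#' Read probe intensities with nearest-pixel lookup
#'
#' Positions are rounded to the nearest pixel center and clamped to the
#' image border, so extraction is total even for extreme pose estimates.
#' Split nodes later threshold differences `value[u] - value[v]` of the
#' returned vector.
#'
#' @param img an intensity [ThermalImage-class] (pixels in [0, 1]).
#' @param positions n x 2 matrix of (x, y) probe positions from
#'   [warpPoints()].
#' @return numeric vector of n intensities in [0, 1].
#' @export
extractFeatures <- function(img, positions) {
  p <- img@pixels
  H <- nrow(p); W <- ncol(p)
  cx <- pmin(pmax(round(positions[, 1]), 0), W - 1L)
  cy <- pmin(pmax(round(positions[, 2]), 0), H - 1L)
  p[cbind(cy + 1L, cx + 1L)]
}
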