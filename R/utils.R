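#' Construct the core value objects
#'
#' Convenience constructors validating their arguments: `thermalImage()`,
#' `faceShape()`, `bBox()` and `annotatedSample()`.
#'
#' @param pixels numeric H x W matrix.
#' @param unit `"celsius"` or `"intensity"`.
#' @param meta named list of metadata.
#' @return the corresponding S4 object.
#' @export
thermalImage <- function(pixels, unit = "celsius", meta = list()) {
  new("ThermalImage", pixels = pixels, unit = unit, meta = meta)
}

#' @rdname thermalImage
#' @param coords numeric M x 2 matrix (or length-2M vector, x/y interleaved).
#' @export
faceShape <- function(coords) {
  if (is.null(dim(coords)))
    coords <- matrix(coords, ncol = 2L, byrow = TRUE)
  dimnames(coords) <- list(NULL, c("x", "y"))
  new("FaceShape", coords = coords)
}

#' @rdname thermalImage
#' @param x,y top-left corner (0-based pixels).
#' @param w,h box extent in pixels.
#' @export
bBox <- function(x, y, w, h) new("BBox", x = x, y = y, w = w, h = h)

#' @rdname thermalImage
#' @param image a [ThermalImage-class].
#' @param shape a [FaceShape-class].
#' @param bbox a [BBox-class].
#' @param subject subject id string.
#' @param distance camera distance (cm) or NA.
#' @param section recording-interval label.
#' @param flipped flip-provenance flag.
#' @export
annotatedSample <- function(image, shape, bbox, subject, distance = NA_real_,
                            section = "", flipped = FALSE) {
  new("AnnotatedSample", image = image, shape = shape, bbox = bbox,
      subject = as.character(subject), distance = as.numeric(distance),
      section = section, flipped = flipped)
}

## Shape <-> vector plumbing -------------------------------------------------

#' Convert between landmark matrices and interleaved shape vectors
#'
#' The regressor works on S = (x1, y1, ..., xM, yM); these helpers convert a
#' [FaceShape-class] (or raw M x 2 matrix) to that vector form and back.
#'
#' @param shape a FaceShape or M x 2 matrix.
#' @return `asShapeVector`: numeric vector of length 2M.
#' @export
asShapeVector <- function(shape) {
  m <- if (is(shape, "FaceShape")) shape@coords else shape
  as.numeric(t(m))
}

#' @rdname asShapeVector
#' @param v numeric vector of length 2M.
#' @return `fromShapeVector`: an M x 2 matrix.
#' @export
fromShapeVector <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

## Seed substreams -----------------------------------------------------------

# Deterministic integer mixing for named substreams: keeps every derived seed
# in [1, 2^31 - 2] and independent of evaluation order.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## Configuration -------------------------------------------------------------

#' Training configuration for the cascaded regressor
#'
#' Builds a validated configuration list. Defaults are the study settings:
#' T = 10 cascade stages, tree depth F = 4, K = 500 boosted trees per stage
#' and P = 400 shape-indexed probe pixels per stage pool. Unknown keys are
#' rejected.
#'
#' @param T number of cascade stages.
#' @param K number of boosted regression trees per stage.
#' @param F tree depth (a depth-F tree has 2^F leaves).
#' @param P probe pixels per stage feature pool.
#' @param shrinkage gradient-boosting learning rate nu in (0, 1].
#' @param spread half-width of the probe-offset window, in mean-shape
#'   reference units (the face bbox maps to the unit square).
#' @param nCandidates candidate (u, v, threshold) triples scored per split
#'   node.
#' @param lambdaPrior exponential closeness prior on probe-pair selection,
#'   weight exp(-lambda * ||u - v||); 0 gives the uniform pairing the study
#'   procedure states.
#' @param seed master seed; all stage/tree substreams derive from it.
#' @param normalization intensity normalization mode, `"minmax"` or `"fixed"`.
#' @param fixedRange the Celsius window for `"fixed"` normalization.
#' @param oversampleInits extra random initializations per training image
#'   (0 = the single mean-shape initialization the protocol states).
#' @param minLeaf minimum samples for a node to be split further (1 = grow
#'   complete depth-F trees, unsplit nodes pass through).
#' @return a named list of class `csr_config`.
#' @export
csrConfig <- function(T = 10L, K = 500L, F = 4L, P = 400L, shrinkage = 0.1,
                      spread = 0.15, nCandidates = 400L, lambdaPrior = 0,
                      seed = 1L, normalization = c("minmax", "fixed"),
                      fixedRange = c(20, 40), oversampleInits = 0L,
                      minLeaf = 1L) {
  # unknown keys are rejected by R's argument matching itself
  normalization <- match.arg(normalization)
  cfg <- list(T = as.integer(T), K = as.integer(K), F = as.integer(F),
              P = as.integer(P), shrinkage = shrinkage, spread = spread,
              nCandidates = as.integer(nCandidates),
              lambdaPrior = lambdaPrior, seed = as.integer(seed),
              normalization = normalization, fixedRange = fixedRange,
              oversampleInits = as.integer(oversampleInits),
              minLeaf = as.integer(minLeaf))
  if (cfg$T < 1L) stop("config error: T must be >= 1")
  if (cfg$K < 1L) stop("config error: K must be >= 1")
  if (cfg$F < 1L) stop("config error: tree depth F must be >= 1")
  if (cfg$P < 2L) stop("config error: P must be >= 2")
  if (cfg$shrinkage <= 0 || cfg$shrinkage > 1)
    stop("config error: shrinkage must be in (0, 1]")
  if (cfg$spread <= 0) stop("config error: spread must be > 0")
  if (cfg$nCandidates < 1L) stop("config error: nCandidates must be >= 1")
  if (cfg$normalization == "fixed" && cfg$fixedRange[1] >= cfg$fixedRange[2])
    stop("config error: fixedRange must satisfy lo < hi")
  class(cfg) <- "csr_config"
  cfg
}
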