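#' @import methods
NULL

#' ThermalImage: a single thermal infrared frame
#'
#' A 2-D matrix of pixel values, either calibrated surface temperature in
#' degrees Celsius (`unit = "celsius"`) or raw/display intensity
#' (`unit = "intensity"`). Rows are image rows (y), columns are image columns
#' (x); the package-wide coordinate convention is 0-based with x = column
#' index and y = row index, pixel centers at integers.
#'
#' @slot pixels numeric matrix, H x W.
#' @slot unit either `"celsius"` or `"intensity"`.
#' @slot meta named list of free-form acquisition metadata (subject id,
#'   camera distance, head-direction label, emissivity, TIFF scale/offset ...).
#' @export
setClass("ThermalImage",
  representation(pixels = "matrix", unit = "character", meta = "list"),
  prototype(pixels = matrix(0, 1, 1), unit = "celsius", meta = list())
)

setValidity("ThermalImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (any(!is.finite(p))) return("all pixel values must be finite")
  if (!object@unit %in% c("celsius", "intensity"))
    return("unit must be 'celsius' or 'intensity'")
  if (object@unit == "celsius" && (min(p) < -20 || max(p) > 60))
    return("celsius pixels outside the sanity range [-20, 60]")
  TRUE
})

#' FaceShape: an ordered set of facial landmarks
#'
#' Wraps an M x 2 coordinate matrix (columns x, y, image pixels, 0-based).
#' The vectorized form S = (x1, y1, ..., xM, yM) used by the regressor is
#' obtained with [asShapeVector()].
#'
#' @slot coords numeric M x 2 matrix of landmark positions.
#' @export
setClass("FaceShape", representation(coords = "matrix"))

setValidity("FaceShape", function(object) {
  cc <- object@coords
  if (!is.numeric(cc) || ncol(cc) != 2L) return("coords must be an M x 2 matrix")
  if (nrow(cc) < 2L) return("a shape needs at least 2 landmarks")
  if (any(!is.finite(cc))) return("all landmark coordinates must be finite")
  TRUE
})

#' BBox: a face bounding box
#'
#' @slot x,y top-left corner, pixels (0-based).
#' @slot w,h extent in pixels, strictly positive.
#' @export
setClass("BBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric"))

setValidity("BBox", function(object) {
  v <- c(object@x, object@y, object@w, object@h)
  if (length(v) != 4L || any(!is.finite(v))) return("x, y, w, h must be finite scalars")
  if (object@w <= 0 || object@h <= 0) return("bounding box must have w > 0 and h > 0")
  TRUE
})

#' AnnotatedSample: one image with its ground-truth annotation
#'
#' @slot image a [ThermalImage-class].
#' @slot shape ground-truth [FaceShape-class].
#' @slot bbox face [BBox-class].
#' @slot subject subject identifier (flip copies keep the original id so
#'   subject-wise cross-validation cannot leak a subject across folds).
#' @slot distance camera distance label in cm (60, 90 or 120; NA if unknown).
#' @slot section recording-interval label ("Small", "Large", "Random", or "").
#' @slot flipped TRUE for a mirror-augmented copy.
#' @export
setClass("AnnotatedSample",
  representation(image = "ThermalImage", shape = "FaceShape", bbox = "BBox",
    subject = "character", distance = "numeric", section = "character",
    flipped = "logical"),
  prototype(subject = "?", distance = NA_real_, section = "", flipped = FALSE)
)

setValidity("AnnotatedSample", function(object) {
  b <- object@bbox
  img <- object@image
  W <- ncol(img@pixels); H <- nrow(img@pixels)
  # bbox must overlap the image area
  if (b@x >= W || b@y >= H || b@x + b@w <= 0 || b@y + b@h <= 0)
    return("bounding box does not overlap the image")
  if (!nzchar(object@subject)) return("subject id must be non-empty")
  TRUE
})

#' FeaturePool: shape-indexed probe points for one cascade stage
#'
#' Each probe is an anchor landmark index plus an (dx, dy) offset expressed in
#' the mean-shape reference frame; probes are warped to the current shape
#' estimate by a similarity transform before intensities are read.
#'
#' @slot anchor integer vector of landmark indices (1-based, length P).
#' @slot offset numeric P x 2 matrix of offsets in mean-shape units.
#' @slot stage cascade stage index this pool was drawn for.
#' @export
setClass("FeaturePool",
  representation(anchor = "integer", offset = "matrix", stage = "integer"))

setValidity("FeaturePool", function(object) {
  if (length(object@anchor) != nrow(object@offset))
    return("anchor and offset lengths differ")
  if (length(object@anchor) < 2L) return("a pool needs at least 2 probes")
  if (any(object@anchor < 1L)) return("anchor indices must be >= 1")
  if (any(!is.finite(object@offset))) return("offsets must be finite")
  TRUE
})

#' CSRModel: a trained cascaded shape regressor
#'
#' The model holds the bbox-normalized mean shape used for initialization and
#' T cascade stages; each stage is a feature pool plus K gradient-boosted
#' regression trees of depth F whose leaves store shape-update vectors.
#'
#' @slot meanShape M x 2 mean landmark layout in the unit bbox frame.
#' @slot stages list of stages; each a list with elements `pool`
#'   ([FeaturePool-class]), `trees` (list of fitted trees) and `nu`
#'   (shrinkage).
#' @slot M landmark count.
#' @slot config the training configuration snapshot (see [csrConfig()]).
#' @slot trainLog data.frame of per-stage training diagnostics (mean training
#'   NPPE after each stage).
#' @slot lossTrace list of length-T numeric vectors: the normalized-frame
#'   training loss after each boosted tree within each stage (entry 1 =
#'   stage-entry loss).
#' @export
setClass("CSRModel",
  representation(meanShape = "matrix", stages = "list", M = "integer",
    config = "list", trainLog = "data.frame", lossTrace = "list"))

setValidity("CSRModel", function(object) {
  if (nrow(object@meanShape) != object@M) return("meanShape rows must equal M")
  for (st in object@stages) {
    if (!all(c("pool", "trees", "nu") %in% names(st)))
      return("each stage needs pool, trees and nu")
    if (st$nu <= 0 || st$nu > 1) return("shrinkage must be in (0, 1]")
  }
  TRUE
})

#' NPPEReport: per-image normalized point-to-point errors with summaries
#'
#' @slot perImage data.frame with columns `id`, `nppe`, `subject`, `distance`,
#'   `faceWidthPx` (pixels per face width), and `fold` when produced by
#'   cross-validation.
#' @slot summary named list with elements `mean` and `sd` over all rows.
#' @slot byDistance data.frame with per-distance mean and sd.
#' @export
setClass("NPPEReport",
  representation(perImage = "data.frame", summary = "list",
    byDistance = "data.frame"))

setValidity("NPPEReport", function(object) {
  pi <- object@perImage
  need <- c("id", "nppe", "subject", "distance", "faceWidthPx")
  if (!all(need %in% names(pi)))
    return(paste("perImage must have columns", paste(need, collapse = ", ")))
  if (nrow(pi) > 0 && any(pi$nppe < 0)) return("NPPE values must be >= 0")
  if (nrow(pi) > 0 &&
      abs(object@summary$mean - mean(pi$nppe)) > 1e-8)
    return("summary mean inconsistent with per-image values")
  TRUE
})
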