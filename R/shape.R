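## Shape arithmetic: bbox-normalized mean shape, initialization, similarity
## alignment, flip augmentation.

bboxNormalize <- function(coords, bb) {
  cbind((coords[, 1] - bb@x) / bb@w, (coords[, 2] - bb@y) / bb@h)
}

bboxDenormalize <- function(coords, bb) {
  cbind(coords[, 1] * bb@w + bb@x, coords[, 2] * bb@h + bb@y)
}

#' Mean shape over a training set, in the unit bbox frame
#'
#' Each shape is mapped into the unit reference frame (translate/scale so its
#' face bounding box becomes the unit square) and coordinates are averaged
#' per landmark. The result is the cascade's initial-shape template: scaled
#' back out by a test bbox it gives S0.
#'
#' @param shapes list of [FaceShape-class], all with the same landmark count.
#' @param bboxes list of matching [BBox-class], one per shape.
#' @return a [FaceShape-class] in the unit frame.
#' @export
meanShape <- function(shapes, bboxes) {
  if (!length(shapes)) stop("value error: no shapes to average")
  if (length(shapes) != length(bboxes))
    stop("value error: shapes and bboxes differ in length")
  Ms <- vapply(shapes, nLandmarks, integer(1))
  if (length(unique(Ms)) != 1L)
    stop("dimension error: shapes have mixed landmark counts")
  acc <- matrix(0, Ms[1], 2L)
  for (i in seq_along(shapes))
    acc <- acc + bboxNormalize(shapes[[i]]@coords, bboxes[[i]])
  faceShape(acc / length(shapes))
}

#' Initial shape from a bounding box
#'
#' Places the unit-frame mean shape into a face box: S0 = mean scaled by
#' (w, h) and translated by (x, y). Deterministic and affine-equivariant in
#' the box.
#'
#' @param box a [BBox-class].
#' @param mean unit-frame mean [FaceShape-class].
#' @return a [FaceShape-class] in image pixels.
#' @export
initShape <- function(box, mean) {
  validObject(box)
  faceShape(bboxDenormalize(mean@coords, box))
}

#' Least-squares similarity alignment of two shapes
#'
#' Closed-form (Umeyama-style) fit of the scale/rotation/translation
#' minimizing sum ||T(src_i) - dst_i||^2, with no reflection component.
#'
#' @param src,dst [FaceShape-class] objects (or M x 2 matrices) with the same
#'   landmark count, M >= 2.
#' @return a list with elements `scale`, `rotation` (radians), `tx`, `ty`.
#' @export
alignSimilarity <- function(src, dst) {
  a <- if (is(src, "FaceShape")) src@coords else src
  b <- if (is(dst, "FaceShape")) dst@coords else dst
  if (nrow(a) != nrow(b)) stop("dimension error: landmark counts differ")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  denom <- sum(A * A)
  if (denom < 1e-24)
    stop("degenerate-configuration error: source points are coincident")
  p <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2]) / denom
  q <- sum(A[, 1] * B[, 2] - A[, 2] * B[, 1]) / denom
  s <- sqrt(p^2 + q^2)
  th <- atan2(q, p)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t <- cb - s * as.numeric(R %*% ca)
  list(scale = s, rotation = th, tx = unname(t[1]), ty = unname(t[2]))
}

#' Apply or invert a similarity transform
#'
#' @param tf transform list from [alignSimilarity()].
#' @param pts n x 2 coordinate matrix.
#' @return `applyTransform`: the transformed n x 2 matrix.
#' @export
applyTransform <- function(tf, pts) {
  R <- matrix(c(cos(tf$rotation), sin(tf$rotation),
                -sin(tf$rotation), cos(tf$rotation)), 2L, 2L)
  sweep(tf$scale * pts %*% t(R), 2L, c(tf$tx, tf$ty), "+")
}

#' @rdname applyTransform
#' @return `invertTransform`: the inverse transform list.
#' @export
invertTransform <- function(tf) {
  s <- 1 / tf$scale; th <- -tf$rotation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t <- -s * as.numeric(R %*% c(tf$tx, tf$ty))
  list(scale = s, rotation = th, tx = t[1], ty = t[2])
}

## Flip augmentation ---------------------------------------------------------

#' Left/right mirror map for the standard 68-point annotation scheme
#'
#' Returns the involutive permutation pairing left and right landmarks: jaw
#' 1<->17 ..., brows 18<->27 ..., eyes 37<->46 ..., outer/inner lips; the ten
#' midline landmarks (chin, nose bridge and tip, under-nose center, lip
#' centers) are fixed points. Indices here are 1-based.
#'
#' @return integer vector of length 68; `perm[perm[i]] == i` for all i.
#' @export
defaultMirrorMap68 <- function() {
  p <- integer(68)
  swap <- function(i, j) { p[i + 1L] <<- j + 1L; p[j + 1L] <<- i + 1L }
  keep <- function(i) p[i + 1L] <<- i + 1L
  for (i in 0:16) p[i + 1L] <- 16L - i + 1L          # jaw (8 fixed)
  for (k in 0:4) swap(17 + k, 26 - k)                # brows
  for (i in 27:30) keep(i)                           # nose bridge + tip
  swap(31, 35); swap(32, 34); keep(33)               # nostril base
  swap(36, 45); swap(37, 44); swap(38, 43); swap(39, 42)  # eye tops
  swap(40, 47); swap(41, 46)                         # eye bottoms
  swap(48, 54); swap(49, 53); swap(50, 52); keep(51) # outer upper lip
  swap(55, 59); swap(56, 58); keep(57)               # outer lower lip
  swap(60, 64); swap(61, 63); keep(62)               # inner upper lip
  swap(65, 67); keep(66)                             # inner lower lip
  as.integer(p)
}

#' Horizontal flip augmentation with landmark reindexing
#'
#' Mirrors the image about its vertical axis (x -> W - 1 - x under the
#' pixel-center convention, so flipping twice is exact), reindexes landmarks
#' by the left/right mirror permutation, mirrors the bounding box, and keeps
#' subject/condition labels so subject-wise cross-validation stays leak-free.
#'
#' @param sample an [AnnotatedSample-class].
#' @param mirror involutive permutation of 1..M (default:
#'   [defaultMirrorMap68()] when M == 68).
#' @return the mirrored [AnnotatedSample-class], flip-provenance toggled.
#' @export
flipSample <- function(sample, mirror = NULL) {
  M <- nLandmarks(sample@shape)
  if (is.null(mirror)) {
    if (M != 68L) stop("no default mirror map for M = ", M)
    mirror <- defaultMirrorMap68()
  }
  if (length(mirror) != M) stop("validation error: mirror map length != M")
  mirror <- as.integer(mirror)
  if (!identical(mirror[mirror], seq_len(M)))
    stop("validation error: mirror map is not an involution")
  img <- sample@image
  W <- ncol(img@pixels)
  fImg <- thermalImage(img@pixels[, W:1, drop = FALSE], unit = img@unit,
                       meta = img@meta)
  cc <- sample@shape@coords
  fcc <- cbind(W - 1 - cc[, 1], cc[, 2])[mirror, , drop = FALSE]
  bb <- sample@bbox
  fbb <- bBox(W - bb@x - bb@w, bb@y, bb@w, bb@h)
  annotatedSample(fImg, faceShape(fcc), fbb, subject = sample@subject,
                  distance = sample@distance, section = sample@section,
                  flipped = !sample@flipped)
}

#' Augment a dataset with mirrored copies
#'
#' @param samples list of [AnnotatedSample-class].
#' @param mirror mirror permutation (default 68-point map).
#' @return list of length `2 * length(samples)`: originals then flips.
#' @export
augmentFlips <- function(samples, mirror = NULL) {
  c(samples, lapply(samples, flipSample, mirror = mirror))
}
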