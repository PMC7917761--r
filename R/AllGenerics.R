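#' Accessors for thermalign classes
#'
#' Small accessor generics in the Bioconductor style: `pixels()` returns the
#' raw matrix of a [ThermalImage-class], `coords()` the M x 2 landmark matrix
#' of a [FaceShape-class], `nLandmarks()` its point count, `imageUnit()` the
#' pixel unit, `bbox()` / `subjectId()` the annotation slots of an
#' [AnnotatedSample-class], and `perImageErrors()` the per-image table of an
#' [NPPEReport-class].
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ThermalImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("imageUnit", function(x) standardGeneric("imageUnit"))
#' @rdname accessors
#' @export
setMethod("imageUnit", "ThermalImage", function(x) x@unit)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "FaceShape", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))
#' @rdname accessors
#' @export
setMethod("nLandmarks", "FaceShape", function(x) nrow(x@coords))
#' @rdname accessors
#' @export
setMethod("nLandmarks", "CSRModel", function(x) x@M)

#' @rdname accessors
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))
#' @rdname accessors
#' @export
setMethod("bbox", "AnnotatedSample", function(x) x@bbox)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "AnnotatedSample", function(x) x@subject)

#' @rdname accessors
#' @export
setGeneric("perImageErrors", function(x) standardGeneric("perImageErrors"))
#' @rdname accessors
#' @export
setMethod("perImageErrors", "NPPEReport", function(x) x@perImage)

#' @export
setMethod("show", "ThermalImage", function(object) {
  p <- object@pixels
  cat(sprintf("ThermalImage %d x %d [%s], range [%.3f, %.3f]\n",
    nrow(p), ncol(p), object@unit, min(p), max(p)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' @export
setMethod("show", "FaceShape", function(object) {
  cc <- object@coords
  cat(sprintf("FaceShape with %d landmarks; x in [%.2f, %.2f], y in [%.2f, %.2f]\n",
    nrow(cc), min(cc[, 1]), max(cc[, 1]), min(cc[, 2]), max(cc[, 2])))
})

#' @export
setMethod("show", "BBox", function(object) {
  cat(sprintf("BBox x=%.1f y=%.1f w=%.1f h=%.1f\n",
    object@x, object@y, object@w, object@h))
})

#' @export
setMethod("show", "AnnotatedSample", function(object) {
  cat(sprintf("AnnotatedSample subject=%s distance=%s section=%s%s\n",
    object@subject,
    ifelse(is.na(object@distance), "?", paste0(object@distance, "cm")),
    object@section, if (object@flipped) " (flipped)" else ""))
  show(object@image)
  show(object@shape)
})

#' @export
setMethod("show", "CSRModel", function(object) {
  cfg <- object@config
  cat(sprintf("CSRModel: %d landmarks, T=%d stages, K=%d trees/stage, depth F=%d, P=%d probes\n",
    object@M, length(object@stages),
    if (length(object@stages)) length(object@stages[[1]]$trees) else 0L,
    cfg$F %||% NA_integer_, cfg$P %||% NA_integer_))
  if (nrow(object@trainLog))
    cat(sprintf("  final mean training NPPE: %.4f\n",
      object@trainLog$trainNPPE[nrow(object@trainLog)]))
})

#' @export
setMethod("show", "NPPEReport", function(object) {
  cat(sprintf("NPPEReport over %d images: mean NPPE %.4f (sd %.4f)\n",
    nrow(object@perImage), object@summary$mean, object@summary$sd))
  if (nrow(object@byDistance)) {
    for (i in seq_len(nrow(object@byDistance)))
      cat(sprintf("  %3s cm: %.4f +/- %.4f (n=%d)\n",
        as.character(object@byDistance$distance[i]),
        object@byDistance$mean[i], object@byDistance$sd[i],
        object@byDistance$n[i]))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
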