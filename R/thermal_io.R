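## I/O for thermal frames, pts landmark files, manifests and models.
##
## Coordinate convention everywhere: 0-based, x = column, y = row, pixel
## centers at integers. pts files on disk use the iBUG dialect's 1-based
## origin; 1 is subtracted on read and added back on write.

formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", tif = "tiff16", tiff = "tiff16", png = "png8",
    stop("cannot infer image format from extension '", ext, "'"))
}

#' Read and write thermal infrared frames
#'
#' Three carriers are supported: plain-matrix CSV (rows of comma-separated
#' temperatures in degrees Celsius), 16-bit grayscale TIFF storing
#' `round((celsius - offset) / scale)` counts (default scale 0.01 degC/count,
#' offset 0 degC -- an explicit linear map, since raw radiometric formats
#' vary), and 8-bit grayscale PNG for pre-normalized intensity input.
#'
#' @param path file path.
#' @param format `"csv"`, `"tiff16"` or `"png8"`; inferred from the extension
#'   when omitted.
#' @param scale,offset linear calibration of the tiff16 carrier
#'   (celsius = raw * scale + offset).
#' @return `readThermalImage`: a [ThermalImage-class].
#' @export
readThermalImage <- function(path, format = NULL, scale = 0.01, offset = 0) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  format <- format %||% formatFromPath(path)
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("I/O error: empty CSV image: ", path)
    rows <- strsplit(lines, ",", fixed = TRUE)
    wid <- lengths(rows)
    if (length(unique(wid)) != 1L)
      stop("format error: ragged CSV rows in ", path,
           " (row widths ", paste(unique(wid), collapse = "/"), ")")
    m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                nrow = length(rows), byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("validation error: non-numeric/NaN cell at row ", bad[1],
           ", col ", bad[2], " in ", path)
    }
    thermalImage(m, unit = "celsius", meta = list(source = path))
  } else if (format == "tiff16") {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stop("I/O error reading ", path, ": ",
                                             conditionMessage(e)))
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    thermalImage(raw * scale + offset, unit = "celsius",
                 meta = list(source = path, scale = scale, offset = offset))
  } else if (format == "png8") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop("I/O error reading ", path, ": ",
                                             conditionMessage(e)))
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    thermalImage(round(raw * 255), unit = "intensity",
                 meta = list(source = path))
  } else stop("unknown image format: ", format)
}

#' @rdname readThermalImage
#' @param img a [ThermalImage-class].
#' @param digits decimal places kept by the CSV writer.
#' @return `writeThermalImage`: the path, invisibly.
#' @export
writeThermalImage <- function(img, path, format = NULL, scale = 0.01,
                              offset = 0, digits = 6L) {
  stopifnot(is(img, "ThermalImage"))
  format <- format %||% formatFromPath(path)
  p <- img@pixels
  if (format == "csv") {
    txt <- apply(p, 1L, function(r)
      paste(formatC(r, digits = digits, format = "f"), collapse = ","))
    writeLines(txt, path)
  } else if (format == "tiff16") {
    counts <- round((p - offset) / scale)
    if (min(counts) < 0 || max(counts) > 65535)
      stop("value error: temperatures not representable with scale=", scale,
           ", offset=", offset)
    tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (format == "png8") {
    v <- p
    if (img@unit == "intensity") v <- v / 255
    else stop("png8 carries intensity images; normalize first")
    png::writePNG(pmin(pmax(v, 0), 1), path)
  } else stop("unknown image format: ", format)
  invisible(path)
}

## pts landmark files --------------------------------------------------------

#' Read and write 68-point landmark annotations (iBUG pts format)
#'
#' The text format is `version: 1` / `n_points: <M>` / `{` / one `x y` line
#' per landmark / `}`. On disk coordinates are 1-based (the iBUG dialect);
#' in memory they follow the package's 0-based pixel-center convention.
#'
#' @param path pts file path.
#' @return `readLandmarks`: a [FaceShape-class] with the declared number of
#'   points.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  npLine <- grep("^n_points:", lines, value = TRUE)
  if (length(npLine) != 1L) stop("format error: missing n_points header in ", path)
  n <- suppressWarnings(as.integer(sub("^n_points:\\s*", "", npLine)))
  if (is.na(n) || n < 1L) stop("format error: bad n_points in ", path)
  open <- which(lines == "{"); close <- which(lines == "}")
  if (length(open) != 1L || length(close) != 1L || close < open)
    stop("format error: missing { } block in ", path)
  body <- lines[(open + 1L):(close - 1L)]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("format error: header declares ", n, " points but file has ",
         length(body), " coordinate lines")
  toks <- strsplit(body, "\\s+")
  if (any(lengths(toks) != 2L))
    stop("format error: coordinate lines must be 'x y' pairs")
  xy <- suppressWarnings(matrix(as.numeric(unlist(toks)), ncol = 2L,
                                byrow = TRUE))
  if (anyNA(xy)) stop("format error: non-numeric coordinate token in ", path)
  faceShape(xy - 1)   # 1-based on disk -> 0-based in memory
}

#' @rdname readLandmarks
#' @param shape a [FaceShape-class].
#' @return `writeLandmarks`: the path, invisibly.
#' @export
writeLandmarks <- function(shape, path) {
  stopifnot(is(shape, "FaceShape"))
  cc <- shape@coords + 1   # 0-based in memory -> 1-based on disk
  lines <- c("version: 1",
             sprintf("n_points: %d", nrow(cc)),
             "{",
             sprintf("%.6f %.6f", cc[, 1], cc[, 2]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

## Manifests and datasets ----------------------------------------------------

#' Read, write and load dataset manifests
#'
#' A manifest is a CSV with columns `image, pts, bx, by, bw, bh, subject,
#' distance, section` describing one annotated frame per row. Relative paths
#' resolve against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return `readManifest`: a data.frame of records.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("I/O error: manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "pts", "bx", "by", "bw", "bh", "subject", "distance",
            "section")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: manifest missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(!nzchar(df$subject))) stop("validation error: empty subject id")
    if (any(df$bw <= 0 | df$bh <= 0))
      stop("validation error: bounding boxes must have bw > 0 and bh > 0")
  }
  attr(df, "dir") <- dirname(path)
  df
}

#' @rdname readManifest
#' @param manifest data.frame of manifest records.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readManifest
#' @param tiffScale,tiffOffset calibration forwarded to [readThermalImage()]
#'   for tiff16 records.
#' @return `loadDataset`: a list of [AnnotatedSample-class], one per record,
#'   in manifest order.
#' @export
loadDataset <- function(manifest, tiffScale = 0.01, tiffOffset = 0) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    out[[i]] <- tryCatch({
      img <- readThermalImage(resolve(rec$image), scale = tiffScale,
                              offset = tiffOffset)
      shp <- readLandmarks(resolve(rec$pts))
      annotatedSample(img, shp, bBox(rec$bx, rec$by, rec$bw, rec$bh),
                      subject = rec$subject, distance = rec$distance,
                      section = rec$section)
    }, error = function(e)
      stop("manifest record ", i, " (", rec$image, "): ",
           conditionMessage(e), call. = FALSE))
  }
  out
}

## Model serialization -------------------------------------------------------

MODEL_FORMAT <- "thermalign-csr"
MODEL_VERSION <- 1L

#' Save and load trained cascade models
#'
#' The archive is a single self-describing file carrying a format tag and a
#' format-version field; doubles round-trip bitwise, so a reloaded model's
#' predictions are identical to the original's.
#'
#' @param model a [CSRModel-class].
#' @param path destination file.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CSRModel"))
  payload <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
                  meanShape = model@meanShape, stages = model@stages,
                  M = model@M, config = model@config,
                  trainLog = model@trainLog, lossTrace = model@lossTrace)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModel
#' @return `loadModel`: the reconstructed [CSRModel-class].
#' @export
loadModel <- function(path) {
  payload <- tryCatch(readRDS(path),
    error = function(e) stop("I/O error: cannot read model file ", path, ": ",
                             conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, MODEL_FORMAT))
    stop("incompatibility error: not a ", MODEL_FORMAT, " archive: ", path)
  if (!identical(payload$version, MODEL_VERSION))
    stop("incompatibility error: model format version ", payload$version,
         " != supported version ", MODEL_VERSION)
  new("CSRModel", meanShape = payload$meanShape, stages = payload$stages,
      M = payload$M, config = payload$config, trainLog = payload$trainLog,
      lossTrace = payload$lossTrace %||% list())
}
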