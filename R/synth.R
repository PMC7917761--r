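## Synthetic thermal-face study generator.
##
## Emulates a 7-subject acquisition protocol: three camera distances (60, 90,
## 120 cm, giving mean face widths of about 184, 126 and 97 px in a 640x480
## frame), three recording intervals per distance (Small and Large cycling
## nine head directions at 20 and 45 degree amplitude, Random drawing free
## pose and expression jitter), smooth facial temperature fields calibrated
## per subject, and truncated Gaussian sensor noise. Landmarks are
## transformed together with the rendering, so every image carries exact
## ground truth.

#' Canonical 68-point face template
#'
#' A fixed, bilaterally symmetric landmark layout in the unit frame (x, y in
#' [0, 1], y down): 17 jaw points, two 5-point brows, 9 nose points, two
#' 6-point eyes and a 20-point mouth. Applying the left/right mirror map
#' together with x -> 1 - x maps the template onto itself.
#'
#' @return a [FaceShape-class] in the unit frame; constant across calls.
#' @export
canonicalTemplate68 <- function() {
  phi <- pi * (0:16) / 16
  jaw <- cbind(0.5 - 0.46 * cos(phi), 0.30 + 0.58 * sin(phi))
  browR <- cbind(c(0.13, 0.20, 0.27, 0.335, 0.40),
                 c(0.260, 0.235, 0.225, 0.230, 0.245))
  browL <- cbind(c(0.60, 0.665, 0.73, 0.80, 0.87),
                 c(0.245, 0.230, 0.225, 0.235, 0.260))
  bridge <- cbind(rep(0.5, 4), c(0.30, 0.37, 0.44, 0.51))
  nostril <- cbind(c(0.42, 0.46, 0.50, 0.54, 0.58),
                   c(0.575, 0.585, 0.595, 0.585, 0.575))
  eyeR <- cbind(c(0.18, 0.245, 0.315, 0.38, 0.315, 0.245),
                c(0.320, 0.300, 0.300, 0.320, 0.345, 0.345))
  eyeL <- cbind(c(0.62, 0.685, 0.755, 0.82, 0.755, 0.685),
                c(0.320, 0.300, 0.300, 0.320, 0.345, 0.345))
  mouthOuter <- cbind(
    c(0.34, 0.405, 0.46, 0.50, 0.54, 0.595, 0.66, 0.60, 0.545, 0.50, 0.455, 0.40),
    c(0.745, 0.715, 0.700, 0.705, 0.700, 0.715, 0.745, 0.785, 0.810, 0.815, 0.810, 0.785))
  mouthInner <- cbind(
    c(0.38, 0.46, 0.50, 0.54, 0.62, 0.545, 0.50, 0.455),
    c(0.745, 0.735, 0.740, 0.735, 0.745, 0.765, 0.770, 0.765))
  cc <- rbind(jaw, browR, browL, bridge, nostril, eyeR, eyeL,
              mouthOuter, mouthInner)
  # enforce exact bilateral symmetry: average with the mirrored layout
  perm <- defaultMirrorMap68()
  mir <- cbind(1 - cc[, 1], cc[, 2])[perm, , drop = FALSE]
  faceShape((cc + mir) / 2)
}

# Facial skin temperature statistics of the seven study subjects (degC):
# per-subject minimum, maximum and mean over the face, plus ambient.
studySubjectTemperatures <- function() {
  data.frame(
    subject = c("S1", "S2", "S3", "S4", "S5", "S6", "S7"),
    tMin = c(30.64, 29.23, 29.99, 30.81, 31.42, 30.32, 31.20),
    tMax = c(34.27, 33.76, 33.67, 34.13, 34.18, 34.05, 34.15),
    tMean = c(32.50, 31.89, 31.85, 32.64, 32.98, 32.27, 32.80),
    ambient = c(24.42, 24.38, 24.46, 24.02, 24.33, 24.44, 24.11))
}

#' Acquisition-protocol specification for the synthetic study
#'
#' Defaults reproduce the emulated study: 7 subjects x 87 images each (609
#' total), three camera distances with target face widths 184/126/97 px and
#' width scatter 20/13/10 px, head-direction amplitudes of 20 (Small) and 45
#' (Large) degrees, 640 x 480 frames, and sensor noise of 0.05 degC.
#'
#' @param nSubjects number of subjects.
#' @param imagesPerSubject images per subject (split evenly over the three
#'   distances; within a distance roughly a third each of Small, Large --
#'   capped at the nine directions -- and Random).
#' @param distances camera distances, cm.
#' @param faceWidths target mean face width (px) per distance.
#' @param widthSd face-width scatter (px) per distance.
#' @param smallAngle,largeAngle direction amplitudes, degrees.
#' @param imageSize c(width, height) of the frame, px.
#' @param noiseSd sensor noise standard deviation, degC (truncated at 3 sd).
#' @param deformSd per-subject landmark deformation scale, unit-frame units.
#' @param exprJitterSd expression jitter on mouth/brow landmarks in the
#'   Random section, unit-frame units.
#' @param emulateStudy use the seven reference subjects' temperature
#'   statistics for the first seven profiles.
#' @param seed master seed; the generated dataset is a pure function of the
#'   spec.
#' @return a validated list of class `protocol_spec`.
#' @export
protocolSpec <- function(nSubjects = 7L, imagesPerSubject = 87L,
                         distances = c(60, 90, 120),
                         faceWidths = c(184, 126, 97),
                         widthSd = c(20, 13, 10),
                         smallAngle = 20, largeAngle = 45,
                         imageSize = c(640L, 480L), noiseSd = 0.05,
                         deformSd = 0.012, exprJitterSd = 0.02,
                         emulateStudy = TRUE, seed = 1L) {
  spec <- list(nSubjects = as.integer(nSubjects),
               imagesPerSubject = as.integer(imagesPerSubject),
               distances = distances, faceWidths = faceWidths,
               widthSd = widthSd, smallAngle = smallAngle,
               largeAngle = largeAngle, imageSize = as.integer(imageSize),
               noiseSd = noiseSd, deformSd = deformSd,
               exprJitterSd = exprJitterSd, emulateStudy = emulateStudy,
               seed = as.integer(seed))
  if (spec$nSubjects < 1L) stop("config error: nSubjects must be >= 1")
  if (spec$imagesPerSubject < 1L)
    stop("config error: imagesPerSubject must be >= 1")
  if (length(distances) != length(faceWidths) ||
      length(distances) != length(widthSd))
    stop("config error: distances/faceWidths/widthSd lengths differ")
  if (any(faceWidths <= 0)) stop("config error: face widths must be positive")
  if (is.unsorted(rev(faceWidths)))
    stop("config error: face widths must decrease with distance")
  class(spec) <- "protocol_spec"
  spec
}

#' Draw per-subject profiles
#'
#' A profile is a per-landmark deformation of the canonical template plus
#' facial temperature parameters (t_min < t_mean < t_max) and ambient
#' temperature. In emulate-study mode the first seven profiles use the
#' reference subject statistics; additional profiles draw uniformly within
#' that envelope.
#'
#' @param spec a [protocolSpec()].
#' @return list of profiles (`deform`, `tMin`, `tMax`, `tMean`, `ambient`).
#' @export
subjectProfiles <- function(spec = protocolSpec()) {
  tbl <- studySubjectTemperatures()
  withSeed(deriveSeed(spec$seed, 11L), {
    lapply(seq_len(spec$nSubjects), function(s) {
      if (spec$emulateStudy && s <= nrow(tbl)) {
        tmp <- tbl[s, ]
      } else {
        tmp <- data.frame(tMin = stats::runif(1, 29.2, 31.4),
                          tMax = stats::runif(1, 33.7, 34.3),
                          tMean = NA, ambient = stats::runif(1, 24.0, 24.5))
        tmp$tMean <- stats::runif(1, tmp$tMin + 0.8, tmp$tMax - 0.8)
      }
      list(deform = matrix(stats::rnorm(136, 0, spec$deformSd), 68, 2),
           tMin = tmp$tMin, tMax = tmp$tMax, tMean = tmp$tMean,
           ambient = tmp$ambient)
    })
  })
}

# Face ellipse (center, semi-axes) from a landmark layout: covers the
# landmarks plus a forehead extension above the brows.
faceEllipse <- function(cc) {
  xs <- range(cc[, 1])
  browTop <- min(cc[18:27, 2])
  chin <- max(cc[, 2])
  top <- browTop - 0.45 * (chin - browTop)
  bottom <- chin + 0.02 * (chin - browTop)
  list(cx = mean(xs), cy = (top + bottom) / 2,
       a = diff(xs) / 2 * 1.08, b = (bottom - top) / 2)
}

#' Facial temperature statistics of a rendered frame
#'
#' Minimum, maximum and mean temperature over the face region (the ellipse
#' spanned by the landmarks plus forehead), the same region the renderer
#' calibrates.
#'
#' @param img a Celsius [ThermalImage-class].
#' @param shape the face's [FaceShape-class].
#' @return named vector `tMin`, `tMax`, `tMean`.
#' @export
faceTemperatureStats <- function(img, shape) {
  e <- faceEllipse(shape@coords)
  p <- img@pixels
  W <- ncol(p); H <- nrow(p)
  xs <- max(0, floor(e$cx - e$a)):min(W - 1, ceiling(e$cx + e$a))
  ys <- max(0, floor(e$cy - e$b)):min(H - 1, ceiling(e$cy + e$b))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  inside <- ((gx - e$cx) / e$a)^2 + ((gy - e$cy) / e$b)^2 <= 1
  vals <- p[cbind(gy[inside] + 1L, gx[inside] + 1L)]
  c(tMin = min(vals), tMax = max(vals), tMean = mean(vals))
}

# Piecewise-linear map [0,1] -> [tMin, tMax] whose knot value is solved so
# the mapped field has exactly the requested mean (pre-noise).
calibrateField <- function(fNorm, tMin, tMax, tMean) {
  m <- mean(fNorm)
  m <- min(max(m, 0.05), 0.95)
  lowMask <- fNorm < m
  # E[g] = A + B*c with g piecewise-linear through (0,tMin),(m,c),(1,tMax)
  fl <- fNorm[lowMask] / m
  fh <- (fNorm[!lowMask] - m) / (1 - m)
  n <- length(fNorm)
  A <- (sum(tMin * (1 - fl)) + sum(tMax * fh)) / n
  B <- (sum(fl) + sum(1 - fh)) / n
  c0 <- (tMean - A) / B
  c0 <- min(max(c0, tMin + 0.05 * (tMax - tMin)),
            tMax - 0.05 * (tMax - tMin))
  out <- numeric(n)
  out[lowMask] <- tMin + (c0 - tMin) * fl
  out[!lowMask] <- c0 + (tMax - c0) * fh
  out
}

#' Render one synthetic thermal face
#'
#' Deforms the template by the subject profile, applies a pose approximation
#' (in-plane rotation for roll, anisotropic compression by cos(yaw) /
#' cos(pitch) for out-of-plane turns), scales the face to the distance's
#' target width, places it in the frame, and renders a smooth temperature
#' field: ambient background, face interior interpolating warm regions
#' (inner eye canthi, forehead near t_max) and cool ones (nose tip near
#' t_min), calibrated so the face region's min/max/mean equal the profile's
#' parameters before noise. Truncated Gaussian sensor noise (3 sd clip) is
#' added last. Landmarks receive the identical geometric transform and are
#' stored as ground truth; the bounding box is the landmark extent padded by
#' 10%.
#'
#' @param profile a subject profile from [subjectProfiles()].
#' @param pose c(yaw, pitch, roll) in degrees; |yaw|, |pitch| <= 60.
#' @param distance camera distance label (cm).
#' @param spec the [protocolSpec()] supplying widths, frame size and noise.
#' @param seed per-image substream seed.
#' @param section recording-interval label stored with the sample; the
#'   Random section adds expression jitter to mouth and brow landmarks.
#' @param subject subject id string.
#' @return an [AnnotatedSample-class]; generation ground truth (pose, the
#'   pre-transform layout, scale/translation) is kept in the image `meta`.
#' @export
renderFace <- function(profile, pose = c(0, 0, 0), distance = 60,
                       spec = protocolSpec(), seed = 1L, section = "Small",
                       subject = "S1") {
  if (abs(pose[1]) > 60 || abs(pose[2]) > 60)
    stop("value error: |yaw| and |pitch| must be <= 60 degrees")
  di <- match(distance, spec$distances)
  if (is.na(di)) stop("value error: unknown distance ", distance)
  W <- spec$imageSize[1]; H <- spec$imageSize[2]

  withSeed(seed, {
    cc <- canonicalTemplate68()@coords + profile$deform
    if (identical(section, "Random") && spec$exprJitterSd > 0) {
      jit <- c(18:27, 49:68)  # brows + mouth (1-based rows)
      cc[jit, ] <- cc[jit, ] +
        matrix(stats::rnorm(2 * length(jit), 0, spec$exprJitterSd),
               length(jit), 2)
    }
    shape0 <- cc
    ctr <- colMeans(cc)
    yaw <- pose[1] * pi / 180; pitch <- pose[2] * pi / 180
    roll <- pose[3] * pi / 180
    cc[, 1] <- ctr[1] + (cc[, 1] - ctr[1]) * cos(yaw)
    cc[, 2] <- ctr[2] + (cc[, 2] - ctr[2]) * cos(pitch)
    if (roll != 0) {
      R <- matrix(c(cos(roll), sin(roll), -sin(roll), cos(roll)), 2, 2)
      cc <- sweep(sweep(cc, 2, ctr) %*% t(R), 2, ctr, "+")
    }
    targetW <- spec$faceWidths[di] +
      max(-2.5, min(2.5, stats::rnorm(1))) * spec$widthSd[di]
    targetW <- max(targetW, 0.3 * spec$faceWidths[di])
    sc <- targetW / diff(range(cc[, 1]))
    cc <- cc * sc
    # place the face: uniform jitter around the frame center, kept in frame
    spanX <- diff(range(cc[, 1])); spanY <- diff(range(cc[, 2]))
    mar <- 4
    txLo <- mar - min(cc[, 1]); txHi <- (W - 1 - mar) - max(cc[, 1])
    tyLo <- mar - min(cc[, 2]); tyHi <- (H - 1 - mar) - max(cc[, 2])
    ctrTx <- (W - 1) / 2 - (min(cc[, 1]) + spanX / 2)
    ctrTy <- (H - 1) / 2 - (min(cc[, 2]) + spanY / 2)
    jitX <- 0.08 * W; jitY <- 0.08 * H
    tx <- if (txLo < txHi)
      min(max(stats::runif(1, ctrTx - jitX, ctrTx + jitX), txLo), txHi)
      else ctrTx
    ty <- if (tyLo < tyHi)
      min(max(stats::runif(1, ctrTy - jitY, ctrTy + jitY), tyLo), tyHi)
      else ctrTy
    cc[, 1] <- cc[, 1] + tx
    cc[, 2] <- cc[, 2] + ty

    pix <- renderTemperatureField(cc, profile, W, H)
    noise <- stats::rnorm(W * H, 0, spec$noiseSd)
    noise <- pmin(pmax(noise, -3 * spec$noiseSd), 3 * spec$noiseSd)
    pix <- pix + matrix(noise, H, W)

    xr <- range(cc[, 1]); yr <- range(cc[, 2])
    padX <- 0.1 * diff(xr); padY <- 0.1 * diff(yr)
    bb <- bBox(xr[1] - padX, yr[1] - padY,
               diff(xr) + 2 * padX, diff(yr) + 2 * padY)

    img <- thermalImage(pix, unit = "celsius",
      meta = list(subject = subject, distance = distance, section = section,
                  yaw = pose[1], pitch = pose[2], roll = pose[3],
                  scale = sc, tx = tx, ty = ty, shape0 = shape0,
                  noiseSd = spec$noiseSd))
    annotatedSample(img, faceShape(cc), bb, subject = subject,
                    distance = distance, section = section)
  })
}

# Smooth face temperature field: ambient background, elliptical face with
# Gaussian warm/cool anchor bumps, calibrated to the profile's min/mean/max
# over the ellipse. A narrow cosine ring blends face to background.
renderTemperatureField <- function(cc, profile, W, H) {
  e <- faceEllipse(cc)
  pix <- matrix(profile$ambient, H, W)
  ring <- 1.15
  xs <- max(0, floor(e$cx - ring * e$a)):min(W - 1, ceiling(e$cx + ring * e$a))
  ys <- max(0, floor(e$cy - ring * e$b)):min(H - 1, ceiling(e$cy + ring * e$b))
  if (!length(xs) || !length(ys)) return(pix)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  re <- sqrt(((gx - e$cx) / e$a)^2 + ((gy - e$cy) / e$b)^2)
  sel <- re <= ring
  px <- gx[sel]; py <- gy[sel]; rr <- re[sel]

  wF <- 2 * e$a
  bump <- function(f, cx, cy, amp, s) {
    f + amp * exp(-((px - cx)^2 + (py - cy)^2) / (2 * (s * wF)^2))
  }
  browTop <- min(cc[18:27, 2])
  chin <- max(cc[, 2])
  f <- rep(0.55, length(px))
  f <- bump(f, cc[40, 1], cc[40, 2], 0.50, 0.055)       # inner canthus R
  f <- bump(f, cc[43, 1], cc[43, 2], 0.50, 0.055)       # inner canthus L
  f <- bump(f, e$cx, browTop - 0.22 * (chin - browTop), 0.40, 0.16) # forehead
  f <- bump(f, cc[31, 1], cc[31, 2], -0.75, 0.065)      # nose tip
  f <- bump(f, cc[34, 1], cc[34, 2], -0.40, 0.050)      # under nose
  f <- bump(f, cc[63, 1], cc[63, 2], 0.25, 0.06)        # inner mouth
  f <- bump(f, cc[9, 1], cc[9, 2], -0.20, 0.08)         # chin
  f <- bump(f, 0.5 * (cc[3, 1] + cc[32, 1]), cc[32, 2], 0.15, 0.09) # cheek R
  f <- bump(f, 0.5 * (cc[15, 1] + cc[36, 1]), cc[36, 2], 0.15, 0.09) # cheek L
  # cool towards the silhouette
  f <- f - 0.25 * pmin(rr, 1)^4

  core <- rr <= 1
  fn <- f
  lo <- min(f[core]); hi <- max(f[core])
  fn <- pmin(pmax((f - lo) / max(hi - lo, 1e-12), 0), 1)
  temps <- numeric(length(px))
  temps[core] <- calibrateField(fn[core], profile$tMin, profile$tMax,
                                profile$tMean)
  if (any(!core)) {
    edge <- fn[!core] * 0 +
      (profile$tMin + 0.3 * (profile$tMax - profile$tMin))
    w <- (ring - rr[!core]) / (ring - 1)
    w <- 0.5 - 0.5 * cos(pi * pmin(pmax(w, 0), 1))
    temps[!core] <- profile$ambient + w * (edge - profile$ambient)
  }
  pix[cbind(py + 1L, px + 1L)] <- temps
  pix
}

nineDirections <- function(a) {
  # center, then the 8 compass directions at amplitude a (yaw, pitch)
  list(c(0, 0), c(0, -a), c(a, -a), c(a, 0), c(a, a),
       c(0, a), c(-a, a), c(-a, 0), c(-a, -a))
}

# Split n images at one distance into Small/Large/Random section counts.
sectionCounts <- function(n) {
  small <- min(9L, as.integer(ceiling(n / 3)))
  large <- min(9L, as.integer(ceiling((n - small) / 2)))
  c(Small = small, Large = large, Random = n - small - large)
}

#' Generate the full synthetic study
#'
#' Draws the subject profiles, allocates each subject's images across the
#' three distances (even split, remainder to the nearer distances) and the
#' three recording intervals, renders every frame, and returns the samples
#' in subject / distance / section order. A fixed seed yields a bit-identical
#' dataset.
#'
#' @param spec a [protocolSpec()].
#' @param verbose print per-subject progress.
#' @return list of `nSubjects * imagesPerSubject` [AnnotatedSample-class].
#' @export
generateStudy <- function(spec = protocolSpec(), verbose = FALSE) {
  profiles <- subjectProfiles(spec)
  nd <- length(spec$distances)
  base <- spec$imagesPerSubject %/% nd
  extra <- spec$imagesPerSubject %% nd
  perDist <- rep(base, nd) + (seq_len(nd) <= extra)
  samples <- vector("list", spec$nSubjects * spec$imagesPerSubject)
  k <- 0L
  for (s in seq_len(spec$nSubjects)) {
    sid <- sprintf("S%d", s)
    if (verbose) message("subject ", sid)
    for (di in seq_len(nd)) {
      counts <- sectionCounts(perDist[di])
      imgIdx <- 0L
      for (section in names(counts)) {
        nSec <- counts[[section]]
        if (nSec <= 0L) next
        amp <- switch(section, Small = spec$smallAngle,
                      Large = spec$largeAngle, Random = NA)
        dirs <- if (!is.na(amp)) nineDirections(amp) else NULL
        for (j in seq_len(nSec)) {
          imgIdx <- imgIdx + 1L
          imgSeed <- deriveSeed(spec$seed, 23L, s, di, imgIdx)
          pose <- if (!is.null(dirs)) {
            c(dirs[[(j - 1L) %% 9L + 1L]], 0)
          } else {
            withSeed(deriveSeed(imgSeed, 1L),
                     c(stats::runif(2, -45, 45), stats::runif(1, -10, 10)))
          }
          k <- k + 1L
          samples[[k]] <- renderFace(profiles[[s]], pose,
                                     spec$distances[di], spec,
                                     seed = imgSeed, section = section,
                                     subject = sid)
        }
      }
    }
  }
  samples
}

#' Write a generated study to disk
#'
#' Emits one image file per sample (csv, tiff16 or png8), one pts landmark
#' file, and a `manifest.csv` with columns `image, pts, bx, by, bw, bh,
#' subject, distance, section`.
#'
#' @param samples list of [AnnotatedSample-class].
#' @param dir output directory (created if missing).
#' @param format image carrier format.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(samples, dir, format = c("tiff16", "csv", "png8"),
                       overwrite = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("refusing to write into non-empty directory ", dir,
         " (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(format, csv = "csv", tiff16 = "tif", png8 = "png")
  rec <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stem <- sprintf("img%04d", i)
    img <- s@image
    if (format == "png8" && img@unit != "intensity")
      img <- thermalImage(round(normalizeToIntensity(img)@pixels * 255),
                          unit = "intensity", meta = img@meta)
    writeThermalImage(img, file.path(dir, paste0(stem, ".", ext)), format)
    writeLandmarks(s@shape, file.path(dir, paste0(stem, ".pts")))
    b <- s@bbox
    rec[[i]] <- data.frame(image = paste0(stem, ".", ext),
                           pts = paste0(stem, ".pts"),
                           bx = b@x, by = b@y, bw = b@w, bh = b@h,
                           subject = s@subject, distance = s@distance,
                           section = s@section)
  }
  manifest <- do.call(rbind, rec)
  path <- file.path(dir, "manifest.csv")
  writeManifest(manifest, path)
  invisible(path)
}
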