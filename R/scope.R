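# Simulated scanning electron microscope.
#
# The microscope contract is a set of generics (moveStage, setWorkingDistance,
# setScanRotation, setStigmation, scanImage); SimScope is the simulator
# backend. A hardware backend would provide the same methods.

#' Simulation parameters for the microscope backend
#'
#' @param stageFieldAmpUm amplitude of the smooth, repeatable stage targeting
#'   error field (uncorrected targeting error can reach about +/-15 um). The
#'   field emulates wafer-map chain errors: it varies across the wafer but is
#'   locally almost uniform, so short moves are accurate.
#' @param stageFieldScaleUm lateral wavelength of the error field.
#' @param stageJitterSdUm s.d. of the fresh per-move positioning jitter.
#' @param reloadSdUm,reloadSdDeg wafer reload perturbation distribution
#'   (translation s.d. in micrometres -- hundreds of microns -- and rotation
#'   s.d. in degrees).
#' @param blurSigma0Px in-focus blur sigma in pixels (beam point spread).
#' @param blurDefocusK blur growth: micrometres of blur per micrometre of
#'   |working-distance offset - z_surf|.
#' @param stigElongation relative blur elongation per unit of stigmation
#'   error (direction-dependent blur).
#' @param noiseSigma1000 additive noise s.d. at 1000 ns dwell; noise scales
#'   as 1/sqrt(dwell).
#' @param autofocusFailureRate probability that a hardware
#'   focus-stig-focus settle silently fails, leaving a working distance drawn
#'   uniformly from +/-10 um (exercises the retake logic).
#' @param pixelSizeScale actual/nominal pixel size ratio (1 = perfectly
#'   calibrated; used to inject scale miscalibration).
#' @return named list of simulation parameters.
#' @export
simParams <- function(stageFieldAmpUm = 15, stageFieldScaleUm = 40000,
                      stageJitterSdUm = 0.1,
                      reloadSdUm = 300, reloadSdDeg = 1,
                      blurSigma0Px = 0.5, blurDefocusK = 0.2,
                      stigElongation = 0.5, noiseSigma1000 = 0.02,
                      autofocusFailureRate = 0.05, pixelSizeScale = 1) {
  stopifnot(stageFieldAmpUm >= 0, stageJitterSdUm >= 0, reloadSdUm >= 0,
            blurSigma0Px >= 0, blurDefocusK >= 0, noiseSigma1000 >= 0,
            autofocusFailureRate >= 0, autofocusFailureRate <= 1,
            pixelSizeScale > 0)
  list(stageFieldAmpUm = stageFieldAmpUm,
       stageFieldScaleUm = stageFieldScaleUm,
       stageJitterSdUm = stageJitterSdUm,
       reloadSdUm = reloadSdUm, reloadSdDeg = reloadSdDeg,
       blurSigma0Px = blurSigma0Px, blurDefocusK = blurDefocusK,
       stigElongation = stigElongation, noiseSigma1000 = noiseSigma1000,
       autofocusFailureRate = autofocusFailureRate,
       pixelSizeScale = pixelSizeScale)
}

#' Scan request: field of view, pixel counts and dwell time
#' @param fovUm field of view (width, height or a single square value), um.
#' @param pixels pixel counts (width, height or single value), >= 1.
#' @param dwellNs per-pixel dwell time in nanoseconds, > 0.
#' @export
scanRequest <- function(fovUm, pixels, dwellNs = 1000) {
  fovUm <- rep_len(as.numeric(fovUm), 2)
  pixels <- rep_len(as.integer(pixels), 2)
  if (any(fovUm <= 0)) stop("field of view must be positive")
  if (any(pixels < 1)) stop("pixel counts must be >= 1")
  if (dwellNs <= 0) stop("dwell time must be positive")
  list(fovUm = fovUm, pixels = pixels, dwellNs = dwellNs)
}

#' Create a simulated microscope over a wafer scene
#' @param scene a [WaferScene-class].
#' @param params simulation parameters from [simParams].
#' @param seed integer seed for the scope's private noise stream.
#' @return a [SimScope-class].
#' @export
simScope <- function(scene, params = simParams(), seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$xUm <- 0; st$yUm <- 0
  st$actualX <- 0; st$actualY <- 0
  st$wdOffsetUm <- 0
  st$scanRotationDeg <- 0
  st$stig <- c(0, 0)
  st$reload <- NULL
  st$rngSeed <- as.integer(seed)
  st$rngCounter <- 0L
  st$clamped <- FALSE
  st$faults <- list()
  scope <- new("SimScope", scene = scene, params = params, state = st)
  moveStage(scope, 0, 0)
  scope
}

## one deterministic draw from the scope's private stream
scopeDraw <- function(scope, fn) {
  st <- scope@state
  st$rngCounter <- st$rngCounter + 1L
  withSeed(st$rngSeed + 7919L * st$rngCounter, fn())
}

#' Reset the scope's private noise stream
#'
#' Repeated scans after identical reseeds are bitwise identical; the montage
#' acquisition loop reseeds per section so that interrupted and resumed runs
#' produce identical files.
#' @param scope a [SimScope-class].
#' @param seed integer.
#' @export
reseedScope <- function(scope, seed) {
  scope@state$rngSeed <- as.integer(seed %% .Machine$integer.max)
  scope@state$rngCounter <- 0L
  invisible(scope)
}

## smooth repeatable stage-error field (micrometres), per axis
stageErrorField <- function(scope, x, y) {
  p <- scope@params
  if (p$stageFieldAmpUm == 0) return(c(0, 0))
  L <- p$stageFieldScaleUm
  sd0 <- scope@scene@seed
  c(p$stageFieldAmpUm * (2 * fbm3(x / L, y / L, 0, sd0 + 401L, 1L) - 1),
    p$stageFieldAmpUm * (2 * fbm3(x / L, y / L, 0, sd0 + 409L, 1L) - 1))
}

#' @rdname microscope-contract
#' @export
setGeneric("moveStage", function(scope, xUm, yUm) standardGeneric("moveStage"))

#' Microscope contract
#'
#' The abstract instrument interface used by every acquisition operation:
#' move the stage, set working distance / scan rotation / stigmation, scan.
#' `SimScope` implements it against the phantom; stage positions are clamped
#' to the wafer bounds (with a warning flag in the scope state).
#'
#' @param scope a [SimScope-class].
#' @param xUm,yUm commanded stage position (micrometres).
#' @name microscope-contract
#' @aliases moveStage
setMethod("moveStage", "SimScope", function(scope, xUm, yUm) {
  st <- scope@state
  R <- scope@scene@diameterUm / 2
  cx <- min(max(xUm, -R), R)
  cy <- min(max(yUm, -R), R)
  st$clamped <- (cx != xUm || cy != yUm)
  st$xUm <- cx; st$yUm <- cy
  err <- stageErrorField(scope, cx, cy)
  jit <- if (scope@params$stageJitterSdUm > 0) {
    scopeDraw(scope, function() stats::rnorm(2, 0, scope@params$stageJitterSdUm))
  } else c(0, 0)
  st$actualX <- cx + err[1] + jit[1]
  st$actualY <- cy + err[2] + jit[2]
  invisible(scope)
})

#' @rdname microscope-contract
#' @export
setGeneric("setWorkingDistance", function(scope, offsetUm)
  standardGeneric("setWorkingDistance"))

#' @rdname microscope-contract
setMethod("setWorkingDistance", "SimScope", function(scope, offsetUm) {
  scope@state$wdOffsetUm <- offsetUm
  invisible(scope)
})

#' @rdname microscope-contract
#' @export
setGeneric("setScanRotation", function(scope, deg)
  standardGeneric("setScanRotation"))

#' @rdname microscope-contract
setMethod("setScanRotation", "SimScope", function(scope, deg) {
  scope@state$scanRotationDeg <- deg
  invisible(scope)
})

#' @rdname microscope-contract
#' @export
setGeneric("setStigmation", function(scope, sx, sy)
  standardGeneric("setStigmation"))

#' @rdname microscope-contract
setMethod("setStigmation", "SimScope", function(scope, sx, sy) {
  scope@state$stig <- c(sx, sy)
  invisible(scope)
})

#' Current (commanded) microscope state snapshot
#' @param scope a [SimScope-class].
#' @return list: stage, working distance, scan rotation, stigmation.
#' @export
scopeState <- function(scope) {
  st <- scope@state
  list(xUm = st$xUm, yUm = st$yUm, wdOffsetUm = st$wdOffsetUm,
       scanRotationDeg = st$scanRotationDeg, stig = st$stig,
       clamped = st$clamped)
}

#' Apply a wafer reload perturbation
#'
#' Draws a rigid perturbation (translation in the hundreds of micrometres,
#' small rotation about the wafer centre) and displaces all subsequent
#' renders by it. The true transform maps original wafer coordinates to new
#' stage coordinates; it is recorded in the scope and accessible via
#' [reloadTruth] (for tests), while the pipeline must recover it from
#' fiducial re-imaging ([reloadCorrection]).
#'
#' @param scope a [SimScope-class].
#' @param seed integer seed for the draw.
#' @return the truth [SimilarityTransform-class], invisibly.
#' @export
applyReload <- function(scope, seed = 1L) {
  p <- scope@params
  pert <- withSeed(seed + 104729L, list(
    t = stats::rnorm(2, 0, p$reloadSdUm),
    th = stats::rnorm(1, 0, p$reloadSdDeg)))
  tr <- rigidTransform(pert$th, pert$t[1], pert$t[2])
  scope@state$reload <- tr
  invisible(tr)
}

#' Set (or clear) the reload perturbation explicitly
#' @param scope a [SimScope-class].
#' @param transform a rigid [SimilarityTransform-class], or NULL to clear.
#' @export
setReload <- function(scope, transform) {
  scope@state$reload <- transform
  invisible(scope)
}

#' True reload transform held by the simulator (test access)
#' @param scope a [SimScope-class].
#' @export
reloadTruth <- function(scope) {
  tr <- scope@state$reload
  if (is.null(tr)) rigidTransform() else tr
}

#' Inject a one-shot fault into the simulator
#' @param scope a [SimScope-class].
#' @param type "defocus_once": the next scan is rendered with an extra 10 um
#'   working-distance error, then the fault clears.
#' @export
injectFault <- function(scope, type = "defocus_once") {
  scope@state$faults[[type]] <- TRUE
  invisible(scope)
}

#' Render a scene region directly (no instrument state)
#'
#' Ground-truth renderer used by the scope and by tests: samples the wafer
#' scene on a pixel grid centred at `centerUm`, optionally rotated. Two
#' styles mirror the two full-wafer imaging pathways: "sem" samples the
#' tissue phantom inside section footprints; "optical" draws sections as
#' bright, lightly textured patches with a lateral shading gradient.
#'
#' @param scene a [WaferScene-class].
#' @param centerUm (x, y) centre in scene coordinates.
#' @param pixelSizeUm pixel size.
#' @param nx,ny pixel counts (columns, rows).
#' @param rotationDeg grid rotation (+x toward +y).
#' @param style "sem" or "optical".
#' @return numeric matrix \[ny, nx\] in \[0, 1\].
#' @export
renderScene <- function(scene, centerUm, pixelSizeUm, nx, ny,
                        rotationDeg = 0, style = c("sem", "optical")) {
  style <- match.arg(style)
  lv <- scene@levels
  ph <- scene@phantom
  R <- scene@diameterUm / 2
  ux <- (seq_len(nx) - (nx + 1) / 2) * pixelSizeUm
  uy <- (seq_len(ny) - (ny + 1) / 2) * pixelSizeUm
  axisAligned <- rotationDeg == 0
  if (axisAligned) {
    xCol <- centerUm[1] + ux
    yRow <- centerUm[2] + uy
    X <- matrix(xCol, ny, nx, byrow = TRUE)
    Y <- matrix(yRow, ny, nx)
  } else {
    th <- deg2rad(rotationDeg)
    U <- matrix(ux, ny, nx, byrow = TRUE)
    V <- matrix(uy, ny, nx)
    X <- centerUm[1] + cos(th) * U - sin(th) * V
    Y <- centerUm[2] + sin(th) * U + cos(th) * V
  }
  ## linear indices of pixels within `rad` (bounding box) of (cx, cy); on the
  ## axis-aligned fast path this is a submatrix window, else the full image
  regionIdx <- function(cx, cy, rad) {
    if (axisAligned) {
      ic <- which(xCol >= cx - rad & xCol <= cx + rad)
      ir <- which(yRow >= cy - rad & yRow <= cy + rad)
      if (!length(ic) || !length(ir)) return(integer(0))
      as.vector(outer(ir, (ic - 1L) * ny, `+`))
    } else {
      seq_len(nx * ny)
    }
  }
  out <- matrix(lv$offWafer, ny, nx)
  on <- (X * X + Y * Y) <= R * R
  if (any(on)) {
    bg <- lv$background
    if (style == "optical") {
      out[on] <- (bg + 0.05) * (1 + 0.15 * X[on] / R)
    } else {
      out[on] <- bg
    }
  }
  fovRadius <- sqrt(max(abs(ux))^2 + max(abs(uy))^2) + 2 * pixelSizeUm
  ## fiducial marks: dark cross with an off-axis dot and tick breaking symmetry
  fid <- scene@fiducials
  for (i in seq_len(nrow(fid))) {
    fx <- fid$x_um[i]; fy <- fid$y_um[i]; sz <- fid$sizeUm[i]
    if (sqrt((fx - centerUm[1])^2 + (fy - centerUm[2])^2) >
        fovRadius + sz) next
    idx <- regionIdx(fx, fy, 0.8 * sz)
    if (!length(idx)) next
    dx <- X[idx] - fx; dy <- Y[idx] - fy
    bar <- sz / 10
    ## coarse structure: cross + off-axis dot and tick (low-res localisation)
    hit <- (abs(dx) <= sz / 2 & abs(dy) <= bar) |
      (abs(dy) <= sz / 2 & abs(dx) <= bar) |
      ((dx - sz / 3)^2 + (dy - sz / 3)^2) <= (sz / 7)^2 |
      (abs(dx + sz / 3) <= bar / 2 & dy <= -sz / 6 & dy >= -sz / 2.2)
    out[idx[hit]] <- lv$fiducial
    ## fine central structure (high-res localisation): bright square with a
    ## dark centre dot and an asymmetric notch inside the cross centre
    inner <- abs(dx) <= sz / 12 & abs(dy) <= sz / 12
    out[idx[inner]] <- lv$background + 0.55
    dot <- (dx^2 + dy^2) <= (sz / 40)^2
    notch <- dx >= sz / 30 & dx <= sz / 14 & abs(dy - sz / 25) <= sz / 60
    out[idx[dot | notch]] <- lv$fiducial
  }
  ## debris: section-like intensity, non-section wobbly outline
  deb <- scene@debris
  for (i in seq_len(nrow(deb))) {
    cx <- deb$x_um[i]; cy <- deb$y_um[i]; r0 <- deb$radiusUm[i]
    if (sqrt((cx - centerUm[1])^2 + (cy - centerUm[2])^2) >
        fovRadius + 2 * r0) next
    idx <- regionIdx(cx, cy, 1.5 * r0)
    if (!length(idx)) next
    dx <- X[idx] - cx; dy <- Y[idx] - cy
    rr <- sqrt(dx * dx + dy * dy)
    phi <- atan2(dy, dx)
    edge <- r0 * (1 + 0.25 * sin(3 * phi + deb$phase[i]) +
                    0.15 * sin(7 * phi + 2.3 * deb$phase[i]))
    lev <- if (style == "optical") lv$optical else lv$sectionLow + 0.45
    out[idx[rr <= edge]] <- lev
  }
  ## sections: phantom tissue inside the (jittered, rotated) footprint
  sec <- scene@sections
  if (nrow(sec)) {
    cand <- which(!sec$lost &
      sqrt((sec$x_um - centerUm[1])^2 + (sec$y_um - centerUm[2])^2) <=
        fovRadius + sqrt(sec$width_um^2 + sec$height_um^2) / 2)
    for (i in cand) {
      halfDiag <- sqrt(sec$width_um[i]^2 + sec$height_um[i]^2) / 2
      idx <- regionIdx(sec$x_um[i], sec$y_um[i], halfDiag)
      if (!length(idx)) next
      thS <- deg2rad(sec$thetaDeg[i])
      co <- cos(thS); si <- sin(thS)
      dx <- X[idx] - sec$x_um[i]; dy <- Y[idx] - sec$y_um[i]
      lx <- co * dx + si * dy
      ly <- -si * dx + co * dy
      inside <- abs(lx) <= sec$width_um[i] / 2 &
        abs(ly) <= sec$height_um[i] / 2
      if (!any(inside)) next
      tgt <- idx[inside]
      if (style == "sem") {
        txc <- lx[inside] + ph@extentUm[1] / 2
        tyc <- ly[inside] + ph@extentUm[2] / 2
        out[tgt] <- lv$sectionLow + lv$sectionSpan *
          phantomIntensity(ph, txc, tyc, sec$zIndex[i], pixelSizeUm)
      } else {
        n <- valueNoise3(lx[inside] / 300, ly[inside] / 300,
                         sec$zIndex[i] * 0.05, scene@seed + 53L)
        out[tgt] <- (lv$optical + 0.08 * (n - 0.5)) *
          (1 + 0.15 * X[tgt] / R)
      }
    }
  }
  pmin(pmax(out, 0), 1)
}

#' @rdname microscope-contract
#' @export
setGeneric("scanImage", function(scope, request) standardGeneric("scanImage"))

#' Acquire one simulated scan
#'
#' Renders the scene at the *actual* (error-perturbed) stage position through
#' the current reload perturbation, rotated by the scan rotation, blurred
#' according to the defocus/astigmatism model, with additive noise scaled by
#' 1/sqrt(dwell). Metadata records the commanded pose; the actual pose is
#' kept under `meta$.actual` for ground-truth evaluation in tests.
#'
#' @param scope a [SimScope-class].
#' @param request a [scanRequest].
#' @return a [ScanImage-class].
#' @rdname microscope-contract
setMethod("scanImage", "SimScope", function(scope, request) {
  st <- scope@state
  p <- scope@params
  scene <- scope@scene
  psNomX <- request$fovUm[1] / request$pixels[1]
  psNomY <- request$fovUm[2] / request$pixels[2]
  if (abs(psNomX - psNomY) > 1e-9 * psNomX) {
    stop("non-square pixels are not supported")
  }
  psActual <- psNomX * p$pixelSizeScale
  wdErr <- 0
  if (isTRUE(st$faults$defocus_once)) {
    wdErr <- 10
    st$faults$defocus_once <- NULL
  }
  centerStage <- c(st$actualX, st$actualY)
  rot <- st$scanRotationDeg
  if (!is.null(st$reload)) {
    inv <- invertTransform(st$reload)
    centerScene <- as.vector(applyTransform(inv, centerStage))
    rotScene <- rot - st$reload@thetaDeg
  } else {
    centerScene <- centerStage
    rotScene <- rot
  }
  img <- renderScene(scene, centerScene, psActual,
                     request$pixels[1], request$pixels[2], rotScene, "sem")
  zSurf <- surfaceHeight(scene, centerScene[1], centerScene[2])
  defocus <- abs(st$wdOffsetUm + wdErr - zSurf)
  sBase <- p$blurSigma0Px + p$blurDefocusK * defocus / psActual
  sx <- sBase * (1 + p$stigElongation * abs(st$stig[1]))
  sy <- sBase * (1 + p$stigElongation * abs(st$stig[2]))
  img <- gaussBlur(img, sx, sy)
  sigmaN <- p$noiseSigma1000 * sqrt(1000 / request$dwellNs)
  if (sigmaN > 0) {
    img <- img + scopeDraw(scope, function() {
      matrix(stats::rnorm(length(img), 0, sigmaN), nrow(img), ncol(img))
    })
  }
  img <- pmin(pmax(img, 0), 1)
  halfSpanX <- request$fovUm[1] / 2
  halfSpanY <- request$fovUm[2] / 2
  R <- scene@diameterUm / 2
  beyond <- any(abs(centerStage) + c(halfSpanX, halfSpanY) > R)
  new("ScanImage", data = img, pixelSizeUm = psNomX,
      centerUm = c(st$xUm, st$yUm), scanRotationDeg = rot,
      meta = list(dwellNs = request$dwellNs, wdOffsetUm = st$wdOffsetUm,
                  stig = st$stig, beyondScene = beyond,
                  defocusUm = defocus,
                  .actual = list(center = centerStage,
                                 scene = centerScene)))
})

#' Move then scan at a commanded position
#' @param scope a [SimScope-class].
#' @param xUm,yUm commanded stage position.
#' @param request a [scanRequest].
#' @export
scanAt <- function(scope, xUm, yUm, request) {
  moveStage(scope, xUm, yUm)
  scanImage(scope, request)
}

setMethod("show", "SimScope", function(object) {
  st <- object@state
  cat(sprintf(
    "SimScope over wafer %d: stage (%.1f, %.1f) um, WD %+.2f um, rot %.1f deg%s\n",
    object@scene@waferId, st$xUm, st$yUm, st$wdOffsetUm, st$scanRotationDeg,
    if (!is.null(st$reload)) " [reloaded]" else ""))
})

setMethod("show", "ScanImage", function(object) {
  cat(sprintf(
    "ScanImage: %d x %d px at %.4g um/px, centre (%.1f, %.1f), rot %.1f deg\n",
    ncol(object@data), nrow(object@data), object@pixelSizeUm,
    object@centerUm[1], object@centerUm[2], object@scanRotationDeg))
})

#' Image pixel data of a scan
#' @param x a [ScanImage-class].
#' @export
scanData <- function(x) x@data

#' Write a scan image (TIFF) with a JSON metadata sidecar
#'
#' @param image a [ScanImage-class].
#' @param path output path ending in .tif; the sidecar is written next to it
#'   with extension .json.
#' @param bits 8 (default) or 16.
#' @export
writeScanImage <- function(image, path, bits = 8) {
  tiff::writeTIFF(image@data, path, bits.per.sample = bits)
  meta <- image@meta
  meta$.actual <- NULL
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(centerUm = image@centerUm, pixelSizeUm = image@pixelSizeUm,
         scanRotationDeg = image@scanRotationDeg, meta = meta),
    side, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a scan image written by [writeScanImage]
#' @param path TIFF path.
#' @export
readScanImage <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- sub("\\.tiff?$", ".json", path)
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    new("ScanImage", data = img, pixelSizeUm = m$pixelSizeUm,
        centerUm = as.numeric(m$centerUm),
        scanRotationDeg = m$scanRotationDeg,
        meta = as.list(m$meta))
  } else {
    new("ScanImage", data = img, pixelSizeUm = NA_real_,
        centerUm = c(NA_real_, NA_real_), scanRotationDeg = 0, meta = list())
  }
}
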