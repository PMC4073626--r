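# Wafer mapping phase: register the full-wafer image to stage space, detect
# and number sections, calibrate pixel-to-stage scale, acquire fiducials and
# per-section overview images.

#' Binary threshold mask
#'
#' @param image numeric matrix.
#' @param lo,hi inclusive gray bounds, `lo <= hi`.
#' @return logical matrix, TRUE where `lo <= pixel <= hi`.
#' @export
thresholdMask <- function(image, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  image >= lo & image <= hi
}

#' Detect section locations by rotated mask matching
#'
#' The example-section mask is used as a matching kernel and correlated with
#' the wafer mask at multiple rotations (FFT convolution). The heat value at
#' each position is the maximum over rotations of the overlap fraction
#' (overlap pixel count divided by the rotated example area, so the heat is
#' at most 1 and the threshold is scale-free), optionally minus a
#' centre-surround penalty (see `surroundPenalty`). Pixels at or above
#' `heatThreshold` are thinned by non-maximum suppression at the merge
#' radius -- half the example's smaller dimension -- so neighbouring
#' sections closer than that merge into the stronger peak; each kept peak
#' is refined to the heat-weighted centroid of its neighbourhood, with the
#' argmax rotation recorded.
#'
#' @param waferMask logical matrix (thresholded wafer image).
#' @param exampleMask logical matrix (thresholded example section cutout).
#' @param rotationRangeDeg rotation search half-range (default 15).
#' @param rotationStepDeg rotation step (default 3), > 0.
#' @param heatThreshold detection threshold on the overlap fraction
#'   (default 0.8).
#' @param surroundPenalty weight of the centre-surround term: the occupancy
#'   fraction of a thin ring around the rotated example is subtracted from
#'   the overlap fraction with this weight. A section centred under the
#'   kernel keeps heat 1 (the ring sits on background), while positions
#'   inside a blob of touching sections are penalised, so neighbouring
#'   jittered sections resolve into separate peaks. Set to 0 for the plain
#'   overlap statistic.
#' @param surroundPx ring thickness in pixels.
#' @return data.frame with one row per detection: `col`, `row` (pixel
#'   position, 1-based), `heat`, `thetaDeg`. The full heat map is attached as
#'   attribute "heat".
#' @export
automapSections <- function(waferMask, exampleMask, rotationRangeDeg = 15,
                            rotationStepDeg = 3, heatThreshold = 0.8,
                            surroundPenalty = 0.5, surroundPx = 2L) {
  if (!any(exampleMask)) stop("example mask is empty")
  if (rotationStepDeg <= 0) stop("rotation step must be positive")
  er <- nrow(exampleMask); ec <- ncol(exampleMask)
  if (er > nrow(waferMask) || ec > ncol(waferMask)) {
    stop("example mask larger than wafer mask")
  }
  ## crop to the occupied bounding box (padded by the example size) and round
  ## up to an FFT-friendly size: the heat is zero far from any ON pixel
  occRows <- which(rowSums(waferMask) > 0)
  if (!length(occRows)) {
    out <- data.frame(col = numeric(0), row = numeric(0), heat = numeric(0),
                      thetaDeg = numeric(0))
    attr(out, "heat") <- matrix(0, nrow(waferMask), ncol(waferMask))
    return(out)
  }
  occR <- range(occRows)
  occC <- range(which(colSums(waferMask) > 0))
  r0 <- max(1L, occR[1] - er); r1 <- min(nrow(waferMask), occR[2] + er)
  c0 <- max(1L, occC[1] - ec); c1 <- min(ncol(waferMask), occC[2] + ec)
  nr <- stats::nextn(r1 - r0 + 1L, c(2, 3, 5))
  nc <- stats::nextn(c1 - c0 + 1L, c(2, 3, 5))
  r1 <- min(nrow(waferMask), r0 + nr - 1L); nr <- r1 - r0 + 1L
  c1 <- min(ncol(waferMask), c0 + nc - 1L); nc <- c1 - c0 + 1L
  W <- waferMask[r0:r1, c0:c1] * 1
  rots <- seq(-rotationRangeDeg, rotationRangeDeg, by = rotationStepDeg)
  fW <- stats::fft(W)
  heat <- matrix(-Inf, nr, nc)
  rotIdx <- matrix(1L, nr, nc)
  ex <- exampleMask * 1
  ## pad the example so a dilation ring fits around any rotation of it
  t <- as.integer(surroundPx)
  pad <- t + 1L
  epR <- er + 2L * pad; epC <- ec + 2L * pad
  exPad0 <- matrix(0, epR, epC)
  exPad0[pad + seq_len(er), pad + seq_len(ec)] <- ex
  cyP <- (epR + 1) / 2; cxP <- (epC + 1) / 2
  corrWith <- function(kern, cy, cx) {
    K <- matrix(0, nr, nc)
    ri <- ((seq_len(nrow(kern)) - round(cy)) %% nr) + 1
    ci <- ((seq_len(ncol(kern)) - round(cx)) %% nc) + 1
    K[ri, ci] <- kern
    Re(stats::fft(fW * Conj(stats::fft(K)), inverse = TRUE)) / (nr * nc)
  }
  for (k in seq_along(rots)) {
    exR <- if (rots[k] == 0) exPad0 else
      (rotateImage(exPad0, rots[k], fill = 0) > 0.5) * 1
    area <- sum(exR)
    if (area == 0) next
    S <- corrWith(exR, cyP, cxP) / area
    if (surroundPenalty > 0 && t > 0) {
      ring <- boxDilate(exR, t) - exR
      nRing <- sum(ring)
      if (nRing > 0) {
        S <- S - surroundPenalty * corrWith(ring, cyP, cxP) / nRing
      }
    }
    upd <- S > heat
    heat[upd] <- S[upd]
    rotIdx[upd] <- k
  }
  ## peak extraction: hot pixels thinned by non-maximum suppression at the
  ## merge radius (half the example's smaller dimension), so two sections
  ## whose heat plateaus touch are still resolved as two detections; each
  ## kept peak is refined to the heat-weighted centroid of its neighbourhood
  mergeR <- min(er, ec) / 2
  hotIdx <- which(heat >= heatThreshold)
  det <- data.frame(col = numeric(0), row = numeric(0), heat = numeric(0),
                    thetaDeg = numeric(0))
  if (length(hotIdx)) {
    hr <- ((hotIdx - 1L) %% nr) + 1L
    hc <- ((hotIdx - 1L) %/% nr) + 1L
    hv <- heat[hotIdx]
    ord <- order(-hv, hr, hc)
    hr <- hr[ord]; hc <- hc[ord]; hv <- hv[ord]; hotIdx <- hotIdx[ord]
    avail <- rep(TRUE, length(hv))
    while (any(avail)) {
      i <- which.max(avail)  # highest remaining heat
      near <- (hr - hr[i])^2 + (hc - hc[i])^2 < mergeR^2
      sel <- near & avail
      w <- hv[sel] - heatThreshold + 1e-6
      det[nrow(det) + 1L, ] <- c(
        sum(hc[sel] * w) / sum(w),
        sum(hr[sel] * w) / sum(w),
        hv[i],
        rots[rotIdx[hotIdx[i]]])
      avail[near] <- FALSE
    }
    det$col <- det$col + c0 - 1L
    det$row <- det$row + r0 - 1L
    det <- det[order(det$row, det$col), , drop = FALSE]
    rownames(det) <- NULL
  }
  attr(det, "heat") <- heat
  attr(det, "heatOrigin") <- c(row = r0, col = c0)
  det
}

#' Strip model for tape-order numbering
#'
#' @param gapUm minimum gap between strips along y used for single-linkage
#'   clustering of centroids (default 1000).
#' @param reversed logical vector (recycled over strips): strips mounted in
#'   reversed (serpentine) order.
#' @param startLabel first label to assign (continues the library-wide
#'   counter across wafers; default 1).
#' @export
stripModel <- function(gapUm = 1000, reversed = FALSE, startLabel = 1L) {
  list(gapUm = gapUm, reversed = reversed, startLabel = as.integer(startLabel))
}

#' Assign tape-order labels to detected sections
#'
#' Clusters detection centroids by the coordinate perpendicular to the strip
#' axis (strips run along x; clustering is single-linkage on y with a gap
#' threshold), orders strips top-to-bottom and sections left-to-right within
#' each strip (reversed strips right-to-left), and assigns consecutive
#' integer labels continuing from `startLabel`.
#'
#' @param detections data.frame with columns `x_um`, `y_um` (stage
#'   coordinates) plus any others, one row per detection.
#' @param model a [stripModel].
#' @param sectionHeightUm nominal section height; used only to flag ambiguous
#'   strip clustering (two strips closer than one section height).
#' @return the detections with `label`, `strip`, `posInStrip` columns, sorted
#'   by label; attribute "ambiguous" is TRUE when strip clustering is
#'   suspect and manual strip assignment is advised.
#' @export
numberSections <- function(detections, model = stripModel(),
                           sectionHeightUm = NULL) {
  if (!nrow(detections)) stop("no detections to number")
  y <- detections$y_um
  ord <- order(y)
  gaps <- which(diff(y[ord]) > model$gapUm)
  bounds <- c(0, gaps, length(y))
  strip <- integer(length(y))
  for (s in seq_len(length(bounds) - 1)) {
    strip[ord[(bounds[s] + 1):bounds[s + 1]]] <- s
  }
  nStrips <- max(strip)
  ambiguous <- FALSE
  if (!is.null(sectionHeightUm) && nStrips > 1) {
    mu <- vapply(seq_len(nStrips), function(s) mean(y[strip == s]), 0)
    ambiguous <- any(diff(sort(mu)) < sectionHeightUm)
  }
  rev <- rep_len(model$reversed, nStrips)
  detections$strip <- strip
  detections$posInStrip <- NA_integer_
  detections$label <- NA_integer_
  lab <- model$startLabel
  for (s in seq_len(nStrips)) {
    idx <- which(strip == s)
    idx <- idx[order(detections$x_um[idx], decreasing = rev[s])]
    detections$posInStrip[idx] <- seq_along(idx)
    detections$label[idx] <- seq(lab, by = 1L, length.out = length(idx))
    lab <- lab + length(idx)
  }
  out <- detections[order(detections$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Add or remove a section record, then relabel
#'
#' Programmatic counterpart of the manual correction step after automatic
#' section mapping. Adding appends a record with status "manually_added";
#' removing drops the record (it is retained with status "manually_removed"
#' in the attribute "removed"). Labels are reassigned in tape order after
#' every edit.
#'
#' @param records labeled section table (see [numberSections]); must carry
#'   `x_um`, `y_um`, `status` columns.
#' @param edit list: either `list(add = c(x, y), thetaDeg = 0)` or
#'   `list(remove = <label>)`.
#' @param model the [stripModel] used for relabeling.
#' @param waferDiameterUm when given, additions outside the wafer disc are
#'   rejected.
#' @param ... passed to [numberSections].
#' @return the edited, relabeled table.
#' @export
editSections <- function(records, edit, model = stripModel(),
                         waferDiameterUm = NULL, ...) {
  if (!is.null(edit$add)) {
    p <- edit$add
    if (!is.null(waferDiameterUm) &&
        sqrt(p[1]^2 + p[2]^2) > waferDiameterUm / 2) {
      stop("cannot add a section outside the wafer")
    }
    row <- records[0, , drop = FALSE]
    row[1, c("x_um", "y_um")] <- c(p[1], p[2])
    if ("thetaDeg" %in% names(records)) {
      row$thetaDeg <- if (is.null(edit$thetaDeg)) 0 else edit$thetaDeg
    }
    row$status <- "manually_added"
    for (cn in setdiff(names(records), names(row)[!is.na(row[1, ])])) {
      if (all(is.na(row[[cn]]))) row[[cn]] <- row[[cn]]
    }
    records <- rbind(records, row)
  } else if (!is.null(edit$remove)) {
    hit <- which(records$label == edit$remove)
    if (!length(hit)) stop(sprintf("no section with label %s", edit$remove))
    removed <- records[hit, , drop = FALSE]
    removed$status <- "manually_removed"
    records <- records[-hit, , drop = FALSE]
    attr(records, "removed") <- rbind(attr(records, "removed"), removed)
  } else {
    stop("edit must name either add or remove")
  }
  rem <- attr(records, "removed")
  out <- numberSections(records, model, ...)
  attr(out, "removed") <- rem
  out
}

#' Pixel-to-stage calibration
#'
#' Scans an anchor region, commands a +x stage move of `stepUm` and re-scans,
#' then repeats along +y. Each per-axis pixel displacement is measured by
#' subpixel cross-correlation; the calibration factor is
#' commanded distance / (pixel displacement x nominal pixel size), averaged
#' over the two axes. A factor of 1.02 means stage travel is 2% longer than
#' the nominal pixel size implies.
#'
#' @param scope a [SimScope-class].
#' @param anchorUm (x, y) stage position of a textured calibration target.
#' @param stepUm commanded move (default 100); must displace the image by at
#'   least 2 px and should keep most of the field overlapping.
#' @param request imaging conditions (defaults to the overview conditions:
#'   1 um pixels, 256 px field).
#' @return list: `factor`, `perAxis` (x, y), `score` (worst correlation).
#' @export
calibratePixelToStage <- function(scope, anchorUm, stepUm = 100,
                                  request = scanRequest(256, 256, 4000)) {
  ps <- request$fovUm[1] / request$pixels[1]
  img0 <- scanAt(scope, anchorUm[1], anchorUm[2], request)
  if (stats::sd(img0@data) < 3 * scope@params$noiseSigma1000) {
    stop("calibration target featureless")
  }
  measure <- function(dxUm, dyUm) {
    img1 <- scanAt(scope, anchorUm[1] + dxUm, anchorUm[2] + dyUm, request)
    r <- measureShift(img0@data, img1@data)
    if (r$score < 0.2) stop("calibration target featureless")
    c(px = r$dx, py = r$dy, score = r$score)
  }
  mx <- measure(stepUm, 0)
  my <- measure(0, stepUm)
  dispX <- abs(mx["px"]); dispY <- abs(my["py"])
  if (dispX < 2 || dispY < 2) stop("step too small")
  fx <- stepUm / (dispX * ps)
  fy <- stepUm / (dispY * ps)
  list(factor = unname((fx + fy) / 2), perAxis = c(x = unname(fx),
       y = unname(fy)), score = unname(min(mx["score"], my["score"])))
}

#' Acquire low- and high-resolution fiducial images
#'
#' Images each fiducial position first at low resolution (3 um per pixel, to
#' be findable after a coarse reload offset) and then at high resolution
#' (0.25 um per pixel, for precise registration).
#'
#' @param scope a [SimScope-class].
#' @param positions n x 2 matrix of stage positions, n >= 2.
#' @param lowPx,highPx image sizes in pixels.
#' @param lowPixelUm,highPixelUm pixel sizes (defaults 3 and 0.25).
#' @param dwellNs dwell time.
#' @return list with one element per fiducial: `positionUm`, `low`, `high`
#'   ([ScanImage-class]s).
#' @export
acquireFiducials <- function(scope, positions, lowPx = 512, highPx = 256,
                             lowPixelUm = 3, highPixelUm = 0.25,
                             dwellNs = 4000) {
  positions <- rbind2cols(positions)
  if (nrow(positions) < 2) {
    stop("at least 2 fiducial positions are required")
  }
  lapply(seq_len(nrow(positions)), function(i) {
    p <- positions[i, ]
    low <- scanAt(scope, p[1], p[2],
                  scanRequest(lowPx * lowPixelUm, lowPx, dwellNs))
    high <- scanAt(scope, p[1], p[2],
                   scanRequest(highPx * highPixelUm, highPx, dwellNs))
    list(positionUm = p, low = low, high = high)
  })
}

#' Overview acquisition parameters
#' @param pixelSizeUm overview pixel size (default 0.9, slightly below 1).
#' @param marginUm margin added around the section bounding box on every side
#'   (default 1000: one millimetre larger than the section).
#' @param dwellNs dwell time.
#' @export
overviewParams <- function(pixelSizeUm = 0.9, marginUm = 1000,
                           dwellNs = 1000) {
  list(pixelSizeUm = pixelSizeUm, marginUm = marginUm, dwellNs = dwellNs)
}

#' Scan request for one section overview
#' @param sectionWidthUm,sectionHeightUm nominal section footprint.
#' @param params an [overviewParams] list.
#' @return a [scanRequest] covering the section plus margins.
#' @export
overviewScanRequest <- function(sectionWidthUm, sectionHeightUm,
                                params = overviewParams()) {
  fov <- c(sectionWidthUm, sectionHeightUm) + 2 * params$marginUm
  px <- ceiling(fov / params$pixelSizeUm)
  scanRequest(px * params$pixelSizeUm, px, params$dwellNs)
}

#' Acquire section overview images
#'
#' Drives to each labeled section centroid and acquires one overview image
#' with a field of view covering the section bounding box plus a margin.
#' Files are named by tape-order label (`S%04d.tif`) with JSON sidecars.
#'
#' @param scope a [SimScope-class].
#' @param sections labeled section table (columns `label`, `x_um`, `y_um`).
#' @param outDir output directory (created if needed).
#' @param params an [overviewParams] list.
#' @param sectionWidthUm,sectionHeightUm nominal footprint used for the FOV.
#' @param skip labels to skip.
#' @param autofocusEach run a quick [autofocus] at each section before its
#'   overview scan (keeps overviews sharp on a non-flat wafer surface).
#' @return data.frame manifest: label, file, x_um, y_um, ok.
#' @export
acquireOverviews <- function(scope, sections, outDir,
                             params = overviewParams(),
                             sectionWidthUm, sectionHeightUm,
                             skip = integer(0), autofocusEach = TRUE) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create overview output directory")
  }
  req <- overviewScanRequest(sectionWidthUm, sectionHeightUm, params)
  rows <- list()
  for (i in seq_len(nrow(sections))) {
    lab <- sections$label[i]
    if (lab %in% skip) next
    file <- file.path(outDir, sprintf("S%04d.tif", lab))
    ok <- TRUE
    tryCatch({
      moveStage(scope, sections$x_um[i], sections$y_um[i])
      if (autofocusEach) autofocus(scope, steps = 9)
      img <- scanImage(scope, req)
      writeScanImage(img, file)
    }, error = function(e) ok <<- FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, file = file, x_um = sections$x_um[i],
      y_um = sections$y_um[i], ok = ok)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  attr(out, "request") <- req
  out
}

#' Construct a wafer record
#'
#' Bundles one wafer's mapping products: the full-wafer-image-to-stage
#' transform, the fiducial set, the labelled section table, the
#' pixel-to-stage calibration factor and the overview parameters used.
#'
#' @param waferId integer id.
#' @param mapTransform a [SimilarityTransform-class] (wafer-image pixels to
#'   stage micrometres).
#' @param sections labelled section table (see [numberSections]).
#' @param fiducials fiducial list from [acquireFiducials] (optional).
#' @param pixelToStageFactor calibration factor (see
#'   [calibratePixelToStage]).
#' @param overviewParams an [overviewParams] list.
#' @param paths named list of file locations.
#' @return a [WaferRecord-class].
#' @export
waferRecord <- function(waferId, mapTransform = similarityTransform(),
                        sections = data.frame(), fiducials = list(),
                        pixelToStageFactor = 1,
                        overviewParams = utslmap::overviewParams(),
                        paths = list()) {
  new("WaferRecord", waferId = as.integer(waferId),
      mapTransform = mapTransform, fiducials = fiducials,
      sections = sections, pixelToStageFactor = pixelToStageFactor,
      overviewParams = overviewParams, paths = paths)
}

setMethod("show", "WaferRecord", function(object) {
  cat(sprintf(
    "WaferRecord %d: %d sections, factor %.4f, %d fiducials\n",
    object@waferId, nrow(object@sections), object@pixelToStageFactor,
    length(object@fiducials)))
})

#' Persist a wafer record as `wafer.json`
#'
#' Fiducial images are not embedded; store them with [writeScanImage] and
#' record their paths.
#'
#' @param record a [WaferRecord-class].
#' @param path output JSON path.
#' @export
writeWaferRecord <- function(record, path) {
  tf <- record@mapTransform
  jsonlite::write_json(
    list(formatVersion = 1L, waferId = record@waferId,
         mapTransform = list(scale = tf@scale, thetaDeg = tf@thetaDeg,
                             tx = tf@tx, ty = tf@ty),
         pixelToStageFactor = record@pixelToStageFactor,
         overviewParams = record@overviewParams,
         fiducialPositions = lapply(record@fiducials, function(f)
           as.numeric(f$positionUm)),
         sections = record@sections, paths = record@paths),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a wafer record written by [writeWaferRecord]
#' @param path JSON path.
#' @return a [WaferRecord-class] (fiducial images not reloaded; positions
#'   are kept).
#' @export
readWaferRecord <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  waferRecord(j$waferId,
              similarityTransform(j$mapTransform$scale,
                                  j$mapTransform$thetaDeg,
                                  j$mapTransform$tx, j$mapTransform$ty),
              sections = as.data.frame(j$sections),
              fiducials = lapply(seq_len(length(j$fiducialPositions)),
                                 function(i) list(positionUm =
                                   as.numeric(j$fiducialPositions[[i]]))),
              pixelToStageFactor = j$pixelToStageFactor,
              overviewParams = as.list(j$overviewParams),
              paths = as.list(j$paths))
}
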