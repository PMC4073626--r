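# High-resolution montage imaging phase: reload correction, image-based
# stage correction (IBSC), sparse-sampling quality metric, autofocus and
# autostigmation strategies, tile planning, quality-gated acquisition with
# retakes, and stage-stitched previews.

## weight of the unstructured (interleaved) pattern in the kernel quality;
## calibrated so E[q] ~ 0 for i.i.d. Gaussian noise kernels:
## E[S] = 4 sqrt(2/pi) sqrt(2/3), E[U] = sqrt(2/pi) sqrt(1/5 + 1/4),
## ratio = 4 sqrt(2/3) / sqrt(0.45) = 4.868
kernelQualityBeta <- 4.87

#' Quality value of one 3 x 3 pixel kernel
#'
#' Contrast of structured minus unstructured patterns. The structured term S
#' sums the absolute differences of the mean intensities of adjacent pixel
#' lines (two horizontal and two vertical comparisons); the unstructured
#' term U is the absolute difference between the means of the two
#' interleaved checkerboard groups (corners + centre vs edge mid-points).
#' The quality is q = S - 4.87 U: a well-focused image of membranes yields
#' much more line contrast than interleaved contrast, while single-pixel
#' noise is penalised -- for i.i.d. Gaussian noise E\[q\] ~ 0.
#'
#' @param kernel 3 x 3 numeric matrix (or length-9 vector, column-major).
#' @return scalar quality q.
#' @export
kernelQuality <- function(kernel) {
  v <- as.numeric(kernel)
  if (length(v) != 9 || any(!is.finite(v))) {
    stop("kernel must be 9 finite values")
  }
  k <- matrix(v, 3, 3)
  r <- rowMeans(k); cm <- colMeans(k)
  S <- abs(r[1] - r[2]) + abs(r[2] - r[3]) + abs(cm[1] - cm[2]) +
    abs(cm[2] - cm[3])
  A <- (k[1, 1] + k[1, 3] + k[3, 1] + k[3, 3] + k[2, 2]) / 5
  B <- (k[1, 2] + k[2, 1] + k[2, 3] + k[3, 2]) / 4
  unname(S - kernelQualityBeta * abs(A - B))
}

#' Sparse-sampling image quality check
#'
#' Reads a grid (default 200 x 200) of 3 x 3 pixel kernels at evenly spaced
#' positions, computes a quality value per kernel ([kernelQuality]), and
#' aggregates by averaging the best `topFraction` of grid points. Basing the
#' score on the best regions makes it robust to tissue statistics (vessel
#' interiors, section edges) while sampling only a small fraction of the
#' pixels keeps it fast on large tiles.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @param gridDims grid dimensions (rows, cols), default c(200, 200);
#'   reduced automatically (and recorded) when the image is too small.
#' @param topFraction fraction of best grid points averaged (default 0.01).
#' @param threshold pass threshold on the aggregate score.
#' @return a [QualityResult-class].
#' @export
qualityCheck <- function(image, gridDims = c(200, 200), topFraction = 0.01,
                         threshold = 0) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image smaller than 3 x 3")
  if (topFraction <= 0 || topFraction > 1) {
    stop("topFraction must be in (0, 1]")
  }
  gr <- min(gridDims[1], nr - 2)
  gc <- min(gridDims[2], nc - 2)
  rc <- round(seq(2, nr - 1, length.out = gr))
  cc <- round(seq(2, nc - 1, length.out = gc))
  R <- matrix(rc, gr, gc)
  C <- matrix(cc, gr, gc, byrow = TRUE)
  at <- function(dr, dc) matrix(image[cbind(as.vector(R) + dr,
                                            as.vector(C) + dc)], gr, gc)
  k11 <- at(-1, -1); k12 <- at(-1, 0); k13 <- at(-1, 1)
  k21 <- at(0, -1);  k22 <- at(0, 0);  k23 <- at(0, 1)
  k31 <- at(1, -1);  k32 <- at(1, 0);  k33 <- at(1, 1)
  r1 <- (k11 + k12 + k13) / 3
  r2 <- (k21 + k22 + k23) / 3
  r3 <- (k31 + k32 + k33) / 3
  c1 <- (k11 + k21 + k31) / 3
  c2 <- (k12 + k22 + k32) / 3
  c3 <- (k13 + k23 + k33) / 3
  S <- abs(r1 - r2) + abs(r2 - r3) + abs(c1 - c2) + abs(c2 - c3)
  A <- (k11 + k13 + k31 + k33 + k22) / 5
  B <- (k12 + k21 + k23 + k32) / 4
  q <- S - kernelQualityBeta * abs(A - B)
  n <- length(q)
  top <- sort(as.vector(q), decreasing = TRUE)[seq_len(ceiling(topFraction * n))]
  score <- mean(top)
  new("QualityResult", grid = q, score = score, pass = score >= threshold,
      threshold = threshold)
}

#' Aggregate score of a quality result
#' @param x a [QualityResult-class].
#' @export
qualityScore <- function(x) x@score

setMethod("show", "QualityResult", function(object) {
  cat(sprintf("QualityResult: %d x %d grid, score %.4f (threshold %.3f): %s\n",
              nrow(object@grid), ncol(object@grid), object@score,
              object@threshold, if (object@pass) "pass" else "FAIL"))
})

#' Pick an autofocus spot inside an image
#'
#' Returns the centre of the block with the highest intensity standard
#' deviation: the autofocus routine then works on the most contrast-rich
#' region and avoids featureless areas such as vessel interiors. Ties are
#' broken toward the image centre.
#'
#' @param image numeric matrix.
#' @param blockPx block side in pixels (default 32).
#' @return list: `col`, `row` (block centre), `sd`, `lowContrast` flag (TRUE
#'   for a near-constant image, in which case the image centre is returned).
#' @export
chooseFocusSpot <- function(image, blockPx = 32) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < blockPx || nc < blockPx) stop("image smaller than one block")
  nbr <- nr %/% blockPx; nbc <- nc %/% blockPx
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)
  best <- NULL
  for (br in seq_len(nbr)) {
    for (bc in seq_len(nbc)) {
      rows <- ((br - 1) * blockPx + 1):(br * blockPx)
      cols <- ((bc - 1) * blockPx + 1):(bc * blockPx)
      s <- stats::sd(image[rows, cols])
      pos <- c(mean(range(cols)), mean(range(rows)))
      d2 <- sum((pos - ctr)^2)
      if (is.null(best) || s > best$sd + 1e-12 ||
          (abs(s - best$sd) <= 1e-12 && d2 < best$d2)) {
        best <- list(col = pos[1], row = pos[2], sd = s, d2 = d2)
      }
    }
  }
  if (best$sd < 1e-6) {
    return(list(col = ctr[1], row = ctr[2], sd = best$sd,
                lowContrast = TRUE))
  }
  list(col = best$col, row = best$row, sd = best$sd, lowContrast = FALSE)
}

#' Autofocus by bracketed quality search
#'
#' Scans a small image at each working-distance offset across the bracket,
#' scores each with [qualityCheck], then refines the argmax with a 3-point
#' parabolic fit and sets the working distance to the estimate. If the best
#' sampled offset lies on the bracket edge the bracket edge is returned with
#' a `failed` flag.
#'
#' @param scope a [SimScope-class]; the stage is not moved (drive to the
#'   focus spot first).
#' @param bracketUm half-range of the sweep (default 25).
#' @param steps number of offsets sampled (default 11, >= 3).
#' @param centerUm bracket centre (absolute working-distance offset,
#'   default 0).
#' @param request scan used for scoring (default 64 px at 0.5 um).
#' @param gridDims,topFraction quality-check settings for the small scans.
#' @param scoreThreshold below this achieved score the result is flagged
#'   failed.
#' @return list: `wdOffsetUm`, `score`, `failed`, `sampled` (data.frame of
#'   offset/score pairs).
#' @export
autofocus <- function(scope, bracketUm = 25, steps = 11, centerUm = 0,
                      request = scanRequest(32, 64, 4000),
                      gridDims = c(40, 40), topFraction = 0.02,
                      scoreThreshold = 0) {
  if (bracketUm <= 0) stop("bracket must be positive")
  if (steps < 3) stop("at least 3 steps are required")
  offs <- seq(centerUm - bracketUm, centerUm + bracketUm,
              length.out = steps)
  scores <- numeric(steps)
  for (i in seq_len(steps)) {
    setWorkingDistance(scope, offs[i])
    img <- scanImage(scope, request)
    scores[i] <- qualityCheck(img@data, gridDims, topFraction)@score
  }
  k <- which.max(scores)
  if (k == 1L || k == steps) {
    setWorkingDistance(scope, offs[k])
    img <- scanImage(scope, request)
    sc <- qualityCheck(img@data, gridDims, topFraction)@score
    return(list(wdOffsetUm = offs[k], score = sc, failed = TRUE,
                sampled = data.frame(offsetUm = offs, score = scores)))
  }
  ## fine sweep around the coarse argmax, then a parabolic sub-step estimate
  step <- offs[2] - offs[1]
  fine <- seq(offs[k] - step, offs[k] + step, length.out = 5)
  fscores <- numeric(5)
  for (i in 1:5) {
    setWorkingDistance(scope, fine[i])
    img <- scanImage(scope, request)
    fscores[i] <- qualityCheck(img@data, gridDims, topFraction)@score
  }
  kf <- which.max(fscores)
  fstep <- fine[2] - fine[1]
  est <- if (kf == 1L || kf == 5L) fine[kf] else
    fine[kf] + fstep * parabolicPeak(fscores[kf - 1], fscores[kf],
                                     fscores[kf + 1])
  setWorkingDistance(scope, est)
  img <- scanImage(scope, request)
  sc <- qualityCheck(img@data, gridDims, topFraction)@score
  list(wdOffsetUm = est, score = max(sc, scores[k]),
       failed = sc < scoreThreshold,
       sampled = data.frame(offsetUm = offs, score = scores))
}

#' Autostigmation by grid search
#'
#' Grid-searches the two stigmator axes at the current working distance,
#' scoring each setting like [autofocus], with a parabolic refinement per
#' axis.
#'
#' @param scope a [SimScope-class].
#' @param amplitude stigmation search half-range (default 1).
#' @param steps grid points per axis (default 5).
#' @inheritParams autofocus
#' @return list: `stig` (sx, sy), `score`.
#' @export
autoStig <- function(scope, amplitude = 1, steps = 5,
                     request = scanRequest(32, 64, 4000),
                     gridDims = c(40, 40), topFraction = 0.02) {
  offs <- seq(-amplitude, amplitude, length.out = steps)
  best <- NULL
  scoreAt <- function(sx, sy) {
    setStigmation(scope, sx, sy)
    img <- scanImage(scope, request)
    qualityCheck(img@data, gridDims, topFraction)@score
  }
  grid <- matrix(NA_real_, steps, steps)
  for (i in seq_len(steps)) {
    for (j in seq_len(steps)) {
      grid[i, j] <- scoreAt(offs[i], offs[j])
      if (is.null(best) || grid[i, j] > best$score) {
        best <- list(sx = offs[i], sy = offs[j], score = grid[i, j],
                     i = i, j = j)
      }
    }
  }
  step <- offs[2] - offs[1]
  sx <- best$sx
  sy <- best$sy
  if (best$i > 1 && best$i < steps) {
    sx <- sx + step * parabolicPeak(grid[best$i - 1, best$j], best$score,
                                    grid[best$i + 1, best$j])
  }
  if (best$j > 1 && best$j < steps) {
    sy <- sy + step * parabolicPeak(grid[best$i, best$j - 1], best$score,
                                    grid[best$i, best$j + 1])
  }
  setStigmation(scope, sx, sy)
  list(stig = c(sx, sy), score = best$score)
}

#' Focus, stigmate, focus again
#'
#' The focus-stig-focus sequence used before imaging. With probability
#' `autofocusFailureRate` the simulated hardware settle silently fails,
#' leaving a working distance drawn uniformly from +/-10 um; the quality
#' gate during acquisition is what catches such failures and triggers a
#' refocus/retake.
#'
#' @param scope a [SimScope-class].
#' @param ... passed to [autofocus] / [autoStig].
#' @return list: `wdOffsetUm`, `stig`, `score`, `failed`.
#' @export
focusStigFocus <- function(scope, ...) {
  f1 <- autofocus(scope, ...)
  st <- autoStig(scope)
  f2 <- autofocus(scope, ...)
  out <- list(wdOffsetUm = f2$wdOffsetUm, stig = st$stig, score = f2$score,
              failed = f1$failed && f2$failed)
  rate <- scope@params$autofocusFailureRate
  if (rate > 0) {
    bad <- scopeDraw(scope, function() stats::runif(1) < rate)
    if (bad) {
      wd <- scopeDraw(scope, function() stats::runif(1, -10, 10))
      setWorkingDistance(scope, wd)
    }
  }
  out
}

#' Fit a focus plane z = a x + b y + c
#'
#' Least-squares plane through >= 3 non-collinear focus measurements; exact
#' interpolant for 3 points. Used by the 3 x 3-grid focusing strategy to
#' predict the optimal working distance at every tile of a large montage.
#'
#' @param points matrix/data.frame with columns (x_um, y_um, z_um), >= 3
#'   non-collinear rows.
#' @return a [FocusPlane-class].
#' @export
fitFocusPlane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("at least 3 focus points are required")
  X <- cbind(points[, 1], points[, 2], 1)
  if (qr(X)$rank < 3) stop("focus points are collinear")
  cf <- qr.solve(X, points[, 3])
  new("FocusPlane", a = cf[1], b = cf[2], c = cf[3])
}

#' Predict focus from a plane
#' @param plane a [FocusPlane-class].
#' @param xUm,yUm stage position(s).
#' @export
predictFocus <- function(plane, xUm, yUm) {
  plane@a * xUm + plane@b * yUm + plane@c
}

setMethod("show", "FocusPlane", function(object) {
  cat(sprintf("FocusPlane: z = %.4g x + %.4g y + %.4g um\n",
              object@a, object@b, object@c))
})

#' Montage parameters
#'
#' @param tileFovUm tile field of view (square), micrometres.
#' @param tilePixels pixels per tile side.
#' @param rows,cols tile grid dimensions.
#' @param overlapUm overlap between adjacent tiles (default 4).
#' @param xOffsetUm,yOffsetUm montage centre offset from the aligned target
#'   point, in the montage (north-rotated) frame.
#' @param northAngleDeg montage frame rotation, applied as scan rotation so
#'   all sections are acquired in the same orientation.
#' @param dwellNs pixel dwell.
#' @param subsetMask logical rows x cols matrix (default: all tiles).
#' @param qualityThreshold per-tile quality gate (pass when score >= this).
#' @param focusStrategy "per_montage", "per_section" (focus-stig-focus,
#'   default), "plane_3x3" or "pooled_2x2".
#' @param ibsc use image-based stage correction at each section?
#' @param focusOffsetUm (x, y) offset of the autofocus point from the
#'   target, montage frame.
#' @return a [MontageParams-class].
#' @export
montageParams <- function(tileFovUm = 51.2, tilePixels = 512, rows = 1,
                          cols = 1, overlapUm = 4, xOffsetUm = 0,
                          yOffsetUm = 0, northAngleDeg = 0, dwellNs = 1000,
                          subsetMask = NULL, qualityThreshold = 0,
                          focusStrategy = "per_section", ibsc = TRUE,
                          focusOffsetUm = c(0, 0)) {
  if (is.null(subsetMask)) subsetMask <- matrix(TRUE, rows, cols)
  new("MontageParams", xOffsetUm = xOffsetUm, yOffsetUm = yOffsetUm,
      northAngleDeg = northAngleDeg, tileFovUm = tileFovUm,
      tilePixels = tilePixels, rows = rows, cols = cols,
      overlapUm = overlapUm, dwellNs = dwellNs, subsetMask = subsetMask,
      qualityThreshold = qualityThreshold, focusStrategy = focusStrategy,
      ibsc = ibsc, focusOffsetUm = focusOffsetUm)
}

#' Montage pitch and bounding box
#' @param params a [MontageParams-class].
#' @return list: `pitchUm`, `widthUm`, `heightUm` (bounding box of the full
#'   tile grid including the tile FOV).
#' @export
montageExtent <- function(params) {
  pitch <- params@tileFovUm - params@overlapUm
  list(pitchUm = pitch,
       widthUm = (params@cols - 1) * pitch + params@tileFovUm,
       heightUm = (params@rows - 1) * pitch + params@tileFovUm)
}

setMethod("show", "MontageParams", function(object) {
  ext <- montageExtent(object)
  cat(sprintf(
    "MontageParams: %d x %d tiles of %g um (%d px), overlap %g um -> %.1f x %.1f um; north %g deg; focus %s; IBSC %s\n",
    object@rows, object@cols, object@tileFovUm, as.integer(object@tilePixels),
    object@overlapUm, ext$widthUm, ext$heightUm, object@northAngleDeg,
    object@focusStrategy, if (object@ibsc) "on" else "off"))
})

#' Plan the tile grid of a montage
#'
#' Tile pitch is tile FOV minus overlap; the grid is centred at the target
#' plus the configured (x, y) offset, everything rotated by the north angle
#' (which is also applied as scan rotation during acquisition). Tiles
#' excluded by the subset mask are omitted. Tiles are ordered by ascending
#' distance from the focus spot so imaging starts where focus is freshest;
#' ties fall back to row-major order.
#'
#' @param params a [MontageParams-class].
#' @param targetStageUm (x, y) aligned target position on the stage.
#' @param focusSpotUm optional (x, y) of the focus spot (default: montage
#'   centre).
#' @return data.frame: row, col, x_um, y_um (tile centres), ordered for
#'   acquisition.
#' @export
planTiles <- function(params, targetStageUm, focusSpotUm = NULL) {
  ext <- montageExtent(params)
  pitch <- ext$pitchUm
  th <- deg2rad(params@northAngleDeg)
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centre <- as.numeric(targetStageUm) +
    as.vector(Rm %*% c(params@xOffsetUm, params@yOffsetUm))
  rows <- list()
  for (r in seq_len(params@rows)) {
    for (cI in seq_len(params@cols)) {
      if (!params@subsetMask[r, cI]) next
      u <- (cI - (params@cols + 1) / 2) * pitch
      v <- (r - (params@rows + 1) / 2) * pitch
      p <- centre + as.vector(Rm %*% c(u, v))
      rows[[length(rows) + 1L]] <- data.frame(
        row = r, col = cI, x_um = p[1], y_um = p[2])
    }
  }
  tiles <- do.call(rbind, rows)
  fs <- if (is.null(focusSpotUm)) centre else as.numeric(focusSpotUm)
  d <- sqrt((tiles$x_um - fs[1])^2 + (tiles$y_um - fs[2])^2)
  tiles <- tiles[order(round(d, 9), tiles$row, tiles$col), , drop = FALSE]
  rownames(tiles) <- NULL
  tiles
}

#' Recover the wafer-to-stage transform after a reload
#'
#' Drives to each mapped fiducial position (through the coarse offset the
#' operator set), re-images at low then high resolution, cross-correlates
#' with the stored fiducial images to measure where each fiducial actually
#' sits, and fits a least-squares rigid transform (rotation + translation)
#' from mapped to current stage coordinates. This transform translates
#' between wafer-map space and stage space for the rest of the session.
#'
#' @param scope a [SimScope-class] (after [applyReload]).
#' @param storedFiducials fiducial list from [acquireFiducials] taken during
#'   mapping (>= 2 entries).
#' @param coarseOffset rigid [SimilarityTransform-class] roughly undoing the
#'   reload (operator's manual rotation/translation, within ~1 mm).
#' @param minScore fiducial correlation below this raises a
#'   "fiducial not found" error naming the corner.
#' @param residualWarnUm residual RMS above this sets a warning flag.
#' @return list: `transform` (mapped -> current stage), `residualRmsUm`,
#'   `scores`, `warn`.
#' @export
reloadCorrection <- function(scope, storedFiducials,
                             coarseOffset = rigidTransform(),
                             minScore = 0.2, residualWarnUm = 10) {
  if (length(storedFiducials) < 2) {
    stop("at least 2 stored fiducials are required")
  }
  mapped <- t(vapply(storedFiducials, function(f) f$positionUm, numeric(2)))
  measured <- matrix(NA_real_, nrow(mapped), 2)
  scores <- numeric(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    f <- storedFiducials[[i]]
    q <- as.vector(applyTransform(coarseOffset, mapped[i, ]))
    psLow <- f$low@pixelSizeUm
    reqLow <- scanRequest(dim(f$low@data)[c(2, 1)] * psLow,
                         dim(f$low@data)[c(2, 1)], f$low@meta$dwellNs)
    img <- scanAt(scope, q[1], q[2], reqLow)
    r <- measureShift(f$low@data, img@data, maxResidualPx = 4)
    if (r$score < minScore) {
      stop(sprintf("fiducial not found: corner %d (score %.2f)", i, r$score))
    }
    est <- q - c(r$dx, r$dy) * psLow
    psHigh <- f$high@pixelSizeUm
    reqHigh <- scanRequest(dim(f$high@data)[c(2, 1)] * psHigh,
                          dim(f$high@data)[c(2, 1)], f$high@meta$dwellNs)
    img2 <- scanAt(scope, est[1], est[2], reqHigh)
    r2 <- measureShift(f$high@data, img2@data, maxResidualPx = 4)
    if (r2$score < minScore) {
      stop(sprintf("fiducial not found: corner %d (high-res score %.2f)",
                   i, r2$score))
    }
    measured[i, ] <- est - c(r2$dx, r2$dy) * psHigh
    scores[i] <- min(r$score, r2$score)
  }
  fit <- fitSimilarity(mapped, measured, rigid = TRUE)
  list(transform = fit$transform, residualRmsUm = fit$residualRms,
       scores = scores, warn = fit$residualRms > residualWarnUm)
}

#' Image-based stage correction at a target
#'
#' Takes a quick scan at the commanded target position under overview-like
#' conditions, band-passes both the scan and the stored aligned subregion
#' window with a difference-of-Gaussians filter tuned to cell-body scales,
#' and cross-correlates them; the offset is applied as a stage correction
#' and verified with a second scan (at most `maxIter` correction
#' iterations). The residual of the verification scan is reported and
#' logged by the acquisition loop.
#'
#' @param scope a [SimScope-class].
#' @param targetStageUm commanded stage position of the target.
#' @param windowImage stored aligned subregion image (from
#'   [alignTargetPoints]).
#' @param pixelSizeUm pixel size of `windowImage` (overview conditions).
#' @param dogSigmaUm the two difference-of-Gaussians scales in micrometres
#'   (default c(5, 12), cell-body scale).
#' @param dwellNs dwell for the quick scans.
#' @param maxIter correction iterations (default 2).
#' @param minScore below this correlation on every attempt the section is
#'   flagged and acquisition proceeds at the uncorrected position.
#' @param sectionRotationDeg the section's rotation in the aligned stack
#'   frame; the stored (stack-frame) window is derotated by this amount so
#'   it matches the unrotated quick scan.
#' @return list: `correctionUm` (x, y to add to the commanded position),
#'   `residualUm`, `score`, `flagged`, `iterations`.
#' @export
ibsc <- function(scope, targetStageUm, windowImage, pixelSizeUm,
                 dogSigmaUm = c(5, 12), dwellNs = 1000, maxIter = 2,
                 minScore = 0.2, sectionRotationDeg = 0) {
  if (sectionRotationDeg != 0) {
    windowImage <- rotateImage(windowImage, -sectionRotationDeg)
  }
  w <- dim(windowImage)
  req <- scanRequest(c(w[2], w[1]) * pixelSizeUm, c(w[2], w[1]), dwellNs)
  s1 <- dogSigmaUm[1] / pixelSizeUm
  s2 <- dogSigmaUm[2] / pixelSizeUm
  refF <- dogFilter(windowImage, s1, s2)
  pos <- as.numeric(targetStageUm)
  correction <- c(0, 0)
  residual <- NA_real_
  score <- 0
  flagged <- FALSE
  iterations <- 0L
  for (it in seq_len(maxIter)) {
    img <- scanAt(scope, pos[1], pos[2], req)
    r <- measureShift(refF, dogFilter(img@data, s1, s2))
    score <- max(score, r$score)
    if (r$score < minScore) {
      if (it == 1L) {
        ## one more attempt, then give up uncorrected
        img <- scanAt(scope, pos[1], pos[2], req)
        r <- measureShift(refF, dogFilter(img@data, s1, s2))
        score <- max(score, r$score)
      }
      if (r$score < minScore) {
        flagged <- TRUE
        break
      }
    }
    offUm <- -c(r$dx, r$dy) * pixelSizeUm
    residual <- sqrt(sum(offUm^2))
    iterations <- it
    if (residual <= 0.75 * pixelSizeUm && it > 1L) break
    pos <- pos + offUm
    correction <- correction + offUm
  }
  list(correctionUm = correction, residualUm = residual, score = score,
       flagged = flagged, iterations = iterations)
}

## block-mean downscale by integer factor (pads the tail by truncation)
downscaleMean <- function(img, f) {
  if (f <= 1) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- matrix(0, nr / f, nc / f)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      m <- m + img[seq(i, nr, by = f), seq(j, nc, by = f)]
    }
  }
  m / f^2
}

#' Stage-stitched montage preview
#'
#' Pastes tiles at their planned grid positions (no feature-based
#' stitching), downscaled, and records per-tile pass/fail for a green/red
#' quality overlay. Missing tiles leave a background hole and are flagged.
#'
#' @param tiles named list of tile matrices, names "r_c" (row_col); NULL or
#'   absent entries are holes.
#' @param params the [MontageParams-class] used for acquisition.
#' @param downscale integer downscale factor (default 4).
#' @param pass named logical vector (names "r_c"): quality gate outcome.
#' @return list: `image` (matrix), `pixelSizeUm`, `tiles` (data.frame with
#'   row, col, present, pass and pixel rectangle), `holes` flag.
#' @export
stitchPreview <- function(tiles, params, downscale = 4, pass = NULL) {
  ext <- montageExtent(params)
  psTile <- params@tileFovUm / params@tilePixels
  psOut <- psTile * downscale
  W <- ceiling(ext$widthUm / psOut)
  H <- ceiling(ext$heightUm / psOut)
  canvas <- matrix(0, H, W)
  rows <- list()
  holes <- FALSE
  pitch <- ext$pitchUm
  for (r in seq_len(params@rows)) {
    for (cI in seq_len(params@cols)) {
      if (!params@subsetMask[r, cI]) next
      key <- sprintf("%d_%d", r, cI)
      tl <- tiles[[key]]
      x0 <- (cI - 1) * pitch / psOut
      y0 <- (r - 1) * pitch / psOut
      px <- round(params@tilePixels / downscale)
      present <- !is.null(tl)
      if (present) {
        d <- downscaleMean(tl, downscale)
        ri <- round(y0) + seq_len(nrow(d))
        ci <- round(x0) + seq_len(ncol(d))
        ri <- ri[ri <= H]; ci <- ci[ci <= W]
        canvas[ri, ci] <- d[seq_along(ri), seq_along(ci)]
      } else {
        holes <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        row = r, col = cI, present = present,
        pass = if (is.null(pass)) NA else isTRUE(pass[[key]]),
        px0 = round(x0) + 1, py0 = round(y0) + 1, pxw = px, pxh = px)
    }
  }
  list(image = canvas, pixelSizeUm = psOut, tiles = do.call(rbind, rows),
       holes = holes)
}

#' Write a preview as PNG with a green/red quality overlay
#' @param preview result of [stitchPreview].
#' @param path output PNG path.
#' @export
writePreviewPNG <- function(preview, path) {
  img <- preview$image
  rgb <- array(rep(img, 3), c(dim(img), 3))
  tl <- preview$tiles
  for (i in seq_len(nrow(tl))) {
    if (is.na(tl$pass[i])) next
    ri <- tl$py0[i]:min(tl$py0[i] + tl$pxh[i] - 1, nrow(img))
    ci <- tl$px0[i]:min(tl$px0[i] + tl$pxw[i] - 1, ncol(img))
    edge <- c(ri[1], ri[length(ri)])
    chan <- if (tl$pass[i]) 2L else 1L  # green pass, red fail
    rgb[edge, ci, chan] <- 1
    rgb[ri, c(ci[1], ci[length(ci)]), chan] <- 1
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Write montage parameters as a JSON configuration
#' @param params a [MontageParams-class].
#' @param path output JSON path.
#' @export
writeMontageConfig <- function(params, path) {
  jsonlite::write_json(
    list(formatVersion = 1L,
         xOffsetUm = params@xOffsetUm, yOffsetUm = params@yOffsetUm,
         northAngleDeg = params@northAngleDeg, tileFovUm = params@tileFovUm,
         tilePixels = params@tilePixels, rows = params@rows,
         cols = params@cols, overlapUm = params@overlapUm,
         dwellNs = params@dwellNs,
         subsetMask = params@subsetMask,
         qualityThreshold = params@qualityThreshold,
         focusStrategy = params@focusStrategy, ibsc = params@ibsc,
         focusOffsetUm = params@focusOffsetUm),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a montage configuration written by [writeMontageConfig]
#' @param path JSON path.
#' @return a [MontageParams-class].
#' @export
readMontageConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  montageParams(tileFovUm = j$tileFovUm, tilePixels = j$tilePixels,
                rows = j$rows, cols = j$cols, overlapUm = j$overlapUm,
                xOffsetUm = j$xOffsetUm, yOffsetUm = j$yOffsetUm,
                northAngleDeg = j$northAngleDeg, dwellNs = j$dwellNs,
                subsetMask = matrix(as.logical(t(j$subsetMask)),
                                    j$rows, j$cols, byrow = TRUE),
                qualityThreshold = j$qualityThreshold,
                focusStrategy = j$focusStrategy, ibsc = j$ibsc,
                focusOffsetUm = as.numeric(j$focusOffsetUm))
}
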