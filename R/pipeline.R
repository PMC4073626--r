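# Acquisition driver: per-section montage imaging with reload correction,
# IBSC, focus strategies, quality gating with retakes, resumability and
# logging; plus a desk-scale end-to-end simulation of the whole workflow.

tileFileName <- function(r, c) sprintf("tile_r%02d_c%02d.tif", r, c)

#' Stage position of the aligned target on one section
#'
#' Converts the aligned target's overview pixel position into stage
#' coordinates using the overview pose, the pixel-to-stage calibration
#' factor, and (after a reload) the recovered wafer-to-stage transform.
#'
#' @param stack an [OverviewStack-class].
#' @param targets an [AlignedTargetList-class].
#' @param label section label.
#' @param poses data.frame: label, x_um, y_um (commanded overview centres).
#' @param calibFactor pixel-to-stage calibration factor.
#' @param reloadTf rigid [SimilarityTransform-class] from map space to the
#'   current stage (identity before any reload).
#' @return (x, y) stage position.
#' @export
targetStageFor <- function(stack, targets, label, poses, calibFactor = 1,
                           reloadTf = rigidTransform()) {
  i <- match(label, stack@labels)
  j <- match(label, poses$label)
  if (is.na(i) || is.na(j)) stop(sprintf("unknown section %s", label))
  img <- stack@images[[i]]
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  px <- targetPixelOn(stack, targets, label)
  p0 <- c(poses$x_um[j], poses$y_um[j]) +
    (px - ctr) * stack@pixelSizeUm * calibFactor
  as.vector(applyTransform(reloadTf, p0))
}

#' Acquire quality-gated montages for a set of sections
#'
#' For each section in tape order: drive to the aligned target (optionally
#' refined by image-based stage correction), choose a focus spot, focus
#' according to the configured strategy, then acquire the planned tiles.
#' Each tile is written (with a JSON sidecar) before the next is scanned;
#' failing the quality gate triggers one refocus-and-retake, a second
#' failure flags the tile and acquisition continues. Sections whose complete
#' tile set already exists on disk are skipped, which makes an interrupted
#' run resumable; the scope's noise stream is reseeded per section so a
#' resumed run produces files identical to an uninterrupted one.
#'
#' @param scope a [SimScope-class].
#' @param stack an [OverviewStack-class].
#' @param targets an [AlignedTargetList-class].
#' @param params a [MontageParams-class].
#' @param outDir montage output directory (`S%04d/tile_r%02d_c%02d.tif`).
#' @param poses overview pose table (see [targetStageFor]).
#' @param calibFactor pixel-to-stage factor.
#' @param reloadTf recovered reload transform.
#' @param labels subset of section labels to acquire (default: all).
#' @param qualityCheckOn gate tiles on the quality score?
#' @param resume skip sections with a complete tile set?
#' @param seedBase base for the per-section scope reseed.
#' @param logPath JSON-lines log (default `log.jsonl` in `outDir`).
#' @param previews write a stage-stitched preview per section?
#' @return data.frame: one row per tile with section, row, col, file,
#'   quality, retakes, status.
#' @export
acquireMontage <- function(scope, stack, targets, params, outDir, poses,
                           calibFactor = 1, reloadTf = rigidTransform(),
                           labels = NULL, qualityCheckOn = TRUE,
                           resume = TRUE, seedBase = 0,
                           logPath = file.path(outDir, "log.jsonl"),
                           previews = TRUE) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create montage output directory")
  }
  if (is.null(labels)) labels <- stack@labels
  tileReq <- scanRequest(params@tileFovUm, params@tilePixels,
                         params@dwellNs)
  ps <- stack@pixelSizeUm
  results <- list()
  for (label in sort(labels)) {
    secDir <- file.path(outDir, sprintf("S%04d", label))
    planned0 <- planTiles(params, c(0, 0))
    files <- file.path(secDir, tileFileName(planned0$row, planned0$col))
    if (resume && all(file.exists(files))) {
      writeLogEvent(logPath, list(event = "section_skipped",
                                  section = label, reason = "complete"))
      next
    }
    dir.create(secDir, recursive = TRUE, showWarnings = FALSE)
    ## reseed and reset instrument state per section: a resumed run then
    ## reproduces an uninterrupted run bit for bit
    reseedScope(scope, seedBase + 1009 * label)
    setWorkingDistance(scope, 0)
    setStigmation(scope, 0, 0)
    setScanRotation(scope, 0)
    secOK <- TRUE
    tryCatch({
      tStage <- targetStageFor(stack, targets, label, poses, calibFactor,
                               reloadTf)
      writeLogEvent(logPath, list(event = "move_to_section",
                                  section = label,
                                  stage = round(tStage, 3)))
      j <- match(label, targets@entries$label)
      if (params@ibsc && !is.null(targets@windows[[j]])) {
        ib <- ibsc(scope, tStage, targets@windows[[j]], ps,
                   dwellNs = params@dwellNs,
                   sectionRotationDeg = alignments(stack)$thetaDeg[
                     match(label, stack@labels)])
        if (!ib$flagged) {
          tStage <- tStage + ib$correctionUm
        }
        writeLogEvent(logPath, list(
          event = "ibsc", section = label,
          correctionUm = round(ib$correctionUm, 3),
          residualUm = round(ib$residualUm, 3), score = round(ib$score, 3),
          flagged = ib$flagged))
      }
      ## focus spot: most contrast-rich block of a quick overview-scale scan
      fprobe <- scanAt(scope, tStage[1], tStage[2],
                       scanRequest(64 * ps, 64, params@dwellNs))
      spot <- chooseFocusSpot(fprobe@data, blockPx = 16)
      fsStage <- tStage + (c(spot$col, spot$row) - (64 + 1) / 2) * ps +
        params@focusOffsetUm
      setScanRotation(scope, params@northAngleDeg)
      tiles <- planTiles(params, tStage, fsStage)
      plane <- NULL
      focusScore <- NA_real_
      if (params@focusStrategy == "per_section") {
        moveStage(scope, fsStage[1], fsStage[2])
        f <- focusStigFocus(scope, steps = 9)
        focusScore <- f$score
      } else if (params@focusStrategy == "per_montage") {
        moveStage(scope, fsStage[1], fsStage[2])
        f <- autofocus(scope, steps = 9)
        focusScore <- f$score
      } else if (params@focusStrategy == "plane_3x3") {
        ext <- montageExtent(params)
        pts <- list()
        for (gy in c(-1, 0, 1)) {
          for (gx in c(-1, 0, 1)) {
            p <- tStage + c(gx * ext$widthUm, gy * ext$heightUm) / 3
            moveStage(scope, p[1], p[2])
            f <- autofocus(scope, steps = 9)
            pts[[length(pts) + 1L]] <- c(p, f$wdOffsetUm)
          }
        }
        plane <- fitFocusPlane(do.call(rbind, pts))
      }
      writeLogEvent(logPath, list(event = "focus", section = label,
                                  strategy = params@focusStrategy,
                                  score = round(focusScore, 5)))
      lastPool <- NULL
      pass <- list()
      tileImgs <- list()
      for (k in seq_len(nrow(tiles))) {
        tr <- tiles$row[k]; tc <- tiles$col[k]
        tpos <- c(tiles$x_um[k], tiles$y_um[k])
        if (!is.null(plane)) {
          setWorkingDistance(scope, predictFocus(plane, tpos[1], tpos[2]))
        } else if (params@focusStrategy == "pooled_2x2") {
          pool <- c(ceiling(tr / 2), ceiling(tc / 2))
          if (!identical(pool, lastPool)) {
            moveStage(scope, tpos[1], tpos[2])
            f <- autofocus(scope, steps = 9)
            lastPool <- pool
          }
        }
        moveStage(scope, tpos[1], tpos[2])
        img <- scanImage(scope, tileReq)
        retakes <- 0L
        q <- NA_real_
        ok <- TRUE
        if (qualityCheckOn) {
          qr <- qualityCheck(img@data, threshold = params@qualityThreshold)
          q <- qr@score
          if (!qr@pass) {
            ## refocus and retake once
            moveStage(scope, fsStage[1], fsStage[2])
            autofocus(scope, steps = 9)
            moveStage(scope, tpos[1], tpos[2])
            img <- scanImage(scope, tileReq)
            qr <- qualityCheck(img@data,
                               threshold = params@qualityThreshold)
            q <- qr@score
            retakes <- 1L
            ok <- qr@pass
          }
        }
        file <- file.path(secDir, tileFileName(tr, tc))
        img@meta$quality <- q
        img@meta$retakes <- retakes
        writeScanImage(img, file)
        tileImgs[[sprintf("%d_%d", tr, tc)]] <- img@data
        pass[[sprintf("%d_%d", tr, tc)]] <- ok
        status <- if (!qualityCheckOn) "pass"
          else if (ok) "pass" else "failed_after_retries"
        writeLogEvent(logPath, list(
          event = "tile", section = label, tile = c(tr, tc),
          stage = round(tpos, 3),
          wdUm = round(scope@state$wdOffsetUm, 3),
          quality = if (is.na(q)) NULL else round(q, 6),
          retakes = retakes, status = status))
        results[[length(results) + 1L]] <- data.frame(
          section = label, row = tr, col = tc, file = file, quality = q,
          retakes = retakes, status = status)
      }
      if (previews) {
        pv <- stitchPreview(tileImgs, params,
                            pass = if (qualityCheckOn) unlist(pass) else NULL)
        writePreviewPNG(pv, file.path(secDir, "preview.png"))
      }
    }, error = function(e) {
      secOK <<- FALSE
      writeLogEvent(logPath, list(event = "section_failed", section = label,
                                  error = conditionMessage(e)))
    })
    if (secOK) {
      writeLogEvent(logPath, list(event = "section_done", section = label))
    }
  }
  if (length(results)) do.call(rbind, results) else
    data.frame(section = integer(0), row = integer(0), col = integer(0),
               file = character(0), quality = numeric(0),
               retakes = integer(0), status = character(0))
}

#' Desk-scale end-to-end simulation of the full workflow
#'
#' Builds a small synthetic UTSL (one wafer), runs the complete pipeline --
#' optical wafer image, threshold + automap + tape-order numbering,
#' pixel-to-stage calibration, fiducial imaging, section overviews, stack
#' alignment, target-point alignment, wafer reload with fiducial-based
#' correction, and IBSC-corrected montage acquisition -- and evaluates the
#' achieved targeting against the phantom's ground truth.
#'
#' Image sizes are deliberately small (sections of a few hundred
#' micrometres, ~1 um overview pixels, one 20 um tile per section) so the
#' whole run takes minutes on a desktop while preserving every coordinate
#' hand-off of the full-scale workflow.
#'
#' @param seed master seed for phantom, scene, scope and reload.
#' @param nSections sections on the wafer (default 30).
#' @param outDir working directory for the UTSL store (default: a fresh
#'   temporary directory).
#' @param simP simulation parameters (default [simParams]).
#' @param montage montage parameters (default: one 20 um, 128 px tile with
#'   IBSC and quality gating).
#' @param keepScope return the scope for further inspection?
#' @return list: `residualUm` (per-section distance from the ground-truth
#'   target point to the achieved central-tile centre), `fracWithin2um`,
#'   `automapCorrect`, `calibFactor`, `reloadResidualUm`, `tiles`,
#'   `outDir`, and optionally `scope`.
#' @export
simulateEnd2End <- function(seed = 1L, nSections = 30, outDir = NULL,
                            simP = simParams(),
                            montage = montageParams(
                              tileFovUm = 20, tilePixels = 128, rows = 1,
                              cols = 1, overlapUm = 4, dwellNs = 8000,
                              qualityThreshold = 0.07,
                              focusStrategy = "per_section", ibsc = TRUE),
                            keepScope = FALSE) {
  if (is.null(outDir)) {
    outDir <- file.path(tempfile("utsl"), "store")
  }
  secW <- 240; secH <- 180
  lay <- waferLayout(nStrips = 3, nSections = nSections,
                     sectionWidthUm = secW, sectionHeightUm = secH,
                     alongPitchUm = secW + 80, stripPitchUm = 4 * secH,
                     jitterSdUm = 20, jitterSdDeg = 2, debrisCount = 1)
  ph <- makeTissuePhantom(extentUm = c(600, 600, 10), seed = seed)
  scene <- makeWaferScene(ph, lay, seed = seed + 1L,
                          surface = waferSurface(amplitudeUm = 5))
  scope <- simScope(scene, simP, seed = seed + 2L)
  rec <- initUtsl(outDir, list(name = "end2end", masterSeed = seed),
                  force = TRUE)
  ## --- wafer mapping: optical image, threshold, automap, numbering
  psMap <- 10
  nMap <- 512
  wimg <- renderScene(scene, c(0, 0), psMap, nMap, nMap, style = "optical")
  ## register render to stage space from three known correspondences (the
  ## programmatic equivalent of clicking fiducial points on the wafer image)
  ctrMap <- (nMap + 1) / 2
  pix <- rbind(c(ctrMap, ctrMap), c(ctrMap + 100, ctrMap),
               c(ctrMap, ctrMap + 80))
  stg <- (pix - ctrMap) * psMap
  mapTf <- fitSimilarity(pix, stg)$transform
  mask <- thresholdMask(wimg, 0.5, 1)
  ex <- matrix(TRUE, round(secH / psMap), round(secW / psMap))
  det <- automapSections(mask, ex, rotationRangeDeg = 9,
                         rotationStepDeg = 3)
  stgDet <- applyTransform(mapTf, as.matrix(det[, c("col", "row")]))
  det$x_um <- stgDet[, 1]; det$y_um <- stgDet[, 2]
  det$status <- "auto"
  labeled <- numberSections(det, stripModel(gapUm = 300),
                            sectionHeightUm = secH)
  truth <- sectionTruth(scene)
  automapCorrect <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((labeled$x_um - truth$x_um[i])^2 +
                (labeled$y_um - truth$y_um[i])^2)
    k <- which.min(d)
    if (d[k] < secW / 2 && labeled$label[k] == truth$collectOrder[i]) {
      automapCorrect <- automapCorrect + 1L
    }
  }
  ## --- calibration (focused first) and fiducials
  moveStage(scope, labeled$x_um[1], labeled$y_um[1])
  autofocus(scope, steps = 9)
  cal <- calibratePixelToStage(
    scope, c(labeled$x_um[1], labeled$y_um[1]), stepUm = 60,
    request = scanRequest(160, 160, 4000))
  fids <- acquireFiducials(scope, as.matrix(scene@fiducials[, c("x_um",
                                                                "y_um")]),
                           lowPx = 512, highPx = 192)
  ## --- section overviews
  ovP <- overviewParams(pixelSizeUm = 1, marginUm = 40, dwellNs = 2000)
  ovDir <- file.path(outDir, "wafers", "W01", "overviews")
  man <- acquireOverviews(scope, labeled, ovDir, ovP, secW, secH)
  images <- lapply(man$label, function(l) {
    readScanImage(file.path(ovDir, sprintf("S%04d.tif", l)))@data
  })
  names(images) <- man$label
  ## --- stack alignment and target setup
  stack <- alignOverviewStack(images, ovP$pixelSizeUm, template = 1L,
                              rotRangeDeg = 8, rotStepDeg = 1)
  tmplImg <- images[["1"]]
  targetPoint <- c((ncol(tmplImg) + 1) / 2 + 20,
                   (nrow(tmplImg) + 1) / 2 - 12)
  targets <- alignTargetPoints(stack, targetPoint, windowPx = 96,
                               runningDepth = 10)
  writeTargetList(targets, file.path(outDir, "targets", "t1"))
  ## --- reload and correction
  truthReload <- applyReload(scope, seed = seed + 3L)
  coarse <- rigidTransform(truthReload@thetaDeg + 0.03,
                           truthReload@tx + 150, truthReload@ty - 120)
  rc <- reloadCorrection(scope, fids, coarse)
  ## --- montage acquisition
  monDir <- file.path(outDir, "montages", "t1", "W01")
  tiles <- acquireMontage(scope, stack, targets, montage, monDir,
                          poses = man, calibFactor = cal$factor,
                          reloadTf = rc$transform, seedBase = seed * 17)
  ## --- ground-truth evaluation
  ## reference tissue point: target pixel on the template section mapped
  ## through the template overview's actual pose and true section pose
  evalTruth <- evaluateTargeting(scope, scene, stack, targets, man, tiles,
                                 montage)
  out <- list(residualUm = evalTruth$residualUm,
              fracWithin2um = mean(evalTruth$residualUm <= 2),
              automapCorrect = automapCorrect, nSections = nrow(truth),
              calibFactor = cal$factor,
              reloadResidualUm = rc$residualRmsUm,
              reloadErrorUm = sqrt(sum((c(rc$transform@tx, rc$transform@ty) -
                                          c(truthReload@tx,
                                            truthReload@ty))^2)),
              tiles = tiles, stack = stack, targets = targets,
              outDir = outDir)
  if (keepScope) out$scope <- scope
  out
}

#' Ground-truth targeting evaluation of an acquired montage set
#'
#' Uses simulator-held truth (true section poses, the stage error field and
#' the true reload transform) to measure, per section, the distance between
#' the achieved central-tile centre and the true stage position of the
#' target tissue point. Test/evaluation support; a real microscope offers
#' no such oracle.
#'
#' @param scope the [SimScope-class] used for acquisition (reload applied).
#' @param scene the [WaferScene-class].
#' @param stack,targets,poses,tiles,params the acquisition inputs/outputs.
#' @return list: `residualUm` (one value per acquired section).
#' @export
evaluateTargeting <- function(scope, scene, stack, targets, poses, tiles,
                              params) {
  truth <- sectionTruth(scene)
  ps <- stack@pixelSizeUm
  tmplLabel <- stack@templateLabel
  it <- match(tmplLabel, stack@labels)
  jt <- match(tmplLabel, poses$label)
  img <- stack@images[[it]]
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  cmd <- c(poses$x_um[jt], poses$y_um[jt])
  actual <- cmd + stageErrorField(scope, cmd[1], cmd[2])
  ## target pixel on the template -> stage at map time -> tissue-local
  pxT <- targetPixelOn(stack, targets, tmplLabel)
  qStage <- actual + (pxT - ctr) * ps
  kt <- which(truth$collectOrder == tmplLabel)
  thT <- deg2rad(truth$thetaDeg[kt])
  d <- qStage - c(truth$x_um[kt], truth$y_um[kt])
  tissueLocal <- c(cos(thT) * d[1] + sin(thT) * d[2],
                   -sin(thT) * d[1] + cos(thT) * d[2])
  reload <- reloadTruth(scope)
  ## central tile of each section
  ctile <- tiles[tiles$row == ceiling(params@rows / 2) &
                   tiles$col == ceiling(params@cols / 2), , drop = FALSE]
  res <- numeric(nrow(ctile))
  for (i in seq_len(nrow(ctile))) {
    k <- which(truth$collectOrder == ctile$section[i])
    th <- deg2rad(truth$thetaDeg[k])
    p <- c(truth$x_um[k], truth$y_um[k]) +
      c(cos(th) * tissueLocal[1] - sin(th) * tissueLocal[2],
        sin(th) * tissueLocal[1] + cos(th) * tissueLocal[2])
    pTrue <- as.vector(applyTransform(reload, p))
    side <- jsonlite::read_json(sub("\\.tif$", ".json", ctile$file[i]),
                                simplifyVector = TRUE)
    cmdT <- as.numeric(side$centerUm)
    achieved <- cmdT + stageErrorField(scope, cmdT[1], cmdT[2])
    res[i] <- sqrt(sum((achieved - pTrue)^2))
  }
  list(residualUm = res)
}

#' Automatic section-mapping study on synthetic wafers
#'
#' Renders default-scale synthetic wafers (162 jittered sections in 10
#' strips, debris distractors), runs threshold masking, rotated-example
#' matching and tape-order numbering, and scores each wafer: a section
#' counts as correct when a detection lies within half a section width of
#' its true centroid and carries its true tape-order label.
#'
#' @param seeds integer vector, one synthetic wafer per seed.
#' @param phantomSeed seed of the shared tissue phantom.
#' @param heatThreshold,rotationRangeDeg,rotationStepDeg automap settings.
#' @return data.frame: seed, correct, total, pct.
#' @export
automapWaferStudy <- function(seeds, phantomSeed = 2L, heatThreshold = 0.8,
                              rotationRangeDeg = 15, rotationStepDeg = 3) {
  lay <- waferLayout()
  phantom <- makeTissuePhantom(seed = phantomSeed)
  rows <- lapply(seeds, function(seed) {
    scene <- makeWaferScene(phantom, lay, seed = seed)
    psMap <- 100
    nMap <- 1024
    img <- renderScene(scene, c(0, 0), psMap, nMap, nMap,
                       style = "optical")
    mask <- thresholdMask(img, 0.55, 1)
    ex <- matrix(TRUE, round(lay$sectionHeightUm / psMap),
                 round(lay$sectionWidthUm / psMap))
    det <- automapSections(mask, ex, rotationRangeDeg, rotationStepDeg,
                           heatThreshold)
    det$x_um <- (det$col - (nMap + 1) / 2) * psMap
    det$y_um <- (det$row - (nMap + 1) / 2) * psMap
    lab <- numberSections(det, stripModel(),
                          sectionHeightUm = lay$sectionHeightUm)
    truth <- sectionTruth(scene)
    ok <- 0L
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((lab$x_um - truth$x_um[i])^2 +
                  (lab$y_um - truth$y_um[i])^2)
    j <- which.min(d)
      if (d[j] < lay$sectionWidthUm / 2 &&
          lab$label[j] == truth$collectOrder[i]) {
        ok <- ok + 1L
      }
    }
    data.frame(seed = seed, correct = ok, total = nrow(truth),
               pct = 100 * ok / nrow(truth))
  })
  do.call(rbind, rows)
}
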