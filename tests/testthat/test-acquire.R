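# Quality metric, focus operations, reload correction, IBSC, tile planning,
# montage acquisition and previews.

test_that("kernel quality matches hand-computed pattern values", {
  expect_equal(kernelQuality(matrix(0.37, 3, 3)), 0)
  ## two bright rows flanking a dark row: strong line contrast
  membrane <- matrix(c(9, 0, 9, 9, 0, 9, 9, 0, 9), 3, 3)
  expect_equal(kernelQuality(membrane), 18 - 4.87 * 2.7, tolerance = 1e-6)
  ## unit checkerboard: pure interleaved contrast is penalised
  board <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3)
  expect_equal(kernelQuality(board), 4 / 3 - 4.87, tolerance = 1e-6)
  expect_error(kernelQuality(c(1, 2, 3)), "9 finite")
  expect_error(kernelQuality(matrix(c(NA, 1:8), 3, 3)), "9 finite")
})

test_that("the interleaved-pattern weight neutralises i.i.d. noise", {
  set.seed(123)
  n <- 1e6
  K <- matrix(rnorm(9 * n), ncol = 9)
  S <- abs(rowMeans(K[, c(1, 4, 7)]) - rowMeans(K[, c(2, 5, 8)])) +
    abs(rowMeans(K[, c(2, 5, 8)]) - rowMeans(K[, c(3, 6, 9)])) +
    abs(rowMeans(K[, 1:3]) - rowMeans(K[, 4:6])) +
    abs(rowMeans(K[, 4:6]) - rowMeans(K[, 7:9]))
  U <- abs(rowMeans(K[, c(1, 3, 5, 7, 9)]) - rowMeans(K[, c(2, 4, 6, 8)]))
  expect_gte(mean(S) / mean(U), 4.7)
  expect_lte(mean(S) / mean(U), 5.0)
})

test_that("the sparse quality grid has the configured shape and noise floor", {
  img <- matrix(0.4, 650, 650)
  q <- qualityCheck(img)
  expect_equal(dim(q@grid), c(200L, 200L))
  expect_equal(q@score, 0)
  ## mean grid q on pure noise is near zero relative to the noise sd
  set.seed(7)
  noisy <- matrix(rnorm(650 * 650, 0.5, 0.05), 650, 650)
  qn <- qualityCheck(noisy)
  expect_lt(abs(mean(qn@grid)), 0.05 * 0.05)
  ## small images reduce the grid instead of failing
  qs <- qualityCheck(matrix(runif(100), 10, 10))
  expect_equal(dim(qs@grid), c(8L, 8L))
  expect_error(qualityCheck(matrix(1, 2, 2)), "3 x 3")
  expect_error(qualityCheck(noisy, topFraction = 0), "topFraction")
})

test_that("quality strictly decreases along a blur ladder", {
  base <- phantomImage(n = 256, psUm = 0.3, seed = 5L)
  scores <- vapply(c(0, 1, 2, 4), function(s) {
    qualityCheck(if (s > 0) gaussBlur(base, s) else base)@score
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("the focus spot lands on texture and avoids flat regions", {
  set.seed(3)
  img <- matrix(0.5, 128, 128)
  img[1:64, 65:128] <- 0.5 + matrix(rnorm(64 * 64, 0, 0.1), 64)  # textured
  spot <- chooseFocusSpot(img, blockPx = 32)
  expect_true(spot$col > 64 && spot$row <= 64)
  expect_false(spot$lowContrast)
  ## uniform image: centre plus flag
  flat <- chooseFocusSpot(matrix(0.2, 64, 64), blockPx = 16)
  expect_true(flat$lowContrast)
  expect_equal(c(flat$col, flat$row), c(32.5, 32.5))
  ## a vessel-like flat disc embedded in texture is avoided
  tex <- phantomImage(n = 128, psUm = 0.5, seed = 31L)
  yy <- row(tex) - 64.5; xx <- col(tex) - 64.5
  tex[xx^2 + yy^2 < 30^2] <- mean(tex)
  spot2 <- chooseFocusSpot(tex, blockPx = 32)
  expect_gt(sqrt((spot2$col - 64.5)^2 + (spot2$row - 64.5)^2), 30)
})

test_that("autofocus recovers the surface height within a micron", {
  sc <- smallScene(surface = waferSurface(type = "plane", c = 8))
  scope <- simScope(sc, quietParams(noiseSigma1000 = 0.005), seed = 2L)
  s1 <- sc@sections[1, ]
  moveStage(scope, s1$x_um, s1$y_um)
  af <- autofocus(scope)
  expect_false(af$failed)
  expect_lt(abs(af$wdOffsetUm - 8), 1)
  expect_gte(af$score + 1e-9, max(af$sampled$score))
  ## surface outside the bracket: edge returned, flagged
  far <- makeWaferScene(smallPhantom(), smallLayout(),
                        seed = 8L, surface = waferSurface(type = "plane",
                                                          c = 40))
  scope2 <- simScope(far, quietParams(), seed = 2L)
  moveStage(scope2, s1$x_um, s1$y_um)
  af2 <- autofocus(scope2)
  expect_true(af2$failed)
  expect_equal(af2$wdOffsetUm, 25)
  expect_error(autofocus(scope, bracketUm = -1), "positive")
  expect_error(autofocus(scope, steps = 2), "3 steps")
})

test_that("focus planes fit exactly and reject degenerate input", {
  flatP <- fitFocusPlane(cbind(c(0, 5, 0), c(0, 0, 5), 3))
  expect_equal(c(flatP@a, flatP@b, flatP@c), c(0, 0, 3), tolerance = 1e-12)
  set.seed(2)
  x <- runif(9, -50, 50); y <- runif(9, -50, 50)
  pl <- fitFocusPlane(cbind(x, y, 0.01 * x - 0.02 * y + 5))
  expect_equal(c(pl@a, pl@b, pl@c), c(0.01, -0.02, 5), tolerance = 1e-9)
  expect_equal(predictFocus(pl, 10, 10), 0.01 * 10 - 0.02 * 10 + 5,
               tolerance = 1e-9)
  expect_error(fitFocusPlane(cbind(1:2, 1:2, 1:2)), "at least 3")
  expect_error(fitFocusPlane(cbind(1:5, 2 * (1:5) + 1, rnorm(5))),
               "collinear")
})

test_that("tile plans reproduce the montage geometry", {
  one <- planTiles(montageParams(tileFovUm = 50, tilePixels = 128), c(10, -5))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$x_um, one$y_um), c(10, -5))
  ## 3 x 5 grid of 51.2 um tiles with 4 um overlap
  mp <- montageParams(tileFovUm = 51.2, tilePixels = 12800, rows = 3,
                      cols = 5, overlapUm = 4)
  ext <- montageExtent(mp)
  expect_equal(ext$pitchUm, 47.2)
  expect_equal(ext$widthUm, 240.0)
  expect_equal(ext$heightUm, 145.6)
  tl <- planTiles(mp, c(0, 0))
  expect_equal(nrow(tl), 15L)
  expect_equal(tl$row[1], 2L)  # starts at the focus spot (montage centre)
  expect_equal(tl$col[1], 3L)
  ## subset mask: 3 of 21 excluded
  mask <- matrix(TRUE, 3, 7)
  mask[1, 1] <- mask[2, 4] <- mask[3, 7] <- FALSE
  sub <- planTiles(montageParams(tileFovUm = 51.2, tilePixels = 128,
                                 rows = 3, cols = 7, subsetMask = mask),
                   c(0, 0))
  expect_equal(nrow(sub), 18L)
  ## geometric coverage: with pitch = fov - overlap the tile footprints
  ## tile the nominal rectangle with overlap/2 of slack on every seam
  xs <- sort(unique(round(tl$x_um, 6)))
  expect_true(all(abs(diff(xs) - 47.2) < 1e-9))
  expect_error(montageParams(tileFovUm = 10, overlapUm = 10), "overlap")
  ## north angle rotates the whole grid
  rot <- planTiles(montageParams(tileFovUm = 50, tilePixels = 128, rows = 1,
                                 cols = 2, overlapUm = 4,
                                 northAngleDeg = 90), c(0, 0))
  expect_equal(diff(rot$x_um), 0, tolerance = 1e-9)
  expect_equal(abs(diff(rot$y_um)), 46, tolerance = 1e-9)
})

test_that("reload correction recovers the wafer-to-stage transform", {
  sc <- smallScene()
  scope <- simScope(sc, simParams(autofocusFailureRate = 0), seed = 4L)
  pos <- as.matrix(sc@fiducials[, c("x_um", "y_um")])
  fids <- acquireFiducials(scope, pos, lowPx = 256, highPx = 128)
  ## no reload, zero coarse offset: identity within (1 um, 0.02 deg)
  rc0 <- reloadCorrection(scope, fids)
  expect_lt(sqrt(rc0$transform@tx^2 + rc0$transform@ty^2), 1)
  expect_lt(abs(rc0$transform@thetaDeg), 0.02)
  expect_false(rc0$warn)
  ## fiducials from a different wafer are not found
  other <- smallScene(seed = 77L)
  scopeO <- simScope(other, simParams(autofocusFailureRate = 0), seed = 4L)
  fidsO <- acquireFiducials(scopeO, pos, lowPx = 256, highPx = 128)
  ## swap the stored high-res images for featureless background cutouts
  for (i in seq_along(fidsO)) {
    fidsO[[i]]$low@data <- matrix(0.15, 256, 256)
  }
  expect_error(reloadCorrection(scope, fidsO), "fiducial not found")
  expect_error(reloadCorrection(scope, fids[1]), "at least 2")
})

test_that("IBSC leaves an accurate target untouched and flags blank windows", {
  sc <- smallScene(surface = waferSurface(type = "flat"))
  scope <- simScope(sc, quietParams(noiseSigma1000 = 0.005), seed = 6L)
  s1 <- sc@sections[1, ]
  tpos <- c(s1$x_um, s1$y_um)
  ## stored window: noise-free render at the exact target
  win <- renderScene(sc, tpos, 1, 96, 96)
  ib <- ibsc(scope, tpos, win, 1, dwellNs = 4000)
  expect_false(ib$flagged)
  expect_lte(sqrt(sum(ib$correctionUm^2)), 1)
  ## featureless window: flagged, no correction applied
  blank <- matrix(0.5, 96, 96)
  ib2 <- ibsc(scope, tpos, blank, 1, dwellNs = 4000)
  expect_true(ib2$flagged)
  expect_equal(ib2$correctionUm, c(0, 0))
})

test_that("stage-stitched previews tile the grid without interior gaps", {
  mp <- montageParams(tileFovUm = 32, tilePixels = 64, rows = 2, cols = 2,
                      overlapUm = 4)
  tiles <- list()
  for (r in 1:2) for (cc in 1:2) {
    tiles[[sprintf("%d_%d", r, cc)]] <- matrix(0.4 + 0.1 * r, 64, 64)
  }
  pv <- stitchPreview(tiles, mp, downscale = 2,
                      pass = c(`1_1` = TRUE, `1_2` = TRUE, `2_1` = FALSE,
                               `2_2` = TRUE))
  expect_false(pv$holes)
  ## no background-filled interior pixels
  expect_true(all(pv$image > 0.3))
  ext <- montageExtent(mp)
  expect_equal(dim(pv$image),
               ceiling(c(ext$heightUm, ext$widthUm) / pv$pixelSizeUm))
  expect_equal(sum(!pv$tiles$pass), 1L)
  ## single tile preview is a block-mean downscaled copy of the tile
  tile1 <- matrix(runif(64^2), 64, 64)
  one <- stitchPreview(list(`1_1` = tile1),
                       montageParams(tileFovUm = 32, tilePixels = 64),
                       downscale = 2)
  expect_equal(dim(one$image), c(32, 32))
  expect_equal(one$image[1, 1], mean(tile1[1:2, 1:2]))
  ## missing tile leaves a flagged hole
  holey <- stitchPreview(tiles[-2], mp, downscale = 2)
  expect_true(holey$holes)
  expect_false(holey$tiles$present[holey$tiles$row == 1 &
                                     holey$tiles$col == 2])
  f <- tempfile(fileext = ".png")
  writePreviewPNG(pv, f)
  expect_true(file.exists(f))
})

test_that("montage acquisition writes gated tiles with terminal log records", {
  ## miniature end-to-end acquisition: 3 sections, 2 x 2 tiles
  sc <- smallScene(seed = 31L, surface = waferSurface(type = "flat"))
  scope <- simScope(sc, quietParams(noiseSigma1000 = 0.01), seed = 5L)
  truth <- sectionTruth(sc)[1:3, ]
  truth$label <- 1:3
  ovDir <- tempfile("ov")
  ovP <- overviewParams(pixelSizeUm = 1, marginUm = 30, dwellNs = 2000)
  man <- acquireOverviews(scope, truth, ovDir, ovP, 240, 180,
                          autofocusEach = FALSE)
  images <- lapply(man$label, function(l) {
    scanData(readScanImage(file.path(ovDir, sprintf("S%04d.tif", l))))
  })
  names(images) <- man$label
  stack <- alignOverviewStack(images, 1, template = 1L, rotRangeDeg = 4,
                              rotStepDeg = 1)
  tg <- alignTargetPoints(stack, c(150, 110), windowPx = 64)
  mp <- montageParams(tileFovUm = 16, tilePixels = 64, rows = 2, cols = 2,
                      overlapUm = 4, dwellNs = 8000,
                      qualityThreshold = 0.02, focusStrategy = "per_montage",
                      ibsc = TRUE)
  outDir <- tempfile("mon")
  tiles <- acquireMontage(scope, stack, tg, mp, outDir, man, seedBase = 77)
  expect_equal(nrow(tiles), 12L)
  expect_true(all(file.exists(tiles$file)))
  expect_true(all(tiles$status == "pass"))
  lg <- readLog(file.path(outDir, "log.jsonl"))
  tileEvents <- Filter(function(e) e$event == "tile", lg)
  expect_equal(length(tileEvents), 12L)
  expect_true(all(file.exists(file.path(outDir, sprintf("S%04d", 1:3),
                                        "preview.png"))))
  ## every tile has exactly one terminal record
  keys <- vapply(tileEvents, function(e) {
    paste(e$section, paste(e$tile, collapse = "_"))
  }, "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("a failed quality gate triggers one refocus-and-retake", {
  sc <- smallScene(seed = 31L, surface = waferSurface(type = "flat"))
  ## hardware focus always fails: every first tile is badly defocused
  scope <- simScope(sc, simParams(stageFieldAmpUm = 0, stageJitterSdUm = 0,
                                  noiseSigma1000 = 0.005,
                                  autofocusFailureRate = 1), seed = 5L)
  truth <- sectionTruth(sc)[1, , drop = FALSE]
  truth$label <- 1L
  ovDir <- tempfile("ov")
  man <- acquireOverviews(scope, truth, ovDir,
                          overviewParams(pixelSizeUm = 1, marginUm = 30,
                                         dwellNs = 2000), 240, 180,
                          autofocusEach = FALSE)
  images <- list(`1` = scanData(readScanImage(man$file[1])))
  stack <- alignOverviewStack(images, 1, template = 1L, rotRangeDeg = 2,
                              rotStepDeg = 1)
  tg <- alignTargetPoints(stack, c(150, 110), windowPx = 64)
  mp <- montageParams(tileFovUm = 16, tilePixels = 64, rows = 1, cols = 1,
                      dwellNs = 8000, qualityThreshold = 0.09,
                      focusStrategy = "per_section", ibsc = FALSE)
  outDir <- tempfile("mon")
  tiles <- acquireMontage(scope, stack, tg, mp, outDir, man, seedBase = 3)
  expect_equal(tiles$retakes, 1L)
  expect_equal(tiles$status, "pass")
})
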