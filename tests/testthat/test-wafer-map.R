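# Wafer mapping: similarity fits, threshold masks, automap, numbering,
# calibration, fiducials and overviews.

test_that("similarity transforms compose, invert and fit exactly", {
  tr <- similarityTransform(2, 30, 10, 5)
  idc <- composeTransform(tr, invertTransform(tr))
  expect_equal(c(idc@scale, idc@thetaDeg, idc@tx, idc@ty), c(1, 0, 0, 0),
               tolerance = 1e-9)
  set.seed(1)
  P <- matrix(runif(8, -10, 10), ncol = 2)
  fit <- fitSimilarity(P, applyTransform(tr, P))
  expect_equal(fit$transform@scale, 2, tolerance = 1e-9)
  expect_equal(fit$transform@thetaDeg, 30, tolerance = 1e-9)
  expect_equal(c(fit$transform@tx, fit$transform@ty), c(10, 5),
               tolerance = 1e-9)
  expect_lt(fit$residualRms, 1e-9)
  ## identity correspondences give the identity transform
  fid <- fitSimilarity(P, P)
  expect_equal(fid$transform@scale, 1, tolerance = 1e-9)
  expect_lt(fid$residualRms, 1e-9)
  ## under-determined and degenerate inputs
  expect_error(fitSimilarity(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(fitSimilarity(matrix(1, 4, 2), matrix(runif(8), 4, 2)),
               "degenerate")
  ## rigid fit works from 2 points
  rg <- fitSimilarity(P[1:2, ], applyTransform(rigidTransform(10, 3, -2),
                                               P[1:2, ]), rigid = TRUE)
  expect_equal(rg$transform@thetaDeg, 10, tolerance = 1e-9)
  expect_equal(rg$transform@scale, 1)
})

test_that("threshold masks obey their bounds", {
  img <- matrix(c(0, 0.25, 0.5, 0.75, 1, 0.5), 2, 3)
  expect_true(all(thresholdMask(img, 0, 1)))
  expect_equal(sum(thresholdMask(img, 0.5, 0.5)), 2L)
  expect_false(any(thresholdMask(img, 0.51, 0.6) &
                     !(img >= 0.51 & img <= 0.6)))
  expect_error(thresholdMask(img, 0.7, 0.3), "exceed")
})

test_that("wafer threshold mask covers sections and excludes background", {
  sc <- smallScene(seed = 12L)
  img <- renderScene(sc, c(0, 0), 10, 512, 512, style = "optical")
  mask <- thresholdMask(img, 0.5, 1)
  truth <- sectionTruth(sc)
  ctr <- (512 + 1) / 2
  inside <- matrix(FALSE, 512, 512)
  for (i in seq_len(nrow(truth))) {
    th <- truth$thetaDeg[i] * pi / 180
    co <- cos(th); si <- sin(th)
    cols <- matrix(rep(seq_len(512), each = 512) - ctr, 512, 512) * 10
    rows <- matrix(rep(seq_len(512), times = 512) - ctr, 512, 512) * 10
    dx <- cols - truth$x_um[i]; dy <- rows - truth$y_um[i]
    lx <- co * dx + si * dy; ly <- -si * dx + co * dy
    inside <- inside | (abs(lx) <= truth$width_um[i] / 2 - 10 &
                          abs(ly) <= truth$height_um[i] / 2 - 10)
  }
  expect_gte(mean(mask[inside]), 0.90)
  expect_lte(mean(mask[!inside]), 0.05)
})

test_that("automap finds an isolated section exactly", {
  lay <- smallLayout(nSections = 1)
  sc <- makeWaferScene(smallPhantom(), lay, seed = 3L)
  truth <- sectionTruth(sc)
  ps <- 10
  img <- renderScene(sc, c(truth$x_um[1], truth$y_um[1]), ps, 128, 128,
                     style = "optical")
  mask <- thresholdMask(img, 0.5, 1)
  ex <- matrix(TRUE, round(180 / ps), round(240 / ps))
  det <- automapSections(mask, ex, rotationRangeDeg = 9)
  expect_equal(nrow(det), 1L)
  expect_gte(det$heat[1], 0.99)
  expect_lt(abs(det$col[1] - (128 + 1) / 2), 2.5)
  expect_lt(abs(det$row[1] - (128 + 1) / 2), 2.5)
  ## empty mask yields an empty detection list, not an error
  none <- automapSections(mask & FALSE, ex)
  expect_equal(nrow(none), 0L)
  ## empty example is an error
  expect_error(automapSections(mask, ex & FALSE), "empty")
})

test_that("automap heat matches a brute-force placement oracle", {
  set.seed(42)
  wafer <- matrix(FALSE, 72, 72)
  wafer[20:34, 15:38] <- TRUE   # a 15 x 24 block
  wafer[45:59, 30:53] <- TRUE   # a second block
  wafer[10:13, 55:60] <- TRUE   # debris-like clutter
  ex <- matrix(TRUE, 15, 24)
  det <- automapSections(wafer, ex, rotationRangeDeg = 6,
                         rotationStepDeg = 3, heatThreshold = 0.8)
  heat <- attr(det, "heat")
  org <- attr(det, "heatOrigin")
  rots <- c(-6, -3, 0, 3, 6)
  ## compare the heat value at a sample of positions against direct placement
  pts <- rbind(c(27, 26), c(52, 41), c(27, 30), c(24, 26), c(40, 35))
  for (k in seq_len(nrow(pts))) {
    want <- max(vapply(rots, function(th) {
      oracleHeatAt(wafer, ex, pts[k, 1], pts[k, 2], th)
    }, 0))
    got <- heat[pts[k, 1] - org["row"] + 1, pts[k, 2] - org["col"] + 1]
    expect_equal(got, want, tolerance = 1e-9)
  }
  ## detections sit on the two blocks
  expect_equal(nrow(det), 2L)
  expect_equal(sort(round(det$row)), c(27, 52))
})

test_that("tape-order numbering follows strips, reversal and continuation", {
  det <- data.frame(
    x_um = c(0, 1000, 2000, 0, 1000, 2000),
    y_um = c(0, 30, -20, 5000, 5020, 4990))
  lab <- numberSections(det, stripModel(gapUm = 1000))
  expect_equal(lab$label, 1:6)
  expect_equal(lab$x_um[lab$label %in% 1:3], c(0, 1000, 2000))
  expect_equal(unique(lab$strip[lab$label %in% 1:3]), 1L)
  ## serpentine second strip
  rev2 <- numberSections(det, stripModel(gapUm = 1000,
                                         reversed = c(FALSE, TRUE)))
  expect_equal(rev2$x_um[rev2$label == 4], 2000)
  expect_equal(rev2$x_um[rev2$label == 6], 0)
  ## continuation across wafers
  cont <- numberSections(det, stripModel(gapUm = 1000, startLabel = 163L))
  expect_equal(cont$label, 163:168)
  ## ambiguous strip clustering is flagged
  amb <- numberSections(data.frame(x_um = c(0, 1000, 0, 1000),
                                   y_um = c(0, 0, 120, 130)),
                        stripModel(gapUm = 100), sectionHeightUm = 1500)
  expect_true(attr(amb, "ambiguous"))
})

test_that("section edits relabel and keep provenance", {
  det <- data.frame(x_um = c(0, 1000, 2000), y_um = c(0, 10, -10),
                    status = "auto")
  lab <- numberSections(det, stripModel(gapUm = 500))
  added <- editSections(lab, list(add = c(3000, 0)),
                        model = stripModel(gapUm = 500))
  expect_equal(nrow(added), 4L)
  expect_equal(added$status[added$label == 4], "manually_added")
  backAgain <- editSections(added, list(remove = 4L),
                            model = stripModel(gapUm = 500))
  expect_equal(backAgain$label, lab$label)
  expect_equal(backAgain$x_um, lab$x_um)
  expect_equal(attr(backAgain, "removed")$status, "manually_removed")
  ## removing one of n keeps labels consecutive
  less <- editSections(lab, list(remove = 2L), model = stripModel(gapUm = 500))
  expect_equal(less$label, 1:2)
  ## unknown remove and out-of-wafer add are rejected
  expect_error(editSections(lab, list(remove = 99L)), "no section")
  expect_error(editSections(lab, list(add = c(9e5, 0)),
                            waferDiameterUm = 1e5), "outside")
})

test_that("pixel-to-stage calibration passes the null case and edge checks", {
  sc <- smallScene()
  scope <- simScope(sc, simParams(autofocusFailureRate = 0), seed = 10L)
  s1 <- sc@sections[1, ]
  moveStage(scope, s1$x_um, s1$y_um)
  autofocus(scope, steps = 9)
  cal <- calibratePixelToStage(scope, c(s1$x_um, s1$y_um), stepUm = 40,
                               request = scanRequest(120, 120, 4000))
  expect_lt(abs(cal$factor - 1), 0.005)
  expect_gte(cal$score, 0.2)
  ## featureless anchor errors
  expect_error(
    calibratePixelToStage(scope, c(-30000, 0), stepUm = 40,
                          request = scanRequest(120, 120, 4000)),
    "featureless")
  ## too-small step errors
  expect_error(
    calibratePixelToStage(scope, c(s1$x_um, s1$y_um), stepUm = 1,
                          request = scanRequest(120, 120, 4000)),
    "too small")
})

test_that("fiducials are imaged at 3 and 0.25 um per pixel", {
  sc <- smallScene()
  scope <- simScope(sc, quietParams(), seed = 2L)
  pos <- as.matrix(sc@fiducials[, c("x_um", "y_um")])
  fids <- acquireFiducials(scope, pos, lowPx = 128, highPx = 96)
  expect_length(fids, 4L)
  for (f in fids) {
    expect_equal(f$low@pixelSizeUm, 3)
    expect_equal(f$high@pixelSizeUm, 0.25)
    expect_gt(sd(scanData(f$low)), 0.01)   # pattern visible
    expect_gt(sd(scanData(f$high)), 0.01)
  }
  expect_error(acquireFiducials(scope, pos[1, , drop = FALSE]),
               "at least 2")
  ## deterministic under reseed
  reseedScope(scope, 3L)
  a <- acquireFiducials(scope, pos[1:2, ], lowPx = 64, highPx = 48)
  reseedScope(scope, 3L)
  b <- acquireFiducials(scope, pos[1:2, ], lowPx = 64, highPx = 48)
  expect_identical(scanData(a[[1]]$low), scanData(b[[1]]$low))
})

test_that("overview requests honour the sub-micron pixel and margin defaults", {
  req <- overviewScanRequest(2000, 1500)
  ps <- req$fovUm[1] / req$pixels[1]
  expect_lt(ps, 1)
  expect_gte(req$fovUm[1], 2000 + 2 * 1000)
  expect_gte(req$fovUm[2], 1500 + 2 * 1000)
})

test_that("overview acquisition writes one labelled file per section", {
  sc <- smallScene(seed = 21L)
  scope <- simScope(sc, seed = 3L)
  truth <- sectionTruth(sc)[1:5, ]
  truth$label <- 1:5
  dir <- tempfile("ov")
  ovP <- overviewParams(pixelSizeUm = 2, marginUm = 40, dwellNs = 2000)
  man <- acquireOverviews(scope, truth, dir, ovP, 240, 180,
                          skip = 4L, autofocusEach = FALSE)
  expect_equal(man$label, c(1:3, 5L))
  expect_true(all(file.exists(man$file)))
  expect_true(all(man$ok))
  ## ground-truth centroid reprojects inside each overview
  for (i in seq_len(nrow(man))) {
    k <- match(man$label[i], truth$label)
    img <- readScanImage(man$file[i])
    px <- (c(truth$x_um[k], truth$y_um[k]) - img@centerUm) /
      img@pixelSizeUm + c(ncol(scanData(img)), nrow(scanData(img))) / 2
    expect_true(all(px >= 1 & px <= rev(dim(scanData(img)))))
  }
})
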