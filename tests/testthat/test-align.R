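# Rigid overview alignment and running-average target-point alignment.

test_that("rigid registration recovers known transforms", {
  tmpl <- phantomImage(n = 160, psUm = 2)
  r0 <- registerRigid(tmpl, tmpl, rotRangeDeg = 5, rotStepDeg = 1)
  expect_gte(r0@score, 0.999)
  expect_lt(abs(r0@dx), 0.1)
  expect_lt(abs(r0@dy), 0.1)
  expect_equal(r0@thetaDeg, 0)
  ## shifted by (5, -3) and rotated 2 degrees
  img <- rotateImage(translateImage(tmpl, 3, -5), -2)
  r <- registerRigid(img, tmpl, rotRangeDeg = 5, rotStepDeg = 1)
  expect_lt(abs(r@dx - 5), 0.5)
  expect_lt(abs(r@dy + 3), 0.5)
  expect_lt(abs(r@thetaDeg - 2), 0.25)
  ## constant image flags instead of erroring
  flat <- registerRigid(matrix(0.5, 160, 160), tmpl)
  expect_true(flat@flagged)
  expect_equal(flat@score, 0)
  expect_error(registerRigid(tmpl[1:80, ], tmpl), "identical dimensions")
})

test_that("rigid registration agrees with the exhaustive brute-force oracle", {
  base <- phantomImage(n = 64, psUm = 3, seed = 11L)
  rots <- seq(-4, 4, by = 2)
  for (case in list(c(4, -6, 2), c(-9, 3, -4), c(0, 0, 0))) {
    img <- rotateImage(translateImage(base, case[2], case[1]), -case[3])
    want <- oracleRigid(img, base, rots)
    got <- registerRigid(img, base, rotRangeDeg = 4, rotStepDeg = 2)
    expect_equal(round(got@dx), want$dx)
    expect_equal(round(got@dy), want$dy)
    expect_lte(abs(got@thetaDeg - want$th), 2 / 10 + 1e-9)
    expect_equal(got@score, want$score, tolerance = 0.05)
  }
})

makeJitteredStack <- function(n, base, sdPx = 6, sdDeg = 2, seed = 1L,
                              noiseSd = 0.01) {
  set.seed(seed)
  truth <- data.frame(dx = runif(n, -sdPx, sdPx), dy = runif(n, -sdPx, sdPx),
                      th = runif(n, -sdDeg, sdDeg))
  truth[1, ] <- 0
  images <- lapply(seq_len(n), function(i) {
    img <- rotateImage(translateImage(base, -truth$dy[i], -truth$dx[i]),
                       -truth$th[i])
    img + matrix(rnorm(length(base), 0, noiseSd), nrow(base))
  })
  names(images) <- seq_len(n)
  list(images = images, truth = truth)
}

test_that("template alignment recovers perturbations without drift", {
  base <- phantomImage(n = 128, psUm = 2, seed = 9L)
  st <- makeJitteredStack(40, base, seed = 4L)
  stack <- alignOverviewStack(st$images, 2, template = 1L,
                              rotRangeDeg = 3, rotStepDeg = 1)
  al <- alignments(stack)
  errT <- sqrt((al$dx - st$truth$dx)^2 + (al$dy - st$truth$dy)^2)
  errR <- abs(al$thetaDeg - st$truth$th)
  expect_gte(mean(errT <= 1 & errR <= 0.5), 0.98)
  ## template aligns to itself exactly
  expect_equal(al$dx[1], 0, tolerance = 1e-6)
  expect_equal(al$score[1], 1)
  ## no drift: late sections no worse than early ones
  n <- nrow(al)
  firstDecile <- errT[2:(n %/% 10 + 1)]
  lastDecile <- errT[(n - n %/% 10 + 1):n]
  expect_lte(mean(lastDecile), mean(firstDecile) + 0.5)
})

test_that("missing overviews are flagged, not fatal", {
  base <- phantomImage(n = 96, psUm = 2, seed = 9L)
  st <- makeJitteredStack(5, base, seed = 2L)
  st$images[[3]] <- NULL
  st$images <- c(st$images[1:2], list(`3` = NULL), st$images[3:4])
  stack <- alignOverviewStack(st$images, 2, template = 1L,
                              rotRangeDeg = 2, rotStepDeg = 1)
  al <- alignments(stack)
  expect_true(al$flagged[3])
  expect_true(al$missing[3])
  expect_false(any(al$flagged[-3]))
})

test_that("manual alignment overrides store, apply and clear", {
  base <- phantomImage(n = 96, psUm = 2, seed = 9L)
  st <- makeJitteredStack(4, base, seed = 3L)
  stack <- alignOverviewStack(st$images, 2, template = 1L,
                              rotRangeDeg = 2, rotStepDeg = 1)
  auto <- alignments(stack)[2, c("dx", "dy", "thetaDeg")]
  stack <- setManualAlignment(stack, 2L, c(4, -1, 0.5))
  al <- alignments(stack)
  expect_equal(unlist(al[2, c("dx", "dy", "thetaDeg")]),
               c(dx = 4, dy = -1, thetaDeg = 0.5))
  expect_true(al$manual[2])
  stack <- setManualAlignment(stack, 2L, NULL)
  expect_equal(alignments(stack)[2, c("dx", "dy", "thetaDeg")], auto)
  expect_error(setManualAlignment(stack, 99L, c(0, 0, 0)), "unknown")
  expect_error(setManualAlignment(stack, 2L, c(Inf, 0, 0)), "finite")
})

test_that("two wafers chained through a shared template agree on a point", {
  ph <- smallPhantom(seed = 13L)
  n1 <- 6; n2 <- 6
  mk <- function(z, dx, dy, th) {
    g <- expand.grid(col = 1:128, row = 1:128)
    base <- matrix(phantomIntensity(ph, 150 + g$col * 2, 150 + g$row * 2, z,
                                    pixelSizeUm = 2), 128, 128, byrow = TRUE)
    rotateImage(translateImage(base, -dy, -dx), -th)
  }
  set.seed(6)
  t1 <- data.frame(dx = runif(n1, -4, 4), dy = runif(n1, -4, 4),
                   th = runif(n1, -1, 1))
  t2 <- data.frame(dx = runif(n2, -4, 4), dy = runif(n2, -4, 4),
                   th = runif(n2, -1, 1))
  t1[1, ] <- 0
  w1 <- lapply(seq_len(n1), function(i) mk(i - 1, t1$dx[i], t1$dy[i],
                                           t1$th[i]))
  names(w1) <- seq_len(n1)
  w2 <- lapply(seq_len(n2), function(i) mk(n1 + i - 1, t2$dx[i], t2$dy[i],
                                           t2$th[i]))
  names(w2) <- n1 + seq_len(n2)
  s1 <- alignOverviewStack(w1, 2, template = 1L, rotRangeDeg = 2,
                           rotStepDeg = 0.5)
  ## chain wafer 2 to the last aligned section of wafer 1
  a1 <- alignments(s1)
  tmpl <- list(image = w1[[n1]],
               alignment = c(a1$dx[n1], a1$dy[n1], a1$thetaDeg[n1]))
  s2 <- alignOverviewStack(w2, 2, template = tmpl, rotRangeDeg = 2,
                           rotStepDeg = 0.5)
  ## a fixed tissue pixel maps consistently into the shared stack frame:
  ## image pixel of the point on each section, mapped forward, must agree
  a2 <- alignments(s2)
  ctr <- c((128 + 1) / 2, (128 + 1) / 2)
  fwd <- function(al, p) {
    th <- al[3] * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    as.vector(R %*% (p - ctr)) + ctr + al[1:2]
  }
  ## a fixed tissue point `pt` of the untranslated frame appears on section
  ## i's image at R(-th_i)(pt - t_i - ctr) + ctr; mapping that forward
  ## through the recovered alignment must give the same stack position for
  ## every section of both wafers
  pt <- c(70, 60)
  imgPt <- function(tr, i) {
    rotatePoint(pt - c(tr$dx[i], tr$dy[i]), -tr$th[i], ctr)
  }
  mapped <- rbind(
    t(vapply(seq_len(n1), function(i) {
      fwd(c(a1$dx[i], a1$dy[i], a1$thetaDeg[i]), imgPt(t1, i))
    }, numeric(2))),
    t(vapply(seq_len(n2), function(i) {
      fwd(c(a2$dx[i], a2$dy[i], a2$thetaDeg[i]), imgPt(t2, i))
    }, numeric(2))))
  spread <- apply(mapped, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 2)
})

test_that("target-point alignment is exact on an already-aligned stack", {
  base <- phantomImage(n = 128, psUm = 2, seed = 5L)
  images <- lapply(1:6, function(i) base)
  names(images) <- 1:6
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 1,
                              rotStepDeg = 1)
  tg <- alignTargetPoints(stack, c(64, 64), windowPx = 48, runningDepth = 5)
  e <- targetEntries(tg)
  expect_true(all(abs(e$dx) <= 0.5))
  expect_true(all(abs(e$dy) <= 0.5))
  expect_false(any(e$flagged))
})

test_that("target alignment recovers injected residual offsets", {
  ph <- smallPhantom(seed = 19L)
  g <- expand.grid(col = 1:160, row = 1:160)
  set.seed(8)
  n <- 20
  off <- data.frame(dx = rnorm(n, 0, 3), dy = rnorm(n, 0, 3))
  off[1, ] <- 0
  images <- lapply(seq_len(n), function(i) {
    matrix(phantomIntensity(ph, 100 + (g$col + off$dx[i]) * 2,
                            100 + (g$row + off$dy[i]) * 2, i - 1,
                            pixelSizeUm = 2), 160, 160, byrow = TRUE)
  })
  names(images) <- seq_len(n)
  ## force identity global alignment: offsets are purely local residuals
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  for (l in seq_len(n)) stack <- setManualAlignment(stack, l, c(0, 0, 0))
  tg <- alignTargetPoints(stack, c(80, 80), windowPx = 64,
                          runningDepth = 10)
  e <- targetEntries(tg)
  ## window content is displaced by -off, so the entry offset tracks -off
  err <- sqrt((e$dx + off$dx)^2 + (e$dy + off$dy)^2)
  expect_gte(mean(err <= 1), 0.95)
})

test_that("occluded windows are flagged with a zero-offset fallback", {
  base <- phantomImage(n = 128, psUm = 2, seed = 5L)
  images <- lapply(1:4, function(i) base)
  images[[3]] <- matrix(0.5, 128, 128)  # simulated fold: no content
  names(images) <- 1:4
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  for (l in 1:4) stack <- setManualAlignment(stack, l, c(0, 0, 0))
  tg <- alignTargetPoints(stack, c(64, 64), windowPx = 48)
  e <- targetEntries(tg)
  expect_true(e$flagged[3])
  expect_equal(c(e$dx[3], e$dy[3]), c(0, 0))
  expect_false(any(e$flagged[-3]))
})

test_that("out-of-bounds target windows name the failing section", {
  base <- phantomImage(n = 96, psUm = 2, seed = 5L)
  images <- list(`1` = base, `2` = base)
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  expect_error(alignTargetPoints(stack, c(5, 5), windowPx = 48),
               "section 1")
})

test_that("manual target offsets override and restore", {
  base <- phantomImage(n = 128, psUm = 2, seed = 5L)
  images <- lapply(1:3, function(i) base)
  names(images) <- 1:3
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  tg <- alignTargetPoints(stack, c(64, 64), windowPx = 48)
  auto <- targetEntries(tg)[2, c("dx", "dy")]
  tg <- setManualTargetOffset(tg, 2L, c(3, -2))
  expect_equal(unlist(targetEntries(tg)[2, c("dx", "dy")]),
               c(dx = 3, dy = -2))
  ## override propagates into the acquisition-side pixel position
  px <- targetPixelOn(stack, tg, 2L)
  expect_equal(px, c(64 + 3, 64 - 2), tolerance = 1e-6)
  tg <- setManualTargetOffset(tg, 2L, NULL)
  expect_equal(targetEntries(tg)[2, c("dx", "dy")], auto)
  expect_error(setManualTargetOffset(tg, 9L, c(0, 0)), "unknown")
  expect_error(setManualTargetOffset(tg, 2L, c(NA, 0)), "finite")
})

test_that("running average tracks slow content drift where direct matching fails", {
  ## windows drawn from a phantom whose texture decorrelates over ~50
  ## sections; every section also carries a known jitter
  ph <- smallPhantom(seed = 23L)
  g <- expand.grid(col = 1:96, row = 1:96)
  n <- 60
  set.seed(12)
  jit <- data.frame(dx = rnorm(n, 0, 2), dy = rnorm(n, 0, 2))
  jit[1, ] <- 0
  images <- lapply(seq_len(n), function(i) {
    matrix(phantomIntensity(ph, 200 + (g$col + jit$dx[i]) * 2,
                            200 + (g$row + jit$dy[i]) * 2, (i - 1) * 2,
                            pixelSizeUm = 2), 96, 96, byrow = TRUE)
  })
  names(images) <- seq_len(n)
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  for (l in seq_len(n)) stack <- setManualAlignment(stack, l, c(0, 0, 0))
  tg <- alignTargetPoints(stack, c(48, 48), windowPx = 64,
                          runningDepth = 10)
  e <- targetEntries(tg)
  runErr <- sqrt((e$dx + jit$dx)^2 + (e$dy + jit$dy)^2)
  ## direct-to-first-window alignment for comparison
  w1 <- resampleAlignedForTest(images[[1]], c(48, 48), 64)
  dirErr <- vapply(seq_len(n), function(i) {
    wi <- resampleAlignedForTest(images[[i]], c(48, 48), 64)
    r <- nccShift(w1, wi)
    sqrt((-r$dx + jit$dx[i])^2 + (-r$dy + jit$dy[i])^2)
  }, 0)
  lastQ <- (n - 14):n
  expect_lt(max(runErr), 2)
  expect_gt(mean(dirErr[lastQ]), mean(runErr[lastQ]))
})

test_that("aligned target lists round-trip through the JSON store", {
  base <- phantomImage(n = 128, psUm = 2, seed = 5L)
  images <- lapply(1:3, function(i) base)
  names(images) <- 1:3
  stack <- alignOverviewStack(images, 2, template = 1L, rotRangeDeg = 0.5,
                              rotStepDeg = 0.5)
  tg <- alignTargetPoints(stack, c(64, 64), windowPx = 48)
  dir <- tempfile("tgt")
  writeTargetList(tg, dir)
  back <- readTargetList(dir)
  expect_equal(back@targetPoint, tg@targetPoint)
  expect_equal(back@windowPx, tg@windowPx)
  expect_equal(targetEntries(back)$dx, targetEntries(tg)$dx,
               tolerance = 1e-9)
  expect_lt(max(abs(back@windows[[2]] - tg@windows[[2]])), 1 / 255)
})
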