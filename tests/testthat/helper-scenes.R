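# Shared fixtures (built in code at test time) and independent oracles.

## small tissue phantom used across tests
smallPhantom <- function(seed = 7L) {
  makeTissuePhantom(extentUm = c(600, 600, 10), seed = seed)
}

## miniature wafer layout: 3 strips x 10 sections of 240 x 180 um
smallLayout <- function(nSections = 30, jitterSdUm = 20, jitterSdDeg = 2,
                        debrisCount = 0, ...) {
  waferLayout(nStrips = 3, nSections = nSections, sectionWidthUm = 240,
              sectionHeightUm = 180, alongPitchUm = 320, stripPitchUm = 720,
              jitterSdUm = jitterSdUm, jitterSdDeg = jitterSdDeg,
              debrisCount = debrisCount, ...)
}

smallScene <- function(seed = 8L, surface = waferSurface(), ...) {
  makeWaferScene(smallPhantom(), smallLayout(...), seed = seed,
                 surface = surface)
}

## noise-free, error-free simulation parameters (overridable)
quietParams <- function(...) {
  do.call(simParams, utils::modifyList(
    list(stageFieldAmpUm = 0, stageJitterSdUm = 0, noiseSigma1000 = 0,
         autofocusFailureRate = 0),
    list(...)))
}

## a reproducible textured image sampled straight from the phantom
phantomImage <- function(n = 128, psUm = 1, z = 3, seed = 7L, x0 = 150,
                         y0 = 150) {
  ph <- smallPhantom(seed)
  g <- expand.grid(col = seq_len(n), row = seq_len(n))
  matrix(phantomIntensity(ph, x0 + g$col * psUm, y0 + g$row * psUm, z,
                          pixelSizeUm = psUm), n, n, byrow = TRUE)
}

## ---- independent oracles --------------------------------------------------

## brute-force rigid registration: exhaustive integer shifts x rotation grid
## using direct (non-FFT) circular correlation of zero-mean unit-norm images
oracleRigid <- function(image, template, rots) {
  zt <- template - mean(template)
  nt <- sqrt(sum(zt^2))
  best <- NULL
  nr <- nrow(image); nc <- ncol(image)
  for (th in rots) {
    rot <- if (th == 0) image else rotateImage(image, th)
    zr <- rot - mean(rot)
    nz <- sqrt(sum(zr^2))
    for (dy in seq_len(nr) - 1L) {
      for (dx in seq_len(nc) - 1L) {
        ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
        ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
        s <- sum(zt * zr[ri, ci]) / (nt * nz)
        sdy <- if (dy > nr / 2) dy - nr else dy
        sdx <- if (dx > nc / 2) dx - nc else dx
        cand <- list(th = th, dy = sdy, dx = sdx, score = s)
        if (is.null(best) || s > best$score + 1e-12 ||
            (abs(s - best$score) <= 1e-12 &&
             (sdy^2 + sdx^2 < best$dy^2 + best$dx^2 ||
              (sdy^2 + sdx^2 == best$dy^2 + best$dx^2 &&
               abs(th) < abs(best$th))))) {
          best <- cand
        }
      }
    }
  }
  best
}

## brute-force automap heat at one position/rotation: direct overlap count
## minus the surround penalty, computed by explicit mask placement
oracleHeatAt <- function(waferMask, exampleMask, row, col, thetaDeg,
                         surroundPenalty = 0.5, surroundPx = 2L) {
  er <- nrow(exampleMask); ec <- ncol(exampleMask)
  pad <- surroundPx + 1L
  exPad <- matrix(0, er + 2L * pad, ec + 2L * pad)
  exPad[pad + seq_len(er), pad + seq_len(ec)] <- exampleMask * 1
  exR <- if (thetaDeg == 0) exPad else
    (rotateImage(exPad, thetaDeg, fill = 0) > 0.5) * 1
  ring <- utslmap:::boxDilate(exR, surroundPx) - exR
  placeSum <- function(kern) {
    kr <- nrow(kern); kc <- ncol(kern)
    cy <- round((kr + 1) / 2); cx <- round((kc + 1) / 2)
    tot <- 0
    for (i in seq_len(kr)) {
      for (j in seq_len(kc)) {
        if (kern[i, j] == 0) next
        wr <- row + i - cy; wc <- col + j - cx
        if (wr >= 1 && wr <= nrow(waferMask) &&
            wc >= 1 && wc <= ncol(waferMask) && waferMask[wr, wc]) {
          tot <- tot + 1
        }
      }
    }
    tot
  }
  h <- placeSum(exR) / sum(exR)
  if (surroundPenalty > 0 && sum(ring) > 0) {
    h <- h - surroundPenalty * placeSum(ring) / sum(ring)
  }
  h
}

## rotate a point by thetaDeg about a centre (same convention as the package)
rotatePoint <- function(p, thetaDeg, ctr) {
  th <- thetaDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.vector(R %*% (p - ctr)) + ctr
}

## identity-alignment window resampling (direct access to the package's
## stack-frame cutout, used to build comparison references in tests)
resampleAlignedForTest <- function(img, pt, w) {
  utslmap:::resampleAligned(img, c(0, 0, 0), pt, w)
}
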