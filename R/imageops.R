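# Low-level image utilities shared across the pipeline.
#
# Images are numeric matrices indexed [row, col]; row corresponds to stage y
# (y-down), col to stage x. Angles are in degrees; positive angles rotate +x
# toward +y.

deg2rad <- function(d) d * pi / 180

#' Smoothstep interpolation weight
#' @param t numeric in \[0,1\]
#' @return t^2 (3 - 2 t)
#' @keywords internal
smoothstep01 <- function(t) t * t * (3 - 2 * t)

## clamped smoothstep between edges a < b
smoothstepEdge <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  smoothstep01(t)
}

## deterministic lattice hash -> uniform [0,1); vectorised over ix/iy/iz
latticeHash3 <- function(ix, iy, iz, seed) {
  s <- sin(ix * 12.9898 + iy * 78.2330 + iz * 37.7190 + seed * 9.1513) *
    43758.5453123
  s - floor(s)
}

#' Band-limited 3-D value noise
#'
#' Deterministic procedural noise: uniform lattice values interpolated with a
#' smoothstep kernel. Identical inputs and seed give identical outputs on any
#' platform, which is what makes the phantom reproducible without storing a
#' voxel grid.
#'
#' @param x,y,z numeric vectors (same length) of sample coordinates in lattice
#'   units (one lattice cell per unit).
#' @param seed integer scrambling the lattice.
#' @return numeric vector of noise values in \[0, 1\].
#' @keywords internal
valueNoise3 <- function(x, y, z, seed) {
  ix <- floor(x); iy <- floor(y); iz <- floor(z)
  fx <- smoothstep01(x - ix)
  fy <- smoothstep01(y - iy)
  fz <- smoothstep01(z - iz)
  n000 <- latticeHash3(ix,     iy,     iz,     seed)
  n100 <- latticeHash3(ix + 1, iy,     iz,     seed)
  n010 <- latticeHash3(ix,     iy + 1, iz,     seed)
  n110 <- latticeHash3(ix + 1, iy + 1, iz,     seed)
  n001 <- latticeHash3(ix,     iy,     iz + 1, seed)
  n101 <- latticeHash3(ix + 1, iy,     iz + 1, seed)
  n011 <- latticeHash3(ix,     iy + 1, iz + 1, seed)
  n111 <- latticeHash3(ix + 1, iy + 1, iz + 1, seed)
  nx00 <- n000 + (n100 - n000) * fx
  nx10 <- n010 + (n110 - n010) * fx
  nx01 <- n001 + (n101 - n001) * fx
  nx11 <- n011 + (n111 - n011) * fx
  nxy0 <- nx00 + (nx10 - nx00) * fy
  nxy1 <- nx01 + (nx11 - nx01) * fy
  nxy0 + (nxy1 - nxy0) * fz
}

#' Fractal (multi-octave) value noise in \[0, 1\]
#'
#' When `baseWavelength` and `pixelSize` are given (same units), octaves are
#' faded out as their wavelength approaches the sampling pixel size
#' (band-limited rendering): full weight at >= 2 px per lattice cell, zero at
#' <= 1 px. This prevents sub-pixel octaves from aliasing into the render,
#' which would bias sub-pixel correlation estimates.
#'
#' @inheritParams valueNoise3
#' @param octaves number of octaves (lacunarity 2, gain 0.5).
#' @param baseWavelength physical size of one lattice cell of the first
#'   octave (same units as `pixelSize`).
#' @param pixelSize sampling pixel size; 0 disables band-limiting.
#' @keywords internal
fbm3 <- function(x, y, z, seed, octaves = 2L, baseWavelength = 0,
                 pixelSize = 0) {
  out <- 0
  amp <- 1
  tot <- 0
  freq <- 1
  for (o in seq_len(octaves)) {
    w <- amp
    if (pixelSize > 0 && baseWavelength > 0) {
      w <- w * smoothstepEdge(baseWavelength / freq / pixelSize, 1, 2)
    }
    if (w > 0) {
      out <- out + w * valueNoise3(x * freq, y * freq, z * freq,
                                   seed + o * 101L)
      tot <- tot + w
    }
    amp <- amp * 0.5
    freq <- freq * 2
  }
  if (tot == 0) return(rep(0.5, length(x)))
  out / tot
}

#' Rotate an image about its centre
#'
#' Inverse-mapped bilinear rotation; the output has the same dimensions.
#' Positive angles rotate image content from +x (columns) toward +y (rows).
#'
#' @param img numeric matrix.
#' @param thetaDeg rotation angle in degrees.
#' @param fill value used outside the source image (default: image mean).
#' @return rotated matrix of identical dimensions.
#' @export
rotateImage <- function(img, thetaDeg, fill = mean(img)) {
  if (thetaDeg == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- deg2rad(thetaDeg)
  co <- cos(th); si <- sin(th)
  col <- rep(seq_len(nc), each = nr) - cc   # x offsets
  row <- rep(seq_len(nr), times = nc) - cr  # y offsets
  ## inverse rotation of the output grid
  sx <- co * col + si * row + cc
  sy <- -si * col + co * row + cr
  x0 <- floor(sx); y0 <- floor(sy)
  tx <- sx - x0;   ty <- sy - y0
  inside <- x0 >= 1 & x0 <= nc - 1 & y0 >= 1 & y0 <= nr - 1
  out <- rep(fill, nr * nc)
  if (any(inside)) {
    x0i <- x0[inside]; y0i <- y0[inside]
    txi <- tx[inside]; tyi <- ty[inside]
    i00 <- (x0i - 1) * nr + y0i
    v <- img[i00] * (1 - txi) * (1 - tyi) +
      img[i00 + nr] * txi * (1 - tyi) +
      img[i00 + 1] * (1 - txi) * tyi +
      img[i00 + nr + 1] * txi * tyi
    out[inside] <- v
  }
  matrix(out, nr, nc)
}

## 1-D gaussian kernel, truncated at 4 sigma, normalised
gaussKernel1 <- function(sigma) {
  if (sigma <= 0) return(1)
  w <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-w, w), sd = sigma)
  k / sum(k)
}

## convolve each column of m with kernel k, replicating edges
convCols <- function(m, k) {
  if (length(k) == 1L) return(m)
  w <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  pad <- rbind(m[rep(1L, w), , drop = FALSE], m, m[rep(nr, w), , drop = FALSE])
  out <- matrix(0, nr, ncol(m))
  for (t in seq_along(k)) {
    out <- out + k[t] * pad[t:(t + nr - 1L), , drop = FALSE]
  }
  out
}

#' Separable Gaussian blur with (possibly) anisotropic sigma
#'
#' @param img numeric matrix.
#' @param sigmaX blur sigma along columns (x), in pixels.
#' @param sigmaY blur sigma along rows (y), in pixels; defaults to `sigmaX`.
#' @return blurred matrix (edge-replicated boundary handling).
#' @export
gaussBlur <- function(img, sigmaX, sigmaY = sigmaX) {
  out <- img
  if (sigmaY > 0) out <- convCols(out, gaussKernel1(sigmaY))
  if (sigmaX > 0) out <- t(convCols(t(out), gaussKernel1(sigmaX)))
  out
}

#' Difference-of-Gaussians band-pass filter
#'
#' @param img numeric matrix.
#' @param sigma1,sigma2 the two blur scales in pixels, `sigma1 < sigma2`.
#' @return band-passed image (zero-centred).
#' @export
dogFilter <- function(img, sigma1, sigma2) {
  gaussBlur(img, sigma1) - gaussBlur(img, sigma2)
}

#' Circular cross-correlation via FFT
#'
#' Returns the matrix `S` with `S[dy+1, dx+1] = sum_(i,j) a[i,j] * b[i-dy, j-dx]`
#' (indices wrapped), i.e. the correlation of `a` against `b` shifted by
#' `(dy, dx)`. Shifts beyond half the image size are negative shifts.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @keywords internal
crossCorrFFT <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / length(a)
}

## convert a 1-based FFT-correlation index to a signed shift
fftIndexToShift <- function(idx, n) {
  s <- idx - 1L
  ifelse(s > n / 2, s - n, s)
}

## 3-point parabolic sub-sample peak refinement; returns offset in (-0.5, 0.5)
parabolicPeak <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  off <- ifelse(abs(den) < .Machine$double.eps * 100, 0, 0.5 * (ym1 - yp1) / den)
  pmin(pmax(off, -0.5), 0.5)
}

#' Normalised cross-correlation translation search
#'
#' Finds the integer shift `(dy, dx)` of `b` that best matches `a` under the
#' zero-mean, unit-norm normalised cross-correlation score (contrast
#' independent, in \[-1, 1\]), with optional sub-pixel parabolic refinement of
#' the peak. Ties at equal score are broken toward the smallest shift
#' magnitude.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param subpixel refine the peak with a 3-point parabola per axis?
#' @param maxShift optional cap on |dy| and |dx| considered (pixels).
#' @return list with `dy`, `dx` (shift applied to `b` to match `a`),
#'   `score` (NCC at the integer peak).
#' @export
nccShift <- function(a, b, subpixel = TRUE, maxShift = Inf) {
  za <- a - mean(a); zb <- b - mean(b)
  na <- sqrt(sum(za^2)); nb <- sqrt(sum(zb^2))
  if (na < .Machine$double.eps || nb < .Machine$double.eps) {
    return(list(dy = 0, dx = 0, score = 0))
  }
  S <- crossCorrFFT(za, zb) / (na * nb)
  nr <- nrow(S); nc <- ncol(S)
  dys <- fftIndexToShift(seq_len(nr), nr)
  dxs <- fftIndexToShift(seq_len(nc), nc)
  if (is.finite(maxShift)) {
    S[abs(dys) > maxShift, ] <- -Inf
    S[, abs(dxs) > maxShift] <- -Inf
  }
  best <- max(S)
  cand <- which(S >= best - 1e-12, arr.ind = TRUE)
  sh <- cbind(dys[cand[, 1]], dxs[cand[, 2]])
  ord <- order(sh[, 1]^2 + sh[, 2]^2, abs(sh[, 1]), abs(sh[, 2]))[1]
  iy <- cand[ord, 1]; ix <- cand[ord, 2]
  dy <- dys[iy]; dx <- dxs[ix]
  score <- S[iy, ix]
  if (subpixel) {
    wrap <- function(i, n) ((i - 1) %% n) + 1
    dy <- dy + parabolicPeak(S[wrap(iy - 1, nr), ix], score, S[wrap(iy + 1, nr), ix])
    dx <- dx + parabolicPeak(S[iy, wrap(ix - 1, nc)], score, S[iy, wrap(ix + 1, nc)])
  }
  list(dy = dy, dx = dx, score = score)
}

#' Binary box dilation by `t` pixels (4-neighbourhood, iterated)
#' @param mask 0/1 numeric matrix.
#' @param t dilation radius in pixels.
#' @keywords internal
boxDilate <- function(mask, t) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(t)) {
    sh <- out
    sh[2:nr, ] <- pmax(sh[2:nr, ], out[1:(nr - 1), ])
    sh[1:(nr - 1), ] <- pmax(sh[1:(nr - 1), ], out[2:nr, ])
    sh[, 2:nc] <- pmax(sh[, 2:nc], out[, 1:(nc - 1)])
    sh[, 1:(nc - 1)] <- pmax(sh[, 1:(nc - 1)], out[, 2:nc])
    out <- sh
  }
  (out > 0) * 1
}

#' Two-stage displacement measurement
#'
#' Robust version of [nccShift] for possibly large displacements: an integer
#' FFT correlation peak is refined by a second, sub-pixel correlation
#' restricted to the overlapping crop of the two images. The crop removes
#' the circular-wrap mismatch that would otherwise tilt the correlation
#' surface and bias the sub-pixel estimate when the displacement is a large
#' fraction of the field.
#'
## evaluate the circular cross-correlation of zero-mean za against zb at
## arbitrary fractional shifts (sy, sx) directly from the FFT product
fourierCorrAt <- function(F, sy, sx) {
  nr <- nrow(F); nc <- ncol(F)
  ky <- fftIndexToShift(seq_len(nr), nr)
  kx <- fftIndexToShift(seq_len(nc), nc)
  py <- exp(2i * pi * ky * sy / nr)
  px <- exp(2i * pi * kx * sx / nc)
  Re(sum(F * (py %o% px))) / (nr * nc)
}

## continuous sub-pixel peak of the correlation of za vs zb (both zero-mean),
## searched within (-1, 1)^2: coarse 0.25-px grid then parabolic interpolation
fourierSubpixelPeak <- function(za, zb) {
  F <- stats::fft(za) * Conj(stats::fft(zb))
  ss <- seq(-0.75, 0.75, by = 0.25)
  C <- matrix(NA_real_, length(ss), length(ss))
  for (i in seq_along(ss)) {
    for (j in seq_along(ss)) {
      C[i, j] <- fourierCorrAt(F, ss[i], ss[j])
    }
  }
  k <- which(C == max(C), arr.ind = TRUE)[1, ]
  sy <- ss[k[1]]; sx <- ss[k[2]]
  d <- ss[2] - ss[1]
  if (k[1] > 1 && k[1] < length(ss)) {
    sy <- sy + d * parabolicPeak(C[k[1] - 1, k[2]], C[k[1], k[2]],
                                 C[k[1] + 1, k[2]])
  }
  if (k[2] > 1 && k[2] < length(ss)) {
    sx <- sx + d * parabolicPeak(C[k[1], k[2] - 1], C[k[1], k[2]],
                                 C[k[1], k[2] + 1])
  }
  c(sy = sy, sx = sx)
}

#' @param a,b numeric matrices of identical dimensions.
#' @param maxResidualPx residual search range in the refinement stage.
#' @param trimPx border trimmed off the overlap before refining; discards
#'   pixels whose pre-crop blur mixed in content outside the overlap.
#' @param fourierRefine refine the final sub-pixel fraction by evaluating
#'   the correlation at fractional shifts directly in the Fourier domain
#'   (slightly slower, unbiased under blur); otherwise a 3-point parabola.
#' @return list with `dy`, `dx` (shift of `b` to match `a`) and `score`
#'   (NCC over the overlap).
#' @export
measureShift <- function(a, b, maxResidualPx = 8, trimPx = 8,
                         fourierRefine = TRUE) {
  r0 <- nccShift(a, b, subpixel = FALSE)
  dy <- r0$dy; dx <- r0$dx
  nr <- nrow(a); nc <- ncol(a)
  ra <- max(1, 1 + dy):min(nr, nr + dy)
  ca <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ra) > 16 + 2 * trimPx && length(ca) > 16 + 2 * trimPx) {
    ra <- ra[(trimPx + 1):(length(ra) - trimPx)]
    ca <- ca[(trimPx + 1):(length(ca) - trimPx)]
  }
  if (length(ra) < 16 || length(ca) < 16) {
    return(nccShift(a, b, subpixel = TRUE))
  }
  ac <- a[ra, ca, drop = FALSE]
  bc <- b[ra - dy, ca - dx, drop = FALSE]
  r1 <- nccShift(ac, bc, subpixel = FALSE, maxShift = maxResidualPx)
  if (fourierRefine) {
    za <- ac - mean(ac); zb <- bc - mean(bc)
    zb <- circShift(zb, r1$dy, r1$dx)
    frac <- fourierSubpixelPeak(za, zb)
    list(dy = dy + r1$dy + frac[["sy"]], dx = dx + r1$dx + frac[["sx"]],
         score = r1$score)
  } else {
    r2 <- nccShift(ac, bc, subpixel = TRUE, maxShift = maxResidualPx)
    list(dy = dy + r2$dy, dx = dx + r2$dx, score = r2$score)
  }
}

#' Shift an image by an integer number of pixels (circularly)
#' @param img matrix; @param dy,dx integer shifts (content moves down/right).
#' @keywords internal
circShift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  img[ri, ci, drop = FALSE]
}

#' Translate an image by a (possibly fractional) shift with edge fill
#' @keywords internal
translateImage <- function(img, dy, dx, fill = mean(img)) {
  nr <- nrow(img); nc <- ncol(img)
  col <- rep(seq_len(nc), each = nr) - dx
  row <- rep(seq_len(nr), times = nc) - dy
  x0 <- floor(col); y0 <- floor(row)
  tx <- col - x0; ty <- row - y0
  inside <- x0 >= 1 & x0 <= nc - 1 & y0 >= 1 & y0 <= nr - 1
  out <- rep(fill, nr * nc)
  if (any(inside)) {
    i00 <- (x0[inside] - 1) * nr + y0[inside]
    out[inside] <- img[i00] * (1 - tx[inside]) * (1 - ty[inside]) +
      img[i00 + nr] * tx[inside] * (1 - ty[inside]) +
      img[i00 + 1] * (1 - tx[inside]) * ty[inside] +
      img[i00 + nr + 1] * tx[inside] * ty[inside]
  }
  matrix(out, nr, nc)
}
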