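# Similarity / rigid transforms between pixel and stage spaces.

#' Construct a similarity transform
#'
#' @param scale micrometres per pixel (or 1 for a rigid transform).
#' @param thetaDeg rotation in degrees (+x toward +y).
#' @param tx,ty translation components.
#' @return a [SimilarityTransform-class].
#' @export
similarityTransform <- function(scale = 1, thetaDeg = 0, tx = 0, ty = 0) {
  new("SimilarityTransform", scale = scale, thetaDeg = thetaDeg,
      tx = tx, ty = ty)
}

#' @rdname similarityTransform
#' @export
rigidTransform <- function(thetaDeg = 0, tx = 0, ty = 0) {
  similarityTransform(1, thetaDeg, tx, ty)
}

#' Apply a transform to points
#'
#' @param transform a [SimilarityTransform-class].
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
applyTransform <- function(transform, pts) {
  pts <- rbind2cols(pts)
  th <- deg2rad(transform@thetaDeg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- transform@scale * (pts %*% t(R))
  out[, 1] <- out[, 1] + transform@tx
  out[, 2] <- out[, 2] + transform@ty
  out
}

rbind2cols <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  stopifnot(ncol(pts) == 2)
  pts
}

#' Invert a similarity transform
#' @param transform a [SimilarityTransform-class].
#' @export
invertTransform <- function(transform) {
  th <- deg2rad(transform@thetaDeg)
  s <- 1 / transform@scale
  co <- cos(-th); si <- sin(-th)
  tx <- -s * (co * transform@tx - si * transform@ty)
  ty <- -s * (si * transform@tx + co * transform@ty)
  similarityTransform(s, -transform@thetaDeg, tx, ty)
}

#' Compose transforms: `composeTransform(A, B)` applies B first, then A
#' @param a,b [SimilarityTransform-class] objects.
#' @export
composeTransform <- function(a, b) {
  tb <- applyTransform(a, c(b@tx, b@ty))
  similarityTransform(a@scale * b@scale, a@thetaDeg + b@thetaDeg,
                      tb[1], tb[2])
}

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: scale %.6g, theta %.4g deg, t (%.4g, %.4g)\n",
    object@scale, object@thetaDeg, object@tx, object@ty))
})

#' Least-squares similarity fit from point correspondences
#'
#' Fits scale, rotation and translation mapping pixel points to stage points,
#' minimising the stage-space residual (closed-form SVD solution). Used to
#' register a full-wafer image into stage space from three or more manually
#' identified fiducial correspondences.
#'
#' @param pixelPts,stagePts n x 2 matrices of corresponding points, n >= 3.
#' @param rigid when TRUE the scale is constrained to 1 (wafer reload fits);
#'   n >= 2 then suffices.
#' @return list with `transform` ([SimilarityTransform-class]) and
#'   `residualRms` (stage units).
#' @export
fitSimilarity <- function(pixelPts, stagePts, rigid = FALSE) {
  P <- rbind2cols(pixelPts); Q <- rbind2cols(stagePts)
  if (nrow(P) != nrow(Q)) stop("correspondence lists differ in length")
  nmin <- if (rigid) 2L else 3L
  if (nrow(P) < nmin) {
    stop(sprintf("at least %d correspondences are required", nmin))
  }
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  varP <- sum(Pc^2)
  if (varP < .Machine$double.eps) {
    stop("degenerate input: pixel points are coincident")
  }
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  scale <- if (rigid) 1 else sum(diag(D %*% diag(sv$d))) / varP
  th <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t0 <- mq - scale * as.vector(R %*% mp)
  tr <- similarityTransform(scale, th, t0[1], t0[2])
  res <- applyTransform(tr, P) - Q
  list(transform = tr, residualRms = sqrt(mean(rowSums(res^2))))
}
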