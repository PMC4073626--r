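# Target and montage definition phase: rigid alignment of section overviews
# into a single stack frame, and local (translation-only) alignment of a
# small window around the chosen target point.
#
# A section's alignment (dx, dy, thetaDeg) maps its image into the stack
# frame as p' = R(theta) (p - c) + c + (dx, dy), with c the image centre.

alignR <- function(thetaDeg, v) {
  th <- deg2rad(thetaDeg)
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

## compose centred rigid transforms: outer after inner
composeAlign <- function(outer, inner) {
  t0 <- alignR(outer[3], inner[1:2]) + outer[1:2]
  c(t0, outer[3] + inner[3])
}

## map a stack-frame point back into section-image pixel coordinates
invAlignPoint <- function(align, pt, center) {
  alignR(-align[3], pt - center - align[1:2]) + center
}

#' Rigid registration of an image against a template
#'
#' Coarse rotation sweep with an FFT-based translation search at every
#' candidate angle, followed by a fine sweep (one coarse step around the best
#' angle at a tenth of the step), with sub-pixel parabolic refinement of the
#' correlation peak. The score is the zero-mean unit-norm normalised
#' cross-correlation, so thresholds are contrast independent. Ties at equal
#' correlation are broken toward the smallest |shift|, then the smallest
#' |rotation|.
#'
#' @param image,template numeric matrices of identical dimensions and pixel
#'   size.
#' @param rotRangeDeg rotation search half-range (default 10).
#' @param rotStepDeg coarse rotation step (default 1).
#' @param minScore results scoring below this are flagged (default 0.2).
#' @param maxShiftPx optional cap on the translation search.
#' @return an [AlignResult-class]: rotate `image` by `thetaDeg` about its
#'   centre, then shift by (dx, dy), to match `template`. A near-constant
#'   image yields a flagged identity result with score 0 (not an error).
#' @export
registerRigid <- function(image, template, rotRangeDeg = 10, rotStepDeg = 1,
                          minScore = 0.2, maxShiftPx = Inf) {
  if (!all(dim(image) == dim(template))) {
    stop("image and template must have identical dimensions")
  }
  eps <- 1e-6
  if (stats::sd(image) < eps || stats::sd(template) < eps) {
    return(new("AlignResult", dx = 0, dy = 0, thetaDeg = 0, score = 0,
               flagged = TRUE))
  }
  evalTheta <- function(th, subpixel = FALSE) {
    rot <- if (th == 0) image else rotateImage(image, th)
    r <- nccShift(template, rot, subpixel = subpixel, maxShift = maxShiftPx)
    list(th = th, dx = r$dx, dy = r$dy, score = r$score)
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (abs(a$score - b$score) > 1e-12) return(a$score > b$score)
    sa <- a$dx^2 + a$dy^2; sb <- b$dx^2 + b$dy^2
    if (abs(sa - sb) > 1e-12) return(sa < sb)
    abs(a$th) < abs(b$th)
  }
  best <- NULL
  for (th in seq(-rotRangeDeg, rotRangeDeg, by = rotStepDeg)) {
    cand <- evalTheta(th)
    if (better(cand, best)) best <- cand
  }
  if (rotRangeDeg > 0) {
    fine <- seq(best$th - rotStepDeg, best$th + rotStepDeg,
                by = rotStepDeg / 10)
    fine <- fine[abs(fine) <= rotRangeDeg + 1e-9 & abs(fine - best$th) > 1e-9]
    for (th in fine) {
      cand <- evalTheta(th)
      if (better(cand, best)) best <- cand
    }
  }
  ref <- evalTheta(best$th, subpixel = TRUE)
  new("AlignResult", dx = ref$dx, dy = ref$dy, thetaDeg = best$th,
      score = ref$score, flagged = ref$score < minScore)
}

setMethod("show", "AlignResult", function(object) {
  cat(sprintf(
    "AlignResult: d(%.2f, %.2f) px, theta %.3f deg, score %.3f%s\n",
    object@dx, object@dy, object@thetaDeg, object@score,
    if (object@flagged) " [flagged]" else ""))
})

#' Align a wafer's section overviews to a single template
#'
#' Every section is registered directly against the one template image
#' (never chained pairwise), so alignment errors do not accumulate along the
#' stack and a single bad section cannot derail its neighbours. For the
#' first wafer the template is one of its own sections; later wafers pass a
#' template drawn from the previous wafer's aligned stack together with that
#' template's alignment, which places all wafers in one consistent frame.
#'
#' @param images named list of overview matrices; names are tape-order
#'   labels. `NULL` entries (missing overview files) are flagged "missing".
#' @param pixelSizeUm overview pixel size (carried in metadata).
#' @param template either an integer label (template taken from `images`) or
#'   a list `list(image =, alignment =)` where `alignment` is the template's
#'   own (dx, dy, theta) in the global stack frame (chaining).
#' @param rotRangeDeg,rotStepDeg,minScore passed to [registerRigid].
#' @param meta optional list stored on the stack (overview poses etc.).
#' @return an [OverviewStack-class].
#' @export
alignOverviewStack <- function(images, pixelSizeUm, template,
                               rotRangeDeg = 10, rotStepDeg = 1,
                               minScore = 0.2, meta = list()) {
  labels <- as.integer(names(images))
  if (any(is.na(labels))) stop("images must be named by integer labels")
  ord <- order(labels)
  labels <- labels[ord]
  images <- images[ord]
  if (is.list(template) && !is.null(template$image)) {
    tmplImg <- template$image
    tmplAlign <- template$alignment
    if (is(tmplAlign, "AlignResult")) {
      tmplAlign <- c(tmplAlign@dx, tmplAlign@dy, tmplAlign@thetaDeg)
    }
    tmplLabel <- NA_integer_
  } else {
    tmplLabel <- as.integer(template)
    if (!tmplLabel %in% labels) stop("template label not in this stack")
    tmplImg <- images[[match(tmplLabel, labels)]]
    tmplAlign <- c(0, 0, 0)
  }
  n <- length(labels)
  al <- data.frame(label = labels, dx = 0, dy = 0, thetaDeg = 0, score = 0,
                   flagged = FALSE, manual = FALSE, missing = FALSE,
                   auto_dx = 0, auto_dy = 0, auto_theta = 0)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (is.null(img)) {
      al$flagged[i] <- TRUE
      al$missing[i] <- TRUE
      next
    }
    r <- if (!is.na(tmplLabel) && labels[i] == tmplLabel) {
      new("AlignResult", dx = 0, dy = 0, thetaDeg = 0, score = 1,
          flagged = FALSE)
    } else {
      registerRigid(img, tmplImg, rotRangeDeg, rotStepDeg, minScore)
    }
    g <- if (r@flagged) c(0, 0, 0) else
      composeAlign(tmplAlign, c(r@dx, r@dy, r@thetaDeg))
    al$dx[i] <- g[1]; al$dy[i] <- g[2]; al$thetaDeg[i] <- g[3]
    al$auto_dx[i] <- g[1]; al$auto_dy[i] <- g[2]; al$auto_theta[i] <- g[3]
    al$score[i] <- r@score
    al$flagged[i] <- r@flagged
  }
  new("OverviewStack", labels = labels, images = images,
      pixelSizeUm = pixelSizeUm, alignments = al,
      templateLabel = tmplLabel, meta = meta)
}

#' Alignment table of an overview stack
#' @param stack an [OverviewStack-class].
#' @export
alignments <- function(stack) stack@alignments

setMethod("show", "OverviewStack", function(object) {
  a <- object@alignments
  cat(sprintf(
    "OverviewStack: %d sections (labels %d..%d), %.3g um/px, template %s; %d flagged\n",
    length(object@labels), min(object@labels), max(object@labels),
    object@pixelSizeUm,
    if (is.na(object@templateLabel)) "chained" else object@templateLabel,
    sum(a$flagged)))
})

#' Manually override (or clear) one section's stack alignment
#'
#' The programmatic counterpart of correcting an alignment by dragging in a
#' review GUI. Overriding stores the manual (dx, dy, theta), clears the
#' flag and marks provenance; clearing restores the automatic result.
#'
#' @param stack an [OverviewStack-class].
#' @param label section label.
#' @param override numeric (dx, dy, thetaDeg), or NULL to clear.
#' @return the updated stack.
#' @export
setManualAlignment <- function(stack, label, override) {
  i <- match(label, stack@labels)
  if (is.na(i)) stop(sprintf("unknown section %s", label))
  a <- stack@alignments
  if (is.null(override)) {
    a$dx[i] <- a$auto_dx[i]; a$dy[i] <- a$auto_dy[i]
    a$thetaDeg[i] <- a$auto_theta[i]
    a$manual[i] <- FALSE
  } else {
    if (length(override) != 3 || any(!is.finite(override))) {
      stop("override must be three finite values (dx, dy, thetaDeg)")
    }
    a$dx[i] <- override[1]; a$dy[i] <- override[2]
    a$thetaDeg[i] <- override[3]
    a$manual[i] <- TRUE
    a$flagged[i] <- FALSE
  }
  stack@alignments <- a
  stack
}

## resample a square window (side w) around stack-frame point `pt` from a
## section image through the inverse of its global alignment (bilinear);
## returns NULL if any window corner falls outside the image
resampleAligned <- function(img, align, pt, w) {
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  half <- (w - 1) / 2
  u <- seq(-half, half)
  grid <- expand.grid(du = u, dv = u)  # du varies fastest (columns of window)
  th <- deg2rad(-align[3])
  px <- pt[1] + grid$du - ctr[1] - align[1]
  py <- pt[2] + grid$dv - ctr[2] - align[2]
  qx <- cos(th) * px - sin(th) * py + ctr[1]
  qy <- sin(th) * px + cos(th) * py + ctr[2]
  if (min(qx) < 1 || min(qy) < 1 || max(qx) > ncol(img) ||
      max(qy) > nrow(img)) {
    return(NULL)
  }
  x0 <- floor(qx); y0 <- floor(qy)
  x0 <- pmin(x0, ncol(img) - 1L); y0 <- pmin(y0, nrow(img) - 1L)
  tx <- qx - x0; ty <- qy - y0
  nr <- nrow(img)
  i00 <- (x0 - 1) * nr + y0
  v <- img[i00] * (1 - tx) * (1 - ty) + img[i00 + nr] * tx * (1 - ty) +
    img[i00 + 1] * (1 - tx) * ty + img[i00 + nr + 1] * tx * ty
  ## grid has du fastest -> window row = dv, col = du; v indexed (du, dv)
  matrix(v, w, w, byrow = TRUE)
}

#' Local target-point alignment against a running average
#'
#' For each section in tape order, a small window is cropped from the
#' overview at the target point mapped through the section's global (stack)
#' alignment, and registered translation-only against the unweighted mean of
#' the last `runningDepth` previously aligned windows (the first section's
#' window seeds the average). Rotation is deliberately ignored at this
#' scale. The per-section pixel offsets refine the global alignment right at
#' the point that will be imaged at high resolution; following a running
#' average rather than the first section lets the alignment track slow
#' z-drift of the tissue content.
#'
#' @param stack an [OverviewStack-class].
#' @param targetPoint (x, y) pixel position in the stack frame.
#' @param windowPx window side in pixels (default 400).
#' @param runningDepth number of previous aligned windows averaged
#'   (default 10).
#' @param minScore windows scoring below this are flagged and fall back to
#'   offset (0, 0) relative to the global alignment (default 0.2); flagged
#'   windows do not enter the running average.
#' @return an [AlignedTargetList-class]; entries hold the offset (dx, dy) to
#'   add to the globally aligned window position, per section.
#' @export
alignTargetPoints <- function(stack, targetPoint, windowPx = 400,
                              runningDepth = 10, minScore = 0.2) {
  n <- length(stack@labels)
  if (n == 0) stop("empty stack")
  al <- stack@alignments
  e <- data.frame(label = stack@labels, dx = 0, dy = 0, score = 0,
                  flagged = FALSE, manual = FALSE, auto_dx = 0, auto_dy = 0)
  windows <- vector("list", n)
  recent <- list()
  for (i in seq_len(n)) {
    img <- stack@images[[i]]
    if (is.null(img)) {
      e$flagged[i] <- TRUE
      next
    }
    g <- c(al$dx[i], al$dy[i], al$thetaDeg[i])
    ## window resampled in the stack frame: the cutout of the aligned
    ## overview, so rotated sections contribute unrotated content
    w <- resampleAligned(img, g, targetPoint, windowPx)
    if (is.null(w)) {
      stop(sprintf(
        "target window out of bounds for section %d", stack@labels[i]))
    }
    if (length(recent) == 0) {
      e$dx[i] <- 0; e$dy[i] <- 0; e$score[i] <- 1
      windows[[i]] <- w
      recent <- list(w)
      next
    }
    ref <- Reduce(`+`, recent) / length(recent)
    r <- nccShift(ref, w)
    if (r$score < minScore) {
      e$flagged[i] <- TRUE
      e$score[i] <- r$score
      windows[[i]] <- w
      next
    }
    ## the tissue point sits at window centre - (ncc shift)
    e$dx[i] <- -r$dx; e$dy[i] <- -r$dy
    e$auto_dx[i] <- e$dx[i]; e$auto_dy[i] <- e$dy[i]
    e$score[i] <- r$score
    aligned <- translateImage(w, r$dy, r$dx)
    windows[[i]] <- aligned
    recent <- c(recent, list(aligned))
    if (length(recent) > runningDepth) {
      recent <- recent[(length(recent) - runningDepth + 1):length(recent)]
    }
  }
  new("AlignedTargetList", targetPoint = as.numeric(targetPoint),
      windowPx = windowPx, depth = runningDepth, entries = e,
      windows = windows)
}

#' Entries of an aligned target list
#' @param x an [AlignedTargetList-class].
#' @export
targetEntries <- function(x) x@entries

setMethod("show", "AlignedTargetList", function(object) {
  e <- object@entries
  cat(sprintf(
    "AlignedTargetList: %d sections, window %d px at (%.0f, %.0f), depth %d; %d flagged\n",
    nrow(e), object@windowPx, object@targetPoint[1], object@targetPoint[2],
    object@depth, sum(e$flagged)))
})

#' Manually override (or clear) one section's target offset
#' @param list an [AlignedTargetList-class].
#' @param label section label.
#' @param offset numeric (dx, dy), or NULL to restore the automatic value.
#' @return the updated list.
#' @export
setManualTargetOffset <- function(list, label, offset) {
  i <- match(label, list@entries$label)
  if (is.na(i)) stop(sprintf("unknown section %s", label))
  e <- list@entries
  if (is.null(offset)) {
    e$dx[i] <- e$auto_dx[i]; e$dy[i] <- e$auto_dy[i]
    e$manual[i] <- FALSE
  } else {
    if (length(offset) != 2 || any(!is.finite(offset))) {
      stop("offset must be two finite values")
    }
    e$dx[i] <- offset[1]; e$dy[i] <- offset[2]
    e$manual[i] <- TRUE
    e$flagged[i] <- FALSE
  }
  list@entries <- e
  list
}

#' Image pixel position of the aligned target on one section's overview
#'
#' Applies the section's local target offset in the stack frame, then the
#' inverse global alignment.
#'
#' @param stack an [OverviewStack-class].
#' @param targets an [AlignedTargetList-class] built from `stack`.
#' @param label section label.
#' @return (col, row) pixel position on that section's overview image.
#' @export
targetPixelOn <- function(stack, targets, label) {
  i <- match(label, stack@labels)
  if (is.na(i)) stop(sprintf("unknown section %s", label))
  img <- stack@images[[i]]
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  al <- stack@alignments
  g <- c(al$dx[i], al$dy[i], al$thetaDeg[i])
  j <- match(label, targets@entries$label)
  invAlignPoint(g, targets@targetPoint +
                  c(targets@entries$dx[j], targets@entries$dy[j]), ctr)
}

#' Persist an aligned target list as JSON (+ window TIFFs)
#'
#' @param targets an [AlignedTargetList-class].
#' @param dir output directory; `AlignedTargetList.json` plus
#'   `subregions/S%04d.tif` are written inside.
#' @export
writeTargetList <- function(targets, dir) {
  dir.create(file.path(dir, "subregions"), recursive = TRUE,
             showWarnings = FALSE)
  e <- targets@entries
  for (i in seq_len(nrow(e))) {
    w <- targets@windows[[i]]
    if (!is.null(w)) {
      tiff::writeTIFF(pmin(pmax(w, 0), 1),
                      file.path(dir, "subregions",
                                sprintf("S%04d.tif", e$label[i])))
    }
  }
  jsonlite::write_json(
    list(formatVersion = 1L, targetPoint = targets@targetPoint,
         windowPx = targets@windowPx, depth = targets@depth, entries = e),
    file.path(dir, "AlignedTargetList.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}

#' Read an aligned target list written by [writeTargetList]
#' @param dir directory containing `AlignedTargetList.json`.
#' @return an [AlignedTargetList-class].
#' @export
readTargetList <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "AlignedTargetList.json"),
                           simplifyVector = TRUE)
  e <- as.data.frame(j$entries)
  windows <- lapply(e$label, function(l) {
    f <- file.path(dir, "subregions", sprintf("S%04d.tif", l))
    if (file.exists(f)) {
      img <- tiff::readTIFF(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    } else NULL
  })
  new("AlignedTargetList", targetPoint = as.numeric(j$targetPoint),
      windowPx = j$windowPx, depth = j$depth, entries = e,
      windows = windows)
}
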