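# Synthetic tissue / wafer phantom with known ground truth.
#
# The phantom is procedural: every intensity is a deterministic function of
# physical position, section index and the seed, so arbitrary pixel sizes can
# be rendered without ever materialising a voxel grid.

## run expr with a private RNG stream, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Default texture parameters for the tissue phantom
#'
#' All scales are physical (micrometres), so the same phantom renders
#' consistently from 4 nm high-resolution tiles up to coarse wafer maps.
#'
#' @param backgroundLevel mid-grey resin level of the rendered tissue.
#' @param contrast amplitude of the textural contrast around the background.
#' @param fineScaleUm wavelength of the finest-but-one texture octave;
#'   four octaves run from this scale down to an eighth of it.
#' @param membraneScaleUm wavelength of the ridge field producing
#'   membrane-like dark edges (edge density ~ 1/scale).
#' @param membraneStrength relative darkness of membrane ridges.
#' @param blobRadiusUm two-vector: radius range of cell-body-like blobs.
#' @param vesselRadiusUm two-vector: radius range of flat vessel-like discs.
#' @param zCorrUm serial-coherence scale along z: texture decorrelates over
#'   roughly this physical depth (default 1.5 um, i.e. ~50 sections at 30 nm).
#' @return named list of texture parameters.
#' @export
phantomTexture <- function(backgroundLevel = 0.5, contrast = 0.35,
                           fineScaleUm = 2, membraneScaleUm = 4,
                           membraneStrength = 0.55,
                           blobRadiusUm = c(3, 5),
                           vesselRadiusUm = c(8, 15),
                           zCorrUm = 1.5) {
  list(backgroundLevel = backgroundLevel, contrast = contrast,
       fineScaleUm = fineScaleUm, membraneScaleUm = membraneScaleUm,
       membraneStrength = membraneStrength, blobRadiusUm = blobRadiusUm,
       vesselRadiusUm = vesselRadiusUm, zCorrUm = zCorrUm)
}

#' Create a procedural tissue phantom
#'
#' @param extentUm physical extent (x, y, z) in micrometres; the z extent
#'   bounds how many sections the phantom can supply.
#' @param thicknessNm section thickness in nanometres (default 30).
#' @param texture texture parameter list from [phantomTexture].
#' @param seed integer master seed; identical seed and parameters give
#'   identical intensities everywhere.
#' @return a [TissuePhantom-class].
#' @export
makeTissuePhantom <- function(extentUm = c(4000, 4000, 100),
                              thicknessNm = 30,
                              texture = phantomTexture(),
                              seed = 1L) {
  if (length(extentUm) != 3 || any(!is.finite(extentUm)) || any(extentUm <= 0)) {
    stop("extentUm must be three positive finite values")
  }
  if (!is.finite(thicknessNm) || thicknessNm <= 0) {
    stop("thicknessNm must be positive")
  }
  new("TissuePhantom", extentUm = as.numeric(extentUm),
      thicknessNm = as.numeric(thicknessNm), texture = texture,
      seed = as.integer(seed))
}

#' Number of sections a phantom can supply
#' @param phantom a [TissuePhantom-class].
#' @export
phantomSectionCapacity <- function(phantom) {
  floor(phantom@extentUm[3] * 1000 / phantom@thicknessNm)
}

#' Sample phantom intensity at physical positions
#'
#' The phantom is a continuous function of in-plane position and section
#' index: a fine multi-octave texture, dark membrane-like ridges (level-set
#' ridges of a smooth noise field), rounded dark cell-body blobs, and flat
#' low-contrast vessel-like discs whose interiors suppress texture (they are
#' deliberately poor autofocus targets).
#'
#' @param phantom a [TissuePhantom-class].
#' @param x,y numeric vectors of positions in micrometres.
#' @param z section index (0-based scalar, or vector matching x).
#' @param pixelSizeUm sampling pixel size for band-limited rendering (0 =
#'   sample the full-resolution field); octaves below the pixel scale are
#'   faded out and membrane ridges widened accordingly, so renders at any
#'   pixel size are alias-free.
#' @return numeric vector of intensities in \[0, 1\].
#' @export
phantomIntensity <- function(phantom, x, y, z, pixelSizeUm = 0) {
  tx <- phantom@texture
  seed <- phantom@seed
  zUm <- z * phantom@thicknessNm / 1000
  zn <- zUm / tx$zCorrUm
  f <- tx$fineScaleUm
  base <- fbm3(x / f, y / f, zn, seed, octaves = 4L,
               baseWavelength = f, pixelSize = pixelSizeUm)
  out <- tx$backgroundLevel + 1.2 * tx$contrast * (base - 0.5)
  m <- tx$membraneScaleUm
  n1 <- fbm3(x / m, y / m, zn, seed + 7L, octaves = 2L,
             baseWavelength = m, pixelSize = pixelSizeUm)
  ## thin dark ridges along the 0.5 iso-contours of a smooth field; ridge
  ## width grows with the sampling pixel size (PSF-like smoothing) so the
  ## nonlinear ridge profile stays resolvable at any render resolution
  ridgeW <- sqrt(0.06^2 + (0.3 * pixelSizeUm)^2)
  ridge <- exp(-((n1 - 0.5) / ridgeW)^2)
  out <- out - 1.5 * tx$membraneStrength * tx$contrast * ridge
  bScale <- 2 * mean(tx$blobRadiusUm)
  n2 <- fbm3(x / bScale, y / bScale, 0.7 * zn, seed + 13L, octaves = 2L)
  wB <- smoothstepEdge(n2, 0.60, 0.65)
  out <- out * (1 - wB) + (tx$backgroundLevel - 0.55 * tx$contrast) * wB
  vScale <- 1.6 * mean(tx$vesselRadiusUm)
  n3 <- fbm3(x / vScale, y / vScale, 0.5 * zn, seed + 29L, octaves = 1L)
  wV <- smoothstepEdge(n3, 0.70, 0.74)
  out <- out * (1 - wV) + (tx$backgroundLevel + 0.25 * tx$contrast) * wV
  ## smooth shoulder instead of hard clipping: saturation would create flat
  ## pools with aliasing-prone sharp boundaries
  out <- 0.5 + 0.48 * tanh((out - 0.5) / 0.48)
  pmin(pmax(out, 0), 1)
}

#' Wafer layout parameters
#'
#' Describes how tape strips of sections are mounted on a wafer. Tape
#' collection order is strip index ascending, position along the strip
#' ascending; a per-strip `reversed` flag simulates serpentine mounting.
#'
#' @param nStrips number of tape strips (rows).
#' @param nSections total sections on the wafer (split near-evenly over
#'   strips); alternatively give `sectionsPerStrip` explicitly.
#' @param sectionsPerStrip optional integer vector, one entry per strip.
#' @param sectionWidthUm,sectionHeightUm nominal section footprint.
#' @param alongPitchUm centre-to-centre spacing along a strip (default:
#'   section width + 500).
#' @param stripPitchUm centre-to-centre spacing between strips (default:
#'   4 x section height).
#' @param jitterSdUm,jitterSdDeg pose jitter of tape mounting (s.d. of the
#'   per-section translation in micrometres and rotation in degrees).
#' @param reversedStrips logical vector (recycled): strips mounted reversed.
#' @param debrisCount number of distractor debris blobs.
#' @param lostSections wafer-local collection indices cut but lost (no
#'   footprint is rendered; the z-index is still consumed).
#' @return named list of layout parameters.
#' @export
waferLayout <- function(nStrips = 10, nSections = 162,
                        sectionsPerStrip = NULL,
                        sectionWidthUm = 2000, sectionHeightUm = 1500,
                        alongPitchUm = sectionWidthUm + 500,
                        stripPitchUm = 4 * sectionHeightUm,
                        jitterSdUm = 200, jitterSdDeg = 3,
                        reversedStrips = FALSE,
                        debrisCount = 2, lostSections = integer(0)) {
  if (is.null(sectionsPerStrip)) {
    base <- nSections %/% nStrips
    extra <- nSections %% nStrips
    sectionsPerStrip <- rep(base, nStrips)
    if (extra > 0) {
      sectionsPerStrip[seq_len(extra)] <- base + 1
    }
  }
  nStrips <- length(sectionsPerStrip)
  list(sectionsPerStrip = as.integer(sectionsPerStrip),
       nStrips = nStrips,
       sectionWidthUm = sectionWidthUm, sectionHeightUm = sectionHeightUm,
       alongPitchUm = alongPitchUm, stripPitchUm = stripPitchUm,
       jitterSdUm = jitterSdUm, jitterSdDeg = jitterSdDeg,
       reversedStrips = rep_len(reversedStrips, nStrips),
       debrisCount = debrisCount,
       lostSections = as.integer(lostSections))
}

#' Wafer surface height field description
#'
#' @param type "noise" (smooth bounded field), "plane" (z = a x + b y + c) or
#'   "flat" (z = 0).
#' @param amplitudeUm amplitude of the noise field (flatness bound, default
#'   10; must not exceed `boundUm`).
#' @param scaleUm lateral wavelength of the noise field.
#' @param a,b,c plane coefficients for type "plane".
#' @param boundUm configured flatness bound (default 25).
#' @export
waferSurface <- function(type = c("noise", "plane", "flat"),
                         amplitudeUm = 10, scaleUm = 30000,
                         a = 0, b = 0, c = 0, boundUm = 25) {
  type <- match.arg(type)
  if (type == "noise" && amplitudeUm > boundUm) {
    stop("surface amplitude exceeds the flatness bound")
  }
  list(type = type, amplitudeUm = amplitudeUm, scaleUm = scaleUm,
       a = a, b = b, c = c, boundUm = boundUm)
}

#' Surface height z_surf(x, y) of a wafer scene
#' @param scene a [WaferScene-class].
#' @param x,y stage coordinates in micrometres (vectors).
#' @return height in micrometres, bounded by the configured flatness bound.
#' @export
surfaceHeight <- function(scene, x, y) {
  s <- scene@surface
  z <- switch(s$type,
    flat = rep(0, length(x)),
    plane = s$a * x + s$b * y + s$c,
    noise = s$amplitudeUm *
      (2 * fbm3(x / s$scaleUm, y / s$scaleUm, 0, scene@seed + 97L, 2L) - 1))
  pmin(pmax(z, -s$boundUm), s$boundUm)
}

#' Build a wafer scene with ground truth
#'
#' Lays out tape strips of near-rectangular sections on a 100 mm wafer with
#' pose jitter, places four corner fiducial marks and debris distractors, and
#' assigns consecutive z-indices in tape-collection order.
#'
#' @param phantom a [TissuePhantom-class].
#' @param layout layout parameters from [waferLayout].
#' @param seed integer seed for this wafer's jitter/debris draws.
#' @param waferId integer wafer id (1-based).
#' @param zStart z-index of this wafer's first collected section (0-based).
#' @param diameterUm wafer diameter (default 1e5 = 100 mm).
#' @param surface surface description from [waferSurface].
#' @return a [WaferScene-class]; ground truth in `sections(scene)`.
#' @export
makeWaferScene <- function(phantom, layout = waferLayout(), seed = 1L,
                           waferId = 1L, zStart = 0L,
                           diameterUm = 1e5, surface = waferSurface()) {
  nPer <- layout$sectionsPerStrip
  nTotal <- sum(nPer)
  R <- diameterUm / 2
  halfDiag <- sqrt(layout$sectionWidthUm^2 + layout$sectionHeightUm^2) / 2
  rows <- list()
  order0 <- 0L
  jit <- withSeed(seed + 331L, list(
    t = matrix(stats::rnorm(2 * nTotal, 0, layout$jitterSdUm), ncol = 2),
    r = stats::rnorm(nTotal, 0, layout$jitterSdDeg)))
  for (s in seq_along(nPer)) {
    k <- nPer[s]
    if (k == 0L) next
    y0 <- (s - (length(nPer) + 1) / 2) * layout$stripPitchUm
    xs <- (seq_len(k) - (k + 1) / 2) * layout$alongPitchUm
    pos <- seq_len(k)
    if (layout$reversedStrips[s]) pos <- rev(pos)
    for (j in seq_len(k)) {
      order0 <- order0 + 1L
      idx <- order0
      rows[[idx]] <- data.frame(
        wafer = as.integer(waferId), strip = s, posInStrip = pos[j],
        collectOrder = idx,
        x_um = xs[pos[j]] + jit$t[idx, 1], y_um = y0 + jit$t[idx, 2],
        thetaDeg = jit$r[idx], width_um = layout$sectionWidthUm,
        height_um = layout$sectionHeightUm,
        zIndex = zStart + idx - 1L, lost = FALSE)
    }
  }
  sections <- if (length(rows)) do.call(rbind, rows) else
    data.frame(wafer = integer(0), strip = integer(0),
               posInStrip = integer(0), collectOrder = integer(0),
               x_um = numeric(0), y_um = numeric(0), thetaDeg = numeric(0),
               width_um = numeric(0), height_um = numeric(0),
               zIndex = integer(0), lost = logical(0))
  if (nrow(sections)) {
    sections$lost <- sections$collectOrder %in% layout$lostSections
    rTest <- sqrt(sections$x_um^2 + sections$y_um^2) + halfDiag
    if (any(rTest > R)) {
      stop("layout error: sections cannot fit on the wafer at requested size")
    }
  }
  fidR <- R - 0.07 * diameterUm
  fidPos <- fidR / sqrt(2) * matrix(c(-1, -1, 1, -1, -1, 1, 1, 1),
                                    ncol = 2, byrow = TRUE)
  fiducials <- data.frame(id = 1:4, x_um = fidPos[, 1], y_um = fidPos[, 2],
                          sizeUm = 400)
  debris <- data.frame(x_um = numeric(0), y_um = numeric(0),
                       radiusUm = numeric(0), phase = numeric(0))
  if (layout$debrisCount > 0) {
    debris <- withSeed(seed + 577L, {
      got <- 0L
      out <- list()
      tries <- 0L
      while (got < layout$debrisCount && tries < 1000L) {
        tries <- tries + 1L
        xd <- stats::runif(1, -0.8 * R, 0.8 * R)
        yd <- stats::runif(1, -0.8 * R, 0.8 * R)
        rd <- stats::runif(1, 400, 800)
        if (sqrt(xd^2 + yd^2) + rd > 0.9 * R) next
        if (nrow(sections) &&
            any((sections$x_um - xd)^2 + (sections$y_um - yd)^2 <
                (2.2 * halfDiag)^2)) next
        got <- got + 1L
        out[[got]] <- data.frame(x_um = xd, y_um = yd, radiusUm = rd,
                                 phase = stats::runif(1, 0, 2 * pi))
      }
      if (got) do.call(rbind, out) else debris
    })
  }
  new("WaferScene", waferId = as.integer(waferId), diameterUm = diameterUm,
      sections = sections, fiducials = fiducials, debris = debris,
      phantom = phantom, surface = surface,
      levels = list(background = 0.15, offWafer = 0.04,
                    sectionLow = 0.25, sectionSpan = 0.65,
                    optical = 0.72, fiducial = 0.05),
      seed = as.integer(seed))
}

#' Ground-truth section table of a scene
#' @param scene a [WaferScene-class].
#' @return data.frame with one row per collected section (lost sections have
#'   `lost = TRUE` and are not rendered).
#' @export
sectionTruth <- function(scene) scene@sections

#' Build a full multi-wafer UTSL ground truth
#'
#' Consecutive wafers carry consecutive z-index ranges (wafer k ends at z_e,
#' wafer k+1 starts at z_e + 1), so cross-wafer alignment chaining is
#' testable. Per-wafer seeds are derived from the master seed by a fixed
#' offset of 1000 per wafer.
#'
#' @param phantom a [TissuePhantom-class].
#' @param nWafers number of wafers (>= 1).
#' @param layout per-wafer layout from [waferLayout] (a single layout reused,
#'   or a list of one layout per wafer).
#' @param seed master seed.
#' @param ... passed to [makeWaferScene] (diameter, surface).
#' @return list of [WaferScene-class], one per wafer.
#' @export
makeUtslTruth <- function(phantom, nWafers, layout = waferLayout(),
                          seed = 1L, ...) {
  if (nWafers < 1) stop("nWafers must be >= 1")
  layouts <- if (is.list(layout) && is.null(layout$sectionsPerStrip)) {
    layout
  } else {
    rep(list(layout), nWafers)
  }
  stopifnot(length(layouts) == nWafers)
  total <- sum(vapply(layouts, function(l) sum(l$sectionsPerStrip), 0L))
  if (total > phantomSectionCapacity(phantom)) {
    stop(sprintf(
      "phantom z-extent supports %d sections but %d were requested",
      phantomSectionCapacity(phantom), total))
  }
  zStart <- 0L
  scenes <- vector("list", nWafers)
  for (k in seq_len(nWafers)) {
    scenes[[k]] <- makeWaferScene(phantom, layouts[[k]],
                                  seed = seed + 1000L * k,
                                  waferId = k, zStart = zStart, ...)
    zStart <- zStart + sum(layouts[[k]]$sectionsPerStrip)
  }
  scenes
}

#' Combined ground-truth table for a list of wafer scenes
#' @param scenes list of [WaferScene-class] (or a single scene).
#' @return data.frame across all wafers, ordered by z-index.
#' @export
utslTruthTable <- function(scenes) {
  if (is(scenes, "WaferScene")) scenes <- list(scenes)
  do.call(rbind, lapply(scenes, sectionTruth))
}

#' Save a ground-truth table as JSON
#' @param scenes list of [WaferScene-class].
#' @param path output JSON path.
#' @export
writeTruthJSON <- function(scenes, path) {
  tab <- utslTruthTable(scenes)
  jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

setMethod("show", "WaferScene", function(object) {
  cat(sprintf(
    "WaferScene %d: %.0f mm wafer, %d sections in %d strips, %d fiducials, %d debris\n",
    object@waferId, object@diameterUm / 1000, nrow(object@sections),
    length(unique(object@sections$strip)), nrow(object@fiducials),
    nrow(object@debris)))
})

setMethod("show", "TissuePhantom", function(object) {
  cat(sprintf(
    "TissuePhantom: %.0f x %.0f x %.0f um, %d nm sections (capacity %d), seed %d\n",
    object@extentUm[1], object@extentUm[2], object@extentUm[3],
    round(object@thicknessNm), phantomSectionCapacity(object), object@seed))
})
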