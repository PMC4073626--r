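# S4 classes for the UTSL acquisition pipeline.

#' @import methods
NULL

#' SimilarityTransform: pixel-to-stage (or frame-to-frame) similarity mapping
#'
#' Maps a 2-D point `p` to `scale * R(theta) %*% p + t`. Used both for
#' full-wafer-image-to-stage registration (scale in micrometres per pixel) and,
#' with `scale = 1`, for rigid transforms between overview images and for the
#' wafer reload correction.
#'
#' @slot scale positive scalar (micrometres per pixel, or 1 for rigid).
#' @slot thetaDeg rotation in degrees (+x toward +y).
#' @slot tx,ty translation.
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", thetaDeg = "numeric",
                 tx = "numeric", ty = "numeric"),
  prototype(scale = 1, thetaDeg = 0, tx = 0, ty = 0),
  validity = function(object) {
    if (length(object@scale) != 1 || !is.finite(object@scale) ||
        object@scale <= 0) {
      return("scale must be a positive finite scalar")
    }
    if (!all(is.finite(c(object@thetaDeg, object@tx, object@ty)))) {
      return("transform parameters must be finite")
    }
    TRUE
  })

#' TissuePhantom: procedural serially-coherent 3-D tissue texture
#'
#' A continuous function of physical position `(x_um, y_um)` and section index
#' `z`, built from band-limited value noise plus smoothly thresholded
#' low-frequency components that produce membrane-like ridges, cell-body
#' blobs and flat vessel-like discs. Nothing is stored on a voxel grid, so
#' arbitrary pixel sizes can be rendered from the same phantom.
#'
#' @slot extentUm physical extent (x, y, z) in micrometres.
#' @slot thicknessNm section thickness in nanometres.
#' @slot texture named list of texture parameters (see [makeTissuePhantom]).
#' @slot seed integer master seed.
#' @export
setClass("TissuePhantom",
  representation(extentUm = "numeric", thicknessNm = "numeric",
                 texture = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@extentUm) != 3 || any(object@extentUm <= 0)) {
      return("extentUm must be three positive values")
    }
    if (object@thicknessNm <= 0) return("thicknessNm must be positive")
    TRUE
  })

#' WaferScene: a silicon wafer carrying tape strips of tissue sections
#'
#' Ground-truth description of one wafer: section footprints (true centroids,
#' rotations, strip assignment, z-index into the phantom), corner fiducial
#' marks, debris blobs, a smooth surface height field used for focus testing,
#' and intensity levels. This is what the simulated microscope renders.
#'
#' @slot waferId integer wafer index (1-based).
#' @slot diameterUm wafer diameter (default 1e5, i.e. a 100 mm wafer).
#' @slot sections data.frame: one row per section (ground truth).
#' @slot fiducials data.frame: one row per corner fiducial mark.
#' @slot debris data.frame: distractor blobs.
#' @slot phantom the [TissuePhantom-class] sampled inside section footprints.
#' @slot surface list describing the height field z_surf(x, y).
#' @slot levels list of background/section/tape intensity levels.
#' @slot seed integer seed this scene was built from.
#' @export
setClass("WaferScene",
  representation(waferId = "integer", diameterUm = "numeric",
                 sections = "data.frame", fiducials = "data.frame",
                 debris = "data.frame", phantom = "TissuePhantom",
                 surface = "list", levels = "list", seed = "integer"),
  validity = function(object) {
    if (object@diameterUm <= 0) return("diameterUm must be positive")
    s <- object@sections
    if (nrow(s)) {
      r <- sqrt(s$x_um^2 + s$y_um^2) +
        sqrt(s$width_um^2 + s$height_um^2) / 2
      if (any(r > object@diameterUm / 2)) {
        return("all section footprints must lie inside the wafer disc")
      }
    }
    TRUE
  })

#' ScanImage: one simulated scan with its metadata
#'
#' @slot data numeric matrix in \[0, 1\], indexed \[row, col\] (y-down).
#' @slot pixelSizeUm pixel size in micrometres.
#' @slot centerUm commanded stage position of the image centre.
#' @slot scanRotationDeg scan rotation applied during the scan.
#' @slot meta list: dwell, working distance, flags, actual pose, etc.
#' @export
setClass("ScanImage",
  representation(data = "matrix", pixelSizeUm = "numeric",
                 centerUm = "numeric", scanRotationDeg = "numeric",
                 meta = "list"))

#' SimScope: simulated scanning electron microscope
#'
#' One backend of the abstract microscope contract (move stage, set working
#' distance / scan rotation / stigmation, scan). Holds mutable instrument
#' state in an environment so that stage moves and reloads behave like a
#' physical instrument. A real-hardware backend would implement the same
#' generics.
#'
#' @slot scene the [WaferScene-class] under the beam.
#' @slot params simulation parameters (see [simParams]).
#' @slot state environment: stage position, working distance, stigmation,
#'   reload transform, RNG counter.
#' @export
setClass("SimScope",
  representation(scene = "WaferScene", params = "list", state = "environment"))

#' AlignResult: rigid registration of one image against a template
#'
#' @slot dx,dy translation in pixels (applied to the image after rotation).
#' @slot thetaDeg rotation in degrees about the image centre.
#' @slot score normalised cross-correlation in \[-1, 1\].
#' @slot flagged TRUE when the score fell below the configured minimum (the
#'   identity transform is kept pending manual correction).
#' @export
setClass("AlignResult",
  representation(dx = "numeric", dy = "numeric", thetaDeg = "numeric",
                 score = "numeric", flagged = "logical"),
  prototype(dx = 0, dy = 0, thetaDeg = 0, score = 0, flagged = FALSE),
  validity = function(object) {
    if (object@score < -1 - 1e-9 || object@score > 1 + 1e-9) {
      return("score must lie in [-1, 1]")
    }
    TRUE
  })

#' OverviewStack: aligned stack of section overview images
#'
#' @slot labels tape-order section labels, ascending.
#' @slot images list of overview matrices (in label order).
#' @slot pixelSizeUm overview pixel size.
#' @slot alignments data.frame: per-section dx, dy, thetaDeg, score, flagged,
#'   manual (one row per label, in order).
#' @slot templateLabel label of the template section (NA when the template
#'   came from a previous wafer's stack).
#' @slot meta list (overview poses, template provenance).
#' @export
setClass("OverviewStack",
  representation(labels = "integer", images = "list", pixelSizeUm = "numeric",
                 alignments = "data.frame", templateLabel = "integer",
                 meta = "list"),
  validity = function(object) {
    if (length(object@images) != length(object@labels)) {
      return("one image per label required")
    }
    if (nrow(object@alignments) != length(object@labels)) {
      return("one alignment per label required")
    }
    if (is.unsorted(object@labels, strictly = TRUE)) {
      return("labels must be strictly increasing (tape order)")
    }
    TRUE
  })

#' AlignedTargetList: per-section local alignment around a target point
#'
#' @slot targetPoint (x, y) pixel position of the target in the stack frame.
#' @slot windowPx side of the square local window in pixels.
#' @slot depth running-average depth (number of previous aligned windows).
#' @slot entries data.frame: label, dx, dy, score, flagged, manual,
#'   auto_dx, auto_dy.
#' @slot windows list of aligned window images (for image-based stage
#'   correction).
#' @export
setClass("AlignedTargetList",
  representation(targetPoint = "numeric", windowPx = "numeric",
                 depth = "numeric", entries = "data.frame", windows = "list"),
  validity = function(object) {
    e <- object@entries
    if (nrow(e) && !all(is.finite(e$dx) & is.finite(e$dy))) {
      return("target offsets must be finite")
    }
    TRUE
  })

#' QualityResult: sparse-sampling image quality evaluation
#'
#' @slot grid matrix of per-kernel quality values q.
#' @slot score aggregate score (mean of the best fraction of grid points).
#' @slot pass TRUE when score >= threshold.
#' @slot threshold the threshold used.
#' @export
setClass("QualityResult",
  representation(grid = "matrix", score = "numeric", pass = "logical",
                 threshold = "numeric"),
  validity = function(object) {
    if (!is.finite(object@score)) return("score must be finite")
    TRUE
  })

#' FocusPlane: planar model z = a x + b y + c of optimal focus
#' @slot a,b,c plane coefficients (z and x, y in stage micrometres).
#' @export
setClass("FocusPlane",
  representation(a = "numeric", b = "numeric", c = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@a, object@b, object@c)))) {
      return("coefficients must be finite")
    }
    TRUE
  })

#' MontageParams: geometry and imaging parameters of a high-resolution montage
#'
#' @slot xOffsetUm,yOffsetUm montage centre offset from the aligned target
#'   point, in the montage frame.
#' @slot northAngleDeg montage frame rotation; applied as scan rotation so all
#'   sections are acquired in the same orientation.
#' @slot tileFovUm field of view of one tile (square), micrometres.
#' @slot tilePixels pixels per tile side.
#' @slot rows,cols tile grid dimensions.
#' @slot overlapUm overlap between adjacent tiles (default 4).
#' @slot dwellNs pixel dwell time in nanoseconds.
#' @slot subsetMask logical rows x cols matrix; FALSE tiles are skipped.
#' @slot qualityThreshold per-tile quality gate.
#' @slot focusStrategy one of "per_montage", "per_section", "plane_3x3",
#'   "pooled_2x2".
#' @slot ibsc use image-based stage correction?
#' @slot focusOffsetUm autofocus spot offset from the target (may differ from
#'   the imaging target).
#' @export
setClass("MontageParams",
  representation(xOffsetUm = "numeric", yOffsetUm = "numeric",
                 northAngleDeg = "numeric", tileFovUm = "numeric",
                 tilePixels = "numeric", rows = "numeric", cols = "numeric",
                 overlapUm = "numeric", dwellNs = "numeric",
                 subsetMask = "matrix", qualityThreshold = "numeric",
                 focusStrategy = "character", ibsc = "logical",
                 focusOffsetUm = "numeric"),
  validity = function(object) {
    if (object@rows < 1 || object@cols < 1) return("rows and cols must be >= 1")
    if (object@overlapUm >= object@tileFovUm) {
      return("overlap must be smaller than the tile field of view")
    }
    if (!all(dim(object@subsetMask) == c(object@rows, object@cols))) {
      return("subsetMask must be rows x cols")
    }
    if (!object@focusStrategy %in%
        c("per_montage", "per_section", "plane_3x3", "pooled_2x2")) {
      return("unknown focus strategy")
    }
    TRUE
  })

#' WaferRecord: metadata for one mapped wafer
#'
#' @slot waferId integer id.
#' @slot mapTransform [SimilarityTransform-class] from full-wafer-image pixels
#'   to stage micrometres.
#' @slot fiducials list: stage positions and stored low/high-res images.
#' @slot sections data.frame of [SectionRecord] rows: label, x_um, y_um,
#'   thetaDeg, strip, status.
#' @slot pixelToStageFactor dimensionless calibration factor.
#' @slot overviewParams list of the overview acquisition parameters used.
#' @slot paths list of file locations (wafer image, overviews directory).
#' @export
setClass("WaferRecord",
  representation(waferId = "integer", mapTransform = "SimilarityTransform",
                 fiducials = "list", sections = "data.frame",
                 pixelToStageFactor = "numeric", overviewParams = "list",
                 paths = "list"),
  prototype(pixelToStageFactor = 1))

#' UTSLRecord: library-level metadata
#'
#' @slot name library name.
#' @slot path root directory of the UTSL store.
#' @slot wafers integer vector of wafer ids, in collection order.
#' @slot sectionCounter last assigned tape-order label.
#' @slot overviewParams list.
#' @slot targets character vector of defined target-point names.
#' @slot provenance list: created, softwareVersion, masterSeed, formatVersion.
#' @export
setClass("UTSLRecord",
  representation(name = "character", path = "character", wafers = "integer",
                 sectionCounter = "integer", overviewParams = "list",
                 targets = "character", provenance = "list"))
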