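# UTSL directory store, metadata persistence, planning arithmetic and
# acquisition logging.

utslFormatVersion <- 1L

#' Initialise a UTSL directory store
#'
#' Creates the canonical skeleton (`utsl.json`, `wafers/`,
#' `aligned_overviews/`, `targets/`, `montages/`) and persists the library
#' record. Refuses to overwrite an existing library unless `force = TRUE`.
#'
#' @param path root directory for the library.
#' @param config list: `name`, `masterSeed`, optional `overviewParams`.
#' @param force overwrite an existing library?
#' @return a [UTSLRecord-class].
#' @export
initUtsl <- function(path, config = list(), force = FALSE) {
  if (file.exists(file.path(path, "utsl.json")) && !force) {
    stop("a UTSL already exists at this path (use force = TRUE)")
  }
  for (d in c("", "wafers", "aligned_overviews", "targets", "montages")) {
    dir.create(file.path(path, d), recursive = TRUE, showWarnings = FALSE)
  }
  rec <- new("UTSLRecord",
             name = if (is.null(config$name)) basename(path) else config$name,
             path = path, wafers = integer(0), sectionCounter = 0L,
             overviewParams = if (is.null(config$overviewParams))
               overviewParams() else config$overviewParams,
             targets = character(0),
             provenance = list(
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               softwareVersion = tryCatch(
                 as.character(utils::packageVersion("utslmap")),
                 error = function(e) "dev"),
               masterSeed = if (is.null(config$masterSeed)) NA_integer_
                 else as.integer(config$masterSeed),
               formatVersion = utslFormatVersion))
  saveUtsl(rec)
  rec
}

#' Persist a UTSL record to its store
#' @param record a [UTSLRecord-class].
#' @export
saveUtsl <- function(record) {
  jsonlite::write_json(
    list(name = record@name, wafers = record@wafers,
         sectionCounter = record@sectionCounter,
         overviewParams = record@overviewParams,
         targets = record@targets, provenance = record@provenance),
    file.path(record@path, "utsl.json"),
    digits = NA, auto_unbox = TRUE, null = "null")
  invisible(record)
}

#' Load a UTSL record from a store
#' @param path library root.
#' @return a [UTSLRecord-class].
#' @export
loadUtsl <- function(path) {
  f <- file.path(path, "utsl.json")
  if (!file.exists(f)) stop("no UTSL at this path")
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  new("UTSLRecord", name = j$name, path = path,
      wafers = as.integer(j$wafers),
      sectionCounter = as.integer(j$sectionCounter),
      overviewParams = as.list(j$overviewParams),
      targets = as.character(j$targets),
      provenance = as.list(j$provenance))
}

setMethod("show", "UTSLRecord", function(object) {
  cat(sprintf(
    "UTSLRecord '%s': %d wafers, %d sections, %d targets (%s)\n",
    object@name, length(object@wafers), object@sectionCounter,
    length(object@targets), object@path))
})

#' Raw pixel scan time of an imaging plan
#'
#' Pure arithmetic used for feasibility planning: seconds =
#' sections x pixels per section / scan rate. At 10 megapixels per second a
#' full 17,000-section library at 500,000 x 600,000 pixels per section is
#' over 15 years of beam time -- the argument for targeted acquisition.
#'
#' @param nSections number of sections.
#' @param pixelsPerSection pixels in one section's montage.
#' @param ratePps scan rate in pixels per second.
#' @return seconds (numeric).
#' @export
estimateScanTime <- function(nSections, pixelsPerSection, ratePps) {
  if (nSections <= 0 || pixelsPerSection <= 0 || ratePps <= 0) {
    stop("all inputs must be positive")
  }
  nSections * pixelsPerSection / ratePps
}

#' Whole days (truncated) in a number of seconds
#' @param seconds numeric.
#' @export
secondsToWholeDays <- function(seconds) floor(seconds / 86400)

#' Years (365.25 days) in a number of seconds
#' @param seconds numeric.
#' @export
secondsToYears <- function(seconds) seconds / (365.25 * 86400)

#' Storage required by an imaging plan
#' @inheritParams estimateScanTime
#' @param bytesPerPixel bytes per stored pixel.
#' @return bytes (numeric).
#' @export
estimateStorage <- function(nSections, pixelsPerSection, bytesPerPixel) {
  if (nSections <= 0 || pixelsPerSection <= 0 || bytesPerPixel <= 0) {
    stop("all inputs must be positive")
  }
  nSections * pixelsPerSection * bytesPerPixel
}

#' Petabytes (1e15 bytes) in a byte count
#' @param bytes numeric.
#' @export
bytesToPetabytes <- function(bytes) bytes / 1e15

#' Widest field of view at a pixel size
#' @param pixels image width in pixels (e.g. 32000 for a 32 k scan
#'   generator).
#' @param pixelSizeNm pixel size in nanometres.
#' @return field of view in micrometres.
#' @export
maxFieldOfViewUm <- function(pixels, pixelSizeNm) {
  pixels * pixelSizeNm / 1000
}

#' Depth spanned by a run of sections
#' @param nSections number of sections.
#' @param thicknessNm section thickness in nanometres.
#' @return depth in micrometres.
#' @export
sectionSpanUm <- function(nSections, thicknessNm) {
  nSections * thicknessNm / 1000
}

#' Acquisition plan with per-section overheads
#'
#' @param nSections sections to image.
#' @param pixelsPerSection pixels per section montage.
#' @param ratePps scan rate (pixels/s).
#' @param bytesPerPixel stored bytes per pixel.
#' @param tilesPerSection tiles in each section's montage.
#' @param moveS stage movement to the section (default 10 s).
#' @param ibscS image-based stage correction (default 60 s).
#' @param focusS focus-stigmation-focus (default 120 s).
#' @param tileGapS time between tiles including the quality check
#'   (default 8 s).
#' @return list of class "planEstimate".
#' @export
planEstimate <- function(nSections, pixelsPerSection, ratePps,
                         bytesPerPixel = 1, tilesPerSection = 1,
                         moveS = 10, ibscS = 60, focusS = 120,
                         tileGapS = 8) {
  if (any(c(moveS, ibscS, focusS, tileGapS) < 0)) {
    stop("overheads must be non-negative")
  }
  structure(list(nSections = nSections,
                 pixelsPerSection = pixelsPerSection, ratePps = ratePps,
                 bytesPerPixel = bytesPerPixel,
                 tilesPerSection = tilesPerSection, moveS = moveS,
                 ibscS = ibscS, focusS = focusS, tileGapS = tileGapS),
            class = "planEstimate")
}

#' Itemised acquisition time estimate
#'
#' Raw scan time plus per-section (move, IBSC, focus) and per-tile
#' overheads.
#'
#' @param plan a [planEstimate].
#' @return list: `rawScanS`, `overheadS`, `totalS`, `totalBytes`, `items`
#'   (named breakdown in seconds).
#' @export
estimateAcquisition <- function(plan) {
  raw <- estimateScanTime(plan$nSections, plan$pixelsPerSection,
                          plan$ratePps)
  items <- c(rawScan = raw,
             move = plan$nSections * plan$moveS,
             ibsc = plan$nSections * plan$ibscS,
             focus = plan$nSections * plan$focusS,
             tileGap = plan$nSections * plan$tilesPerSection * plan$tileGapS)
  overhead <- sum(items) - raw
  list(rawScanS = raw, overheadS = overhead, totalS = raw + overhead,
       totalBytes = estimateStorage(plan$nSections, plan$pixelsPerSection,
                                    plan$bytesPerPixel),
       items = items)
}

#' Append one event to a JSON-lines acquisition log
#'
#' Every stage movement, quality result and retake during acquisition is
#' logged as one JSON object per line; the log is append-only.
#'
#' @param path log file path (created on first write).
#' @param record named list; a `ts` timestamp is added when missing.
#' @export
writeLogEvent <- function(path, record) {
  if (is.null(record$ts)) {
    record$ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  }
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                           null = "null")
  cat(line, "\n", file = path, sep = "", append = TRUE)
  invisible(path)
}

#' Read a JSON-lines acquisition log
#' @param path log file path.
#' @return list of event records (empty list for an empty/missing file);
#'   malformed lines raise an error naming the line number.
#' @export
readLog <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("malformed log line %d: %s", i,
                            conditionMessage(e)), call. = FALSE)
             })
  })
}
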