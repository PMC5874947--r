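#' Load a scanned film TIFF
#'
#' Reads an RGB TIFF (8 or 16 bits per channel; 8-bit input is rescaled to
#' the 16-bit range with a warning). Resolution is taken from the file's
#' x-resolution metadata when present and expressed in dpi; otherwise the
#' \code{dpi} argument is required. The unexposed reference is either given
#' directly or measured as the per-channel mean over a rectangular patch.
#'
#' @param path TIFF file path.
#' @param dpi scan resolution override (dots per inch); required when the
#'   file carries no resolution metadata.
#' @param unexposedPatch optional integer vector \code{c(row1, row2, col1,
#'   col2)} delimiting an unexposed patch (inclusive pixel indices).
#' @param unexposedReference optional per-channel reference value(s);
#'   a scalar is recycled over the three channels. Overrides the patch.
#' @return a \linkS4class{FilmScan}.
#' @export
loadScan <- function(path, dpi = NULL, unexposedPatch = NULL,
                     unexposedReference = NULL) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop("not a readable TIFF: ", path,
                                           " (", conditionMessage(e), ")"))
  info <- attributes(img)
  if (length(dim(img)) < 3)
    stop("expected 3 channels (RGB) in ", path, "; got a single channel")
  if (dim(img)[3] < 3)
    stop("expected 3 channels (RGB) in ", path, "; got ", dim(img)[3])
  img <- img[, , 1:3, drop = FALSE]
  bps <- info$bits.per.sample %||% 16L
  if (bps < 8) stop("expected >= 8 bits per channel in ", path)
  if (bps == 8)
    warning("8-bit scan rescaled to the 16-bit range")
  # readTIFF normalizes to [0, 1]; rescale to 16-bit integers
  px <- round(img * 65535)

  if (is.null(dpi)) {
    xr <- info$x.resolution
    unit <- info$resolution.unit %||% "inch"
    if (!is.null(xr) && is.finite(xr) && xr > 0 &&
        identical(unit, "inch")) {
      dpi <- xr
    } else {
      stop("no resolution metadata in ", path,
           "; supply the scan resolution explicitly via dpi=")
    }
  }
  if (dpi <= 0) stop("dpi must be > 0")

  ref <- rep(NA_real_, 3)
  if (!is.null(unexposedReference)) {
    ref <- rep_len(as.numeric(unexposedReference), 3)
  } else if (!is.null(unexposedPatch)) {
    p <- as.integer(unexposedPatch)
    if (length(p) != 4 || p[1] > p[2] || p[3] > p[4] ||
        p[1] < 1 || p[2] > dim(px)[1] || p[3] < 1 || p[4] > dim(px)[2])
      stop("unexposedPatch must be c(row1, row2, col1, col2) inside the scan")
    ref <- apply(px[p[1]:p[2], p[3]:p[4], , drop = FALSE], 3, mean)
  }
  new("FilmScan", pixels = px, dpi = as.numeric(dpi),
      unexposedReference = ref)
}

#' Write a FilmScan to a 16-bit RGB TIFF
#'
#' Note: the underlying writer stores no resolution metadata, so the dpi
#' must travel alongside the file (e.g. as a flag when re-loading).
#'
#' @param scan a \linkS4class{FilmScan}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScan <- function(scan, path) {
  stopifnot(is(scan, "FilmScan"))
  tiff::writeTIFF(scan@pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Convert a film scan to a 2D dose map
#'
#' Per pixel, the net MPV is the unexposed reference minus the pixel value
#' on the chosen channel, clamped at zero (pixels brighter than the
#' reference are read as zero dose, as expected for unexposed corners),
#' then pushed through the calibration curve. Pixels darker than the
#' calibrated ceiling are flagged in the out-of-range mask.
#'
#' @param scan a \linkS4class{FilmScan} with a finite unexposed reference.
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param channel \code{"red"} (default; highest sensitivity for this film
#'   class), \code{"green"}, \code{"blue"} or \code{"mean"} (luminance
#'   average).
#' @param raw if \code{TRUE}, use the raw pixel value as the MPV instead of
#'   the net difference from the unexposed reference.
#' @return a \linkS4class{DoseMap} with \code{pixelSpacing = 25.4 / dpi}.
#' @export
scanToDoseMap <- function(scan, curve,
                          channel = c("red", "green", "blue", "mean"),
                          raw = FALSE) {
  stopifnot(is(scan, "FilmScan"), is(curve, "CalibrationCurve"))
  channel <- match.arg(channel)
  ch <- switch(channel, red = 1L, green = 2L, blue = 3L, mean = 0L)
  vals <- if (ch == 0L) apply(scan@pixels, c(1, 2), mean)
          else scan@pixels[, , ch]
  if (raw) {
    net <- vals
  } else {
    ref <- if (ch == 0L) mean(scan@unexposedReference)
           else scan@unexposedReference[ch]
    if (!is.finite(ref))
      stop("scan has no unexposed reference; supply one at load time ",
           "or use raw = TRUE")
    net <- pmax(ref - vals, 0)
  }
  d <- mpvToDose(curve, as.numeric(net))
  oor <- matrix(attr(d, "outOfRange"), nrow = nrow(net))
  dm <- matrix(as.numeric(d), nrow = nrow(net))
  new("DoseMap", dose = dm, pixelSpacing = 25.4 / scan@dpi,
      outOfRange = oor)
}

#' Construct a circular region of interest
#'
#' Geometry is in millimetres from the image top-left corner, x rightward
#' (columns), y downward (rows).
#'
#' @param centerX,centerY circle center, mm.
#' @param radius circle radius, mm.
#' @return a \linkS4class{CircularROI}.
#' @export
circularROI <- function(centerX, centerY, radius) {
  new("CircularROI", center = c(centerX, centerY), radius = radius)
}

#' Mean dose inside a circular mask
#'
#' Unweighted mean over the pixels whose centers lie inside the circle
#' (pixel (r, c) center at ((c - 0.5) s, (r - 0.5) s) for spacing s).
#'
#' @param map a \linkS4class{DoseMap}.
#' @param roi a \linkS4class{CircularROI}.
#' @return list with \code{mean} (mGy), \code{n} (contributing pixel
#'   count), \code{sd} (per-pixel SD inside the mask) and
#'   \code{n_out_of_range} (flagged pixels inside the mask).
#' @export
roiMeanDose <- function(map, roi) {
  stopifnot(is(map, "DoseMap"), is(roi, "CircularROI"))
  s <- map@pixelSpacing
  nr <- nrow(map@dose); nc <- ncol(map@dose)
  cx <- (seq_len(nc) - 0.5) * s
  cy <- (seq_len(nr) - 0.5) * s
  dx2 <- (cx - roi@center[1])^2
  dy2 <- (cy - roi@center[2])^2
  inside <- outer(dy2, dx2, `+`) <= roi@radius^2
  n <- sum(inside)
  if (n == 0)
    stop("circular ROI contains no pixel centers (empty intersection)")
  v <- map@dose[inside]
  list(mean = mean(v), n = n, sd = stats::sd(v),
       n_out_of_range = sum(map@outOfRange[inside]))
}

#' Read a circular-ROI table from CSV
#'
#' Expected header: \code{center_x_mm,center_y_mm,radius_mm,slice_id}.
#'
#' @param path CSV path.
#' @return data.frame with a list-column free layout; one ROI per row.
#' @export
readRoiTable <- function(path) {
  if (!file.exists(path)) stop("ROI table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("center_x_mm", "center_y_mm", "radius_mm", "slice_id")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns: ", paste(need, collapse = ","))
  if (any(df$radius_mm <= 0)) stop("ROI radii must be > 0")
  df
}
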