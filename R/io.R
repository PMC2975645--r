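#' Read a planar NIR image from TIFF (+ optional JSON sidecar)
#'
#' Accepts single-plane grayscale TIFF (8/16-bit integer or 32-bit
#' float). Integer TIFFs are read back as their original integer values;
#' float TIFFs are rescaled by the \code{scale} recorded in the sidecar.
#' Metadata come from the JSON sidecar (\code{<path>.json} by default);
#' without one, metadata default to the acquisition filters of the NIR
#' window (excitation 710 nm, emission 790 nm) and view "unknown".
#'
#' @param path TIFF file path.
#' @param sidecar path of the JSON metadata sidecar; defaults to
#'   \code{paste0(path, ".json")}, silently skipped when absent.
#' @return a [NIRImage].
#' @export
readNIRImage <- function(path, sidecar = paste0(path, ".json")) {
  raw <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(raw)) == 3L)
    stop("unsupported format: multi-channel/RGB TIFF (single grayscale plane required)",
         call. = FALSE)
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  px <- if (bits <= 16L) {
    # integer TIFF: readTIFF rescales by 2^bits - 1; undo it exactly
    matrix(round(as.numeric(raw) * (2^bits - 1)), nrow(raw), ncol(raw))
  } else matrix(as.numeric(raw), nrow(raw), ncol(raw)) # float plane
  meta <- list(subject_id = "unknown", timepoint_h = NA_real_, view = "unknown",
               excitation_nm = 710, emission_nm = 790, pixel_size_mm = NA_real_)
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (f in intersect(names(meta), names(sc)))
      if (!is.null(sc[[f]])) meta[[f]] <- sc[[f]]
    num <- c("timepoint_h", "excitation_nm", "emission_nm", "pixel_size_mm")
    for (f in num) if (!is.null(meta[[f]])) meta[[f]] <- as.numeric(meta[[f]])
    if (!is.null(sc$scale)) px <- px * as.numeric(sc$scale)
  }
  if (any(px < 0))
    stop("validation error: negative pixel intensities in ", path, call. = FALSE)
  NIRImage(px, subject_id = meta$subject_id, timepoint_h = meta$timepoint_h,
           view = meta$view, excitation_nm = meta$excitation_nm,
           emission_nm = meta$emission_nm, pixel_size_mm = meta$pixel_size_mm)
}

#' Write a planar NIR image as TIFF with a JSON metadata sidecar
#'
#' \code{bits = 16} stores integer intensities in 0..65535 exactly (the
#' writer refuses non-integer or out-of-range values rather than silently
#' quantizing); \code{bits = 32} stores floating-point intensities at
#' float32 precision, rescaled into [0, 1] with the scale factor recorded
#' in the sidecar.
#'
#' @param img a [NIRImage].
#' @param path output TIFF path.
#' @param bits 16 (integer) or 32 (float).
#' @param sidecar sidecar path (default \code{paste0(path, ".json")}).
#' @return invisibly, \code{path}.
#' @export
writeNIRImage <- function(img, path, bits = 16L, sidecar = paste0(path, ".json")) {
  px <- pixels(img)
  meta <- imageMeta(img)
  if (bits == 16L) {
    if (any(px != round(px)) || any(px > 65535))
      stop("16-bit TIFF requires integer intensities in 0..65535; ",
           "use bits = 32 for floating-point images", call. = FALSE)
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
    scale <- 65535
  } else if (bits == 32L) {
    scale <- max(px, 1)
    tiff::writeTIFF(px / scale, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  } else stop("bits must be 16 or 32", call. = FALSE)
  sc <- c(meta, list(scale = if (bits == 32L) scale else NULL, bits = bits))
  sc <- sc[!vapply(sc, is.null, logical(1))]
  jsonlite::write_json(sc, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a RegionSet from a labeled TIFF mask plus a JSON name map
#'
#' @param maskPath 16-bit labeled TIFF (0 = unassigned).
#' @param namesPath JSON object mapping label to region name, e.g.
#'   \code{{"1": "body", "2": "tumor"}}.
#' @return a validated [RegionSet]; a name map referencing an absent
#'   label is a validation error.
#' @export
readRegionSet <- function(maskPath, namesPath) {
  raw <- tiff::readTIFF(maskPath, as.is = TRUE)
  if (length(dim(raw)) == 3L)
    stop("unsupported format: label mask must be single-plane", call. = FALSE)
  lab <- matrix(as.integer(raw), nrow(raw), ncol(raw))
  nm <- jsonlite::read_json(namesPath, simplifyVector = TRUE)
  RegionSet(lab, stats::setNames(as.character(nm), names(nm)))
}

#' Write a RegionSet as a labeled 16-bit TIFF plus a JSON name map
#'
#' @param regions a [RegionSet].
#' @param maskPath output TIFF path.
#' @param namesPath output JSON path.
#' @return invisibly, \code{maskPath}.
#' @export
writeRegionSet <- function(regions, maskPath, namesPath) {
  lab <- labelMatrix(regions)
  if (max(lab) > 65535) stop("more than 65535 labels not representable", call. = FALSE)
  tiff::writeTIFF(lab / 65535, maskPath, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(as.list(regions@regionNames), namesPath,
                       auto_unbox = TRUE)
  invisible(maskPath)
}

#' Composite overlay of fluorescence on a white-field image
#'
#' Purely presentational: the white-field frame is rendered in grayscale
#' and NIR pixels above the \code{displayFloor} quantile are pseudocolored
#' and alpha-blended on top; pixels below the floor stay fully
#' transparent. With \code{displayFloor = 0} every pixel is colored. The
#' floor quantile is computed over \code{floorMask} when given (typically
#' the body mask) so that the display threshold tracks within-body
#' intensity, else over all pixels.
#'
#' @param whitefield [NIRImage] (or matrix) anatomical frame.
#' @param nir [NIRImage] (or matrix) fluorescence frame, same shape.
#' @param displayFloor quantile in [0, 1) below which NIR is transparent
#'   (default 0.95).
#' @param colormap palette name passed to [grDevices::hcl.colors()]
#'   (default "Inferno").
#' @param alpha blend weight of the pseudocolor layer in [0, 1].
#' @param floorMask optional logical matrix over which the floor quantile
#'   is computed.
#' @return rows x cols x 3 array of RGB values in [0, 1], with attribute
#'   \code{"colored"} giving the logical matrix of pseudocolored pixels.
#' @export
compositeOverlay <- function(whitefield, nir, displayFloor = 0.95,
                             colormap = "Inferno", alpha = 0.6,
                             floorMask = NULL) {
  wf <- if (is(whitefield, "NIRImage")) pixels(whitefield) else whitefield
  fl <- if (is(nir, "NIRImage")) pixels(nir) else nir
  stopShapeMatch(wf, fl, "whitefield and NIR images")
  if (displayFloor < 0 || displayFloor >= 1)
    stop("displayFloor must be in [0, 1)", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  gray <- if (max(wf) > 0) wf / max(wf) else wf
  rgb <- array(gray, c(dim(wf), 3L))
  qsrc <- if (is.null(floorMask)) fl else fl[floorMask]
  if (displayFloor == 0) {
    colored <- matrix(TRUE, nrow(fl), ncol(fl))
    thr <- min(fl)
  } else {
    thr <- stats::quantile(qsrc, displayFloor, names = FALSE)
    colored <- fl > thr
  }
  if (any(colored)) {
    pal <- grDevices::hcl.colors(256L, colormap)
    rng <- range(fl[colored])
    idx <- if (rng[2] > rng[1])
      1L + as.integer(round(255 * (fl[colored] - rng[1]) / (rng[2] - rng[1])))
    else rep(256L, sum(colored))
    colrgb <- grDevices::col2rgb(pal[idx]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[colored] <- (1 - alpha) * plane[colored] + alpha * colrgb[ch, ]
      rgb[, , ch] <- plane
    }
  }
  attr(rgb, "colored") <- colored
  rgb
}

#' Write an RGB array as PNG
#' @param rgb rows x cols x 3 array in [0, 1] (e.g. from
#'   [compositeOverlay()]).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeOverlayPNG <- function(rgb, path) {
  attr(rgb, "colored") <- NULL
  png::writePNG(rgb, path)
  invisible(path)
}
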