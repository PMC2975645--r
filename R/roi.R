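#' Construct ThresholdParams
#'
#' @param method "otsu" (default; between-class variance maximization on
#'   a 256-level histogram of the working pixels) or "quantile".
#' @param quantileQ quantile in (0, 1), used when method = "quantile".
#' @param minArea minimum component area in pixels (default 25 px,
#'   rejecting small bright specks such as residual hairs).
#' @param seedPoints optional named list of c(row, col) seeds; each named
#'   region becomes the component containing its seed.
#' @param restrictTo optional logical mask (typically the body).
#' @return a [ThresholdParams].
#' @export
thresholdParams <- function(method = c("otsu", "quantile"), quantileQ = 0.95,
                            minArea = 25, seedPoints = NULL, restrictTo = NULL) {
  method <- match.arg(method)
  new("ThresholdParams", method = method, quantileQ = quantileQ,
      minArea = minArea,
      seedPoints = if (is.null(seedPoints)) list() else seedPoints,
      restrictTo = restrictTo)
}

# Otsu threshold of a value vector: exhaustive between-class-variance
# maximization over the distinct values (the classic formulation on
# quantized data); continuous data with more than `levels` distinct values
# are first quantized to `levels` bins. Returns a threshold on the original
# intensity scale; pixels are foreground when strictly above it.
otsuThreshold <- function(values, levels = 256L) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(u[1]) # degenerate: strict > yields nothing
  if (length(u) > levels) {
    edges <- seq(u[1], u[length(u)], length.out = levels + 1L)
    bins <- pmin(findInterval(values, edges, all.inside = TRUE), levels)
    w <- tabulate(bins, nbins = levels)
    keep <- w > 0L
    # class boundary at a bin's upper edge keeps the strict-> partition
    vals <- edges[-1][keep]
    w <- w[keep]
  } else {
    w <- tabulate(match(values, u), nbins = length(u))
    vals <- u
  }
  p <- w / sum(w)
  w0 <- cumsum(p)
  mu <- cumsum(p * vals)
  muT <- mu[length(mu)]
  n <- length(vals)
  bcv <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  vals[which.max(bcv[-n])]
}

#' Detect ROIs by threshold analysis
#'
#' Reproduces threshold-based ROI determination against a reference
#' image: when a reference is supplied (e.g. the skin-removed frame of
#' the same subject, or a phantom's noise-free ground truth), the working
#' image is the pixelwise minimum of image and reference, so a candidate
#' ROI must be bright in both. The working pixels (within
#' \code{restrictTo} when given) are thresholded (strictly above, so a
#' constant image yields no detection), 8-connected components are
#' extracted, and components smaller than \code{minArea} are dropped.
#' With seed points, each named region is the surviving component
#' containing its seed; otherwise components are named
#' \code{roi_1, roi_2, ...} by decreasing mean working intensity.
#'
#' @param image a [NIRImage].
#' @param reference optional [NIRImage] of identical shape.
#' @param params a [ThresholdParams].
#' @return a [RegionSet]; empty (with a warning) when nothing survives.
#' @export
detectROIs <- function(image, reference = NULL, params = thresholdParams()) {
  px <- pixels(image)
  if (!is.null(reference)) {
    rpx <- pixels(reference)
    stopShapeMatch(px, rpx, "image and reference")
    px <- pmin(px, rpx)
  }
  restrict <- params@restrictTo
  if (is.null(restrict)) restrict <- matrix(TRUE, nrow(px), ncol(px))
  vals <- px[restrict]
  thr <- if (params@method == "otsu") otsuThreshold(vals)
         else stats::quantile(vals, params@quantileQ, names = FALSE)
  fg <- px > thr & restrict
  lab <- label8(fg)
  keep <- which(tabulate(lab[lab > 0L]) >= params@minArea)
  if (!length(keep)) {
    warning("detectROIs: no component survives the threshold/minArea filter; ",
            "returning an empty RegionSet")
    return(RegionSet(matrix(0L, nrow(px), ncol(px))))
  }
  if (length(params@seedPoints)) {
    out <- matrix(0L, nrow(px), ncol(px))
    nm <- character()
    nextLab <- 1L
    for (rn in names(params@seedPoints)) {
      sp <- params@seedPoints[[rn]]
      l <- lab[sp[1], sp[2]]
      if (l == 0L || !(l %in% keep))
        stop("detection error: seed for region '", rn,
             "' lies in no surviving component", call. = FALSE)
      out[lab == l] <- nextLab
      nm[as.character(nextLab)] <- rn
      nextLab <- nextLab + 1L
    }
    return(RegionSet(out, nm))
  }
  means <- vapply(keep, function(l) mean(px[lab == l]), numeric(1))
  ord <- keep[order(means, decreasing = TRUE)]
  out <- matrix(0L, nrow(px), ncol(px))
  nm <- character()
  for (i in seq_along(ord)) {
    out[lab == ord[i]] <- i
    nm[as.character(i)] <- paste0("roi_", i)
  }
  RegionSet(out, nm)
}

#' Background annulus around an ROI ("scattered light" reference)
#'
#' The noise reference for the normalized SNR is the scattered light from
#' internal organs near the ROI; this builds a morphological dilation
#' ring around the named region: \code{dilate(roi, rOut)} minus
#' \code{dilate(roi, rIn)}, intersected with the body silhouette and
#' excluding every other named region. Dilation uses the Chebyshev
#' (8-connectivity) metric, so \code{rIn = 0, rOut = 1} around a single
#' pixel gives its 8 neighbors.
#'
#' @param regions a [RegionSet] containing the ROI (and usually "body").
#' @param roiName region name.
#' @param rIn,rOut inner / outer dilation radii (pixels), 0 <= rIn < rOut.
#' @return logical matrix; errors when the annulus is empty after
#'   exclusions (try a larger rOut).
#' @export
backgroundAnnulus <- function(regions, roiName, rIn = 3, rOut = 10) {
  if (rIn < 0 || rIn >= rOut) stop("need 0 <= rIn < rOut", call. = FALSE)
  roi <- regionMask(regions, roiName)
  if (!any(roi)) stop("empty region '", roiName, "'", call. = FALSE)
  ring <- dilateMask(roi, rOut) & !dilateMask(roi, rIn)
  if (hasRegion(regions, "body")) ring <- ring & regionMask(regions, "body")
  for (nm in regionNames(regions)) {
    if (nm %in% c("body", roiName)) next
    ring <- ring & !regionMask(regions, nm)
  }
  ring <- ring & !roi
  if (!any(ring))
    stop("annulus error: empty background annulus for '", roiName,
         "' after exclusions; try a larger rOut", call. = FALSE)
  ring
}

#' Hip reference ROI used for luminosity normalization
#'
#' Returns the mask of the region named \code{hip_ref}, validating that
#' it does not overlap the tumor or any organ region (it must carry only
#' autofluorescence for the normalization to remove global luminosity
#' differences).
#'
#' @param regions a [RegionSet].
#' @return logical matrix.
#' @export
hipReferenceROI <- function(regions) {
  if (!hasRegion(regions, "hip_ref"))
    stop("configuration error: no 'hip_ref' region; hip normalization cannot proceed",
         call. = FALSE)
  hip <- regionMask(regions, "hip_ref")
  for (nm in setdiff(regionNames(regions), c("body", "hip_ref")))
    if (any(hip & regionMask(regions, nm)))
      stop("validation error: hip_ref overlaps region '", nm, "'", call. = FALSE)
  hip
}
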