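#' Cumulative pixel-value histogram over a mask
#'
#' Normalized cumulative frequency of the masked pixels, with the mask's
#' mean and population SD attached (identical to [meanIntensity()] on the
#' same mask). When two masks are to be compared, shared bin edges must
#' be supplied (see [sharedBinEdges()]).
#'
#' @param image a [NIRImage] or matrix.
#' @param mask non-empty logical matrix.
#' @param nBins bin count when edges are computed from the mask's own
#'   range (default 64).
#' @param edges optional shared bin edges; values outside are clamped
#'   into the terminal bins.
#' @param maskName label stored in the result.
#' @return a [CumulativeHistogram].
#' @export
cumulativeHistogram <- function(image, mask, nBins = 64L, edges = NULL,
                                maskName = "mask") {
  px <- if (is(image, "NIRImage")) pixels(image) else image
  stopShapeMatch(px, mask, "image and mask")
  if (!any(mask)) stop("empty-region error: mask selects no pixels", call. = FALSE)
  v <- px[mask]
  if (is.null(edges)) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) # constant image: one hot bin
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  }
  nb <- length(edges) - 1L
  idx <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  new("CumulativeHistogram", binEdges = edges,
      cumFreq = cumsum(counts) / length(v), maskName = maskName,
      mean = mean(v), sd = popSD(v))
}

#' Shared bin edges over the pooled range of two masks
#'
#' @param image a [NIRImage] or matrix.
#' @param maskA,maskB logical masks.
#' @param nBins bin count (default 64).
#' @return numeric vector of nBins + 1 edges spanning the pooled min-max.
#' @export
sharedBinEdges <- function(image, maskA, maskB, nBins = 64L) {
  px <- if (is(image, "NIRImage")) pixels(image) else image
  rng <- range(c(px[maskA], px[maskB]))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = nBins + 1L)
}

#' Construct a CumulativeHistogram from summary statistics
#'
#' For worked examples where only the printed mean and SD of a pixel
#' distribution are available (no pixel data), this builds a degenerate
#' two-bin histogram carrying those statistics, usable with
#' [distributionContrast()].
#'
#' @param mean,sd summary statistics of the masked pixels.
#' @param maskName label.
#' @param edges bin edges (default a trivial two-bin span around mean).
#' @return a [CumulativeHistogram].
#' @export
histogramFromStats <- function(mean, sd, maskName = "mask", edges = NULL) {
  if (is.null(edges)) edges <- c(mean - 3 * sd - 1, mean, mean + 3 * sd + 1)
  new("CumulativeHistogram", binEdges = edges,
      cumFreq = c(rep(0.5, length(edges) - 2L), 1),
      maskName = maskName, mean = mean, sd = sd)
}

#' Tumor-vs-body pixel distribution contrast
#'
#' Compares two cumulative histograms computed on shared bin edges:
#' \code{meanRatio = mean_tumor / mean_body}, \code{sdRatio = sd_tumor /
#' sd_body}, and \code{separable}, true when the tumor distribution is
#' both brighter (meanRatio > 1) and narrower (sdRatio < 1) than the
#' body's -- the high-slope, high-value pixel distribution that lets a
#' tumor be identified on a composite image.
#'
#' @param tumorHist,bodyHist [CumulativeHistogram]s on identical bin edges.
#' @return list(meanRatio, sdRatio, separable).
#' @export
distributionContrast <- function(tumorHist, bodyHist) {
  if (length(tumorHist@binEdges) != length(bodyHist@binEdges) ||
      any(tumorHist@binEdges != bodyHist@binEdges))
    stop("histograms must share bin edges", call. = FALSE)
  if (bodyHist@mean == 0) stop("degenerate error: body mean is zero", call. = FALSE)
  mr <- tumorHist@mean / bodyHist@mean
  sr <- tumorHist@sd / bodyHist@sd
  list(meanRatio = mr, sdRatio = sr, separable = (mr > 1 && sr < 1))
}

#' Ex vivo lung node-localization analysis
#'
#' Quantifies whether lung fluorescence is diffuse or concentrated around
#' melanoma nodes: \code{localizationIndex = (mean over the union of node
#' rims - A) / (mean over lung parenchyma excluding rims and nodes - A)},
#' where A is the intrinsic lung fluorescence of uninjected controls.
#' An index near 1 means diffuse signal; well above 1 means the signal
#' originates mainly from sites around the node clusters. Also reports
#' the coefficient of variation over the full lung (silhouette) and
#' per-node rim means.
#'
#' @param lungImage ex vivo [NIRImage].
#' @param regions [RegionSet] with \code{lung} and optional
#'   \code{node_k} masks (rims taken from \code{rim_k} masks when
#'   present, else built by dilating each node by \code{ringWidth}).
#' @param ringWidth rim width in pixels (>= 1) when rims must be built.
#' @param aLung intrinsic lung fluorescence baseline (default 0).
#' @param stage optional stage label carried into the result.
#' @return a [LocalizationResult]; with no nodes the index is NA and only
#'   the lung CV is meaningful (\code{hasNodes = FALSE}).
#' @export
nodeLocalization <- function(lungImage, regions, ringWidth = 2, aLung = 0,
                             stage = NA_character_) {
  if (ringWidth < 1) stop("precondition error: ringWidth must be >= 1", call. = FALSE)
  if (!hasRegion(regions, "lung")) stop("RegionSet must contain 'lung'", call. = FALSE)
  px <- pixels(lungImage)
  lab <- labelMatrix(regions)
  lungAll <- lab > 0L # full silhouette: parenchyma + nodes + rims
  nms <- regionNames(regions)
  nodeNames <- grep("^node_", nms, value = TRUE)
  rimNames <- grep("^rim_", nms, value = TRUE)
  st <- meanIntensity(px, lungAll)
  lungCV <- if (st$mean > 0) st$sd / st$mean else NA_real_
  if (!length(nodeNames)) {
    return(new("LocalizationResult", stage = stage,
               localizationIndex = NA_real_, lungCV = lungCV,
               nodeRimMeans = numeric(), hasNodes = FALSE))
  }
  nodeUnion <- Reduce(`|`, lapply(nodeNames, regionMask, x = regions))
  if (length(rimNames) == length(nodeNames)) {
    rims <- lapply(rimNames, regionMask, x = regions)
    names(rims) <- rimNames
  } else {
    rims <- lapply(nodeNames, function(nn) {
      m <- regionMask(regions, nn)
      dilateMask(m, ringWidth) & !m & lungAll
    })
    names(rims) <- sub("^node", "rim", nodeNames)
  }
  rimUnion <- Reduce(`|`, rims)
  paren <- lungAll & !rimUnion & !nodeUnion
  rimMean <- meanIntensity(px, rimUnion)$mean
  parenMean <- meanIntensity(px, paren)$mean
  idx <- (rimMean - aLung) / (parenMean - aLung)
  new("LocalizationResult", stage = stage, localizationIndex = idx,
      lungCV = lungCV,
      nodeRimMeans = vapply(rims, function(m) meanIntensity(px, m)$mean, numeric(1)),
      hasNodes = TRUE)
}

setMethod("show", "LocalizationResult", function(object) {
  cat("LocalizationResult (stage ", object@stage, "): index = ",
      format(object@localizationIndex, digits = 4), ", lung CV = ",
      format(object@lungCV, digits = 4), ", ",
      length(object@nodeRimMeans), " node rim(s)\n", sep = "")
})

#' Render a full analysis report to disk
#'
#' Writes, with deterministic file names and content: the per-measurement
#' and summary CSV tables, a machine-readable JSON summary, a grouped
#' bar chart of cohort mean +/- SD SNR per region and timepoint, one
#' cumulative-histogram plot per supplied histogram pair, and any
#' composite overlays. An empty table still yields a valid report with
#' an explicit "no data" marker.
#'
#' @param tct a [TimeCourseTable].
#' @param histograms named list of [CumulativeHistogram] lists (each
#'   element a list of histograms drawn on one plot).
#' @param composites named list of RGB arrays from [compositeOverlay()].
#' @param outDir output directory (created if needed).
#' @return invisibly, character vector of files written.
#' @export
renderReport <- function(tct, histograms = list(), composites = list(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  meas <- measurements(tct)
  summ <- cohortSummary(tct)
  fp <- function(x) file.path(outDir, x)
  utils::write.csv(meas, fp("timecourse.csv"), row.names = FALSE)
  utils::write.csv(summ, fp("summary.csv"), row.names = FALSE)
  files <- c(files, fp("timecourse.csv"), fp("summary.csv"))
  jsonlite::write_json(
    list(no_data = (nrow(meas) == 0L),
         n_measurements = nrow(meas),
         af_source = tct@afSource,
         reference_level = tct@referenceLevel,
         summary = summ,
         dropped = droppedRows(tct)),
    fp("summary.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, fp("summary.json"))
  if (nrow(summ)) {
    summ$timepoint <- factor(summ$timepoint_h)
    p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$roi_name,
                                            y = .data$mean_snr,
                                            fill = .data$timepoint)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_snr - .data$sd_snr,
                                          ymax = .data$mean_snr + .data$sd_snr),
                             position = ggplot2::position_dodge(0.9), width = 0.3) +
      ggplot2::labs(x = NULL, y = "normalized SNR",
                    fill = "time (h)",
                    title = "Cohort mean ± SD normalized SNR") +
      ggplot2::theme_minimal()
    suppressWarnings(ggplot2::ggsave(fp("snr_barchart.png"), p,
                                     width = 7, height = 4, dpi = 120))
    files <- c(files, fp("snr_barchart.png"))
  }
  for (nm in names(histograms)) {
    hl <- histograms[[nm]]
    df <- do.call(rbind, lapply(hl, function(h) {
      data.frame(value = h@binEdges[-1], cumfreq = h@cumFreq, mask = h@maskName)
    }))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cumfreq,
                                          color = .data$mask)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "pixel value", y = "cumulative frequency", title = nm) +
      ggplot2::theme_minimal()
    f <- fp(paste0("cumhist_", nm, ".png"))
    suppressWarnings(ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120))
    files <- c(files, f)
  }
  for (nm in names(composites)) {
    f <- fp(paste0("composite_", nm, ".png"))
    writeOverlayPNG(composites[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
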