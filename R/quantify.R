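#' Mean pixel intensity over a mask
#'
#' Arithmetic mean and population SD (divide by n, the per-pixel
#' statistics convention) over the masked pixels.
#'
#' @param image a [NIRImage] or numeric matrix.
#' @param mask logical matrix of identical shape, non-empty.
#' @return list(mean, sd, nPixels).
#' @export
meanIntensity <- function(image, mask) {
  px <- if (is(image, "NIRImage")) pixels(image) else image
  stopShapeMatch(px, mask, "image and mask")
  if (!any(mask)) stop("empty-region error: mask selects no pixels", call. = FALSE)
  v <- px[mask]
  list(mean = mean(v), sd = popSD(v), nPixels = length(v))
}

#' Hip-reference luminosity normalization
#'
#' Rescales an image so that its mean over the hip reference ROI equals
#' the reference level R, removing per-image global luminosity
#' differences between animals and timepoints. All downstream SNR values
#' are invariant to both the incoming luminosity and the (arbitrary)
#' choice of R.
#'
#' @param image a [NIRImage].
#' @param hipMask logical matrix (e.g. from [hipReferenceROI()]).
#' @param R reference level (> 0, default 100 arbitrary units).
#' @return list(image = normalized [NIRImage], normFactor = R / hip mean).
#' @export
hipNormalize <- function(image, hipMask, R = 100) {
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  hm <- meanIntensity(image, hipMask)$mean
  if (hm <= 0)
    stop("normalization error: hip reference mean is not positive", call. = FALSE)
  f <- R / hm
  img2 <- NIRImage(pixels(image) * f,
                   subject_id = imageMeta(image)$subject_id,
                   timepoint_h = imageMeta(image)$timepoint_h,
                   view = imageMeta(image)$view,
                   excitation_nm = imageMeta(image)$excitation_nm,
                   emission_nm = imageMeta(image)$emission_nm,
                   pixel_size_mm = imageMeta(image)$pixel_size_mm)
  list(image = img2, normFactor = f)
}

#' Estimate the autofluorescence baseline from a control image
#'
#' In vivo: the control (pre-injection or uninjected subject) is first
#' hip-normalized, then averaged over the body mask; the result is the
#' intrinsic-fluorescence baseline A subtracted from every ROI mean. Ex
#' vivo (\code{exVivo = TRUE}): mean over the lung mask of uninjected
#' lungs, without hip normalization (excised organs have no hip
#' reference).
#'
#' @param control control [NIRImage].
#' @param bodyMask logical body (or lung) mask.
#' @param hipMask logical hip mask (required unless exVivo).
#' @param R hip normalization reference level.
#' @param exVivo logical.
#' @param bodyErode pixels by which the body mask is eroded before
#'   averaging (default 3): pixels at the silhouette boundary are
#'   partial-volume mixtures of tissue and background through the
#'   scattering PSF and would bias the baseline low. Not applied ex vivo.
#' @return autofluorescence level A (normalized intensity units).
#' @export
estimateAutofluorescence <- function(control, bodyMask, hipMask = NULL,
                                     R = 100, exVivo = FALSE, bodyErode = 3) {
  if (exVivo) return(meanIntensity(control, bodyMask)$mean)
  if (is.null(hipMask))
    stop("configuration error: hipMask required for in vivo autofluorescence; ",
         "alternatively use the hip fallback A = R * hipAfFraction", call. = FALSE)
  norm <- hipNormalize(control, hipMask, R)$image
  core <- if (bodyErode > 0) !dilateMask(!bodyMask, bodyErode) else bodyMask
  if (!any(core)) core <- bodyMask # degenerate thin body: fall back uneroded
  meanIntensity(norm, core)$mean
}

#' Normalized signal-to-noise ratio of an ROI
#'
#' The per-ROI statistic of the pipeline. Default mode
#' \code{"noise_sd"}: \code{(mean_roi - A) / sd_bg}, the
#' autofluorescence-corrected ROI mean in units of the SD of the
#' scattered light in the near-ROI background annulus ("background noise
#' from the internal organs near the ROI" names a noise, hence an SD).
#' Mode \code{"mean_ratio"} is the alternative reading:
#' \code{(mean_roi - A) / max(mean_bg - A, 1e-9 * R)}. The value is
#' signed: an ROI dimmer than the autofluorescence scores negative and
#' is reported, not clipped.
#'
#' @param imageNorm hip-normalized [NIRImage] (or matrix).
#' @param roiMask,bgMask non-empty, disjoint logical masks.
#' @param A autofluorescence baseline (normalized units).
#' @param mode "noise_sd" (default) or "mean_ratio".
#' @param R reference level (sets the epsilon guard in mean_ratio mode).
#' @return unitless SNR.
#' @export
snr <- function(imageNorm, roiMask, bgMask, A, mode = c("noise_sd", "mean_ratio"),
                R = 100) {
  mode <- match.arg(mode)
  if (any(roiMask & bgMask)) stop("roiMask and bgMask must be disjoint", call. = FALSE)
  roi <- meanIntensity(imageNorm, roiMask)
  bg <- meanIntensity(imageNorm, bgMask)
  if (mode == "noise_sd") {
    if (bg$sd == 0)
      stop("degenerate-background error: zero SD in the background annulus; ",
           "widen the annulus", call. = FALSE)
    (roi$mean - A) / bg$sd
  } else {
    (roi$mean - A) / max(bg$mean - A, 1e-9 * R)
  }
}

#' Biodistribution time course of normalized SNR
#'
#' Runs the full quantification over a cohort: hip normalization,
#' autofluorescence estimation (from a control image when supplied,
#' otherwise the hip fallback A = R * hipAfFraction, flagged in the
#' result), background annulus construction, and SNR per (subject,
#' region, timepoint). Rows whose quantification fails (missing region,
#' empty annulus, ...) are excluded with a logged reason; the table is
#' still produced.
#'
#' @param cohort list of records \code{list(subject_id, timepoint_h,
#'   image, regions)}, e.g. from [generateCohort()].
#' @param rois region names to quantify; default: every named region
#'   except body and hip_ref.
#' @param control optional \code{list(image =, regions =)} control record
#'   for autofluorescence estimation.
#' @param R hip normalization reference level.
#' @param rIn,rOut background annulus radii (pixels).
#' @param mode SNR mode, see [snr()].
#' @param hipAfFraction autofluorescence fraction of the hip level used
#'   by the fallback (default 1: the hip carries pure autofluorescence).
#' @return a [TimeCourseTable].
#' @export
biodistribution <- function(cohort, rois = NULL, control = NULL, R = 100,
                            rIn = 3, rOut = 10,
                            mode = c("noise_sd", "mean_ratio"),
                            hipAfFraction = 1) {
  mode <- match.arg(mode)
  if (is.null(control)) {
    A <- R * hipAfFraction
    afSource <- "hip_fallback"
  } else {
    hip <- hipReferenceROI(control$regions)
    A <- estimateAutofluorescence(control$image,
                                  regionMask(control$regions, "body"),
                                  hip, R = R)
    afSource <- "control"
  }
  rows <- list()
  dropped <- list()
  for (rec in cohort) {
    rs <- rec$regions
    res <- tryCatch({
      hip <- hipReferenceROI(rs)
      norm <- hipNormalize(rec$image, hip, R)
      list(norm = norm, hip = hip)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      for (rn in (if (is.null(rois)) "all" else rois))
        dropped[[length(dropped) + 1L]] <-
          data.frame(subject_id = rec$subject_id, timepoint_h = rec$timepoint_h,
                     roi_name = rn, reason = conditionMessage(res))
      next
    }
    want <- if (is.null(rois))
      setdiff(regionNames(rs), c("body", "hip_ref")) else rois
    for (rn in want) {
      row <- tryCatch({
        roiMask <- regionMask(rs, rn)
        if (!any(roiMask)) stop("empty region '", rn, "'")
        ann <- backgroundAnnulus(rs, rn, rIn, rOut)
        raw <- meanIntensity(rec$image, roiMask)
        bg <- meanIntensity(res$norm$image, ann)
        s <- snr(res$norm$image, roiMask, ann, A, mode = mode, R = R)
        data.frame(subject_id = rec$subject_id, timepoint_h = rec$timepoint_h,
                   roi_name = rn, n_pixels = raw$nPixels, raw_mean = raw$mean,
                   raw_sd = raw$sd, norm_factor = res$norm$normFactor,
                   autofluorescence = A, bg_mean = bg$mean, bg_sd = bg$sd,
                   snr = s, snr_mode = mode)
      }, error = function(e) e)
      if (inherits(row, "error")) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(subject_id = rec$subject_id, timepoint_h = rec$timepoint_h,
                     roi_name = rn, reason = conditionMessage(row))
      } else rows[[length(rows) + 1L]] <- row
    }
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), timepoint_h = numeric(),
               roi_name = character(), n_pixels = integer(),
               raw_mean = numeric(), raw_sd = numeric(), norm_factor = numeric(),
               autofluorescence = numeric(), bg_mean = numeric(),
               bg_sd = numeric(), snr = numeric(), snr_mode = character())
  drop <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(subject_id = character(), timepoint_h = numeric(),
               roi_name = character(), reason = character())
  summ <- summarizeTimeCourse(meas)
  new("TimeCourseTable", measurements = meas, summary = summ, dropped = drop,
      afSource = afSource, referenceLevel = R)
}

# cohort summaries use the sample SD (error bars across N subjects)
summarizeTimeCourse <- function(meas) {
  if (!nrow(meas))
    return(data.frame(roi_name = character(), timepoint_h = numeric(),
                      mean_snr = numeric(), sd_snr = numeric(), n = integer()))
  agg <- split(meas, list(meas$roi_name, meas$timepoint_h), drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(g)
    data.frame(roi_name = g$roi_name[1], timepoint_h = g$timepoint_h[1],
               mean_snr = mean(g$snr),
               sd_snr = if (nrow(g) > 1) stats::sd(g$snr) else NA_real_,
               n = nrow(g))))
  out <- out[order(out$roi_name, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' @rdname measurements
#' @export
setMethod("measurements", "TimeCourseTable", function(x) x@measurements)

#' @rdname cohortSummary
#' @export
setMethod("cohortSummary", "TimeCourseTable", function(x) x@summary)

#' Rows excluded from a time-course table, with reasons
#' @param x a [TimeCourseTable].
#' @return data.frame (subject_id, timepoint_h, roi_name, reason).
#' @export
droppedRows <- function(x) x@dropped

setMethod("show", "TimeCourseTable", function(object) {
  cat("TimeCourseTable: ", nrow(object@measurements), " measurements, ",
      nrow(object@summary), " summary rows (autofluorescence from ",
      object@afSource, ", R = ", object@referenceLevel, ")\n", sep = "")
  if (nrow(object@summary)) print(utils::head(object@summary, 12))
  if (nrow(object@dropped))
    cat("  ", nrow(object@dropped), " row(s) dropped; see droppedRows()\n")
})
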