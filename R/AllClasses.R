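#' @import methods
NULL

## ---------------------------------------------------------------------------
## NIRImage: one planar fluorescence frame plus acquisition metadata
## ---------------------------------------------------------------------------

#' NIRImage: a planar near-infrared fluorescence frame
#'
#' Holds a single 2-D grid of non-negative pixel intensities (arbitrary
#' units, linear scale) together with acquisition metadata: subject id,
#' timepoint in hours post-injection, view (side / dorsal / ex_vivo /
#' unknown), and the excitation / emission filter wavelengths (defaults
#' 710 / 790 nm, the NIR window used for quantum-dot micelle imaging).
#'
#' @slot pixels numeric matrix of intensities, all finite and >= 0,
#'   at least 16 x 16.
#' @slot meta named list: \code{subject_id}, \code{timepoint_h},
#'   \code{view}, \code{excitation_nm}, \code{emission_nm},
#'   \code{pixel_size_mm} (NA when unknown).
#' @seealso [NIRImage()], [pixels()], [imageMeta()]
#' @export
setClass("NIRImage", representation(pixels = "matrix", meta = "list"))

setValidity("NIRImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 16L || ncol(p) < 16L) return("image must be at least 16 x 16 pixels")
  if (any(!is.finite(p))) return("pixel values must all be finite")
  if (any(p < 0)) return("pixel values must be non-negative")
  m <- object@meta
  need <- c("subject_id", "timepoint_h", "view", "excitation_nm", "emission_nm")
  if (!all(need %in% names(m)))
    return(paste("meta must contain:", paste(need, collapse = ", ")))
  if (!is.na(m$timepoint_h) && m$timepoint_h < 0) return("timepoint_h must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## RegionSet: named labeled pixel regions aligned to an image
## ---------------------------------------------------------------------------

#' RegionSet: named, labeled pixel regions
#'
#' A single integer label map (0 = unassigned) plus a label -> name map.
#' A single map makes named regions mutually disjoint by construction,
#' which is exactly the semantics the ROI quantification requires; derived
#' overlapping masks (background annuli) are represented as separate
#' logical matrices, never in the label map. For in vivo images the
#' conventional names are \code{body}, \code{tumor}, \code{hip_ref} and
#' organ names (\code{liver}, \code{kidney}, \code{spleen}, \code{lung});
#' ex vivo lung sets use \code{lung}, \code{node_k}, \code{rim_k}.
#'
#' @slot labels integer matrix, same shape as the image it annotates.
#' @slot regionNames named character vector mapping label (as name, e.g.
#'   \code{"2"}) to region name.
#' @seealso [RegionSet()], [regionMask()], [regionNames()]
#' @export
setClass("RegionSet", representation(labels = "matrix", regionNames = "character"))

setValidity("RegionSet", function(object) {
  lab <- object@labels
  if (!all(lab == round(lab)) || any(lab < 0)) return("labels must be non-negative integers")
  nm <- object@regionNames
  if (length(nm)) {
    if (is.null(names(nm)) || any(names(nm) == ""))
      return("regionNames must be named by label")
    labs <- suppressWarnings(as.integer(names(nm)))
    if (any(is.na(labs)) || any(labs < 1))
      return("regionNames names must be positive integer labels")
    present <- sort(unique(lab[lab > 0]))
    missing <- setdiff(labs, present)
    if (length(missing))
      return(paste0("named label(s) absent from label map: ",
                    paste(missing, collapse = ", ")))
    if (anyDuplicated(nm)) return("region names must be unique")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## ThresholdParams
## ---------------------------------------------------------------------------

#' ThresholdParams: configuration for threshold ROI detection
#'
#' @slot method \code{"otsu"} or \code{"quantile"}.
#' @slot quantileQ quantile in (0, 1) used when method = "quantile".
#' @slot minArea minimum connected-component area (pixels) kept; the
#'   default of 25 px rejects small bright specks such as residual hairs.
#' @slot seedPoints optional named list of c(row, col) seed pixels; when
#'   given, each named region is the detected component containing its seed.
#' @slot restrictTo optional logical matrix (typically the body mask)
#'   restricting both the threshold computation and the detection.
#' @seealso [thresholdParams()], [detectROIs()]
#' @export
setClass("ThresholdParams",
         representation(method = "character", quantileQ = "numeric",
                        minArea = "numeric", seedPoints = "list",
                        restrictTo = "ANY"))

setValidity("ThresholdParams", function(object) {
  if (!object@method %in% c("otsu", "quantile"))
    return("method must be 'otsu' or 'quantile'")
  if (object@quantileQ <= 0 || object@quantileQ >= 1)
    return("quantileQ must be in (0, 1)")
  if (object@minArea < 1) return("minArea must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomTruth: full generative parameter set for a synthetic mouse image
## ---------------------------------------------------------------------------

#' PhantomTruth: ground-truth parameters for a synthetic in vivo NIR mouse
#'
#' The generative model is additive: a uniform autofluorescence level over
#' an elliptical body silhouette, plus per-region amplitudes following
#' mono-exponential uptake/washout kinetics, all scaled by a per-image
#' luminosity factor, convolved with a Gaussian scattering PSF, then
#' corrupted by Poisson shot noise and Gaussian read noise. Every
#' quantification step in the pipeline has a recoverable ground truth
#' under this model.
#'
#' @slot imageShape integer c(rows, cols).
#' @slot bodyCenter,bodySemiaxes body ellipse (pixels, row/col order).
#' @slot regions list of region specs; each a list with \code{name},
#'   \code{type} ("disc" or "ellipse"), \code{center}, \code{radius} or
#'   \code{semiaxes}, \code{cMax} (peak amplitude, intensity units),
#'   \code{kIn}, \code{kOut} (1/h), \code{ampJitterSigma} (lognormal
#'   sigma of per-subject amplitude variation).
#' @slot autofluorescence uniform body autofluorescence A0 (intensity units).
#' @slot luminosity global multiplicative luminosity L (unitless).
#' @slot psfSigma Gaussian scattering PSF sigma (pixels).
#' @slot poissonGain detector gain, counts per intensity unit; 0 disables
#'   shot noise.
#' @slot readSigma Gaussian read noise SD (intensity units); 0 disables.
#' @slot luminositySigmaLog per-subject lognormal sigma of L (cohorts).
#' @slot centerJitterSigma per-subject region-center jitter SD (pixels,
#'   rounded and truncated to +/- 1 px so regions stay inside the body).
#' @slot hairSpecks logical; add small bright specks outside named ROIs
#'   (residual-hair artifacts). Off by default.
#' @slot seed integer RNG seed; fixed seed gives byte-identical output.
#' @seealso [PhantomTruth()], [generatePhantom()], [generateCohort()]
#' @export
setClass("PhantomTruth",
         representation(imageShape = "integer", bodyCenter = "numeric",
                        bodySemiaxes = "numeric", regions = "list",
                        autofluorescence = "numeric", luminosity = "numeric",
                        psfSigma = "numeric", poissonGain = "numeric",
                        readSigma = "numeric", luminositySigmaLog = "numeric",
                        centerJitterSigma = "numeric", hairSpecks = "logical",
                        seed = "integer"))

## ---------------------------------------------------------------------------
## LungPhantomTruth: ex vivo lung phantom
## ---------------------------------------------------------------------------

#' LungPhantomTruth: ground truth for a synthetic ex vivo lung image
#'
#' Emulates excised lungs bearing small melanoma nodes: a diffuse
#' fluorescence level over a two-lobe lung silhouette, and (in the
#' localized stage) bright rims of stated width around each node over a
#' reduced diffuse background, with dark node cores (melanoma is
#' pigmented and quenches). The ex vivo dose is one tenth of the in vivo
#' dose, represented as a lower default diffuse level.
#'
#' @slot imageShape integer c(rows, cols).
#' @slot lobeCenters 2 x 2 matrix of lobe ellipse centers (row, col).
#' @slot lobeSemiaxes numeric c(a_row, a_col) shared by both lobes.
#' @slot nodeCount number of melanoma nodes (>= 0).
#' @slot nodeRadius node radius (pixels).
#' @slot nodePositions "random" or an n x 2 matrix of (row, col) centers.
#' @slot diffuseLevel diffuse fluorescence level (intensity units).
#' @slot localizedDiffuseFactor multiplier applied to diffuseLevel in the
#'   localized stage (default 0.3: wash-out of unbound agent).
#' @slot rimAmplitude added rim intensity in the localized stage.
#' @slot rimWidth rim ring width (pixels, >= 1).
#' @slot nodeCoreLevel intensity of node cores in the localized stage.
#' @slot poissonGain,readSigma noise model as in [PhantomTruth].
#' @slot seed integer RNG seed.
#' @seealso [LungPhantomTruth()], [generateLungExVivo()]
#' @export
setClass("LungPhantomTruth",
         representation(imageShape = "integer", lobeCenters = "matrix",
                        lobeSemiaxes = "numeric", nodeCount = "integer",
                        nodeRadius = "numeric", nodePositions = "ANY",
                        diffuseLevel = "numeric", localizedDiffuseFactor = "numeric",
                        rimAmplitude = "numeric", rimWidth = "numeric",
                        nodeCoreLevel = "numeric", poissonGain = "numeric",
                        readSigma = "numeric", seed = "integer"))

setValidity("LungPhantomTruth", function(object) {
  if (object@nodeCount < 0) return("nodeCount must be >= 0")
  if (object@rimWidth < 1) return("rimWidth must be >= 1")
  if (object@diffuseLevel < 0 || object@rimAmplitude < 0 ||
      object@nodeCoreLevel < 0)
    return("intensity levels must be >= 0")
  if (object@poissonGain < 0 || object@readSigma < 0)
    return("noise parameters must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## CumulativeHistogram
## ---------------------------------------------------------------------------

#' CumulativeHistogram: cumulative pixel-value frequency over a mask
#'
#' The machine form of the cumulative histograms used to compare the
#' tumor-area pixel distribution with the whole-body distribution:
#' fraction of masked pixels at or below each bin edge, with the mask's
#' mean and (population) SD attached.
#'
#' @slot binEdges monotone increasing bin edges (intensity units).
#' @slot cumFreq nondecreasing fractions in [0, 1], last = 1; length =
#'   length(binEdges) - 1.
#' @slot maskName character label of the mask.
#' @slot mean,sd mean and population SD of the masked pixels.
#' @seealso [cumulativeHistogram()], [distributionContrast()]
#' @export
setClass("CumulativeHistogram",
         representation(binEdges = "numeric", cumFreq = "numeric",
                        maskName = "character", mean = "numeric", sd = "numeric"))

setValidity("CumulativeHistogram", function(object) {
  if (length(object@cumFreq) != length(object@binEdges) - 1L)
    return("cumFreq must have length(binEdges) - 1 entries")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    return("binEdges must be strictly increasing")
  cf <- object@cumFreq
  if (any(cf < -1e-12) || any(cf > 1 + 1e-12)) return("cumFreq must lie in [0, 1]")
  if (is.unsorted(cf)) return("cumFreq must be nondecreasing")
  if (length(cf) && abs(cf[length(cf)] - 1) > 1e-9) return("cumFreq must end at 1")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## LocalizationResult
## ---------------------------------------------------------------------------

#' LocalizationResult: ex vivo lung node-localization summary
#'
#' Scores whether lung fluorescence is diffuse or concentrated around
#' melanoma nodes. The localization index is the ratio of the
#' autofluorescence-corrected mean over the union of node rims to the
#' corrected mean over the remaining lung parenchyma: near 1 means
#' diffuse signal, well above 1 means node-localized signal.
#'
#' @slot stage character stage label ("diffuse", "localized", or NA).
#' @slot localizationIndex rim/parenchyma corrected-mean ratio (NA when
#'   the image has no nodes).
#' @slot lungCV coefficient of variation (SD/mean) over the full lung mask.
#' @slot nodeRimMeans named numeric vector of per-node rim means.
#' @slot hasNodes logical.
#' @seealso [nodeLocalization()]
#' @export
setClass("LocalizationResult",
         representation(stage = "character", localizationIndex = "numeric",
                        lungCV = "numeric", nodeRimMeans = "numeric",
                        hasNodes = "logical"))

## ---------------------------------------------------------------------------
## TimeCourseTable
## ---------------------------------------------------------------------------

#' TimeCourseTable: normalized SNR per subject, region, and timepoint
#'
#' The machine form of the biodistribution time course: one measurement
#' row per (subject, region, timepoint) carrying the full ROIStats record
#' (pixel counts, raw mean/SD, hip normalization factor, autofluorescence,
#' background annulus mean/SD, and the normalized SNR), plus cohort
#' summary rows (mean, sample SD, n) per (region, timepoint).
#'
#' @slot measurements data.frame with columns subject_id, timepoint_h,
#'   roi_name, n_pixels, raw_mean, raw_sd, norm_factor, autofluorescence,
#'   bg_mean, bg_sd, snr, snr_mode.
#' @slot summary data.frame with columns roi_name, timepoint_h, mean_snr,
#'   sd_snr, n.
#' @slot dropped data.frame of excluded rows (subject_id, timepoint_h,
#'   roi_name, reason).
#' @slot afSource "control" or "hip_fallback".
#' @slot referenceLevel hip normalization reference level R.
#' @seealso [biodistribution()], [measurements()], [cohortSummary()]
#' @export
setClass("TimeCourseTable",
         representation(measurements = "data.frame", summary = "data.frame",
                        dropped = "data.frame", afSource = "character",
                        referenceLevel = "numeric"))

setValidity("TimeCourseTable", function(object) {
  m <- object@measurements
  if (nrow(m)) {
    key <- paste(m$subject_id, m$roi_name, m$timepoint_h)
    if (anyDuplicated(key))
      return("one measurement row per (subject, roi, timepoint) required")
  }
  TRUE
})
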