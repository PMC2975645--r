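#' Pixel matrix of an image
#' @param x a [NIRImage].
#' @return numeric matrix of intensities.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Acquisition metadata of an image
#' @param x a [NIRImage].
#' @return named list of metadata fields.
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))

#' Integer label map of a region set
#' @param x a [RegionSet].
#' @return integer matrix (0 = unassigned).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Region names of a region set
#' @param x a [RegionSet].
#' @return character vector of region names (unordered).
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Logical mask of one named region
#'
#' For the special name \code{"body"} (in vivo) the full body silhouette is
#' returned, i.e. the union of all labels: tumor and organ labels are carved
#' out of the body label in the map, but anatomically they lie inside the
#' body outline.
#'
#' @param x a [RegionSet].
#' @param name region name.
#' @return logical matrix.
#' @export
setGeneric("regionMask", function(x, name) standardGeneric("regionMask"))

#' Does a region set contain a named region?
#' @param x a [RegionSet].
#' @param name region name.
#' @return logical scalar.
#' @export
setGeneric("hasRegion", function(x, name) standardGeneric("hasRegion"))

#' Per-measurement rows of a time-course table
#' @param x a [TimeCourseTable].
#' @return data.frame of ROI statistics records.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' Cohort summary rows of a time-course table
#' @param x a [TimeCourseTable].
#' @return data.frame with mean_snr, sd_snr (sample SD across subjects), n.
#' @export
setGeneric("cohortSummary", function(x) standardGeneric("cohortSummary"))
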