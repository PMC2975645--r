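#' Construct an NIRImage
#'
#' @param pixels numeric matrix of non-negative finite intensities,
#'   at least 16 x 16.
#' @param subject_id subject identifier (default "unknown").
#' @param timepoint_h timepoint in hours post-injection (NA when unknown).
#' @param view one of "side", "dorsal", "ex_vivo", "unknown".
#' @param excitation_nm,emission_nm filter wavelengths; defaults 710 / 790 nm.
#' @param pixel_size_mm physical pixel size in mm (NA when unknown).
#' @return a [NIRImage].
#' @examples
#' img <- NIRImage(matrix(100, 32, 32), subject_id = "m1", timepoint_h = 1)
#' dim(pixels(img))
#' @export
NIRImage <- function(pixels, subject_id = "unknown", timepoint_h = NA_real_,
                     view = "unknown", excitation_nm = 710, emission_nm = 790,
                     pixel_size_mm = NA_real_) {
  new("NIRImage", pixels = pixels,
      meta = list(subject_id = subject_id, timepoint_h = timepoint_h,
                  view = view, excitation_nm = excitation_nm,
                  emission_nm = emission_nm, pixel_size_mm = pixel_size_mm))
}

#' @rdname pixels
#' @export
setMethod("pixels", "NIRImage", function(x) x@pixels)

#' @rdname imageMeta
#' @export
setMethod("imageMeta", "NIRImage", function(x) x@meta)

setMethod("show", "NIRImage", function(object) {
  p <- object@pixels
  m <- object@meta
  cat("NIRImage ", nrow(p), " x ", ncol(p),
      " | subject ", m$subject_id,
      " | t = ", m$timepoint_h, " h | view ", m$view,
      " | ex/em ", m$excitation_nm, "/", m$emission_nm, " nm\n", sep = "")
  cat("  intensity range [", format(min(p), digits = 4), ", ",
      format(max(p), digits = 4), "]\n", sep = "")
})

#' @rdname dim
#' @param x a [NIRImage].
#' @export
setMethod("dim", "NIRImage", function(x) dim(x@pixels))
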