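#' Construct a RegionSet
#'
#' @param labels integer matrix, 0 = unassigned.
#' @param regionNames named character vector mapping label (as character,
#'   e.g. \code{c("1" = "body", "2" = "tumor")}) to region name, or a list
#'   with integer-convertible names.
#' @return a [RegionSet].
#' @examples
#' lab <- matrix(0L, 32, 32); lab[10:20, 10:20] <- 1L
#' rs <- RegionSet(lab, c("1" = "tumor"))
#' sum(regionMask(rs, "tumor"))
#' @export
RegionSet <- function(labels, regionNames = character()) {
  if (is.list(regionNames))
    regionNames <- stats::setNames(as.character(unlist(regionNames)),
                                   names(regionNames))
  storage.mode(labels) <- "integer"
  new("RegionSet", labels = labels, regionNames = regionNames)
}

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "RegionSet", function(x) x@labels)

#' @rdname regionNames
#' @export
setMethod("regionNames", "RegionSet", function(x) unname(x@regionNames))

#' @rdname hasRegion
#' @export
setMethod("hasRegion", c("RegionSet", "character"),
          function(x, name) name %in% x@regionNames)

#' @rdname regionMask
#' @export
setMethod("regionMask", c("RegionSet", "character"), function(x, name) {
  if (!hasRegion(x, name))
    stop("region '", name, "' not present in RegionSet", call. = FALSE)
  if (name %in% c("body")) {
    # body silhouette: tumor/organ labels are carved out of the body label
    # in the single-map representation but lie inside the body outline
    return(x@labels > 0L)
  }
  lab <- as.integer(names(x@regionNames)[match(name, x@regionNames)])
  x@labels == lab
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet ", nrow(object@labels), " x ", ncol(object@labels), "\n", sep = "")
  if (length(object@regionNames)) {
    sizes <- vapply(as.integer(names(object@regionNames)),
                    function(l) sum(object@labels == l), integer(1))
    cat(paste0("  ", format(object@regionNames, width = 10), " label ",
               names(object@regionNames), ", ", sizes, " px", collapse = "\n"),
        "\n", sep = "")
  } else cat("  (no named regions)\n")
})

# internal: stack named logical masks into a label map (later masks are not
# allowed to overlap earlier ones)
masksToRegionSet <- function(masks) {
  stopifnot(length(masks) > 0)
  shape <- dim(masks[[1]])
  lab <- matrix(0L, shape[1], shape[2])
  nm <- character()
  nextLab <- 1L
  for (name in names(masks)) {
    m <- masks[[name]]
    if (name != "body" && any(lab[m] > 1L))
      stop("overlapping region masks: '", name, "' collides with an earlier region",
           call. = FALSE)
    lab[m] <- nextLab
    nm[as.character(nextLab)] <- name
    nextLab <- nextLab + 1L
  }
  RegionSet(lab, nm)
}
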