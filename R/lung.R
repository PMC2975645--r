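#' Construct a LungPhantomTruth
#'
#' Defaults emulate excised mouse lungs from a pseudometastatic melanoma
#' model imaged ex vivo at one tenth of the in vivo dose: a 96 x 128 px
#' frame, a two-lobe lung silhouette, 12 small nodes of radius 2 px, a
#' diffuse fluorescence level of 30 intensity units, and (localized
#' stage) bright 2 px rims of 60 units around each node over a 0.3 x
#' reduced diffuse background with dark pigmented node cores.
#'
#' @param imageShape c(rows, cols).
#' @param lobeCenters 2 x 2 matrix of (row, col) lobe ellipse centers.
#' @param lobeSemiaxes c(row, col) semiaxes shared by both lobes.
#' @param nodeCount number of melanoma nodes.
#' @param nodeRadius node radius (pixels).
#' @param nodePositions "random" (seeded rejection sampling inside the
#'   lung) or an n x 2 matrix of centers.
#' @param diffuseLevel diffuse fluorescence level (intensity units).
#' @param localizedDiffuseFactor diffuse multiplier in the localized stage.
#' @param rimAmplitude added rim intensity (localized stage).
#' @param rimWidth rim ring width (pixels, >= 1).
#' @param nodeCoreLevel node-core intensity (localized stage).
#' @param poissonGain,readSigma detector noise model; see [PhantomTruth()].
#' @param seed integer RNG seed.
#' @return a [LungPhantomTruth].
#' @examples
#' lt <- LungPhantomTruth(nodeCount = 6L)
#' loc <- generateLungExVivo(lt, stage = "localized")
#' @export
LungPhantomTruth <- function(imageShape = c(96L, 128L),
                             lobeCenters = rbind(c(48, 52), c(48, 78)),
                             lobeSemiaxes = c(32, 22),
                             nodeCount = 12L, nodeRadius = 2,
                             nodePositions = "random",
                             diffuseLevel = 30, localizedDiffuseFactor = 0.3,
                             rimAmplitude = 60, rimWidth = 2,
                             nodeCoreLevel = 3,
                             poissonGain = 2000, readSigma = 0.05, seed = 202L) {
  new("LungPhantomTruth", imageShape = as.integer(imageShape),
      lobeCenters = lobeCenters, lobeSemiaxes = lobeSemiaxes,
      nodeCount = as.integer(nodeCount), nodeRadius = nodeRadius,
      nodePositions = nodePositions, diffuseLevel = diffuseLevel,
      localizedDiffuseFactor = localizedDiffuseFactor,
      rimAmplitude = rimAmplitude, rimWidth = rimWidth,
      nodeCoreLevel = nodeCoreLevel, poissonGain = poissonGain,
      readSigma = readSigma, seed = as.integer(seed))
}

lungSilhouette <- function(truth) {
  shape <- truth@imageShape
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(truth@lobeCenters)))
    m <- m | ellipseMask(shape, truth@lobeCenters[i, ], truth@lobeSemiaxes)
  m
}

# place node centers so that node + rim stays inside the lung and nodes do
# not collide; seeded rejection sampling when positions are "random"
lungNodeCenters <- function(truth, lung) {
  n <- truth@nodeCount
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (is.matrix(truth@nodePositions)) {
    pos <- truth@nodePositions
    if (nrow(pos) != n) stop("nodePositions must have nodeCount rows", call. = FALSE)
    return(pos)
  }
  margin <- ceiling(truth@nodeRadius + truth@rimWidth)
  interior <- !dilateMask(!lung, margin) # lung eroded by the margin
  minDist <- 2 * (truth@nodeRadius + truth@rimWidth) + 2
  withr::with_seed(deriveSeed(truth@seed, 5L), {
    cand <- which(interior, arr.ind = TRUE)
    if (!nrow(cand))
      stop("no feasible node placement inside the lung geometry", call. = FALSE)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("no feasible placement for ", n, " nodes: lung too small for ",
             "the requested node/rim geometry", call. = FALSE)
      p <- cand[sample(nrow(cand), 1L), ]
      if (nrow(centers) == 0 ||
          all(pmax(abs(centers[, 1] - p[1]), abs(centers[, 2] - p[2])) >= minDist))
        centers <- rbind(centers, p)
    }
    centers
  })
}

#' Generate a synthetic ex vivo lung image
#'
#' Two stages mirror the wash-out time course of a targeted agent in a
#' lung pseudometastatic model: at stage \code{"diffuse"} (early, 1 h)
#' the full diffuse level covers the lung uniformly and the nodes, while
#' present anatomically, are not enhanced; at stage \code{"localized"}
#' (late, 24 h) the diffuse level is reduced by
#' \code{localizedDiffuseFactor} and a bright rim of width
#' \code{rimWidth} at \code{rimAmplitude} above the reduced diffuse level
#' surrounds each node, whose pigmented core drops to
#' \code{nodeCoreLevel}. Detector noise as configured. The returned
#' RegionSet carries \code{lung}, \code{node_k}, and \code{rim_k} masks.
#'
#' @param truth a [LungPhantomTruth].
#' @param stage "diffuse" or "localized".
#' @return list with \code{image} ([NIRImage]), \code{regions}
#'   ([RegionSet]), and \code{clean} (noise-free matrix).
#' @export
generateLungExVivo <- function(truth, stage = c("diffuse", "localized")) {
  stage <- match.arg(stage)
  validObject(truth)
  shape <- truth@imageShape
  lung <- lungSilhouette(truth)
  centers <- lungNodeCenters(truth, lung)
  n <- nrow(centers)
  nodeMasks <- rimMasks <- list()
  for (i in seq_len(n)) {
    nodeMasks[[i]] <- discMask(shape, centers[i, ], truth@nodeRadius)
    outer <- discMask(shape, centers[i, ], truth@nodeRadius + truth@rimWidth)
    rimMasks[[i]] <- outer & !nodeMasks[[i]]
  }
  diffuse <- if (stage == "localized")
    truth@diffuseLevel * truth@localizedDiffuseFactor else truth@diffuseLevel
  clean <- diffuse * lung
  if (stage == "localized" && n > 0) {
    for (i in seq_len(n)) {
      clean[rimMasks[[i]]] <- clean[rimMasks[[i]]] + truth@rimAmplitude
      clean[nodeMasks[[i]]] <- truth@nodeCoreLevel
    }
  }
  img <- applyNoise(clean, truth, deriveSeed(truth@seed, match(stage, c("diffuse", "localized"))))
  masks <- list(lung = lung)
  for (i in seq_len(n)) {
    masks[[paste0("node_", i)]] <- nodeMasks[[i]]
    masks[[paste0("rim_", i)]] <- rimMasks[[i]]
  }
  # carve nodes/rims out of the lung label so the map stays disjoint
  rs <- masksToLungRegionSet(masks)
  nir <- NIRImage(img, subject_id = "lung_phantom", timepoint_h = NA_real_,
                  view = "ex_vivo")
  list(image = nir, regions = rs, clean = clean)
}

masksToLungRegionSet <- function(masks) {
  shape <- dim(masks[[1]])
  lab <- matrix(0L, shape[1], shape[2])
  nm <- character()
  nextLab <- 1L
  for (name in names(masks)) {
    m <- masks[[name]]
    if (name != "lung" && any(lab[m] > 1L))
      stop("overlapping lung region masks at '", name, "'", call. = FALSE)
    lab[m] <- nextLab
    nm[as.character(nextLab)] <- name
    nextLab <- nextLab + 1L
  }
  RegionSet(lab, nm)
}

setMethod("show", "LungPhantomTruth", function(object) {
  cat("LungPhantomTruth ", object@imageShape[1], " x ", object@imageShape[2],
      " px, ", object@nodeCount, " nodes (r = ", object@nodeRadius,
      " px, rim ", object@rimWidth, " px)\n", sep = "")
  cat("  diffuse ", object@diffuseLevel, " (x", object@localizedDiffuseFactor,
      " when localized), rim +", object@rimAmplitude, ", core ",
      object@nodeCoreLevel, ", seed ", object@seed, "\n", sep = "")
})
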