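#' Default region specification for the in vivo phantom
#'
#' @param name region name.
#' @param type "disc" or "ellipse".
#' @param center c(row, col) center in pixels.
#' @param radius disc radius (pixels), for type = "disc".
#' @param semiaxes c(row, col) semiaxes (pixels), for type = "ellipse".
#' @param cMax peak amplitude (intensity units) reached under the uptake
#'   kinetics.
#' @param kIn,kOut uptake and washout rate constants (1/h).
#' @param ampJitterSigma lognormal sigma of the per-subject amplitude
#'   variation used by [generateCohort()].
#' @return a region spec list, for the \code{regions} argument of
#'   [PhantomTruth()].
#' @export
phantomRegion <- function(name, type = c("disc", "ellipse"), center,
                          radius = NULL, semiaxes = NULL, cMax = 0,
                          kIn = 1, kOut = 0, ampJitterSigma = 0.1) {
  type <- match.arg(type)
  if (type == "disc" && is.null(radius)) stop("disc region needs 'radius'")
  if (type == "ellipse" && is.null(semiaxes)) stop("ellipse region needs 'semiaxes'")
  if (cMax < 0 || kIn < 0 || kOut < 0) stop("cMax, kIn, kOut must be >= 0")
  list(name = name, type = type, center = center, radius = radius,
       semiaxes = semiaxes, cMax = cMax, kIn = kIn, kOut = kOut,
       ampJitterSigma = ampJitterSigma)
}

# default study conditions: a side-view mouse at ~2.2 px/mm. The tumor is a
# superficial flank disc; internal organs are visible but optically
# attenuated from the side; the hip reference patch carries only
# autofluorescence. Amplitudes are arbitrary intensity units.
defaultPhantomRegions <- function() {
  list(
    phantomRegion("tumor",   "disc",    center = c(40, 150), radius = 13,
                  cMax = 400, kIn = 3.0, kOut = 0.02, ampJitterSigma = 0.10),
    phantomRegion("liver",   "ellipse", center = c(64, 86),  semiaxes = c(13, 10),
                  cMax = 25,  kIn = 2.5, kOut = 0.15, ampJitterSigma = 0.15),
    phantomRegion("kidney",  "disc",    center = c(54, 106), radius = 7,
                  cMax = 45,  kIn = 2.0, kOut = 0.05, ampJitterSigma = 0.50),
    phantomRegion("spleen",  "disc",    center = c(80, 102), radius = 6,
                  cMax = 40,  kIn = 2.0, kOut = 0.10, ampJitterSigma = 0.20),
    phantomRegion("lung",    "ellipse", center = c(45, 68),  semiaxes = c(10, 8),
                  cMax = 30,  kIn = 4.0, kOut = 0.30, ampJitterSigma = 0.20),
    phantomRegion("hip_ref", "disc",    center = c(84, 146), radius = 8,
                  cMax = 0,   kIn = 0,   kOut = 0,    ampJitterSigma = 0)
  )
}

#' Construct a PhantomTruth
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' a 120 x 200 px side-view mouse, a bright superficial flank tumor with
#' fast uptake and near-zero washout (so its signal is practically
#' unchanged over 1-4 h), dimmer internal organs with the kidney showing
#' the largest inter-subject variability, uniform body autofluorescence,
#' a 1.5 px Gaussian scattering PSF, and a low-noise cooled-CCD detector
#' model (2000 counts per intensity unit, 0.05 units read noise) under
#' which the scattered-light spatial structure near a region, not the
#' detector, dominates the background SD.
#'
#' @param imageShape c(rows, cols).
#' @param bodyCenter,bodySemiaxes body ellipse in pixels.
#' @param regions list of [phantomRegion()] specs.
#' @param autofluorescence uniform autofluorescence A0 (intensity units).
#' @param luminosity global luminosity factor L.
#' @param psfSigma Gaussian PSF sigma (pixels).
#' @param poissonGain counts per intensity unit (0 = shot noise off).
#' @param readSigma read noise SD in intensity units (0 = off).
#' @param luminositySigmaLog per-subject lognormal sigma of L.
#' @param centerJitterSigma per-subject region-center jitter SD (pixels).
#' @param hairSpecks add residual-hair bright specks (off by default).
#' @param seed integer RNG seed.
#' @return a validated [PhantomTruth].
#' @examples
#' truth <- PhantomTruth()
#' out <- generatePhantom(truth, t = 1)
#' mean(pixels(out$image)[regionMask(out$regions, "tumor")])
#' @export
PhantomTruth <- function(imageShape = c(120L, 200L),
                         bodyCenter = c(60, 100), bodySemiaxes = c(45, 90),
                         regions = defaultPhantomRegions(),
                         autofluorescence = 20, luminosity = 1,
                         psfSigma = 1.5, poissonGain = 2000, readSigma = 0.05,
                         luminositySigmaLog = 0.2, centerJitterSigma = 1.0,
                         hairSpecks = FALSE, seed = 101L) {
  obj <- new("PhantomTruth", imageShape = as.integer(imageShape),
             bodyCenter = bodyCenter, bodySemiaxes = bodySemiaxes,
             regions = regions, autofluorescence = autofluorescence,
             luminosity = luminosity, psfSigma = psfSigma,
             poissonGain = poissonGain, readSigma = readSigma,
             luminositySigmaLog = luminositySigmaLog,
             centerJitterSigma = centerJitterSigma,
             hairSpecks = hairSpecks, seed = as.integer(seed))
  validatePhantomTruth(obj)
  obj
}

# geometry/amplitude invariants: non-negative parameters, regions inside the
# body, mutual disjointness, hip reference free of tumor/organ signal overlap
validatePhantomTruth <- function(truth) {
  if (truth@autofluorescence < 0 || truth@luminosity < 0 ||
      truth@psfSigma < 0 || truth@poissonGain < 0 || truth@readSigma < 0)
    stop("autofluorescence, luminosity, psfSigma, poissonGain, readSigma must be >= 0",
         call. = FALSE)
  shape <- truth@imageShape
  body <- ellipseMask(shape, truth@bodyCenter, truth@bodySemiaxes)
  masks <- phantomRegionMasks(truth)
  hip <- NULL
  taken <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    nm <- names(masks)[i]
    if (!all(body[m]))
      stop("region '", nm, "' extends outside the body geometry", call. = FALSE)
    if (any(taken & m))
      stop("region '", nm, "' overlaps another region", call. = FALSE)
    taken <- taken | m
    if (nm == "hip_ref") hip <- m
  }
  for (r in truth@regions)
    if (r$cMax < 0 || r$kIn < 0 || r$kOut < 0)
      stop("region amplitudes and rates must be >= 0", call. = FALSE)
  invisible(TRUE)
}

phantomRegionMasks <- function(truth) {
  shape <- truth@imageShape
  masks <- lapply(truth@regions, function(r) {
    if (r$type == "disc") discMask(shape, r$center, r$radius)
    else ellipseMask(shape, r$center, r$semiaxes)
  })
  names(masks) <- vapply(truth@regions, `[[`, character(1), "name")
  masks
}

#' Mono-exponential uptake/washout kinetics
#'
#' Region amplitude at time t: \code{cMax * (1 - exp(-kIn * t)) *
#' exp(-kOut * t)}. Zero at t = 0 and bounded by cMax for all t. The
#' default tumor parameters (kIn = 3/h, kOut = 0.02/h) put the curve on a
#' plateau over the 1-4 h imaging window, emulating a signal that is
#' practically unchanged for the duration of imaging.
#'
#' @param cMax peak amplitude (intensity units).
#' @param kIn uptake rate (1/h).
#' @param kOut washout rate (1/h).
#' @param t time post-injection (h). Vectorized over t.
#' @return amplitude(s) in intensity units.
#' @examples
#' uptakeKinetics(10, 3, 0.02, c(0, 1, 4))
#' @export
uptakeKinetics <- function(cMax, kIn, kOut, t) {
  if (any(c(cMax, kIn, kOut, t) < 0))
    stop("uptakeKinetics: all arguments must be >= 0", call. = FALSE)
  cMax * (1 - exp(-kIn * t)) * exp(-kOut * t)
}

# noise-free pixel model: L * (A0 * body + sum_r uptake_r * shape_r),
# convolved with the Gaussian scattering PSF
phantomCleanImage <- function(truth, t) {
  shape <- truth@imageShape
  body <- ellipseMask(shape, truth@bodyCenter, truth@bodySemiaxes)
  base <- truth@autofluorescence * body
  masks <- phantomRegionMasks(truth)
  for (i in seq_along(truth@regions)) {
    r <- truth@regions[[i]]
    amp <- uptakeKinetics(r$cMax, r$kIn, r$kOut, t)
    if (amp > 0) base <- base + amp * masks[[i]]
  }
  if (truth@hairSpecks) {
    # residual-hair artifacts: a few fixed bright 1-2 px specks outside ROIs
    specks <- hairSpeckMask(truth)
    base <- base + 0.8 * max(base) * specks
  }
  pmax(psfBlur(truth@luminosity * base, truth@psfSigma), 0)
}

hairSpeckMask <- function(truth) {
  shape <- truth@imageShape
  body <- ellipseMask(shape, truth@bodyCenter, truth@bodySemiaxes)
  taken <- Reduce(`|`, phantomRegionMasks(truth))
  sp <- matrix(FALSE, shape[1], shape[2])
  pts <- withr::with_seed(deriveSeed(truth@seed, 77L), {
    cand <- which(body & !dilateMask(taken, 4), arr.ind = TRUE)
    cand[sample(nrow(cand), 6L), , drop = FALSE]
  })
  sp[pts] <- TRUE
  sp
}

applyNoise <- function(clean, truth, seed) {
  img <- pmax(clean, 0) # FFT blur can leave ~1e-14 negative ringing
  withr::with_seed(seed, {
    if (truth@poissonGain > 0)
      img <- stats::rpois(length(img), truth@poissonGain * img) / truth@poissonGain
    if (truth@readSigma > 0)
      img <- img + stats::rnorm(length(img), 0, truth@readSigma)
  })
  img <- matrix(pmax(img, 0), nrow(clean), ncol(clean)) # detector clips at 0
  img
}

#' Generate one synthetic in vivo NIR mouse image
#'
#' Renders the phantom pixel model at time t: autofluorescence plus
#' kinetic region amplitudes, scaled by the luminosity factor, blurred by
#' the scattering PSF, then Poisson shot noise (at \code{poissonGain}
#' counts per intensity unit) and Gaussian read noise. Deterministic for
#' a fixed truth (the noise seed is derived from \code{truth@seed} and t).
#'
#' @param truth a [PhantomTruth].
#' @param t timepoint in hours (>= 0).
#' @param subject_id subject id recorded in the image metadata.
#' @return list with elements \code{image} ([NIRImage]), \code{regions}
#'   (ground-truth [RegionSet] with body, tumor, organs, hip_ref), and
#'   \code{clean} (noise-free pixel matrix).
#' @export
generatePhantom <- function(truth, t, subject_id = "phantom") {
  validatePhantomTruth(truth)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  clean <- phantomCleanImage(truth, t)
  img <- applyNoise(clean, truth, deriveSeed(truth@seed, round(1000 * t)))
  shape <- truth@imageShape
  masks <- c(list(body = ellipseMask(shape, truth@bodyCenter, truth@bodySemiaxes)),
             phantomRegionMasks(truth))
  rs <- masksToRegionSet(masks)
  nir <- NIRImage(img, subject_id = subject_id, timepoint_h = t, view = "side")
  list(image = nir, regions = rs, clean = clean)
}

# per-subject jittered copy of a truth: luminosity (mean-one lognormal),
# per-region amplitude (mean-one lognormal), region centers (rounded normal,
# truncated to +/- 1 px so geometry invariants cannot be violated)
jitterTruth <- function(truth, seed) {
  withr::with_seed(seed, {
    t2 <- truth
    sL <- truth@luminositySigmaLog
    if (sL > 0)
      t2@luminosity <- truth@luminosity * exp(stats::rnorm(1, -sL^2 / 2, sL))
    for (i in seq_along(t2@regions)) {
      r <- t2@regions[[i]]
      sA <- r$ampJitterSigma
      if (sA > 0) r$cMax <- r$cMax * exp(stats::rnorm(1, -sA^2 / 2, sA))
      if (truth@centerJitterSigma > 0) {
        shift <- round(stats::rnorm(2, 0, truth@centerJitterSigma))
        shift <- pmax(pmin(shift, 1), -1)
        r$center <- r$center + shift
      }
      t2@regions[[i]] <- r
    }
    t2
  })
}

#' Generate a cohort of synthetic subjects across timepoints
#'
#' One image per subject per timepoint. Subjects differ by a mean-one
#' lognormal luminosity factor (default sigma_log 0.2, the per-image
#' global luminosity differences the hip normalization exists to remove),
#' mean-one lognormal per-region amplitudes, and small region-center
#' shifts; a subject's geometry is shared across its timepoints (ROIs
#' propagate). Sub-seeds are derived deterministically from \code{seed},
#' so identical calls are byte-identical.
#'
#' @param truth base [PhantomTruth].
#' @param nSubjects number of subjects (default 5).
#' @param timepoints hours post-injection (default c(1, 2, 4)).
#' @param seed cohort seed (defaults to \code{truth@seed}).
#' @return list of records, each \code{list(subject_id, timepoint_h, image,
#'   regions, clean, truth)}; the jittered per-subject truth is attached.
#' @export
generateCohort <- function(truth, nSubjects = 5L, timepoints = c(1, 2, 4),
                           seed = truth@seed) {
  if (nSubjects < 1) stop("nSubjects must be >= 1", call. = FALSE)
  if (!length(timepoints)) stop("timepoints must be non-empty", call. = FALSE)
  out <- vector("list", nSubjects * length(timepoints))
  k <- 1L
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", s)
    truthS <- jitterTruth(truth, deriveSeed(seed, s))
    truthS@seed <- deriveSeed(seed, s, 999L)
    for (t in timepoints) {
      g <- generatePhantom(truthS, t, subject_id = sid)
      out[[k]] <- list(subject_id = sid, timepoint_h = t, image = g$image,
                       regions = g$regions, clean = g$clean, truth = truthS)
      k <- k + 1L
    }
  }
  class(out) <- c("NIRCohort", "list")
  out
}

#' Noise-free / uninjected variants of a truth
#'
#' \code{noiseFree()} switches the detector noise off (shot and read);
#' \code{uninjected()} additionally zeroes every region amplitude, giving
#' the pre-injection control image that carries only autofluorescence.
#'
#' @param truth a [PhantomTruth].
#' @return a modified [PhantomTruth].
#' @export
noiseFree <- function(truth) {
  truth@poissonGain <- 0
  truth@readSigma <- 0
  truth
}

#' @rdname noiseFree
#' @export
uninjected <- function(truth) {
  for (i in seq_along(truth@regions)) truth@regions[[i]]$cMax <- 0
  truth
}

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth ", object@imageShape[1], " x ", object@imageShape[2],
      " px, ", length(object@regions), " regions\n", sep = "")
  cat("  A0 = ", object@autofluorescence, ", L = ", format(object@luminosity, digits = 3),
      ", PSF sigma = ", object@psfSigma, " px, gain = ", object@poissonGain,
      ", read SD = ", object@readSigma, ", seed = ", object@seed, "\n", sep = "")
  for (r in object@regions)
    cat(sprintf("  %-8s cMax %6.1f  kIn %.2f/h  kOut %.2f/h\n",
                r$name, r$cMax, r$kIn, r$kOut))
})
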