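# Independent oracles and small fixtures, built in code at test time.

# naive pixel-loop mean / population SD over a mask (plain double
# accumulation, no vectorized shortcuts)
oracleMeanSD <- function(px, mask) {
  s <- 0; n <- 0L
  for (j in seq_len(ncol(px))) for (i in seq_len(nrow(px)))
    if (mask[i, j]) { s <- s + px[i, j]; n <- n + 1L }
  m <- s / n
  s2 <- 0
  for (j in seq_len(ncol(px))) for (i in seq_len(nrow(px)))
    if (mask[i, j]) s2 <- s2 + (px[i, j] - m)^2
  list(mean = m, sd = sqrt(s2 / n), nPixels = n)
}

# naive histogram bin counts over a mask for given edges
oracleHistCounts <- function(px, mask, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  v <- px[mask]
  for (x in v) {
    b <- nb
    for (k in seq_len(nb)) if (x < edges[k + 1L]) { b <- k; break }
    counts[b] <- counts[b] + 1L
  }
  counts
}

# exhaustive Otsu oracle on integer-valued (8-bit style) data: maximize
# between-class variance over every integer cut, return the foreground set
oracleOtsuForeground <- function(v) {
  best <- -Inf; bestT <- NA
  for (t in sort(unique(v))) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  v > bestT
}

# direct O(n^2 k^2) circular-boundary convolution with a normalized
# Gaussian kernel (radius chosen as 2*ceiling(3*sigma)+1, matching the
# package's stated PSF support)
oracleGaussBlur <- function(m, sigma) {
  size <- 2L * ceiling(3 * sigma) + 1L
  half <- (size - 1L) %/% 2L
  g1 <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- outer(g1, g1)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- ((i + di - 1) %% nr) + 1
      jj <- ((j + dj - 1) %% nc) + 1
      acc <- acc + m[ii, jj] * k[di + half + 1, dj + half + 1]
    }
    out[i, j] <- acc
  }
  out
}

# compact two-region truth used where the full default phantom would be
# overkill; same acquisition model, smaller frame
smallTruth <- function(seed = 11L, ...) {
  PhantomTruth(
    imageShape = c(64L, 96L), bodyCenter = c(32, 48), bodySemiaxes = c(24, 40),
    regions = list(
      phantomRegion("tumor", "disc", center = c(22, 66), radius = 6,
                    cMax = 300, kIn = 3, kOut = 0.02, ampJitterSigma = 0.10),
      phantomRegion("liver", "ellipse", center = c(36, 36), semiaxes = c(8, 6),
                    cMax = 25, kIn = 2.5, kOut = 0.15, ampJitterSigma = 0.15),
      phantomRegion("hip_ref", "disc", center = c(44, 64), radius = 5,
                    cMax = 0, kIn = 0, kOut = 0, ampJitterSigma = 0)),
    seed = seed, ...)
}

# random integer-valued image + random non-empty mask (16-bit style values:
# sums stay exactly representable in doubles)
randomImageMask <- function(nr = 48L, nc = 48L) {
  px <- matrix(sample.int(65535L, nr * nc, replace = TRUE) - 1L, nr, nc)
  storage.mode(px) <- "double"
  mask <- matrix(stats::runif(nr * nc) < 0.3, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  list(px = px, mask = mask)
}

# full quantification of one phantom record against a control; returns the
# named SNR vector (used by the invariance checks)
pipelineSNRs <- function(img, regions, control, R = 100, mode = "noise_sd") {
  hip <- hipReferenceROI(regions)
  norm <- hipNormalize(img, hip, R)$image
  A <- estimateAutofluorescence(control, regionMask(regions, "body"), hip, R = R)
  rois <- setdiff(regionNames(regions), c("body", "hip_ref"))
  out <- vapply(rois, function(rn) {
    ann <- backgroundAnnulus(regions, rn)
    snr(norm, regionMask(regions, rn), ann, A, mode = mode, R = R)
  }, numeric(1))
  names(out) <- rois
  out
}
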