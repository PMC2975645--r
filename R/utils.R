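# internal helpers shared across modules

# derive a deterministic 32-bit sub-seed; keeps results below 2^31
deriveSeed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) * 1009 + 1) %% 2147483647
  as.integer(s)
}

# elliptical mask on a (rows x cols) grid; center/semiaxes in (row, col)
ellipseMask <- function(shape, center, semiaxes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / semiaxes[1])^2 + ((cc - center[2]) / semiaxes[2])^2 <= 1
}

discMask <- function(shape, center, radius) {
  ellipseMask(shape, center, c(radius, radius))
}

# Gaussian PSF blur; circular boundary so total intensity is conserved
psfBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  b <- EBImage::gblur(m, sigma = sigma)
  matrix(EBImage::imageData(b), nrow(m), ncol(m))
}

# Chebyshev (8-connectivity) morphological dilation by integer radius r
dilateMask <- function(mask, r) {
  r <- as.integer(round(r))
  if (r <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "box")
  out <- EBImage::dilate(mask * 1, brush)
  matrix(EBImage::imageData(out), nrow(mask), ncol(mask)) > 0.5
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  w <- which(a > 0L & b > 0L & a != b)
  if (length(w)) for (i in w) unite(a[i], b[i])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  w <- which(a > 0L & b > 0L & a != b)
  if (length(w)) for (i in w) unite(a[i], b[i])
  roots <- vapply(seq_len(n), findRoot, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

# population SD (divide by n), matching per-pixel statistics convention
popSD <- function(x) {
  n <- length(x)
  m <- mean(x)
  sqrt(sum((x - m)^2) / n)
}

stopShapeMatch <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b)))
    stop("shape mismatch: ", what, " must have identical dimensions", call. = FALSE)
}
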