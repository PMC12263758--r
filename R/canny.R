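## Canny edge detection, applied in 2D to every axial (z) slice. This is
## the anatomical prior channel: edges of the post-contrast T1-weighted
## volume constrain the generator to preserve structure.

.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

## 1D convolution of matrix columns with reflection padding
.convColsReflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  out
}

.gaussSmooth2d <- function(m, sigma) {
  k <- .gaussKernel1d(sigma)
  t(.convColsReflect(t(.convColsReflect(m, k)), k))
}

## shift a matrix by (dx, dy), zero fill
.shift2 <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  sx <- max(1, 1 + dx):min(n1, n1 + dx)
  sy <- max(1, 1 + dy):min(n2, n2 + dy)
  out[sx, sy] <- m[sx - dx, sy - dy]
  out
}

.canny2d <- function(img, sigma, low, high) {
  s <- .gaussSmooth2d(img, sigma)
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  conv3 <- function(m, kern) {
    out <- matrix(0, nrow(m), ncol(m))
    for (a in -1:1) for (b in -1:1)
      out <- out + kern[a + 2, b + 2] * .shift2(m, a, b)
    out
  }
  gx <- conv3(s, sob)
  gy <- conv3(s, t(sob))
  mag <- sqrt(gx^2 + gy^2)
  # zero-fill shifts make the outermost ring spurious; suppress it
  mag[c(1, nrow(mag)), ] <- 0
  mag[, c(1, ncol(mag))] <- 0
  ang <- atan2(gy, gx) %% pi
  # quantize the gradient direction to 0/45/90/135 degrees
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4
  nb <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (b in 0:3) {
    d <- nb[[b + 1]]
    sel <- bin == b
    # strict comparison forward breaks plateau ties to one-voxel edges
    keep[sel] <- mag[sel] > .shift2(mag, d[1], d[2])[sel] &
      mag[sel] >= .shift2(mag, -d[1], -d[2])[sel]
  }
  nms <- mag * keep
  strong <- nms >= high
  weak <- nms >= low
  # hysteresis: grow strong edges through 8-connected weak pixels
  repeat {
    grown <- strong
    for (a in -1:1) for (b in -1:1)
      if (a != 0 || b != 0) grown <- grown | .shift2(strong, a, b) > 0
    grown <- grown & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  strong * 1
}

#' Canny edge channel of a 3D volume
#'
#' Slice-wise (2D, per z-slice) Canny edge detection on the
#' percentile-normalized volume: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis. Thresholds apply to the normalized [0, 1]
#' intensity scale, so the result is invariant to positive rescaling of
#' the input.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param gaussianSigma smoothing scale in voxels (default 1)
#' @param lowThreshold,highThreshold hysteresis thresholds on the
#'   normalized gradient magnitude, 0 <= low < high (defaults 0.1, 0.2)
#' @return a \linkS4class{MaskVolume} (label "brain") of edge voxels
#' @export
cannyEdgeVolume <- function(volume, gaussianSigma = 1, lowThreshold = 0.1,
                            highThreshold = 0.2) {
  if (lowThreshold < 0 || lowThreshold >= highThreshold)
    .paramError("thresholds must satisfy 0 <= low < high")
  a <- volume@data
  if (max(a) <= 0) {
    edges <- array(0, dim(a))
  } else {
    nv <- percentileNormalize(volume, 99)@data
    edges <- array(0, dim(a))
    for (z in seq_len(dim(a)[3]))
      edges[, , z] <- .canny2d(nv[, , z], gaussianSigma, lowThreshold,
                               highThreshold)
  }
  MaskVolume(edges, label = "brain", spacing = volume@spacing,
             origin = volume@origin)
}
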