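## Physics-based degradation operators. All operate on magnitude images and
## are deterministic given (input, parameters, seed). Canonical composition
## order: geometry (B0, chemical shift) -> k-space (ghost, Gibbs/downsample)
## -> Rician noise, because magnitude noise arises at reconstruction, after
## every geometric and sampling effect.

.canonicalStages <- c("b0", "chemshift", "ghost", "gibbs_downsample",
                      "rician")

#' Add Rician noise to a magnitude volume
#'
#' Models magnitude reconstruction of a complex signal with independent
#' zero-mean Gaussian noise of standard deviation sigma in both channels:
#' each voxel becomes \code{sqrt((S + n1)^2 + n2^2)}. In zero-signal regions
#' this reduces to a Rayleigh distribution with mean sigma * sqrt(pi/2); in
#' general \code{E[M^2] = S^2 + 2 sigma^2}.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param sigma noise scale in signal units (>= 0)
#' @param seed RNG seed
#' @return noisy \linkS4class{ImageVolume} (non-negative)
#' @export
addRicianNoise <- function(volume, sigma, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) .paramError("sigma must be >= 0")
  if (sigma == 0) return(volume)
  set.seed(as.integer(seed))
  n <- length(volume@data)
  n1 <- rnorm(n, sd = sigma)
  n2 <- rnorm(n, sd = sigma)
  out <- sqrt((as.vector(volume@data) + n1)^2 + n2^2)
  ImageVolume(array(out, dim(volume@data)), spacing = volume@spacing,
              origin = volume@origin)
}

## per-axis kept-index logical vector for a centred k-space window of m
## coefficients, expressed in unshifted FFT index order; DC always kept
.keptFreqIndices <- function(n, m) {
  s <- (seq_len(n) - 1 + floor(n / 2)) %% n        # shifted position of each
  lo <- floor(n / 2) - floor(m / 2)                # window centred on DC
  s >= lo & s <= lo + m - 1
}

#' Gibbs ringing and k-space downsampling
#'
#' Forward 3D DFT, retention of only the central \code{truncationFraction}
#' of spatial frequencies per axis (zeroing the rest), optional cropping of
#' the k-space grid by \code{downsampleFactor} per axis, inverse DFT and
#' magnitude. Truncation produces the oscillatory Gibbs pattern near sharp
#' edges; cropping additionally reduces the grid, scaling voxel spacing so
#' the physical extent is preserved. The DC coefficient is never touched,
#' so constant volumes pass through unchanged and the mean intensity is
#' conserved.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param truncationFraction fraction of k-space kept per axis, in (0, 1]
#' @param downsampleFactor per-axis grid reduction factor (>= 1)
#' @return degraded \linkS4class{ImageVolume}; on the reduced grid (with
#'   scaled spacing) when downsampling
#' @export
applyGibbsTruncation <- function(volume, truncationFraction = c(1, 1, 1),
                                 downsampleFactor = c(1, 1, 1)) {
  tf <- rep_len(as.numeric(truncationFraction), 3L)
  df <- rep_len(as.numeric(downsampleFactor), 3L)
  if (any(!is.finite(tf)) || any(tf <= 0) || any(tf > 1))
    .paramError("truncationFraction must lie in (0, 1]")
  if (any(df < 1)) .paramError("downsampleFactor must be >= 1")
  if (all(tf == 1) && all(df == 1)) return(volume)
  d <- dim(volume@data)
  K <- fft(volume@data)
  for (ax in 1:3) {
    m <- max(1L, as.integer(round(tf[ax] * d[ax])))
    if (m < d[ax]) {
      drop <- !.keptFreqIndices(d[ax], m)
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[ax]] <- which(drop)
      K[idx[[1]], idx[[2]], idx[[3]]] <- 0
    }
  }
  nd <- pmax(1L, as.integer(round(d / df)))
  if (any(nd < d)) {
    keep <- lapply(1:3, function(ax) which(.keptFreqIndices(d[ax], nd[ax])))
    # reorder kept coefficients into the smaller grid's unshifted layout
    ord <- lapply(1:3, function(ax) {
      s <- (keep[[ax]] - 1 + floor(d[ax] / 2)) %% d[ax]
      keep[[ax]][order(s)]            # ascending shifted position
    })
    Ks <- K[ord[[1]], ord[[2]], ord[[3]], drop = FALSE]
    dim(Ks) <- nd
    # undo the shift on the new grid
    un <- lapply(1:3, function(ax) {
      s <- seq_len(nd[ax])
      c(s[-seq_len(floor(nd[ax] / 2))], s[seq_len(floor(nd[ax] / 2))])
    })
    K <- Ks[un[[1]], un[[2]], un[[3]], drop = FALSE]
    dim(K) <- nd
    K <- K * prod(nd) / prod(d)        # keep intensities on the same scale
  }
  out <- Mod(fft(K, inverse = TRUE)) / prod(dim(K))
  ImageVolume(array(out, dim(K)),
              spacing = volume@spacing * d / dim(K)[1:3],
              origin = volume@origin)
}

#' Nyquist (N/2) ghosting from alternating k-space line modulation
#'
#' Multiplies every k-space line at odd phase-encode index by
#' \code{ghostGain * exp(1i * ghostPhaseRad)} and reconstructs the
#' magnitude. Because the modulation depends only on the phase-encode
#' frequency index, it is applied as a 1D DFT along the phase-encode axis.
#' Zero phase with unit gain is the identity; a pure sign alternation
#' (phase pi) relocates the whole image by half the field of view along the
#' phase-encode axis, the classic EPI N/2 ghost in its extreme form.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param ghostPhaseRad phase applied to odd lines (radians)
#' @param ghostGain gain applied to odd lines
#' @param peAxis phase-encode axis (1, 2 or 3)
#' @return ghosted \linkS4class{ImageVolume}
#' @export
applyNyquistGhost <- function(volume, ghostPhaseRad = 0.2, ghostGain = 1,
                              peAxis = 2L) {
  if (!peAxis %in% 1:3) .paramError("peAxis must be 1, 2 or 3")
  if (ghostPhaseRad == 0 && ghostGain == 1) return(volume)
  mod <- function(n) {
    m <- rep(1 + 0i, n)
    odd <- (seq_len(n) - 1) %% 2 == 1
    m[odd] <- ghostGain * exp(1i * ghostPhaseRad)
    m
  }
  perm <- c(peAxis, setdiff(1:3, peAxis))
  ap <- aperm(volume@data, perm)
  d <- dim(ap)
  k <- stats::mvfft(matrix(ap, nrow = d[1])) * mod(d[1])
  m <- Mod(stats::mvfft(k, inverse = TRUE)) / d[1]
  out <- aperm(array(m, d), order(perm))
  ImageVolume(out, spacing = volume@spacing, origin = volume@origin)
}

#' Chemical shift displacement of the fat component
#'
#' The fat-masked signal is displaced by
#' \code{shiftHz / bandwidthHzPerPx} voxels along the given axis (linear
#' interpolation for fractional shifts, zero fill outside the field of
#' view) and re-added to the unshifted water component. At 3T the fat-water
#' frequency difference is 430 Hz, so an 86 Hz/pixel readout displaces fat
#' by exactly 5 voxels.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param fatMask \linkS4class{MaskVolume} of the fat compartment, same grid
#' @param shiftHz fat-water frequency offset (Hz)
#' @param bandwidthHzPerPx per-voxel readout bandwidth (Hz/pixel, nonzero)
#' @param axis displacement axis (1, 2 or 3)
#' @return \linkS4class{ImageVolume} with displaced fat signal
#' @export
applyChemicalShift <- function(volume, fatMask, shiftHz = 430,
                               bandwidthHzPerPx = 80, axis = 1L) {
  if (bandwidthHzPerPx == 0) .paramError("bandwidth must be nonzero")
  if (!axis %in% 1:3) .paramError("axis must be 1, 2 or 3")
  .checkSameGrid(volume, fatMask, "volume and fatMask")
  if (shiftHz == 0 || sum(fatMask@data) == 0) return(volume)
  shift <- shiftHz / bandwidthHzPerPx
  fat <- volume@data * fatMask@data
  water <- volume@data - fat
  perm <- c(axis, setdiff(1:3, axis))
  fp <- aperm(fat, perm)
  d <- dim(fp)
  m <- matrix(fp, nrow = d[1])
  pos <- seq_len(d[1]) - shift
  lo <- floor(pos); w <- pos - lo
  gather <- function(i) {
    ok <- i >= 1 & i <= d[1]
    g <- m[pmin(pmax(i, 1L), d[1]), , drop = FALSE]
    g[!ok, ] <- 0
    g
  }
  ms <- gather(lo) * (1 - w) + gather(lo + 1) * w
  shifted <- aperm(array(ms, d), order(perm))
  ImageVolume(water + shifted, spacing = volume@spacing,
              origin = volume@origin)
}

#' B0 off-resonance geometric distortion
#'
#' Each voxel is displaced along the phase-encode axis by
#' \code{fieldMap / bandwidthHzPerPx} voxels: the output line samples the
#' input at the inverse-mapped position (linear interpolation, zero fill
#' outside). With \code{jacobian = TRUE} the sampled intensity is modulated
#' by the local compression/stretch factor \code{1 - d'(y)} so total signal
#' along each line is conserved up to interpolation error. A uniform field
#' therefore produces a rigid translation.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param fieldMap off-resonance field in Hz, an \linkS4class{ImageVolume}
#'   on the same grid
#' @param bandwidthHzPerPx per-voxel bandwidth (Hz/pixel, nonzero)
#' @param peAxis phase-encode axis (1, 2 or 3)
#' @param jacobian apply intensity (signal-conservation) modulation
#' @return distorted \linkS4class{ImageVolume}
#' @export
applyB0Distortion <- function(volume, fieldMap, bandwidthHzPerPx = 80,
                              peAxis = 2L, jacobian = TRUE) {
  if (bandwidthHzPerPx == 0) .paramError("bandwidth must be nonzero")
  if (!peAxis %in% 1:3) .paramError("peAxis must be 1, 2 or 3")
  .checkSameGrid(volume, fieldMap, "volume and fieldMap")
  if (all(fieldMap@data == 0)) return(volume)
  perm <- c(peAxis, setdiff(1:3, peAxis))
  ap <- aperm(volume@data, perm)
  dp <- aperm(fieldMap@data / bandwidthHzPerPx, perm)
  d <- dim(ap)
  vm <- matrix(ap, nrow = d[1])
  dm <- matrix(dp, nrow = d[1])
  n <- d[1]
  for (j in seq_len(ncol(vm))) {
    dd <- dm[, j]
    pos <- seq_len(n) - dd
    line <- .interp1Zero(vm[, j], pos)
    if (jacobian) {
      grad <- c(dd[2] - dd[1], (dd[-(1:2)] - dd[-((n - 1):n)]) / 2,
                dd[n] - dd[n - 1])
      line <- line * pmax(1 - grad, 0)
    }
    vm[, j] <- line
  }
  out <- aperm(array(vm, d), order(perm))
  ImageVolume(pmax(out, 0), spacing = volume@spacing,
              origin = volume@origin)
}

#' Synthesize a smooth off-resonance field map
#'
#' A stand-in for susceptibility field modelling: a random low-order
#' polynomial plus Gaussian-smoothed white noise, rescaled so that the peak
#' magnitude lies between 60 and 100 percent of \code{amplitudeHz}.
#' Deterministic given the seed.
#'
#' @param shape integer(3) grid size
#' @param spacing numeric(3) voxel size in mm
#' @param smoothnessMm correlation length of the random component (mm)
#' @param amplitudeHz peak field magnitude bound (Hz, >= 0)
#' @param seed RNG seed
#' @return an \linkS4class{ImageVolume} holding the field in Hz
#' @export
synthesizeFieldMap <- function(shape, spacing = c(1, 1, 1),
                               smoothnessMm = 20, amplitudeHz = 60,
                               seed = 1L) {
  if (!is.finite(amplitudeHz) || amplitudeHz < 0)
    .paramError("amplitudeHz must be >= 0")
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (amplitudeHz == 0)
    return(ImageVolume(array(0, shape), spacing = spacing))
  set.seed(as.integer(seed))
  cc <- lapply(1:3, function(ax) seq_len(shape[ax]) - (shape[ax] + 1) / 2)
  cc <- lapply(1:3, function(ax) cc[[ax]] / max(abs(cc[[ax]]), 1))
  X <- array(rep(cc[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cc[[2]], each = shape[1]), shape[3]), shape)
  Z <- array(rep(cc[[3]], each = shape[1] * shape[2]), shape)
  b <- rnorm(9)
  poly <- b[1] * X + b[2] * Y + b[3] * Z + b[4] * X * Y + b[5] * X * Z +
    b[6] * Y * Z + b[7] * X^2 + b[8] * Y^2 + b[9] * Z^2
  noise <- .gaussSmooth3d(array(rnorm(prod(shape)), shape),
                          smoothnessMm / spacing)
  f <- poly / max(abs(poly)) + 0.5 * noise / max(abs(noise))
  scale <- amplitudeHz * runif(1, 0.6, 1)
  ImageVolume(f / max(abs(f)) * scale, spacing = spacing)
}

#' Compose degradation stages in canonical order
#'
#' Applies a subset of the five artifact families in the fixed order
#' b0 -> chemshift -> ghost -> gibbs_downsample -> rician (geometry before
#' k-space effects, magnitude noise last, as in magnitude reconstruction).
#' The empty stage set is the identity. Deterministic given (input, config,
#' seed).
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param config a \linkS4class{DegradationConfig}
#' @param stages character subset of
#'   \code{c("b0", "chemshift", "ghost", "gibbs_downsample", "rician")},
#'   listed in canonical order
#' @param fatMask \linkS4class{MaskVolume}; required when "chemshift" is in
#'   \code{stages}
#' @return degraded \linkS4class{ImageVolume}
#' @export
composeDegradation <- function(volume, config, stages = .canonicalStages,
                               fatMask = NULL) {
  stopifnot(is(config, "DegradationConfig"))
  if (!all(stages %in% .canonicalStages))
    .paramError("unknown stage name: %s",
                paste(setdiff(stages, .canonicalStages), collapse = ", "))
  if (!identical(stages, .canonicalStages[.canonicalStages %in% stages]))
    .paramError("stages must be listed in canonical order (%s)",
                paste(.canonicalStages, collapse = " -> "))
  v <- volume
  if ("b0" %in% stages) {
    if (is.null(config@fieldMap))
      .paramError("stage 'b0' requires config@fieldMap")
    v <- applyB0Distortion(v, config@fieldMap, config@bandwidthHzPerPx,
                           config@peAxis)
  }
  if ("chemshift" %in% stages) {
    if (is.null(fatMask))
      .paramError("stage 'chemshift' requires a fatMask")
    v <- applyChemicalShift(v, fatMask, config@fatWaterShiftHz,
                            config@bandwidthHzPerPx, axis = 1L)
  }
  if ("ghost" %in% stages)
    v <- applyNyquistGhost(v, config@ghostPhaseRad, config@ghostGain,
                           config@peAxis)
  if ("gibbs_downsample" %in% stages)
    v <- applyGibbsTruncation(v, config@truncationFraction,
                              config@downsampleFactor)
  if ("rician" %in% stages)
    v <- addRicianNoise(v, config@ricianSigma, config@seed)
  v
}
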