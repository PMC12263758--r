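#' Read a volume from a NIfTI-1 file
#'
#' Spacing is taken from the stored transform's scale; the physical origin
#' from its translation. Only axis-aligned geometry is honoured (see the
#' coordinate convention in \linkS4class{ImageVolume}).
#'
#' @param path path to a .nii or .nii.gz file
#' @param mask if TRUE, return a \linkS4class{MaskVolume} (values binarized
#'   at 0.5) with the given \code{label}
#' @param label compartment label when \code{mask = TRUE}
#' @return an \linkS4class{ImageVolume} or \linkS4class{MaskVolume}
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, mask = FALSE, label = "brain") {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf)[1:3])
  spacing[spacing == 0] <- 1
  origin <- xf[1:3, 4]
  a <- array(as.numeric(img), dim = dim(img)[1:3])
  if (mask) MaskVolume((a > 0.5) * 1, label = label, spacing = spacing,
                       origin = origin)
  else ImageVolume(a, spacing = spacing, origin = origin)
}

#' Write a volume to a NIfTI-1 file
#'
#' Image volumes are stored as 32-bit float, masks as unsigned 8-bit.
#'
#' @param volume an \linkS4class{ImageVolume} or \linkS4class{MaskVolume}
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
  sp <- volume@spacing
  or <- volume@origin
  aff <- diag(4)
  diag(aff)[1:3] <- sp
  aff[1:3, 4] <- or
  hdr <- list(pixdim = c(1, sp, 1, 1, 1, 1),
              srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
              sform_code = 2L, qform_code = 0L)
  img <- RNifti::asNifti(volume@data, reference = hdr)
  dtype <- if (is(volume, "MaskVolume")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a volume onto a new voxel grid
#'
#' Output grid size is chosen so the physical extent of the input is
#' preserved (\code{round(shape * spacing / targetSpacing)}); a 48^3 volume
#' at 5.5 mm isotropic spacing therefore lands on a 264^3 grid at 1 mm,
#' preserving the 264 mm field of view. Intensities are interpolated
#' trilinearly; masks must use nearest-neighbour (and are re-binarized at
#' 0.5 by [resampleMask()]).
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param targetSpacing numeric(3) (or scalar) target voxel size in mm
#' @param method "trilinear" (intensities) or "nearest" (labels)
#' @return the resampled \linkS4class{ImageVolume}
#' @examples
#' v <- ImageVolume(array(7, c(12, 12, 12)), spacing = c(5.5, 5.5, 5.5))
#' dim(resampleToGrid(v, 1))
#' @export
resampleToGrid <- function(volume, targetSpacing,
                           method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  ts <- rep_len(as.numeric(targetSpacing), 3L)
  if (any(!is.finite(ts)) || any(ts <= 0))
    .paramError("targetSpacing must be strictly positive")
  d <- dim(volume@data)
  if (prod(d) == 0) .domainError("cannot resample an empty volume")
  sp <- volume@spacing
  if (all(abs(ts - sp) < 1e-12)) return(volume)
  od <- pmax(1L, as.integer(round(d * sp / ts)))
  # source (0-based, fractional) index of each output voxel centre per axis
  src <- lapply(1:3, function(ax) {
    j <- (seq_len(od[ax]) - 1) * ts[ax] / sp[ax]
    pmin(pmax(j, 0), d[ax] - 1)
  })
  out <- if (method == "nearest") {
    ix <- as.integer(round(src[[1]])) + 1L
    iy <- as.integer(round(src[[2]])) + 1L
    iz <- as.integer(round(src[[3]])) + 1L
    array(volume@data[cbind(rep.int(ix, od[2] * od[3]),
                            rep.int(rep(iy, each = od[1]), od[3]),
                            rep(iz, each = od[1] * od[2]))], od)
  } else {
    .trilinear(volume@data, src[[1]], src[[2]], src[[3]])
  }
  ImageVolume(out, spacing = ts, origin = volume@origin)
}

## separable trilinear gather: sx/sy/sz are 0-based fractional coordinates
.trilinear <- function(a, sx, sy, sz) {
  d <- dim(a)
  fx <- pmin(floor(sx), d[1] - 1); wx <- sx - fx
  fy <- pmin(floor(sy), d[2] - 1); wy <- sy - fy
  fz <- pmin(floor(sz), d[3] - 1); wz <- sz - fz
  cx <- pmin(fx + 1, d[1] - 1); cy <- pmin(fy + 1, d[2] - 1)
  cz <- pmin(fz + 1, d[3] - 1)
  od <- c(length(sx), length(sy), length(sz))
  P <- prod(od)
  rx <- rep.int(seq_len(od[1]), od[2] * od[3])
  ry <- rep.int(rep(seq_len(od[2]), each = od[1]), od[3])
  rz <- rep(seq_len(od[3]), each = od[1] * od[2])
  gather <- function(ix, iy, iz)
    a[cbind(ix[rx] + 1L, iy[ry] + 1L, iz[rz] + 1L)]
  wxr <- wx[rx]; wyr <- wy[ry]; wzr <- wz[rz]
  v <- gather(fx, fy, fz) * (1 - wxr) * (1 - wyr) * (1 - wzr) +
       gather(cx, fy, fz) * wxr       * (1 - wyr) * (1 - wzr) +
       gather(fx, cy, fz) * (1 - wxr) * wyr       * (1 - wzr) +
       gather(cx, cy, fz) * wxr       * wyr       * (1 - wzr) +
       gather(fx, fy, cz) * (1 - wxr) * (1 - wyr) * wzr +
       gather(cx, fy, cz) * wxr       * (1 - wyr) * wzr +
       gather(fx, cy, cz) * (1 - wxr) * wyr       * wzr +
       gather(cx, cy, cz) * wxr       * wyr       * wzr
  array(v, od)
}

#' Resample a mask with nearest-neighbour interpolation
#'
#' Nearest-neighbour resampling followed by re-binarization at 0.5, which
#' preserves the nesting/disjointness invariants of compartment masks.
#'
#' @param mask a \linkS4class{MaskVolume}
#' @param targetSpacing numeric(3) target voxel size in mm
#' @return the resampled \linkS4class{MaskVolume}
#' @export
resampleMask <- function(mask, targetSpacing) {
  r <- resampleToGrid(mask, targetSpacing, method = "nearest")
  MaskVolume((r@data > 0.5) * 1, label = mask@label, spacing = r@spacing,
             origin = r@origin)
}

#' Percentile-based intensity normalization
#'
#' Divides by the empirical p-th percentile (the smallest voxel value that
#' at least p percent of voxels do not exceed) and clips to [0, 1]. The
#' result is invariant to positive rescaling of the input and robust to the
#' hyperintense vitreous/lesion tail, which is why it is used to scale
#' network inputs (p = 99 by default).
#'
#' @param volume an \linkS4class{ImageVolume} with at least one positive
#'   voxel
#' @param p percentile in (0, 100]
#' @return normalized \linkS4class{ImageVolume} with values in [0, 1]
#' @export
percentileNormalize <- function(volume, p = 99) {
  if (p <= 0 || p > 100) .paramError("p must lie in (0, 100]")
  div <- percentileDivisor(volume@data, p)
  if (div <= 0)
    .domainError("volume has no positive voxels; cannot normalize")
  ImageVolume(pmin(pmax(volume@data / div, 0), 1),
              spacing = volume@spacing, origin = volume@origin)
}

#' Empirical percentile divisor used by [percentileNormalize()]
#'
#' Type-1 (order-statistic) empirical percentile: the
#' \code{ceiling(p/100 * n)}-th smallest value.
#'
#' @param x numeric values
#' @param p percentile in (0, 100]
#' @return the percentile value
#' @export
percentileDivisor <- function(x, p) {
  x <- as.numeric(x)
  sort(x, method = "quick")[max(1L, ceiling(p / 100 * length(x)))]
}
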