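#' Derive a module-level seed from a global seed
#'
#' Every source of randomness in the package draws its seed from one global
#' seed through this counter-based expansion, so that a single \code{--seed}
#' reproduces a whole pipeline while stages stay decorrelated.
#'
#' @param seed global integer seed
#' @param k counter (stage index, sample index, ...)
#' @return an integer seed in [0, 2^31 - 2]
#' @export
deriveSeed <- function(seed, k = 0L) {
  # Lehmer-style mix; modulus 2^31 - 1 keeps the result a valid R integer
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + as.numeric(k) * 16807 + 1) %% m
  as.integer(s)
}

## stop with a classed condition so callers/tests can distinguish
## parameter errors from domain (data-dependent) errors
.err <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.paramError <- function(fmt, ...) .err("sodiumSR_parameter_error", fmt, ...)
.domainError <- function(fmt, ...) .err("sodiumSR_domain_error", fmt, ...)
.shapeError <- function(fmt, ...) .err("sodiumSR_shape_error", fmt, ...)

.sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

.checkSameGrid <- function(a, b, what = "volumes") {
  if (!.sameGrid(a, b))
    .shapeError("%s must share one grid (shape, spacing and origin)", what)
  invisible(TRUE)
}

## 1D linear-interpolation sample of vector v at (1-based, possibly
## fractional) positions pos; zero outside [1, length(v)]
.interp1Zero <- function(v, pos) {
  n <- length(v)
  lo <- floor(pos)
  w <- pos - lo
  vlo <- ifelse(lo >= 1 & lo <= n, v[pmin(pmax(lo, 1L), n)], 0)
  hi <- lo + 1
  vhi <- ifelse(hi >= 1 & hi <= n, v[pmin(pmax(hi, 1L), n)], 0)
  vlo * (1 - w) + vhi * w
}

## apply FUN(line, ...) to every 1D line of 3D array a along axis,
## returning an array of the same shape
.applyAlongAxis <- function(a, axis, FUN, ...) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  for (j in seq_len(ncol(m))) m[, j] <- FUN(m[, j], ...)
  aperm(array(m, d), order(perm))
}

## frequency-domain Gaussian smoothing (circular boundary); sigma in voxels
.gaussSmooth3d <- function(a, sigmaVox) {
  d <- dim(a)
  tf <- array(1, d)
  for (ax in 1:3) {
    n <- d[ax]
    f <- (seq_len(n) - 1) / n
    f <- ifelse(f > 0.5, f - 1, f)
    g1 <- exp(-2 * pi^2 * sigmaVox[ax]^2 * f^2)
    tf <- sweep(tf, ax, g1, "*")
  }
  Re(fft(fft(a) * tf, inverse = TRUE)) / prod(d)
}
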