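# shared fixtures: everything is generated in code, no stored binaries

# small, fast phantom grid used across tests
tinySpec <- function(seed = 1L, ...)
  PhantomSpec(shape = c(32L, 32L, 16L), spacing = c(2, 2, 2), seed = seed,
              ...)

# sampler and network sizes for the scaled training runs
smallSampler <- function()
  defaultSpecSampler(shape = c(24L, 24L, 8L), spacing = c(2.5, 2.5, 4))

smallBundle <- function(seed = 1L, width = 6L)
  newModelBundle(GeneratorConfig(depth = 2L, baseWidth = width,
                                 recurrence = 1L),
                 DiscriminatorConfig(nLayers = 3L, baseWidth = 4L),
                 seed = seed)

randomVolume <- function(shape, seed = 1L, spacing = c(1, 1, 1)) {
  set.seed(seed)
  ImageVolume(array(runif(prod(shape)), shape), spacing = spacing)
}

# single-window structural similarity (global means/variances/covariance);
# enough to rank degradation severity on a smooth phantom
ssimGlobal <- function(a, b) {
  c1 <- (0.01 * max(a))^2; c2 <- (0.03 * max(a))^2
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}
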