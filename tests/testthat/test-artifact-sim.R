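# brute-force oracles are written with explicit DFT sums / array rolls so
# they stay independent of the fft-based implementation paths

# explicit 1D DFT (naive O(n^2) sums)
naiveDFT <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 1i else -1i
  vapply(0:(n - 1), function(k)
    sum(x * exp(sgn * 2 * pi * k * (0:(n - 1)) / n)), complex(1)) /
    (if (inverse) n else 1)
}

test_that("every operator is the identity at null parameters", {
  v <- randomVolume(c(16, 16, 8), seed = 5)
  relerr <- function(a) max(abs(volData(a) - volData(v))) / max(volData(v))
  expect_identical(addRicianNoise(v, 0), v)
  expect_lt(relerr(applyGibbsTruncation(v, c(1, 1, 1), c(1, 1, 1))), 1e-5)
  expect_lt(relerr(applyNyquistGhost(v, 0, 1)), 1e-5)
  fm0 <- ImageVolume(array(0, dim(v)))
  expect_lt(relerr(applyB0Distortion(v, fm0, 20)), 1e-5)
  fat <- MaskVolume(array(0, dim(v)), "fat")
  expect_lt(relerr(applyChemicalShift(v, fat, 430, 86)), 1e-5)
  fat1 <- MaskVolume((volData(v) > 0.5) * 1, "fat")
  expect_lt(relerr(applyChemicalShift(v, fat1, 0, 86)), 1e-5)
  cfg <- DegradationConfig()
  expect_identical(composeDegradation(v, cfg, character()), v)
})

test_that("Rician noise reproduces the Rayleigh and second-moment laws", {
  n <- 1e6
  zero <- ImageVolume(array(0, c(100, 100, 100)))
  m <- volData(addRicianNoise(zero, 1, seed = 42))
  # zero signal: Rayleigh mean sigma*sqrt(pi/2), sd sigma*sqrt(2 - pi/2)
  se <- sqrt((2 - pi / 2) / n)
  expect_lt(abs(mean(m) - sqrt(pi / 2)), 3 * se)
  s3 <- ImageVolume(array(3, c(100, 100, 100)))
  m2 <- volData(addRicianNoise(s3, 1, seed = 43))^2
  # E[M^2] = S^2 + 2 sigma^2 = 11; Var[M^2] = 4 sigma^2 S^2 + 8 sigma^4
  seM2 <- sqrt((4 * 9 + 8) / n)
  expect_lt(abs(mean(m2) - 11), 3 * seM2)
  expect_true(all(m >= 0))
  expect_error(addRicianNoise(zero, -1), class = "sodiumSR_parameter_error")
})

test_that("Rician noise is seed-deterministic", {
  v <- randomVolume(c(10, 10, 4), seed = 3)
  expect_identical(addRicianNoise(v, 0.5, seed = 7),
                   addRicianNoise(v, 0.5, seed = 7))
})

test_that("Gibbs truncation matches an explicit small-N DFT oracle", {
  # impulse along x, constant along y/z: ringing is purely 1D
  n <- 32
  a <- array(0, c(n, 8, 4)); a[17, , ] <- 1
  out <- applyGibbsTruncation(ImageVolume(a), c(0.5, 1, 1))
  # oracle: naive DFT of the x-profile, zero outside the centred window,
  # naive inverse, magnitude
  prof <- a[, 1, 1]
  K <- naiveDFT(prof)
  m <- round(0.5 * n)
  shiftpos <- ((0:(n - 1)) + n %/% 2) %% n
  lo <- n %/% 2 - m %/% 2
  K[!(shiftpos >= lo & shiftpos <= lo + m - 1)] <- 0
  oracle <- Mod(naiveDFT(K, inverse = TRUE))
  expect_lt(max(abs(volData(out)[, 3, 2] - oracle)), 1e-6)
})

test_that("Gibbs truncation preserves DC (constant volumes, mean signal)", {
  const <- ImageVolume(array(3, c(16, 16, 8)))
  out <- applyGibbsTruncation(const, c(0.4, 0.6, 0.8))
  expect_lt(max(abs(volData(out) - 3)), 1e-9)
  v <- randomVolume(c(16, 16, 8), seed = 8)
  tr <- applyGibbsTruncation(v, c(0.5, 0.5, 1))
  expect_equal(mean(volData(tr)), mean(volData(v)), tolerance = 0.02)
})

test_that("k-space downsampling reduces the grid and scales spacing", {
  v <- ImageVolume(array(7, c(22, 22, 11)), spacing = c(1, 1, 2))
  d <- applyGibbsTruncation(v, c(1, 1, 1), c(5.5, 5.5, 2.75))
  expect_identical(dim(d), c(4L, 4L, 4L))
  expect_equal(dim(d) * voxelSpacing(d), dim(v) * voxelSpacing(v))
  expect_lt(max(abs(volData(d) - 7)), 1e-9)
})

test_that("Nyquist ghost matches a brute-force k-space oracle", {
  n <- 32
  disk <- array(0, c(n, n, 2))
  disk[, 14:18, ][14:18, , ] <- 1
  v <- ImageVolume(disk)
  ghostOracle <- function(line, phase, gain) {
    K <- naiveDFT(line)
    odd <- (seq_along(K) - 1) %% 2 == 1
    K[odd] <- K[odd] * gain * exp(1i * phase)
    Mod(naiveDFT(K, inverse = TRUE))
  }
  for (phase in c(pi, 0.2)) {
    out <- applyNyquistGhost(v, phase, 1, peAxis = 2)
    oracle <- t(apply(disk[, , 1], 1, ghostOracle, phase = phase, gain = 1))
    expect_lt(max(abs(volData(out)[, , 1] - oracle)), 1e-6)
  }
  # pure sign alternation relocates all energy by half the FOV
  out <- applyNyquistGhost(v, pi, 1, peAxis = 2)
  shifted <- disk[, c((n / 2 + 1):n, 1:(n / 2)), ]
  expect_lt(max(abs(volData(out) - shifted)), 1e-9)
})

test_that("chemical shift displaces fat by shift/bandwidth voxels", {
  a <- array(0, c(24, 8, 4)); a[6:10, , ] <- 2
  v <- ImageVolume(a)
  allFat <- MaskVolume(array(1, dim(a)), "fat")
  # 430 Hz at 86 Hz/px: exactly 5 voxels
  out <- applyChemicalShift(v, allFat, 430, 86, axis = 1)
  roll <- array(0, dim(a)); roll[11:15, , ] <- 2
  expect_lt(max(abs(volData(out) - roll)), 1e-12)
  # fractional shift conserves fat mass away from edges
  out2 <- applyChemicalShift(v, allFat, 430, 100, axis = 1)
  expect_equal(sum(volData(out2)), sum(a), tolerance = 1e-9)
  expect_error(applyChemicalShift(v, allFat, 430, 0),
               class = "sodiumSR_parameter_error")
})

test_that("uniform B0 field rigidly translates along the phase axis", {
  a <- array(0, c(8, 24, 4)); a[, 8:12, ] <- 1
  v <- ImageVolume(a)
  fm <- ImageVolume(array(40, dim(a)))
  out <- applyB0Distortion(v, fm, 20, peAxis = 2)
  roll <- array(0, dim(a)); roll[, 10:14, ] <- 1
  expect_lt(max(abs(volData(out) - roll)), 1e-9)
})

test_that("B0 Jacobian modulation conserves per-line signal", {
  set.seed(4)
  a <- array(0, c(6, 40, 4))
  a[, 11:30, ] <- rep(1 + runif(20 * 4), each = 6)
  v <- ImageVolume(a)
  # linear field along the phase axis, moderate gradient
  lin <- array(rep(seq(-15, 15, length.out = 40), each = 6), dim(a))
  fm <- ImageVolume(lin - min(lin))
  out <- applyB0Distortion(v, fm, 40, peAxis = 2, jacobian = TRUE)
  for (z in 1:4) for (x in 1:6) {
    tot0 <- sum(a[x, , z])
    tot1 <- sum(volData(out)[x, , z])
    expect_lt(abs(tot1 - tot0) / tot0, 0.01)
  }
})

test_that("synthesized field maps are bounded, smooth and deterministic", {
  f0 <- synthesizeFieldMap(c(12, 12, 6), amplitudeHz = 0)
  expect_true(all(volData(f0) == 0))
  f1 <- synthesizeFieldMap(c(12, 12, 6), amplitudeHz = 60, seed = 5)
  expect_identical(f1, synthesizeFieldMap(c(12, 12, 6), amplitudeHz = 60,
                                          seed = 5))
  peaks <- vapply(1:100, function(s)
    max(abs(volData(synthesizeFieldMap(c(8, 8, 4), amplitudeHz = 60,
                                       seed = s)))), 1)
  expect_true(all(peaks <= 60))
  expect_true(all(peaks >= 30))
})

test_that("composition is ordered, deterministic, and degrades structure", {
  spec <- tinySpec(seed = 2)
  ph <- generateHeadPhantom(spec)
  v <- ph@hiResSodium
  fm <- synthesizeFieldMap(dim(v), voxelSpacing(v), amplitudeHz = 40,
                          seed = 3)
  cfg <- DegradationConfig(fieldMap = fm, ghostPhaseRad = 0.3,
                           truncationFraction = c(0.5, 0.5, 1),
                           ricianSigma = 3, seed = 11L)
  expect_error(composeDegradation(v, cfg, c("rician", "b0")),
               class = "sodiumSR_parameter_error")
  expect_error(composeDegradation(v, cfg, "warp"),
               class = "sodiumSR_parameter_error")
  full <- c("b0", "chemshift", "ghost", "gibbs_downsample", "rician")
  r1 <- composeDegradation(v, cfg, full, fatMask = ph@masks$fat)
  r2 <- composeDegradation(v, cfg, full, fatMask = ph@masks$fat)
  expect_identical(r1, r2)
  # structural similarity to ground truth never increases as stages
  # accumulate in canonical order
  sims <- vapply(seq_along(full), function(k) {
    out <- composeDegradation(v, cfg, full[seq_len(k)],
                              fatMask = ph@masks$fat)
    ssimGlobal(volData(v), volData(out))
  }, 1)
  expect_true(all(diff(sims) <= 1e-6))
})
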