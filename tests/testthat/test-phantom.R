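test_that("phantom generation is deterministic and mask-consistent", {
  ph1 <- generateHeadPhantom(tinySpec(seed = 4))
  ph2 <- generateHeadPhantom(tinySpec(seed = 4))
  expect_identical(volData(ph1@hiResSodium), volData(ph2@hiResSodium))
  expect_identical(volData(ph1@loResSodium), volData(ph2@loResSodium))
  m <- lapply(ph1@masks, volData)
  # nesting: necrosis within CET within T2hyper; NAWM and eyes disjoint
  # from the lesion; fat ring present
  expect_true(all(m$CET[m$necrosis == 1] == 1))
  expect_true(all(m$T2hyper[m$CET == 1] == 1))
  expect_equal(sum(m$NAWM * m$T2hyper), 0)
  expect_equal(sum((m$eye_left + m$eye_right) * m$T2hyper), 0)
  expect_gt(sum(m$fat), 0)
  for (mm in m) expect_true(all(mm %in% c(0, 1)))
})

test_that("noiseless compartment means equal the spec means", {
  spec <- tinySpec(seed = 1)
  ph <- generateHeadPhantom(spec)
  s <- volData(ph@hiResSodium)
  m <- lapply(ph@masks, volData)
  expect_equal(mean(s[m$NAWM == 1]), spec@sodiumMeans[["brain"]])
  expect_equal(mean(s[m$T2hyper == 1]), spec@sodiumMeans[["t2hyper"]])
  ee <- m$eye_left + m$eye_right
  expect_equal(mean(s[ee == 1]), spec@sodiumMeans[["eye"]])
})

test_that("lesion:NAWM sodium ratio survives acquisition noise", {
  # noise at 2% of the NAWM mean; ratio must hold within 2%
  spec <- tinySpec(seed = 6, sodiumLesionRatio = 1.4, ricianSigma = 2)
  ph <- generateHeadPhantom(spec)
  noisy <- addRicianNoise(ph@hiResSodium, 2, seed = 10)
  s <- volData(noisy)
  m <- lapply(ph@masks, volData)
  ratio <- mean(s[m$T2hyper == 1]) / mean(s[m$NAWM == 1])
  expect_equal(ratio, 1.4, tolerance = 0.02)
})

test_that("5 mm eye spheres hold the right voxel volume on a 1 mm grid", {
  ph <- generateHeadPhantom(PhantomSpec(seed = 2))
  target <- pi / 6 * 5^3
  for (eye in c("eye_left", "eye_right")) {
    n <- sum(volData(ph@masks[[eye]]))
    expect_lt(abs(n - target) / target, 0.10)
  }
})

test_that("low-resolution acquisition lands near the native sodium grid", {
  spec <- PhantomSpec(seed = 3)
  ph <- generateHeadPhantom(spec)
  # integer grids: spacing is the closest achievable to 5.5 mm isotropic
  expect_equal(voxelSpacing(ph@loResSodium), spec@loResSpacing,
               tolerance = 0.1)
  expect_equal(dim(ph@loResSodium) * voxelSpacing(ph@loResSodium),
               dim(ph@hiResSodium) * voxelSpacing(ph@hiResSodium))
})

test_that("impossible geometry is rejected", {
  expect_error(PhantomSpec(shape = c(32L, 32L, 16L), spacing = c(1, 1, 1),
                           lesionCenter = c(14, 0, 0),
                           lesionRadii = c(10, 6, 3)))
  expect_error(PhantomSpec(lesionRadii = c(3, 6, 10)))
})

test_that("training pairs are reproducible and share the clean phantom", {
  p1 <- makeTrainingPairs(3, smallSampler(), curriculumStage = "rician",
                          seed = 7)
  p2 <- makeTrainingPairs(3, smallSampler(), curriculumStage = "rician",
                          seed = 7)
  expect_length(p1, 3)
  for (i in 1:3) {
    expect_identical(volData(p1[[i]]$degraded), volData(p2[[i]]$degraded))
    expect_identical(volData(p1[[i]]$clean),
                     volData(p1[[i]]$sample@hiResSodium))
    expect_identical(dim(p1[[i]]$degraded), dim(p1[[i]]$clean))
  }
  expect_error(makeTrainingPairs(2, curriculumStage = "sharpen"),
               class = "sodiumSR_parameter_error")
})

test_that("noise-only pairs differ from clean by zero-mean structure", {
  pairs <- makeTrainingPairs(4, smallSampler(),
                             curriculumStage = "rician", seed = 9)
  for (pr in pairs) {
    resid <- volData(pr$degraded) - volData(pr$clean)
    sel <- volData(pr$clean) > 0       # Rician bias is confined to S ~ 0
    sigma <- pr$sample@spec@ricianSigma
    expect_gt(sd(resid[sel]), 0)
    # residual mean within a few standard errors of zero (high-SNR Rician
    # noise is approximately symmetric)
    expect_lt(abs(mean(resid[sel])),
              5 * sigma / sqrt(sum(sel)) + 0.02 * sigma)
    # residuals carry no structure correlated with the image
    expect_lt(abs(stats::cor(resid[sel], volData(pr$clean)[sel])), 0.1)
  }
})
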