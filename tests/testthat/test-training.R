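# fast training checks use a deliberately small net and few pairs; the
# full scaled curriculum behaviour lives in the acceptance suite

tinyTrainBundle <- function(seed = 1L)
  newModelBundle(GeneratorConfig(depth = 2L, baseWidth = 2L,
                                 recurrence = 1L),
                 DiscriminatorConfig(nLayers = 2L, baseWidth = 2L),
                 seed = seed)

test_that("training is deterministic under a fixed seed", {
  pairs <- makeTrainingPairs(3, smallSampler(), curriculumStage = "rician",
                             seed = 4)
  st <- CurriculumStage("noise", "rician", epochs = 2,
                        learningRate = 1e-3, init = "previous")
  b1 <- trainStage(tinyTrainBundle(7), st, pairs, seed = 5)
  b2 <- trainStage(tinyTrainBundle(7), st, pairs, seed = 5)
  expect_identical(b1@generator$params, b2@generator$params)
  expect_identical(b1@provenance[[1]]$history, b2@provenance[[1]]$history)
})

test_that("loss history is complete, finite, and reconstruction improves", {
  pairs <- makeTrainingPairs(6, smallSampler(), curriculumStage = "rician",
                             seed = 8)
  st <- CurriculumStage("noise", "rician", epochs = 6,
                        learningRate = 1e-3, init = "previous")
  b <- trainStage(tinyTrainBundle(2), st, pairs, seed = 3)
  h <- b@provenance[[1]]$history
  expect_equal(nrow(h), 6)
  expect_true(all(is.finite(as.matrix(h))))
  expect_lt(h$g_rec[6], h$g_rec[1])
})

test_that("init = previous hands weights over; fresh re-initializes", {
  pairs <- makeTrainingPairs(2, smallSampler(), curriculumStage = "rician",
                             seed = 1)
  st1 <- CurriculumStage("a", "rician", epochs = 1, learningRate = 1e-3,
                         init = "fresh")
  b0 <- tinyTrainBundle(9)
  b1 <- trainStage(b0, st1, pairs, seed = 2)
  # a follow-on stage at a negligible learning rate keeps the incoming
  # weights essentially untouched: the hand-off contract
  st2 <- CurriculumStage("b", "rician", epochs = 1, learningRate = 1e-300,
                         init = "previous")
  b2 <- trainStage(b1, st2, pairs, seed = 3)
  expect_equal(sodiumSR:::.paramChecksum(b2@generator$params),
               sodiumSR:::.paramChecksum(b1@generator$params),
               tolerance = 1e-12)
  # fresh init from the same stage seed ignores the incoming weights
  st3 <- CurriculumStage("c", "rician", epochs = 1, learningRate = 1e-300,
                         init = "fresh")
  b3 <- trainStage(b1, st3, pairs, seed = 4)
  expect_false(isTRUE(all.equal(b3@generator$params, b1@generator$params)))
})

test_that("curricula enforce non-decreasing complexity and chain stages", {
  expect_error(runCurriculum(list(
    CurriculumStage("x", c("gibbs_downsample", "rician"), epochs = 1),
    CurriculumStage("y", "rician", epochs = 1)),
    function(stage, s) list(), seed = 1),
    class = "sodiumSR_parameter_error")
  sampler <- function(stage, s)
    makeTrainingPairs(2, smallSampler(), curriculumStage = stage, seed = s)
  # a single-stage curriculum is exactly trainStage
  st <- CurriculumStage("only", "rician", epochs = 1,
                        learningRate = 1e-3, init = "fresh")
  bC <- runCurriculum(list(st), sampler, seed = 6,
                      bundle = tinyTrainBundle(6))
  bS <- trainStage(tinyTrainBundle(6), st,
                   sampler(st, deriveSeed(6, 1001L)),
                   seed = deriveSeed(6, 1L))
  expect_identical(bC@generator$params, bS@generator$params)
  # two stages record ordered provenance
  b2 <- runCurriculum(list(
    CurriculumStage("s1", "rician", epochs = 1, learningRate = 1e-3),
    CurriculumStage("s2", c("gibbs_downsample", "rician"), epochs = 1,
                    learningRate = 1e-3)),
    sampler, seed = 7, bundle = tinyTrainBundle(7))
  expect_identical(vapply(b2@provenance, `[[`, "", "name"), c("s1", "s2"))
  expect_identical(b2@provenance[[2]]$init, "previous")
})

test_that("bundle save/load round-trips and supports continuation", {
  pairs <- makeTrainingPairs(2, smallSampler(), curriculumStage = "rician",
                             seed = 3)
  st1 <- CurriculumStage("s1", "rician", epochs = 1, learningRate = 1e-3,
                         init = "fresh")
  st2 <- CurriculumStage("s2", "rician", epochs = 1, learningRate = 1e-3,
                         init = "previous")
  b1 <- trainStage(tinyTrainBundle(5), st1, pairs, seed = 11)
  dir <- tempfile()
  saveModelBundle(b1, dir)
  b1r <- loadModelBundle(dir)
  expect_equal(b1r@generator$params, b1@generator$params)
  expect_equal(b1r@discriminator$params, b1@discriminator$params)
  # continuing from the reloaded bundle reproduces the uninterrupted run
  direct <- trainStage(b1, st2, pairs, seed = 12)
  resumed <- trainStage(b1r, st2, pairs, seed = 12)
  expect_equal(resumed@generator$params, direct@generator$params)
})
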