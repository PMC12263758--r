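## Stacked transfer-learning curriculum: sequential adversarial training
## stages on increasingly complex artifact mixtures, each initialized from
## the previous stage's weights. One sample per step (patch batches of one),
## alternating discriminator and generator Adam updates.

#' Create an untrained ModelBundle
#'
#' @param generatorConfig a \linkS4class{GeneratorConfig}
#' @param discriminatorConfig a \linkS4class{DiscriminatorConfig}
#' @param lossConfig a \linkS4class{LossConfig}
#' @param seed weight initialization seed
#' @return a \linkS4class{ModelBundle} with fresh weights and empty
#'   provenance
#' @export
newModelBundle <- function(generatorConfig = GeneratorConfig(),
                           discriminatorConfig = DiscriminatorConfig(),
                           lossConfig = LossConfig(), seed = 1L) {
  new("ModelBundle",
      generator = buildGenerator(generatorConfig, deriveSeed(seed, 1L)),
      discriminator = buildDiscriminator(discriminatorConfig,
                                         deriveSeed(seed, 2L)),
      lossConfig = lossConfig, provenance = list(), seed = as.integer(seed))
}

## turn one training pair into the tensors the networks consume: the
## 2-channel generator input (normalized degraded image + anatomical edge
## prior), the normalized clean target, and the 1-channel conditioning
## image for the discriminator
.preparePair <- function(pair) {
  degNorm <- percentileNormalize(pair$degraded, 99)@data
  tgtNorm <- percentileNormalize(pair$clean, 99)@data
  edgeSrc <- if (!is.null(pair$sample)) pair$sample@t1Post else pair$clean
  edge <- cannyEdgeVolume(edgeSrc)@data
  d <- dim(degNorm)
  list(input = array(c(degNorm, edge), c(d, 2L)),
       target = array(tgtNorm, c(d, 1L)),
       cond = array(degNorm, c(d, 1L)))
}

.paramChecksum <- function(params)
  vapply(params, function(p) sum(p) + sum(p^2), 1)

#' Train one curriculum stage
#'
#' Alternating Adam optimization of discriminator and generator on paired
#' (degraded, clean) volumes. The discriminator judges (conditioning image,
#' candidate) channel pairs; the generator sees (degraded image, anatomical
#' edge prior) and minimizes binary cross-entropy against the real label
#' plus weighted L1 reconstruction. With \code{stage@init == "previous"}
#' the incoming bundle's weights are the starting point (the transfer
#' hand-off); with \code{"fresh"} weights are re-initialized from the seed.
#'
#' @param bundleIn a \linkS4class{ModelBundle}
#' @param stage a \linkS4class{CurriculumStage}
#' @param data non-empty list of pairs as produced by
#'   [makeTrainingPairs()] (elements \code{degraded}, \code{clean},
#'   optionally \code{sample})
#' @param seed stage seed (shuffling; also re-initialization when fresh)
#' @return updated \linkS4class{ModelBundle} with appended provenance
#'   (including the per-epoch loss history)
#' @export
trainStage <- function(bundleIn, stage, data, seed = 1L) {
  validObject(stage)
  if (!length(data)) .paramError("training data must be non-empty")
  bundle <- bundleIn
  if (stage@init == "fresh") {
    bundle@generator <- buildGenerator(bundle@generator$config,
                                       deriveSeed(seed, 1L))
    bundle@discriminator <- buildDiscriminator(
      bundle@discriminator$config, deriveSeed(seed, 2L))
  }
  lossCfg <- bundle@lossConfig
  prep <- lapply(data, .preparePair)
  G <- .paramNodes(bundle@generator$params)
  Dn <- .paramNodes(bundle@discriminator$params)
  gen <- bundle@generator
  disc <- bundle@discriminator
  stateG <- adamState(bundle@generator$params)
  stateD <- adamState(bundle@discriminator$params)
  lr <- stage@learningRate
  history <- data.frame(epoch = integer(), g_total = numeric(),
                        g_adv = numeric(), g_rec = numeric(),
                        d_loss = numeric())
  set.seed(deriveSeed(seed, 33L))
  for (ep in seq_len(stage@epochs)) {
    ord <- sample(length(prep))
    el <- c(g_total = 0, g_adv = 0, g_rec = 0, d_loss = 0)
    for (i in ord) {
      pr <- prep[[i]]
      # discriminator step (generator output detached)
      fake <- generatorForward(gen, pr$input, NULL, paramNodes = G)$value
      d4 <- dim(pr$cond)
      tape <- adTape()
      lgR <- discriminatorForward(disc,
        array(c(pr$cond, pr$target), c(d4[1:3], 2L)), tape, paramNodes = Dn)
      lgF <- discriminatorForward(disc,
        array(c(pr$cond, fake), c(d4[1:3], 2L)), tape, paramNodes = Dn)
      lossD <- adAxpy(tape, 0.5, adBCEWithLogits(tape, lgR, 1), 0.5,
                      adBCEWithLogits(tape, lgF, 0))
      adBackward(tape, lossD)
      stateD <- adamStep(Dn, stateD, lr)
      .zeroGrads(Dn); .zeroGrads(G)
      # generator step (discriminator frozen: grads discarded)
      tape <- adTape()
      fakeN <- generatorForward(gen, pr$input, tape, paramNodes = G)
      condN <- adNode(pr$cond)
      lgG <- discriminatorForward(disc, adConcat(tape, condN, fakeN), tape,
                                  paramNodes = Dn)
      adv <- adBCEWithLogits(tape, lgG, 1)
      rec <- adL1Loss(tape, fakeN, pr$target)
      lossG <- adAxpy(tape, lossCfg@advWeight, adv, lossCfg@recWeight, rec)
      adBackward(tape, lossG)
      stateG <- adamStep(G, stateG, lr)
      .zeroGrads(Dn); .zeroGrads(G)
      el <- el + c(lossG$value, adv$value, rec$value, lossD$value)
    }
    el <- el / length(prep)
    history <- rbind(history,
                     data.frame(epoch = ep, g_total = el[["g_total"]],
                                g_adv = el[["g_adv"]],
                                g_rec = el[["g_rec"]],
                                d_loss = el[["d_loss"]]))
    if (any(!is.finite(unlist(el))))
      .domainError("non-finite loss at epoch %d; lower the learning rate",
                   ep)
  }
  bundle@generator$params <- .paramValues(G)
  bundle@discriminator$params <- .paramValues(Dn)
  bundle@provenance <- c(bundle@provenance, list(list(
    name = stage@name, artifactStages = stage@artifactStages,
    epochs = stage@epochs, learningRate = lr, init = stage@init,
    seed = as.integer(seed), nPairs = length(data), history = history)))
  bundle
}

#' Run a stacked transfer-learning curriculum
#'
#' Chains [trainStage()] over an ordered list of stages of non-decreasing
#' artifact complexity; after the first stage every stage starts from the
#' previous stage's weights.
#'
#' @param stages ordered list of \linkS4class{CurriculumStage}; artifact
#'   stage-set cardinality must be non-decreasing
#' @param dataSampler function(stage, seed) returning the training pairs
#'   for that stage (e.g. wrapping [makeTrainingPairs()])
#' @param seed global seed; per-stage seeds are derived from it
#' @param bundle starting \linkS4class{ModelBundle}; fresh by default
#' @return trained \linkS4class{ModelBundle} with full provenance
#' @export
runCurriculum <- function(stages, dataSampler, seed = 1L,
                          bundle = newModelBundle(seed = seed)) {
  card <- vapply(stages, function(s) length(s@artifactStages), 1L)
  if (any(diff(card) < 0))
    .paramError("curriculum stages must be of non-decreasing complexity")
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (i == 1L && st@init == "previous" && !length(bundle@provenance))
      st@init <- "fresh"
    if (i > 1L) st@init <- "previous"
    data <- dataSampler(st, deriveSeed(seed, 1000L + i))
    bundle <- trainStage(bundle, st, data, seed = deriveSeed(seed, i))
  }
  bundle
}

#' Save a ModelBundle to a directory
#'
#' Weights are serialized as RDS; configurations and provenance go to a
#' JSON sidecar so a curriculum hand-off is reproducible and inspectable.
#'
#' @param bundle a \linkS4class{ModelBundle}
#' @param dir output directory (created if missing)
#' @return dir, invisibly
#' @export
saveModelBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle@generator$params, file.path(dir, "generator.rds"))
  saveRDS(bundle@discriminator$params, file.path(dir, "discriminator.rds"))
  gc <- bundle@generator$config
  dc <- bundle@discriminator$config
  side <- list(
    generator = list(inChannels = gc@inChannels,
                     outChannels = gc@outChannels, depth = gc@depth,
                     baseWidth = gc@baseWidth, recurrence = gc@recurrence,
                     attention = gc@attention),
    discriminator = list(nLayers = dc@nLayers, kernel = dc@kernel,
                         stride = dc@stride, padding = dc@padding,
                         baseWidth = dc@baseWidth,
                         inChannels = dc@inChannels),
    loss = list(advWeight = bundle@lossConfig@advWeight,
                recWeight = bundle@lossConfig@recWeight),
    seed = bundle@seed,
    provenance = lapply(bundle@provenance, function(p)
      p[setdiff(names(p), "history")]))
  jsonlite::write_json(side, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(bundle@provenance)) {
    h <- bundle@provenance[[i]]$history
    if (!is.null(h))
      utils::write.csv(h, file.path(dir, sprintf("loss_stage%02d.csv", i)),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Load a ModelBundle saved by [saveModelBundle()]
#'
#' @param dir bundle directory
#' @return a \linkS4class{ModelBundle}
#' @export
loadModelBundle <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = FALSE)
  g <- lapply(side$generator, unlist)
  d <- lapply(side$discriminator, unlist)
  bundle <- new("ModelBundle",
    generator = list(config = GeneratorConfig(g$inChannels, g$outChannels,
                                              g$depth, g$baseWidth,
                                              g$recurrence, g$attention),
                     params = readRDS(file.path(dir, "generator.rds"))),
    discriminator = list(config = DiscriminatorConfig(d$nLayers, d$kernel,
                                                      d$stride, d$padding,
                                                      d$baseWidth,
                                                      d$inChannels),
                         params = readRDS(file.path(dir,
                                                    "discriminator.rds"))),
    lossConfig = LossConfig(side$loss$advWeight, side$loss$recWeight),
    provenance = lapply(side$provenance, function(p)
      lapply(p, function(x) if (length(x) > 1L) unlist(x) else x[[1]])),
    seed = as.integer(side$seed))
  bundle
}
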