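## Generator: attention recurrent-residual U-Net (R2 conv blocks at every
## level, attention gates on skip connections). Discriminator: 3D PatchGAN.
## Parameters live in flat named lists of arrays; forward passes build an
## autodiff graph on a tape (or run gradient-free with tape = NULL).

.genWidths <- function(config)
  config@baseWidth * 2L^(seq_len(config@depth) - 1L)

## parameter shapes of one R2 block: 1x1 shortcut + two shared-weight
## recurrent 3x3x3 conv units
.r2ParamShapes <- function(cin, cout)
  list(sc_w = c(1, 1, 1, cin, cout), sc_b = cout,
       rc1_w = c(3, 3, 3, cout, cout), rc1_b = cout,
       rc2_w = c(3, 3, 3, cout, cout), rc2_b = cout)

.attParamShapes <- function(cg, cx) {
  fint <- max(1L, cx %/% 2L)
  list(wg_w = c(1, 1, 1, cg, fint), wg_b = fint,
       wx_w = c(1, 1, 1, cx, fint), wx_b = fint,
       psi_w = c(1, 1, 1, fint, 1), psi_b = 1)
}

.generatorParamShapes <- function(config) {
  w <- .genWidths(config)
  D <- config@depth
  shapes <- list()
  addBlock <- function(prefix, sh) {
    names(sh) <- paste0(prefix, "_", names(sh))
    shapes[names(sh)] <<- sh
  }
  cin <- config@inChannels
  for (l in seq_len(max(D - 1L, 0L))) {
    addBlock(sprintf("enc%d", l), .r2ParamShapes(cin, w[l]))
    cin <- w[l]
  }
  addBlock("bot", .r2ParamShapes(cin, w[D]))
  if (D > 1L) for (l in seq(D - 1L, 1L)) {
    if (config@attention)
      addBlock(sprintf("att%d", l), .attParamShapes(w[l + 1L], w[l]))
    addBlock(sprintf("dec%d", l), .r2ParamShapes(w[l + 1L] + w[l], w[l]))
  }
  shapes[["out_w"]] <- c(1, 1, 1, w[1], config@outChannels)
  shapes[["out_b"]] <- config@outChannels
  shapes
}

.initParams <- function(shapes, seed) {
  set.seed(as.integer(seed))
  out <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    # biases start at zero; the generator's final projection starts at
    # zero too, so training begins from a neutral output instead of a
    # large random one (stabilizes the heavily L1-weighted objective)
    out[[nm]] <- if (length(sh) == 1L || nm == "out_w") array(0, sh)
                 else .initConvW(sh)
  }
  out
}

#' Build an attention recurrent-residual U-Net generator
#'
#' Encoder-decoder with recurrent-residual convolution (R2) blocks at every
#' resolution level and attention gates on the skip connections. The
#' network is shape-preserving: a 2-channel 256 x 256 x 16 input yields a
#' 1-channel 256 x 256 x 16 output (super-resolution enters through the
#' grid, before the network). Weight initialization is deterministic given
#' the seed.
#'
#' @param config a \linkS4class{GeneratorConfig}
#' @param seed initialization seed
#' @return list with elements \code{config} and \code{params} (named list
#'   of weight arrays)
#' @seealso [generatorForward()], [buildDiscriminator()]
#' @export
buildGenerator <- function(config = GeneratorConfig(), seed = 1L) {
  validObject(config)
  list(config = config, params = .initParams(.generatorParamShapes(config),
                                             seed))
}

## recurrent conv unit with shared weights: t applications of
## h <- relu(conv(z + h)), seeded by h <- relu(conv(z))
.rclForward <- function(tape, z, w, b, t) {
  h <- adRelu(tape, adConv3d(tape, z, w, b))
  if (t > 1L) for (i in seq_len(t - 1L))
    h <- adRelu(tape, adConv3d(tape, adAdd(tape, z, h), w, b))
  h
}

.r2Forward <- function(tape, x, P, prefix, t) {
  g <- function(nm) P[[paste0(prefix, "_", nm)]]
  x0 <- adConv3d(tape, x, g("sc_w"), g("sc_b"), padding = c(0L, 0L, 0L))
  u <- .rclForward(tape, x0, g("rc1_w"), g("rc1_b"), t)
  u <- .rclForward(tape, u, g("rc2_w"), g("rc2_b"), t)
  adAdd(tape, x0, u)
}

.attForward <- function(tape, gsig, x, P, prefix) {
  g <- function(nm) P[[paste0(prefix, "_", nm)]]
  a <- adAdd(tape,
             adConv3d(tape, gsig, g("wg_w"), g("wg_b"),
                      padding = c(0L, 0L, 0L)),
             adConv3d(tape, x, g("wx_w"), g("wx_b"),
                      padding = c(0L, 0L, 0L)))
  alpha <- adSigmoid(tape, adConv3d(tape, adRelu(tape, a), g("psi_w"),
                                    g("psi_b"), padding = c(0L, 0L, 0L)))
  list(gated = adGateMul(tape, x, alpha), alpha = alpha)
}

#' Run the generator forward
#'
#' @param generator a generator built by [buildGenerator()]
#' @param x 4D input array (x, y, z, channel); spatial extents must be
#'   divisible by 2^(depth - 1)
#' @param tape autodiff tape, or NULL for a gradient-free pass
#' @param paramNodes optional list of parameter nodes (used by the training
#'   loop); defaults to constant nodes around \code{generator$params}
#' @param returnGates if TRUE, attach the attention-gate activation arrays
#'   as attribute "gates" to the result
#' @return output node; \code{$value} is the (x, y, z, outChannels) array
#' @export
generatorForward <- function(generator, x, tape = NULL, paramNodes = NULL,
                             returnGates = FALSE) {
  config <- generator$config
  D <- config@depth
  d <- dim(x)
  if (length(d) != 4L || d[4] != config@inChannels)
    .shapeError("input must be (x, y, z, %d)", config@inChannels)
  div <- 2L^(D - 1L)
  if (any(d[1:3] %% div != 0L))
    .shapeError("spatial extents %s must be divisible by %d",
                paste(d[1:3], collapse = "x"), div)
  P <- if (is.null(paramNodes)) .paramNodes(generator$params) else paramNodes
  t <- config@recurrence
  h <- adNode(x)
  skips <- vector("list", max(D - 1L, 0L))
  for (l in seq_len(max(D - 1L, 0L))) {
    skips[[l]] <- .r2Forward(tape, h, P, sprintf("enc%d", l), t)
    h <- adMaxPool2(tape, skips[[l]])
  }
  h <- .r2Forward(tape, h, P, "bot", t)
  gates <- list()
  if (D > 1L) for (l in seq(D - 1L, 1L)) {
    up <- adUpsample2(tape, h)
    sk <- skips[[l]]
    if (config@attention) {
      at <- .attForward(tape, up, sk, P, sprintf("att%d", l))
      sk <- at$gated
      gates[[sprintf("att%d", l)]] <- at$alpha$value
    }
    h <- .r2Forward(tape, adConcat(tape, up, sk), P, sprintf("dec%d", l), t)
  }
  out <- adConv3d(tape, h, P[["out_w"]], P[["out_b"]],
                  padding = c(0L, 0L, 0L))
  if (returnGates) attr(out, "gates") <- gates
  out
}

.discParamShapes <- function(config) {
  shapes <- list()
  cin <- config@inChannels
  for (i in seq_len(config@nLayers)) {
    cout <- if (i == config@nLayers) 1L
            else config@baseWidth * 2L^(i - 1L)
    shapes[[sprintf("l%d_w", i)]] <- c(config@kernel, cin, cout)
    shapes[[sprintf("l%d_b", i)]] <- cout
    cin <- cout
  }
  shapes
}

#' Build a 3D PatchGAN discriminator
#'
#' A stack of strided 3D convolutions (defaults: 4 layers, 3 x 3 x 3
#' kernels, stride 2, padding 1) mapping a conditioned input volume to a
#' grid of patch logits; each logit judges one receptive-field patch. With
#' the default geometry each spatial extent shrinks by about 2^4, so a
#' 256 x 256 x 16 input yields a 16 x 16 x 1 logit grid.
#'
#' @param config a \linkS4class{DiscriminatorConfig}
#' @param seed initialization seed
#' @return list with elements \code{config} and \code{params}
#' @export
buildDiscriminator <- function(config = DiscriminatorConfig(), seed = 1L) {
  validObject(config)
  list(config = config, params = .initParams(.discParamShapes(config), seed))
}

#' Run the discriminator forward
#'
#' @param discriminator built by [buildDiscriminator()]
#' @param x 4D input array or node (x, y, z, inChannels)
#' @param tape autodiff tape or NULL
#' @param paramNodes optional parameter node list
#' @return output node; \code{$value} holds the patch logit grid
#' @export
discriminatorForward <- function(discriminator, x, tape = NULL,
                                 paramNodes = NULL) {
  config <- discriminator$config
  P <- if (is.null(paramNodes)) .paramNodes(discriminator$params)
       else paramNodes
  h <- if (is.environment(x)) x else adNode(x)
  d <- dim(h$value)
  if (any(d[1:3] < 1L)) .shapeError("input smaller than one patch")
  for (i in seq_len(config@nLayers)) {
    o <- (d[1:3] + 2L * config@padding - config@kernel) %/% config@stride + 1L
    if (any(o < 1L))
      .shapeError("input extent %s too small for %d stride-%d layers",
                  paste(dim(h$value)[1:3], collapse = "x"), config@nLayers,
                  config@stride[1])
    h <- adConv3d(tape, h, P[[sprintf("l%d_w", i)]],
                  P[[sprintf("l%d_b", i)]], stride = config@stride,
                  padding = config@padding)
    d <- dim(h$value)
    if (i < config@nLayers) h <- adLeakyRelu(tape, h, 0.2)
  }
  h
}

#' Closed-form receptive field of the patch discriminator
#'
#' Per axis, the theoretical receptive field grows as
#' \code{RF_n = RF_(n-1) + (k - 1) * prod(strides of layers below)}; the
#' effective extent is this value clipped to the input extent. For the
#' default configuration (4 layers, kernel 3, stride 2) the theoretical
#' extent is 31 per axis, and a 16-slice input clips the through-plane
#' extent to an effective 31 x 31 x 16.
#'
#' @param config a \linkS4class{DiscriminatorConfig}
#' @param inputExtent integer(3) input extent per axis (used for clipping);
#'   NULL for the unclipped theoretical extent
#' @return integer(3) effective receptive-field extent per axis
#' @examples
#' receptiveField(DiscriminatorConfig(), c(256, 256, 16))
#' @export
receptiveField <- function(config = DiscriminatorConfig(),
                           inputExtent = NULL) {
  rf <- c(1, 1, 1)
  jump <- c(1, 1, 1)
  for (i in seq_len(config@nLayers)) {
    rf <- rf + (config@kernel - 1) * jump
    jump <- jump * config@stride
  }
  rf <- as.integer(rf)
  if (!is.null(inputExtent))
    rf <- pmin(rf, as.integer(rep_len(inputExtent, 3L)))
  rf
}

#' Measure the receptive field by gradient support
#'
#' Instantiates the discriminator, runs a central output unit's gradient
#' back to the input, and reports the per-axis extent of the set of input
#' voxels with nonzero sensitivity. This is the brute-force cross-check of
#' [receptiveField()].
#'
#' @param config a \linkS4class{DiscriminatorConfig}
#' @param inputExtent integer(3) input extent per axis
#' @param seed weight initialization seed
#' @return integer(3) measured support extent per axis
#' @export
receptiveFieldOracle <- function(config, inputExtent, seed = 1L) {
  disc <- buildDiscriminator(config, seed = seed)
  inputExtent <- as.integer(rep_len(inputExtent, 3L))
  set.seed(as.integer(seed))
  xval <- array(runif(prod(inputExtent) * config@inChannels, 0.25, 1),
                c(inputExtent, config@inChannels))
  support <- function(unit) {
    tape <- adTape()
    x <- adNode(xval, requiresGrad = TRUE)
    logits <- discriminatorForward(disc, x, tape)
    sel <- array(0, dim(logits$value))
    sel[unit[1], unit[2], unit[3], 1] <- 1
    logits$grad <- sel
    for (i in rev(seq_len(tape$n))) tape$ops[[i]]()
    g <- abs(x$grad) > 0
    vapply(1:3, function(ax) {
      on <- which(apply(g, ax, any))
      if (!length(on)) 0L else as.integer(diff(range(on)) + 1L)
    }, 1L)
  }
  # an even logit grid has no exactly centred unit, and off-centre units
  # lose part of their field to the boundary: take the per-axis maximum
  # over the units nearest the centre
  probe <- discriminatorForward(disc, xval, NULL)
  od <- dim(probe$value)[1:3]
  cand <- lapply(od, function(n)
    unique(pmin(pmax(c(n %/% 2L, n %/% 2L + 1L), 1L), n)))
  ext <- c(0L, 0L, 0L)
  for (ux in cand[[1]]) for (uy in cand[[2]]) for (uz in cand[[3]])
    ext <- pmax(ext, support(c(ux, uy, uz)))
  ext
}

#' Generator losses: adversarial + weighted L1 reconstruction
#'
#' \code{total = advWeight * BCE(discLogitsFake, real-label) +
#' recWeight * mean(|generated - target|)}; binary cross-entropy is
#' computed from logits. The default 1:200 adversarial:reconstruction
#' weighting follows the published training objective.
#'
#' @param generated,target numeric arrays of one shape
#' @param discLogitsFake discriminator patch logits for the generated
#'   volume
#' @param lossConfig a \linkS4class{LossConfig}
#' @return list(total, adversarial, reconstruction)
#' @export
computeLosses <- function(generated, target, discLogitsFake,
                          lossConfig = LossConfig()) {
  if (!identical(dim(generated), dim(target)))
    .shapeError("generated and target must share one shape")
  z <- as.numeric(discLogitsFake)
  adv <- mean(pmax(z, 0) - z + log1p(exp(-abs(z))))
  rec <- mean(abs(generated - target))
  list(total = lossConfig@advWeight * adv + lossConfig@recWeight * rec,
       adversarial = adv, reconstruction = rec)
}
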