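#' ImageVolume: a 3D scalar field with voxel geometry
#'
#' The universal data container of the package: a 3D array of non-negative
#' signal values together with its voxel spacing (mm) and physical origin
#' (mm). Voxel indices are 0-based in physical terms: the centre of voxel
#' \code{(i, j, k)} (R index \code{i+1, j+1, k+1}) sits at
#' \code{origin + c(i, j, k) * spacing}. Axis order is fixed as (x, y, z)
#' with z the slice axis; no orientation matrix beyond this convention is
#' carried.
#'
#' @slot data 3D numeric array, finite values
#' @slot spacing numeric(3), strictly positive voxel size in mm
#' @slot origin numeric(3), physical position of the first voxel centre in mm
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must not contain NaN or Inf")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic)
#' @param origin numeric(3) physical origin in mm (default 0)
#' @return an \linkS4class{ImageVolume}
#' @examples
#' v <- ImageVolume(array(1, c(4, 4, 2)), spacing = c(2, 2, 5))
#' dim(v)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' MaskVolume: a binary compartment mask on a volume grid
#'
#' A binary (0/1) field on the same grid conventions as
#' \linkS4class{ImageVolume}, carrying the compartment label it delineates.
#' Recognised labels follow the tumor-compartment vocabulary: contrast
#' enhancing tumor (\code{CET}), \code{necrosis}, \code{T2hyper},
#' normal-appearing white matter (\code{NAWM}), \code{eye_left},
#' \code{eye_right}, \code{fat} and \code{brain}.
#'
#' @slot label character(1) compartment label
#' @export
setClass("MaskVolume", contains = "ImageVolume",
  representation(label = "character"), prototype(label = "brain"))

.maskLabels <- c("CET", "necrosis", "T2hyper", "NAWM",
                 "eye_left", "eye_right", "fat", "brain")

setValidity("MaskVolume", function(object) {
  msg <- character()
  if (!all(object@data %in% c(0, 1)))
    msg <- c(msg, "mask values must all be 0 or 1")
  if (length(object@label) != 1L || !object@label %in% .maskLabels)
    msg <- c(msg, paste("label must be one of:",
                        paste(.maskLabels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MaskVolume
#'
#' @param data 3D array of 0/1 values (logical arrays are coerced)
#' @param label compartment label, one of CET, necrosis, T2hyper, NAWM,
#'   eye_left, eye_right, fat, brain
#' @inheritParams ImageVolume
#' @return a \linkS4class{MaskVolume}
#' @export
MaskVolume <- function(data, label, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("MaskVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label)
}

#' @rdname volData
#' @export
setMethod("volData", "ImageVolume", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname volOrigin
#' @export
setMethod("volOrigin", "ImageVolume", function(x) x@origin)

#' @rdname maskLabel
#' @export
setMethod("maskLabel", "MaskVolume", function(x) x@label)

#' @describeIn ImageVolume grid dimensions (voxels per axis)
#' @param x an ImageVolume
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (is(object, "MaskVolume"))
    cat(sprintf("  label: %s (%d voxels set)\n", object@label,
                sum(object@data != 0)))
  invisible(NULL)
})

#' DegradationConfig: parameters of the physics-based degradation chain
#'
#' Collects the parameters of the five artifact families applied to clean
#' volumes when building paired training data: B0 susceptibility-driven
#' geometric distortion, chemical shift of the fat component (430 Hz
#' fat-water offset at 3T), Nyquist (N/2) ghosting from alternating k-space
#' line modulation, Gibbs ringing / downsampling by k-space truncation, and
#' Rician magnitude noise.
#'
#' @slot fatWaterShiftHz fat-water frequency offset in Hz (430 at 3T)
#' @slot bandwidthHzPerPx per-voxel readout bandwidth in Hz/pixel
#' @slot peAxis phase-encode axis index (1, 2 or 3)
#' @slot fieldMap off-resonance field in Hz as an \linkS4class{ImageVolume},
#'   or NULL for none
#' @slot ghostPhaseRad phase applied to alternating k-space lines (rad)
#' @slot ghostGain gain applied to alternating k-space lines
#' @slot truncationFraction fraction of k-space kept per axis, in (0, 1]
#' @slot downsampleFactor grid reduction factor per axis, >= 1
#' @slot ricianSigma noise scale in signal units, >= 0
#' @slot seed RNG seed controlling the noise draw
#' @export
setClass("DegradationConfig",
  representation(fatWaterShiftHz = "numeric", bandwidthHzPerPx = "numeric",
                 peAxis = "integer", fieldMap = "ANY",
                 ghostPhaseRad = "numeric", ghostGain = "numeric",
                 truncationFraction = "numeric", downsampleFactor = "numeric",
                 ricianSigma = "numeric", seed = "integer"),
  prototype(fatWaterShiftHz = 430, bandwidthHzPerPx = 80, peAxis = 2L,
            fieldMap = NULL, ghostPhaseRad = 0.2, ghostGain = 1,
            truncationFraction = c(1, 1, 1), downsampleFactor = c(1, 1, 1),
            ricianSigma = 0, seed = 1L))

setValidity("DegradationConfig", function(object) {
  msg <- character()
  if (any(object@truncationFraction <= 0) ||
      any(object@truncationFraction > 1))
    msg <- c(msg, "truncationFraction must lie in (0, 1]")
  if (any(object@downsampleFactor < 1))
    msg <- c(msg, "downsampleFactor must be >= 1")
  if (object@ricianSigma < 0)
    msg <- c(msg, "ricianSigma must be >= 0")
  if (!object@peAxis %in% 1:3)
    msg <- c(msg, "peAxis must be 1, 2 or 3")
  if (!is.null(object@fieldMap) && !is(object@fieldMap, "ImageVolume"))
    msg <- c(msg, "fieldMap must be NULL or an ImageVolume")
  if (length(msg)) msg else TRUE
})

#' Construct a DegradationConfig
#'
#' @param fatWaterShiftHz fat-water offset (Hz); 430 Hz at 3T
#' @param bandwidthHzPerPx readout bandwidth (Hz/pixel); the sodium
#'   acquisition this simulator emulates used 80 Hz/pixel
#' @param peAxis phase-encode axis (1-3)
#' @param fieldMap off-resonance field (ImageVolume, Hz) or NULL
#' @param ghostPhaseRad,ghostGain alternating-line modulation parameters
#' @param truncationFraction kept central k-space fraction per axis
#' @param downsampleFactor per-axis grid reduction factor (>= 1)
#' @param ricianSigma Rician noise scale (signal units)
#' @param seed RNG seed for the noise stage
#' @return a \linkS4class{DegradationConfig}
#' @export
DegradationConfig <- function(fatWaterShiftHz = 430, bandwidthHzPerPx = 80,
                              peAxis = 2L, fieldMap = NULL,
                              ghostPhaseRad = 0.2, ghostGain = 1,
                              truncationFraction = c(1, 1, 1),
                              downsampleFactor = c(1, 1, 1),
                              ricianSigma = 0, seed = 1L) {
  new("DegradationConfig", fatWaterShiftHz = fatWaterShiftHz,
      bandwidthHzPerPx = bandwidthHzPerPx, peAxis = as.integer(peAxis),
      fieldMap = fieldMap, ghostPhaseRad = ghostPhaseRad,
      ghostGain = ghostGain,
      truncationFraction = rep_len(truncationFraction, 3L),
      downsampleFactor = rep_len(downsampleFactor, 3L),
      ricianSigma = ricianSigma, seed = as.integer(seed))
}

#' PhantomSpec: parameters of the digital head-and-tumor phantom
#'
#' Describes a parametric head phantom with nested tumor compartments
#' (necrosis inside contrast-enhancing tumor inside T2-hyperintense lesion),
#' a normal-appearing white matter reference region, two vitreous (eye)
#' spheres, and a scalp fat ring, imaged in two channels: a sodium channel
#' and a post-contrast T1-weighted-like anatomical channel. All geometry is
#' given in mm relative to the grid centre.
#'
#' @slot shape integer(3) high-resolution grid size (voxels)
#' @slot spacing numeric(3) high-resolution voxel size (mm)
#' @slot lesionCenter numeric(3) lesion centre offset from grid centre (mm)
#' @slot lesionRadii numeric(3) radii (mm) of the T2hyper, CET and necrosis
#'   spheres (strictly decreasing)
#' @slot sodiumMeans named numeric: sodium signal means for background,
#'   brain, t2hyper, cet, necrosis, eye, fat; NA lesion entries default to
#'   sodiumLesionRatio times the brain mean
#' @slot t1Means named numeric: anatomical-channel means, same names
#' @slot sodiumLesionRatio lesion:NAWM sodium ratio used for NA lesion means
#' @slot eyeDiameterMm eye VOI sphere diameter (mm); 5 mm as used clinically
#' @slot ricianSigma noise scale applied to the low-resolution acquisition
#' @slot loResSpacing numeric(3) native sodium voxel size (mm); default
#'   5.5 mm isotropic, matching the clinical sodium acquisition
#' @slot seed RNG seed
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 lesionCenter = "numeric", lesionRadii = "numeric",
                 sodiumMeans = "numeric", t1Means = "numeric",
                 sodiumLesionRatio = "numeric", eyeDiameterMm = "numeric",
                 ricianSigma = "numeric", loResSpacing = "numeric",
                 seed = "integer"))

.compartmentNames <- c("background", "brain", "t2hyper", "cet", "necrosis",
                       "eye", "fat")

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be 3 integers >= 8")
  if (any(object@spacing <= 0) || any(object@loResSpacing <= 0))
    msg <- c(msg, "spacings must be positive")
  if (length(object@lesionRadii) != 3L ||
      any(diff(object@lesionRadii) >= 0) || any(object@lesionRadii <= 0))
    msg <- c(msg, "lesionRadii must be 3 strictly decreasing positive radii (T2hyper > CET > necrosis)")
  for (nm in list(object@sodiumMeans, object@t1Means))
    if (!all(.compartmentNames %in% names(nm)))
      msg <- c(msg, "signal means must be named for all compartments")
  pos <- object@sodiumMeans[setdiff(.compartmentNames, "background")]
  if (any(!is.na(pos) & pos <= 0))
    msg <- c(msg, "tissue signal means must be positive")
  ext <- object@shape * object@spacing
  if (any(abs(object@lesionCenter) + object@lesionRadii[1] > ext / 2))
    msg <- c(msg, "lesion extends outside the field of view")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults give a 64 x 64 x 48 voxel, 1 mm isotropic grid holding a scaled
#' head with a 10/6/3 mm nested lesion, 5 mm eyes, a scalp fat ring, brain
#' (NAWM) sodium 100 (arbitrary units) and a lesion:NAWM sodium ratio of
#' 1.4. The lesion compartments share one sodium mean by default so that the
#' whole-lesion to NAWM ratio equals \code{sodiumLesionRatio} exactly;
#' compartment identity is carried by the anatomical channel (enhancing rim
#' bright, necrotic core dark).
#'
#' @param shape,spacing high-resolution grid (voxels, mm)
#' @param lesionCenter lesion centre offset from grid centre (mm)
#' @param lesionRadii radii (mm) of T2hyper, CET, necrosis spheres
#' @param sodiumMeans,t1Means named per-compartment signal means; NA sodium
#'   lesion entries are filled from \code{sodiumLesionRatio}
#' @param sodiumLesionRatio lesion:NAWM sodium ratio (default 1.4)
#' @param eyeDiameterMm eye sphere diameter in mm (default 5)
#' @param ricianSigma noise scale for the simulated low-res acquisition
#' @param loResSpacing native sodium spacing in mm (default 5.5 isotropic)
#' @param seed RNG seed
#' @return a \linkS4class{PhantomSpec}
#' @export
PhantomSpec <- function(shape = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                        lesionCenter = c(12, 4, 2),
                        lesionRadii = c(10, 6, 3),
                        sodiumMeans = c(background = 0, brain = 100,
                                        t2hyper = NA, cet = NA,
                                        necrosis = NA, eye = 250, fat = 30),
                        t1Means = c(background = 0, brain = 100,
                                    t2hyper = 130, cet = 200, necrosis = 40,
                                    eye = 20, fat = 220),
                        sodiumLesionRatio = 1.4, eyeDiameterMm = 5,
                        ricianSigma = 2, loResSpacing = c(5.5, 5.5, 5.5),
                        seed = 1L) {
  na <- is.na(sodiumMeans[c("t2hyper", "cet", "necrosis")])
  sodiumMeans[c("t2hyper", "cet", "necrosis")[na]] <-
    sodiumLesionRatio * sodiumMeans[["brain"]]
  new("PhantomSpec", shape = as.integer(shape),
      spacing = as.numeric(spacing), lesionCenter = as.numeric(lesionCenter),
      lesionRadii = as.numeric(lesionRadii), sodiumMeans = sodiumMeans,
      t1Means = t1Means, sodiumLesionRatio = sodiumLesionRatio,
      eyeDiameterMm = eyeDiameterMm, ricianSigma = ricianSigma,
      loResSpacing = rep_len(as.numeric(loResSpacing), 3L),
      seed = as.integer(seed))
}

#' PhantomSample: one generated phantom with paired acquisitions and masks
#'
#' @slot hiResSodium noiseless high-resolution sodium volume (ground truth)
#' @slot loResSodium simulated native low-resolution sodium acquisition
#'   (k-space downsampling to the native grid plus Rician noise)
#' @slot t1Post post-contrast T1-weighted-like anatomical volume (hi-res grid)
#' @slot masks named list of \linkS4class{MaskVolume} on the hi-res grid:
#'   CET, necrosis, T2hyper, NAWM, eye_left, eye_right, fat, brain
#' @slot spec the generating \linkS4class{PhantomSpec}
#' @export
setClass("PhantomSample",
  representation(hiResSodium = "ImageVolume", loResSodium = "ImageVolume",
                 t1Post = "ImageVolume", masks = "list",
                 spec = "PhantomSpec"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  if (!all(vapply(object@masks, is, TRUE, "MaskVolume")))
    msg <- c(msg, "masks must all be MaskVolume objects")
  need <- c("CET", "necrosis", "T2hyper", "NAWM", "eye_left", "eye_right",
            "fat", "brain")
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, paste("masks must include:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSample", function(object) {
  cat("PhantomSample\n  hiResSodium: "); show(object@hiResSodium)
  cat("  loResSodium: "); show(object@loResSodium)
  cat(sprintf("  masks: %s\n", paste(names(object@masks), collapse = ", ")))
  invisible(NULL)
})

#' GeneratorConfig: attention recurrent-residual U-Net generator settings
#'
#' @slot inChannels input channels (2: normalized image + binary edge prior)
#' @slot outChannels output channels (1)
#' @slot depth number of resolution levels (encoder stages + bottleneck)
#' @slot baseWidth feature channels at the finest level; doubles per level
#' @slot recurrence recurrent steps t in each recurrent-residual conv unit
#' @slot attention logical; gate skip connections with attention gates
#' @export
setClass("GeneratorConfig",
  representation(inChannels = "integer", outChannels = "integer",
                 depth = "integer", baseWidth = "integer",
                 recurrence = "integer", attention = "logical"),
  prototype(inChannels = 2L, outChannels = 1L, depth = 3L, baseWidth = 32L,
            recurrence = 2L, attention = TRUE))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@baseWidth < 1L) msg <- c(msg, "baseWidth must be >= 1")
  if (object@recurrence < 1L) msg <- c(msg, "recurrence must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneratorConfig
#'
#' @param inChannels,outChannels channel counts (defaults 2 and 1)
#' @param depth resolution levels; input extents must be divisible by
#'   2^(depth - 1)
#' @param baseWidth feature width at full resolution (default 32)
#' @param recurrence recurrent steps per recurrent-residual unit (default 2)
#' @param attention use attention gates on skip connections (default TRUE)
#' @return a \linkS4class{GeneratorConfig}
#' @export
GeneratorConfig <- function(inChannels = 2L, outChannels = 1L, depth = 3L,
                            baseWidth = 32L, recurrence = 2L,
                            attention = TRUE) {
  new("GeneratorConfig", inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), depth = as.integer(depth),
      baseWidth = as.integer(baseWidth), recurrence = as.integer(recurrence),
      attention = attention)
}

#' DiscriminatorConfig: 3D PatchGAN discriminator settings
#'
#' Four convolutional layers with 3 x 3 x 3 kernels, stride 2 and padding 1
#' reproduce the published patch discriminator geometry, whose theoretical
#' receptive field is 31 voxels per axis (clipped by a 16-slice input to an
#' effective 31 x 31 x 16).
#'
#' @slot nLayers number of stride-s convolutional layers (default 4)
#' @slot kernel integer(3) kernel extent per axis (default 3)
#' @slot stride integer(3) stride per axis (default 2)
#' @slot padding integer(3) zero padding per axis (default 1)
#' @slot baseWidth feature channels after the first layer
#' @slot inChannels input channels (default 2: conditioning image +
#'   candidate output, per conditional PatchGAN practice)
#' @export
setClass("DiscriminatorConfig",
  representation(nLayers = "integer", kernel = "integer", stride = "integer",
                 padding = "integer", baseWidth = "integer",
                 inChannels = "integer"),
  prototype(nLayers = 4L, kernel = c(3L, 3L, 3L), stride = c(2L, 2L, 2L),
            padding = c(1L, 1L, 1L), baseWidth = 32L, inChannels = 2L))

setValidity("DiscriminatorConfig", function(object) {
  msg <- character()
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (any(object@kernel < 1L) || any(object@stride < 1L) ||
      any(object@padding < 0L))
    msg <- c(msg, "kernel/stride must be >= 1 and padding >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DiscriminatorConfig
#'
#' @param nLayers convolutional layers (default 4)
#' @param kernel,stride,padding per-axis geometry (defaults 3, 2, 1)
#' @param baseWidth channels after the first layer (default 32)
#' @param inChannels input channels (default 2)
#' @return a \linkS4class{DiscriminatorConfig}
#' @export
DiscriminatorConfig <- function(nLayers = 4L, kernel = c(3L, 3L, 3L),
                                stride = c(2L, 2L, 2L),
                                padding = c(1L, 1L, 1L), baseWidth = 32L,
                                inChannels = 2L) {
  new("DiscriminatorConfig", nLayers = as.integer(nLayers),
      kernel = rep_len(as.integer(kernel), 3L),
      stride = rep_len(as.integer(stride), 3L),
      padding = rep_len(as.integer(padding), 3L),
      baseWidth = as.integer(baseWidth), inChannels = as.integer(inChannels))
}

#' LossConfig: adversarial / reconstruction loss weighting
#'
#' The generator objective combines binary cross-entropy on the patch
#' discriminator's logits with an L1 reconstruction term at a 1:200
#' adversarial:reconstruction weighting.
#'
#' @slot advWeight adversarial weight (default 1)
#' @slot recWeight L1 reconstruction weight (default 200)
#' @export
setClass("LossConfig",
  representation(advWeight = "numeric", recWeight = "numeric"),
  prototype(advWeight = 1, recWeight = 200))

setValidity("LossConfig", function(object) {
  if (object@advWeight <= 0 || object@recWeight <= 0)
    "loss weights must be strictly positive" else TRUE
})

#' Construct a LossConfig
#' @param advWeight adversarial weight (default 1)
#' @param recWeight reconstruction weight (default 200)
#' @return a \linkS4class{LossConfig}
#' @export
LossConfig <- function(advWeight = 1, recWeight = 200)
  new("LossConfig", advWeight = advWeight, recWeight = recWeight)

#' CurriculumStage: one stage of the stacked transfer-learning curriculum
#'
#' @slot name stage name
#' @slot artifactStages character vector, subset of
#'   \code{c("b0", "chemshift", "ghost", "gibbs_downsample", "rician")} in
#'   canonical order
#' @slot epochs training epochs (default 50)
#' @slot learningRate initial Adam learning rate (default 1e-4)
#' @slot init weight initialization: "fresh" or "previous"
#' @export
setClass("CurriculumStage",
  representation(name = "character", artifactStages = "character",
                 epochs = "integer", learningRate = "numeric",
                 init = "character"),
  prototype(epochs = 50L, learningRate = 1e-4, init = "previous"))

setValidity("CurriculumStage", function(object) {
  msg <- character()
  canon <- c("b0", "chemshift", "ghost", "gibbs_downsample", "rician")
  if (!all(object@artifactStages %in% canon))
    msg <- c(msg, "unknown artifact stage name")
  if (!identical(object@artifactStages,
                 canon[canon %in% object@artifactStages]))
    msg <- c(msg, "artifactStages must be listed in canonical order")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (!object@init %in% c("fresh", "previous"))
    msg <- c(msg, "init must be 'fresh' or 'previous'")
  if (length(msg)) msg else TRUE
})

#' Construct a CurriculumStage
#'
#' @param name stage name
#' @param artifactStages artifact subset in canonical order
#' @param epochs epochs for this stage (default 50)
#' @param learningRate Adam learning rate (default 1e-4)
#' @param init "fresh" or "previous" (transfer from the prior stage)
#' @return a \linkS4class{CurriculumStage}
#' @export
CurriculumStage <- function(name, artifactStages, epochs = 50L,
                            learningRate = 1e-4, init = "previous") {
  new("CurriculumStage", name = name, artifactStages = artifactStages,
      epochs = as.integer(epochs), learningRate = learningRate, init = init)
}

#' ModelBundle: generator + discriminator weights with training provenance
#'
#' The hand-off unit of the stacked transfer-learning curriculum: both
#' networks' parameters, their configurations, and an ordered provenance
#' record of every stage that touched them (name, seed, epochs, final
#' losses).
#'
#' @slot generator list: \code{config} (\linkS4class{GeneratorConfig}) and
#'   \code{params} (named list of weight arrays)
#' @slot discriminator list: \code{config}
#'   (\linkS4class{DiscriminatorConfig}) and \code{params}
#' @slot lossConfig a \linkS4class{LossConfig}
#' @slot provenance list of per-stage records, in training order
#' @slot seed integer seed the bundle was created with
#' @export
setClass("ModelBundle",
  representation(generator = "list", discriminator = "list",
                 lossConfig = "LossConfig", provenance = "list",
                 seed = "integer"))

setMethod("show", "ModelBundle", function(object) {
  np <- function(p) sum(vapply(p, length, 1L))
  cat(sprintf("ModelBundle: generator %d params, discriminator %d params\n",
              np(object@generator$params), np(object@discriminator$params)))
  if (length(object@provenance))
    cat(sprintf("  curriculum: %s\n",
                paste(vapply(object@provenance, `[[`, "", "name"),
                      collapse = " -> ")))
  invisible(NULL)
})
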