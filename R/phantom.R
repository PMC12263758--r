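## Parametric head-and-tumor digital phantom. Geometry is analytic
## (ellipsoids and spheres) so every compartment mean, volume and SNR has a
## closed form that tests can check exactly.

## squared normalized ellipsoid coordinate field: value <= 1 inside
.ellipsoidField <- function(shape, spacing, center, semiAxes) {
  cc <- lapply(1:3, function(ax) {
    x <- (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * spacing[ax]
    (x - center[ax])^2 / semiAxes[ax]^2
  })
  X <- array(rep(cc[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cc[[2]], each = shape[1]), shape[3]), shape)
  Z <- array(rep(cc[[3]], each = shape[1] * shape[2]), shape)
  X + Y + Z
}

.sphereMask <- function(shape, spacing, center, radius)
  .ellipsoidField(shape, spacing, center, rep(radius, 3)) <= 1

#' Generate a head-and-tumor phantom with paired acquisitions
#'
#' Builds the labelled geometry described by a \linkS4class{PhantomSpec}: a
#' head ellipsoid with a scalp fat ring, a brain ellipsoid, two vitreous
#' (eye) spheres, a nested lesion (necrosis inside contrast-enhancing tumor
#' inside T2-hyperintense lesion), and a normal-appearing white matter
#' (NAWM) reference sphere in the contralateral hemisphere. Two noiseless
#' channels are painted from the spec's compartment means (sodium and a
#' post-contrast T1-weighted-like anatomical channel); the native
#' low-resolution sodium acquisition is then simulated by k-space
#' downsampling of the sodium channel to the spec's low-resolution spacing
#' followed by Rician noise.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return a \linkS4class{PhantomSample}
#' @examples
#' ph <- generateHeadPhantom(PhantomSpec(shape = c(32, 32, 16),
#'                                       spacing = c(2, 2, 2)))
#' ph
#' @export
generateHeadPhantom <- function(spec) {
  validObject(spec)
  shape <- spec@shape; sp <- spec@spacing
  ext <- shape * sp
  headAx <- ext / 2 * c(0.92, 0.92, 0.88)
  head <- .ellipsoidField(shape, sp, c(0, 0, 0), headAx) <= 1
  brain <- .ellipsoidField(shape, sp, c(0, 0, 0), headAx * 0.82) <= 1
  fat <- head & !( .ellipsoidField(shape, sp, c(0, 0, 0), headAx * 0.90) <= 1)
  eyeR <- spec@eyeDiameterMm / 2
  eyeOff <- c(headAx[1] * 0.45, -headAx[2] * 0.78, 0)
  eyeL <- .sphereMask(shape, sp, c(-eyeOff[1], eyeOff[2], eyeOff[3]), eyeR)
  eyeRt <- .sphereMask(shape, sp, eyeOff, eyeR)
  t2h <- .sphereMask(shape, sp, spec@lesionCenter, spec@lesionRadii[1]) &
    brain
  cet <- .sphereMask(shape, sp, spec@lesionCenter, spec@lesionRadii[2]) &
    brain
  nec <- .sphereMask(shape, sp, spec@lesionCenter, spec@lesionRadii[3]) &
    brain
  nawmCtr <- c(-spec@lesionCenter[1], spec@lesionCenter[2:3])
  nawmR <- min(spec@lesionRadii[2], 6)
  nawm <- .sphereMask(shape, sp, nawmCtr, nawmR) & brain & !t2h
  if (any(t2h & (eyeL | eyeRt)))
    .paramError("lesion intersects an eye; adjust lesionCenter/lesionRadii")
  if (!any(nawm))
    .paramError("NAWM reference region is empty for this geometry")

  paint <- function(means) {
    a <- array(means[["background"]], shape)
    a[head] <- means[["fat"]]          # scalp ring fills head minus brain
    a[brain] <- means[["brain"]]
    a[t2h] <- means[["t2hyper"]]
    a[cet] <- means[["cet"]]
    a[nec] <- means[["necrosis"]]
    a[eyeL | eyeRt] <- means[["eye"]]
    a
  }
  sodium <- ImageVolume(paint(spec@sodiumMeans), spacing = sp)
  t1 <- ImageVolume(paint(spec@t1Means), spacing = sp)

  dsFactor <- spec@loResSpacing / sp
  cfg <- DegradationConfig(downsampleFactor = pmax(dsFactor, 1),
                           ricianSigma = spec@ricianSigma,
                           seed = deriveSeed(spec@seed, 101L))
  loRes <- composeDegradation(sodium, cfg,
                              stages = c("gibbs_downsample", "rician"))

  mk <- function(m, label) MaskVolume(m * 1, label = label, spacing = sp)
  new("PhantomSample", hiResSodium = sodium, loResSodium = loRes,
      t1Post = t1,
      masks = list(CET = mk(cet, "CET"), necrosis = mk(nec, "necrosis"),
                   T2hyper = mk(t2h, "T2hyper"), NAWM = mk(nawm, "NAWM"),
                   eye_left = mk(eyeL, "eye_left"),
                   eye_right = mk(eyeRt, "eye_right"),
                   fat = mk(fat, "fat"), brain = mk(brain, "brain")),
      spec = spec)
}

#' Build paired (degraded, clean) training volumes from random phantoms
#'
#' Draws \code{n} phantoms from \code{specSampler} (seed-deterministically),
#' takes each noiseless high-resolution sodium channel as the clean member,
#' and degrades it with the artifact stage set of the given curriculum
#' stage. When the stage set includes \code{gibbs_downsample}, the degraded
#' volume is resampled back to the clean grid so each pair shares one grid
#' (the super-resolution path upsamples before the network).
#'
#' @param n number of pairs (>= 1)
#' @param specSampler function(seed) returning a \linkS4class{PhantomSpec};
#'   defaults to jittered variations of the default spec
#' @param curriculumStage a \linkS4class{CurriculumStage} (its
#'   \code{artifactStages} select the degradation), or a character vector of
#'   stage names
#' @param seed global RNG seed
#' @param config base \linkS4class{DegradationConfig}; per-pair noise seeds
#'   and field maps are derived from \code{seed}
#' @return list of length n; each element is
#'   \code{list(degraded =, clean =, sample =)} with two
#'   \linkS4class{ImageVolume}s on one grid and the source
#'   \linkS4class{PhantomSample}
#' @export
makeTrainingPairs <- function(n, specSampler = NULL, curriculumStage,
                              seed = 1L, config = DegradationConfig()) {
  if (n < 1) .paramError("n must be >= 1")
  stages <- if (is(curriculumStage, "CurriculumStage"))
    curriculumStage@artifactStages else as.character(curriculumStage)
  if (!all(stages %in% .canonicalStages))
    .paramError("unknown stage name: %s",
                paste(setdiff(stages, .canonicalStages), collapse = ", "))
  if (is.null(specSampler)) specSampler <- defaultSpecSampler()
  lapply(seq_len(n), function(i) {
    si <- deriveSeed(seed, i)
    spec <- specSampler(si)
    ph <- generateHeadPhantom(spec)
    clean <- ph@hiResSodium
    cfg <- config
    cfg@seed <- deriveSeed(si, 7L)
    # unless overridden, degrade with the acquisition stated by the spec:
    # its noise level and its low-resolution grid
    if (cfg@ricianSigma == 0) cfg@ricianSigma <- spec@ricianSigma
    if (all(cfg@downsampleFactor == 1))
      cfg@downsampleFactor <- pmax(spec@loResSpacing / spec@spacing, 1)
    if (is.null(cfg@fieldMap) && "b0" %in% stages)
      cfg@fieldMap <- synthesizeFieldMap(dim(clean), clean@spacing,
                                         amplitudeHz = 40,
                                         seed = deriveSeed(si, 11L))
    degraded <- composeDegradation(clean, cfg, stages,
                                   fatMask = ph@masks$fat)
    if (!identical(dim(degraded@data), dim(clean@data)))
      degraded <- resampleToGrid(degraded, clean@spacing)
    list(degraded = degraded, clean = clean, sample = ph)
  })
}

#' Default phantom spec sampler for training-pair generation
#'
#' Jitters lesion position, radii and compartment contrast around the
#' default spec, at a reduced grid suitable for network training patches.
#'
#' @param shape,spacing training-phantom grid (defaults 32 x 32 x 16 voxels
#'   at 2 mm, i.e. the same 64 mm field of view as the default spec)
#' @param ricianSigma noise level passed to the spec
#' @return function(seed) -> \linkS4class{PhantomSpec}
#' @export
defaultSpecSampler <- function(shape = c(32L, 32L, 16L),
                               spacing = c(2, 2, 2), ricianSigma = 4) {
  force(shape); force(spacing); force(ricianSigma)
  function(seed) {
    set.seed(as.integer(seed))
    r1 <- runif(1, 8, 11)
    PhantomSpec(shape = shape, spacing = spacing,
                lesionCenter = c(runif(1, 8, 13), runif(1, -4, 6),
                                 runif(1, -2, 2)),
                lesionRadii = c(r1, r1 * runif(1, 0.5, 0.7),
                                r1 * runif(1, 0.25, 0.4)),
                sodiumLesionRatio = runif(1, 1.25, 1.55),
                ricianSigma = ricianSigma,
                seed = deriveSeed(seed, 3L))
  }
}
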