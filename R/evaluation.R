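## Quantitative validation: vitreous normalization, dual SNR definitions,
## VOI statistics, native-vs-synthetic comparisons, ordinal NHE1 grading
## and cohort summaries.

#' Normalize a sodium volume to the vitreous humor signal
#'
#' Divides the whole volume by the mean intensity over the union of the
#' left- and right-eye VOIs (both eyes pooled as one region), yielding
#' relative sodium values comparable across scans: the normalized mean
#' over the eye union is exactly 1, and the operation is idempotent and
#' invariant to positive rescaling of the input.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param eyeLeft,eyeRight non-empty \linkS4class{MaskVolume}s on the
#'   volume grid
#' @return normalized \linkS4class{ImageVolume}; per-eye means are
#'   attached as attribute "eyeMeans"
#' @export
vitreousNormalize <- function(volume, eyeLeft, eyeRight) {
  .checkSameGrid(volume, eyeLeft, "volume and eye masks")
  .checkSameGrid(volume, eyeRight, "volume and eye masks")
  sl <- eyeLeft@data > 0; sr <- eyeRight@data > 0
  if (!any(sl) || !any(sr)) .domainError("eye VOI masks must be non-empty")
  div <- mean(volume@data[sl | sr])
  if (div <= 0) .domainError("vitreous mean is not positive")
  out <- ImageVolume(volume@data / div, spacing = volume@spacing,
                     origin = volume@origin)
  attr(out, "eyeMeans") <- c(left = mean(volume@data[sl]) / div,
                             right = mean(volume@data[sr]) / div)
  out
}

#' Signal-to-noise ratio from signal and noise VOIs
#'
#' \code{SNR = mean(volume over signalMask) / sd(volume over noiseMask)}.
#' Two uses: lesion SNR passes the T2-hyperintense region as signal and a
#' normal-appearing white matter (NAWM) mask as noise reference; NAWM SNR
#' passes NAWM as both masks (mean over sd within one region). Sample
#' (n - 1) standard deviation throughout.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param signalMask,noiseMask non-empty \linkS4class{MaskVolume}s on the
#'   volume grid; the noise region needs > 1 voxel
#' @return scalar SNR
#' @export
computeSNR <- function(volume, signalMask, noiseMask = signalMask) {
  .checkSameGrid(volume, signalMask, "volume and masks")
  .checkSameGrid(volume, noiseMask, "volume and masks")
  s <- signalMask@data > 0; n <- noiseMask@data > 0
  if (!any(s) || sum(n) < 2)
    .domainError("signal mask empty or noise mask has < 2 voxels")
  sdn <- sd(volume@data[n])
  if (sdn == 0) .domainError("noise region has zero standard deviation")
  mean(volume@data[s]) / sdn
}

#' Per-compartment mean and standard deviation
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param masks named list of \linkS4class{MaskVolume} on the volume grid
#' @return data.frame with columns label, n, mean, sd, empty (empty masks
#'   are flagged, not dropped)
#' @export
voiStatistics <- function(volume, masks) {
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    .checkSameGrid(volume, m, "volume and masks")
    sel <- m@data > 0
    if (!any(sel))
      data.frame(label = nm, n = 0L, mean = NA_real_, sd = NA_real_,
                 empty = TRUE)
    else
      data.frame(label = nm, n = sum(sel), mean = mean(volume@data[sel]),
                 sd = if (sum(sel) > 1) sd(volume@data[sel]) else NA_real_,
                 empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare paired native and synthetic measurements
#'
#' Pearson correlation with the least-squares slope and its 95 percent
#' confidence interval (r-squared reported as r^2), Spearman rank
#' correlation, or a two-sided paired t-test, on equal-length paired
#' vectors.
#'
#' @param native,synthetic equal-length numeric vectors, n >= 3
#' @param method one of "pearson", "spearman", "paired_t"
#' @return named list of statistics, always carrying \code{n} and
#'   \code{method}
#' @export
compareNativeSynthetic <- function(native, synthetic,
                                   method = c("pearson", "spearman",
                                              "paired_t")) {
  method <- match.arg(method)
  if (length(native) != length(synthetic))
    .paramError("vectors must have equal length")
  n <- length(native)
  if (n < 3) .paramError("need at least 3 pairs")
  if (method %in% c("pearson", "spearman") &&
      (sd(native) == 0 || sd(synthetic) == 0))
    .domainError(
      "correlation is undefined: one of the vectors has zero variance")
  if (method == "pearson") {
    ct <- stats::cor.test(native, synthetic, method = "pearson")
    fit <- stats::lm(synthetic ~ native)
    ci <- stats::confint(fit, "native", level = 0.95)
    list(method = "pearson", n = n, r = unname(ct$estimate),
         r2 = unname(ct$estimate)^2, p = ct$p.value,
         slope = unname(stats::coef(fit)["native"]),
         slope_ci = c(ci[1], ci[2]))
  } else if (method == "spearman") {
    ct <- suppressWarnings(stats::cor.test(native, synthetic,
                                           method = "spearman"))
    list(method = "spearman", n = n, rho = unname(ct$estimate),
         p = ct$p.value)
  } else {
    d <- synthetic - native
    if (sd(d) == 0)
      return(list(method = "paired_t", n = n, mean_diff = mean(d),
                  t = NA_real_, p = NA_real_,
                  note = "zero-variance differences; p undefined"))
    tt <- stats::t.test(synthetic, native, paired = TRUE)
    list(method = "paired_t", n = n, mean_diff = unname(tt$estimate),
         t = unname(tt$statistic), p = tt$p.value)
  }
}

#' Ordinal NHE1 expression grade from percent positive cells
#'
#' Grade 0: no expression (0 percent); grade 1 (mild): up to 33 percent;
#' grade 2 (moderate): between 33 and 66; grade 3 (strong): between 66
#' and 100. Boundaries at exactly 33 and 66 belong to the lower grade
#' ("up to" read as inclusive). A grade of 1 or more counts as elevated
#' expression.
#'
#' @param percentPositive numeric vector of percent positive cells, in
#'   [0, 100]
#' @return integer vector of grades 0-3, with logical attribute
#'   "elevated" (grade >= 1)
#' @examples
#' nhe1Grade(c(0, 20, 50, 80))
#' @export
nhe1Grade <- function(percentPositive) {
  if (any(!is.finite(percentPositive)) || any(percentPositive < 0) ||
      any(percentPositive > 100))
    .paramError("percentPositive must lie in [0, 100]")
  g <- ifelse(percentPositive == 0, 0L,
       ifelse(percentPositive <= 33, 1L,
       ifelse(percentPositive <= 66, 2L, 3L)))
  g <- as.integer(g)
  attr(g, "elevated") <- g >= 1L
  g
}

#' Summarize a validation-cohort demographics table
#'
#' Expects one row per patient with columns \code{age}, \code{sex}
#' ("M"/"F"), \code{diagnosis} and optionally \code{biopsies} (number of
#' image-guided biopsies; missing for patients without biopsies). Missing
#' values are excluded from sums, never imputed; diagnosis rows are
#' counted verbatim.
#'
#' @param table data.frame of demographics records
#' @return named list: age mean/sd/range, sex counts, diagnosis counts,
#'   total biopsies and number of patients contributing them
#' @export
cohortSummary <- function(table) {
  if (!nrow(table)) .domainError("demographics table is empty")
  age <- table$age[!is.na(table$age)]
  bio <- if ("biopsies" %in% names(table))
    table$biopsies[!is.na(table$biopsies)] else numeric()
  list(n = nrow(table),
       age_mean = mean(age), age_sd = sd(age), age_range = range(age),
       sex_counts = c(M = sum(table$sex == "M", na.rm = TRUE),
                      F = sum(table$sex == "F", na.rm = TRUE)),
       diagnosis_counts = table(table$diagnosis),
       biopsies_total = sum(bio),
       biopsies_patients = length(bio))
}

#' Evaluate a phantom case: native vs synthetic sodium
#'
#' Applies the full per-case evaluation protocol to one
#' \linkS4class{PhantomSample} and its enhanced (synthetic) volume:
#' vitreous normalization of both the native (resampled to the synthetic
#' grid) and synthetic volumes, normalized VOI means for CET, necrosis and
#' T2-hyperintense compartments, and both SNR definitions for each volume.
#'
#' @param sample a \linkS4class{PhantomSample}
#' @param enhanced synthetic volume from [enhanceVolume()], on the
#'   hi-res grid
#' @return EvalReport-style list: per-VOI normalized means and SNRs for
#'   native and synthetic, each with its n
#' @export
evaluateSample <- function(sample, enhanced) {
  masks <- sample@masks
  grid <- masks$NAWM
  alignTo <- function(v) {
    if (.sameGrid(v, grid)) return(v)
    r <- resampleToGrid(v, grid@spacing)
    if (!identical(dim(r@data), dim(grid@data)))
      .shapeError("volume cannot be aligned to the mask grid")
    r
  }
  one <- function(v) {
    v <- alignTo(v)
    vn <- vitreousNormalize(v, masks$eye_left, masks$eye_right)
    st <- voiStatistics(vn, masks[c("CET", "necrosis", "T2hyper")])
    list(voi = st,
         snr_lesion = computeSNR(v, masks$T2hyper, masks$NAWM),
         snr_nawm = computeSNR(v, masks$NAWM, masks$NAWM))
  }
  list(native = one(sample@loResSodium), synthetic = one(enhanced))
}

#' Write an EvalReport list as JSON plus a flat CSV
#'
#' @param report list as returned by [evaluateSample()] (or a list of
#'   them, one per case)
#' @param path output path without extension; writes path.json and
#'   path.csv
#' @return invisible character vector of the files written
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  cases <- if (!is.null(report$native)) list(case1 = report) else report
  rows <- do.call(rbind, lapply(names(cases), function(cs)
    do.call(rbind, lapply(c("native", "synthetic"), function(arm) {
      st <- cases[[cs]][[arm]]$voi
      data.frame(case = cs, arm = arm, label = st$label, n = st$n,
                 mean = st$mean, sd = st$sd,
                 snr_lesion = cases[[cs]][[arm]]$snr_lesion,
                 snr_nawm = cases[[cs]][[arm]]$snr_nawm)
    }))))
  utils::write.csv(rows, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, c(".json", ".csv")))
}
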