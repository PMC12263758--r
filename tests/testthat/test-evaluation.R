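test_that("vitreous normalization pools both eyes and self-normalizes", {
  a <- array(1, c(10, 10, 4))
  a[1:2, 1:2, 1] <- 2                     # left eye mean 2
  a[9:10, 1:2, 1] <- 4                    # right eye mean 4
  v <- ImageVolume(a)
  mk <- function(sel, lab) {
    m <- array(0, dim(a)); m[sel[[1]], sel[[2]], sel[[3]]] <- 1
    MaskVolume(m, lab)
  }
  el <- mk(list(1:2, 1:2, 1), "eye_left")
  er <- mk(list(9:10, 1:2, 1), "eye_right")
  out <- vitreousNormalize(v, el, er)
  # equal voxel counts: pooled divisor is (2 + 4) / 2 = 3
  expect_equal(volData(out)[1, 1, 1], 2 / 3)
  sel <- (volData(el) + volData(er)) > 0
  expect_equal(mean(volData(out)[sel]), 1)
  expect_equal(attr(out, "eyeMeans"), c(left = 2 / 3, right = 4 / 3))
  # scale invariance and idempotence
  out10 <- vitreousNormalize(ImageVolume(10 * a), el, er)
  expect_equal(volData(out10), volData(out))
  twice <- vitreousNormalize(out, el, er)
  expect_equal(volData(twice), volData(out))
  expect_error(vitreousNormalize(v, mk(list(1, 1, 2), "eye_left"),
                                 MaskVolume(array(0, dim(a)), "eye_right")),
               class = "sodiumSR_domain_error")
})

test_that("SNR follows its closed form and is scale-invariant", {
  a <- array(10, c(8, 8, 4))
  noise <- c(1, 3, 5, 3, 1, 3, 5, 3)       # sd 1.6036...
  a[1, 1:8, 1] <- noise
  v <- ImageVolume(a)
  sig <- MaskVolume(array(c(0, 1)[(a == 10) + 1], dim(a)), "T2hyper")
  noi <- array(0, dim(a)); noi[1, 1:8, 1] <- 1
  noiM <- MaskVolume(noi, "NAWM")
  expect_equal(computeSNR(v, sig, noiM), 10 / sd(noise))
  expect_equal(computeSNR(ImageVolume(3 * a), sig, noiM), 10 / sd(noise))
  # constant signal 10, noise sd 2 -> SNR 5
  b <- array(10, c(4, 4, 2)); b[1, , 1] <- c(8, 12, 8, 12)
  noi2 <- array(0, dim(b)); noi2[1, , 1] <- 1
  expect_equal(computeSNR(ImageVolume(b),
                          MaskVolume((b == 10) * 1, "T2hyper"),
                          MaskVolume(noi2, "NAWM")),
               10 / sd(c(8, 12, 8, 12)))
})

test_that("NAWM SNR recovers the plug-in value on sampled noise", {
  set.seed(22)
  d <- c(25, 25, 16)                       # 10^4 NAWM voxels
  a <- array(100 + rnorm(prod(d), sd = 10), d)
  v <- ImageVolume(pmax(a, 0))
  m <- MaskVolume(array(1, d), "NAWM")
  expect_equal(computeSNR(v, m, m), 10, tolerance = 0.05)
})

test_that("VOI statistics recover compartment means and flag empties", {
  spec <- tinySpec(seed = 2)
  ph <- generateHeadPhantom(spec)
  st <- voiStatistics(ph@hiResSodium, ph@masks)
  expect_equal(st$mean[st$label == "NAWM"], spec@sodiumMeans[["brain"]])
  expect_equal(st$mean[st$label == "T2hyper"],
               spec@sodiumMeans[["t2hyper"]])
  expect_equal(st$sd[st$label == "NAWM"], 0)
  # 5-voxel toy mask, values 1..5
  a <- array(0, c(5, 2, 2)); a[, 1, 1] <- 1:5
  m <- array(0, dim(a)); m[, 1, 1] <- 1
  toy <- voiStatistics(ImageVolume(a),
                       list(roi = MaskVolume(m, "CET"),
                            none = MaskVolume(array(0, dim(a)), "NAWM")))
  expect_equal(toy$mean[1], 3)
  expect_equal(toy$sd[1], sqrt(2.5))
  expect_true(toy$empty[2] && !toy$empty[1])
})

test_that("pearson statistics match a hand-rolled regression oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 2.1, 2.9, 4.3, 5.0)
  res <- compareNativeSynthetic(x, y, "pearson")
  # closed-form least squares + t quantiles, written out explicitly
  n <- 5
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icept <- mean(y) - slope * mean(x)
  resid <- y - icept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sxx * sum((y - mean(y))^2))
  tcrit <- qt(0.975, n - 2)
  expect_equal(res$r, r, tolerance = 1e-10)
  expect_equal(res$r2, r^2, tolerance = 1e-10)
  expect_equal(res$slope, slope, tolerance = 1e-10)
  expect_equal(unname(res$slope_ci),
               c(slope - tcrit * se, slope + tcrit * se),
               tolerance = 1e-10)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
  expect_equal(res$n, n)
})

test_that("spearman and paired-t match their closed forms", {
  x <- c(2, 9, 1, 7, 5, 4)
  res <- compareNativeSynthetic(x, exp(x), "spearman")
  expect_equal(res$rho, 1)                 # monotone transform
  y <- c(3, 8, 2, 9, 4, 7)
  rho <- 1 - 6 * sum((rank(x) - rank(y))^2) / (6 * (36 - 1))
  expect_equal(compareNativeSynthetic(x, y, "spearman")$rho, rho,
               tolerance = 1e-10)
  # paired t oracle
  d <- y - x
  tstat <- mean(d) / (sd(d) / sqrt(6))
  rest <- compareNativeSynthetic(x, y, "paired_t")
  expect_equal(rest$t, tstat, tolerance = 1e-10)
  expect_equal(rest$p, 2 * pt(-abs(tstat), 5), tolerance = 1e-10)
  # identical vectors: r = 1, zero mean difference, flagged p
  same <- suppressWarnings(compareNativeSynthetic(x, x, "pearson"))
  expect_equal(same$r, 1)
  pt0 <- compareNativeSynthetic(x, x, "paired_t")
  expect_equal(pt0$mean_diff, 0)
  expect_true(is.na(pt0$p))
  expect_error(compareNativeSynthetic(rep(1, 5), x[1:5]),
               class = "sodiumSR_domain_error")
  expect_error(compareNativeSynthetic(1:2, 2:3),
               class = "sodiumSR_parameter_error")
})

test_that("NHE1 grading uses the 0/33/66 boundaries and is monotone", {
  expect_identical(as.integer(nhe1Grade(c(0, 20, 50, 80))),
                   c(0L, 1L, 2L, 3L))
  # boundaries belong to the lower grade
  expect_identical(as.integer(nhe1Grade(c(33, 66, 100))), c(1L, 2L, 3L))
  expect_identical(attr(nhe1Grade(c(0, 5)), "elevated"), c(FALSE, TRUE))
  g <- as.integer(nhe1Grade(seq(0, 100, by = 0.5)))
  expect_true(all(diff(g) >= 0))
  expect_error(nhe1Grade(101), class = "sodiumSR_parameter_error")
  expect_error(nhe1Grade(-1), class = "sodiumSR_parameter_error")
})

test_that("cohort summary reproduces the validation-cohort demographics", {
  tab <- read.csv(system.file("extdata", "validation_cohort.csv",
                              package = "sodiumSR"))
  s <- cohortSummary(tab)
  expect_equal(s$n, 20)
  expect_equal(s$age_mean, 46.95, tolerance = 1e-10)
  expect_equal(s$age_sd, sd(tab$age))
  expect_identical(s$age_range, c(27L, 78L))
  expect_identical(unname(s$sex_counts), c(11L, 9L))
  expect_equal(s$biopsies_total, 24)
  expect_equal(s$biopsies_patients, 7)
  expect_error(cohortSummary(tab[0, ]), class = "sodiumSR_domain_error")
})

test_that("per-case evaluation report has both arms and serializes", {
  ph <- generateHeadPhantom(tinySpec(seed = 9))
  enh <- resampleToGrid(ph@loResSodium, voxelSpacing(ph@hiResSodium))
  rep <- evaluateSample(ph, enh)
  for (arm in c("native", "synthetic")) {
    expect_true(all(c("CET", "necrosis", "T2hyper") %in% rep[[arm]]$voi$label))
    expect_true(is.finite(rep[[arm]]$snr_lesion))
    expect_true(is.finite(rep[[arm]]$snr_nawm))
    expect_true(all(rep[[arm]]$voi$n > 0))
  }
  path <- tempfile()
  files <- writeEvalReport(rep, path)
  expect_true(all(file.exists(paste0(path, c(".json", ".csv")))))
  parsed <- jsonlite::read_json(paste0(path, ".json"))
  expect_named(parsed, c("native", "synthetic"))
  csv <- read.csv(paste0(path, ".csv"))
  expect_identical(sort(unique(csv$arm)), c("native", "synthetic"))
})
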