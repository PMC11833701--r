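test_that("the background annulus equals a brute-force distance oracle", {
  set.seed(4)
  dims <- c(10, 48, 48)
  lab <- array(0L, dims)
  lab[3:7, 15:20, 25:31] <- 1L
  lab[5:8, 35:38, 8:11] <- 2L
  ch <- array(runif(prod(dims), 0, 50), dims)
  expect_equal(backgroundAnnulus(ch, lab, 5, 15),
               bruteForceAnnulus(ch, lab, 5, 15))
  uni <- array(7, dims)
  expect_equal(backgroundAnnulus(uni, lab), 7)
  zero <- array(0, dims); zero[lab > 0] <- 99
  expect_equal(backgroundAnnulus(zero, lab), 0)
  expect_error(backgroundAnnulus(ch, array(0L, dims)), "empty")
})

test_that("axis segmentation is a strict mean threshold inside the nucleus", {
  nuc <- makeFilamentNucleus(radius = 7, base = 0, axisExtra = 10)
  m <- segmentAxis(nuc$channel, nuc$nucleus)
  expect_equal(m, nuc$filament & nuc$nucleus)
  const <- array(5, dim(nuc$channel))
  expect_false(any(segmentAxis(const, nuc$nucleus)))
  expect_true(all(m[!nuc$nucleus] == FALSE))
  expect_error(segmentAxis(const, array(FALSE, dim(const))), "empty")
})

test_that("planted filaments are recovered with high overlap under noise", {
  set.seed(12)
  nuc <- makeFilamentNucleus(radius = 8, base = 50, axisExtra = 400)
  noisy <- nuc$channel + array(rnorm(length(nuc$channel), 0, 10),
                               dim(nuc$channel))
  m <- segmentAxis(noisy, nuc$nucleus)
  jacc <- sum(m & nuc$filament) / sum(m | nuc$filament)
  expect_gte(jacc, 0.8)
})

test_that("nucleus metrics report volume, sphericity and intensity totals", {
  dims <- c(16, 16, 16)
  lab <- array(0L, dims)
  lab[4:13, 4:13, 4:13] <- 1L   # 1000-voxel cube
  ch <- array(0, dims); ch[lab == 1L] <- 3
  vol <- LabeledVolume(list(sc = ch), lab, c(0.1, 0.1, 0.1))
  rec <- nucleusMetrics(vol, axisChannel = "sc")
  expect_equal(rec$volume_um3, 1.0)
  expect_equal(rec$nuc_sc, 3000)
  ## constant nucleus: empty axis mask, zero axis total
  expect_equal(rec$axis_sc, 0)

  ## digital ball: sphericity close to 1
  n <- 27; c0 <- 14; R <- 10
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ball <- array(as.integer(rowSums((idx - c0)^2) <= R^2), c(n, n, n))
  ch2 <- array(1, c(n, n, n))
  volB <- LabeledVolume(list(sc = ch2), ball, c(0.2, 0.2, 0.2))
  recB <- nucleusMetrics(volB, axisChannel = "sc")
  expect_lt(abs(recB$sphericity - 1), 0.1)
})

test_that("background correction floors at zero and is monotone", {
  nuc <- makeFilamentNucleus(radius = 6, base = 20, axisExtra = 30)
  lab <- array(0L, dim(nuc$nucleus)); lab[nuc$nucleus] <- 1L
  vol <- LabeledVolume(list(sc = nuc$channel), lab, c(0.2, 0.2, 0.2))
  totals <- sapply(c(0, 10, 25, 1000), function(b)
    nucleusMetrics(vol, backgrounds = c(sc = b), axisChannel = "sc")$nuc_sc)
  expect_true(all(diff(totals) <= 0))
  expect_true(all(totals >= 0))
  expect_equal(totals[4], 0)
})

test_that("nucleus filters follow exclusive volume and inclusive ratio
           bounds", {
  rec <- data.frame(nucleus_id = 1:6,
                    volume_um3 = c(60, 30, 30, 30, 10, 59.9),
                    sphericity = c(0.8, 0.4, 0.8, 0.8, 0.8, 0.41),
                    axis_ratio = c(0.5, 0.5, 0.3, 0.8, 0.5, 0.81))
  out <- filterNuclei(rec, keep = "all")
  expect_equal(out$passed_filters,
               c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(filterNuclei(rec)), 2L)
  ## decisions depend only on the record itself
  out2 <- filterNuclei(rec[3, , drop = FALSE], keep = "all")
  expect_true(out2$passed_filters)
})

test_that("germline straightening maps annotated landmarks to 0 and 1", {
  ## straight line: positions are linear rescales of the coordinate
  n <- 25
  cen <- cbind(rep(2, n), rep(3, n), seq(0, 48, length.out = n))
  sp <- straightenPositions(cen, list(start = 1, end = n))
  expect_equal(sp$position, seq(0, 1, length.out = n), tolerance = 1e-6)
  expect_equal(sp$position[1], 0)
  expect_equal(sp$position[n], 1)
  expect_false(any(sp$flagged))

  ## quarter circle: matches the analytic arc-length parametrization
  th <- seq(0, pi / 2, length.out = 40)
  cen2 <- cbind(1, 20 * sin(th), 20 * cos(th))
  sp2 <- straightenPositions(cen2, list(start = 1, end = 40))
  expect_lt(max(abs(sp2$position - (th - th[1]) / (th[40] - th[1]))), 0.02)

  ## interior annotations flag nuclei outside [0, 1]
  sp3 <- straightenPositions(cen, list(start = 5, end = 20))
  expect_true(sp3$flagged[1])
  expect_gt(sp3$position[n], 1)
  expect_error(straightenPositions(cen[rep(1, 12), ],
                                   list(start = 1, end = 2)), "degenerate")
})

test_that("binned profiles match a hand-rolled group-by", {
  pos <- seq(0, 1, length.out = 400)
  pb <- profileBins(pos, rep(3, 400))
  expect_true(all(pb$mean == 3))
  expect_true(all(pb$se == 0))
  expect_equal(sum(pb$n), 400L)
  pb2 <- profileBins(pos, pos)
  expect_equal(pb2$mean, pb2$mid, tolerance = 0.01)
  set.seed(8)
  p <- runif(200); v <- rnorm(200)
  pb3 <- profileBins(p, v, nbins = 11)
  orc <- groupbyProfile(p, v, 11)
  expect_equal(pb3$mean, orc$mean)
  expect_equal(pb3$se, orc$se)
  expect_equal(pb3$n, orc$n)
  ## empty bin
  pb4 <- profileBins(c(0.05, 0.95), c(1, 2), nbins = 11)
  expect_true(any(pb4$n == 0))
  expect_true(all(is.na(pb4$mean[pb4$n == 0])))
  expect_error(profileBins(c(-0.1, 0.5), c(1, 2)), "\\[0, 1\\]")
})

test_that("slide-wise wild-type normalization self-normalizes to 1", {
  df <- data.frame(slide = rep(c("s1", "s2"), each = 4),
                   genotype = rep(c("WT", "WT", "mut", "mut"), 2),
                   axis_sc = c(10, 12, 22, 22, 5, 5, 20, 20))
  out <- normalizeToSlideWT(df, "axis_sc")
  expect_equal(mean(out$axis_sc_norm[out$genotype == "WT" &
                                     out$slide == "s1"]), 1)
  expect_equal(mean(out$axis_sc_norm[out$genotype == "WT" &
                                     out$slide == "s2"]), 1)
  expect_equal(out$axis_sc_norm[out$slide == "s2" & out$genotype == "mut"],
               c(4, 4))
  df2 <- df[df$genotype == "mut" | df$slide == "s1", ]
  expect_error(normalizeToSlideWT(df2, "axis_sc"), "s2")
})

test_that("foci are detected and localized by 3D Gaussian refinement", {
  ## noise-free planted spot: one focus, centroid within one voxel
  dims <- c(20, 20, 20)
  lab <- array(0L, dims)
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  lab[rowSums((idx - 10.5)^2) <= 8^2] <- 1L
  sp <- c(11.3, 9.2, 12.6)
  ch <- array(0, dims)
  ch[] <- 5 + 200 * exp(-rowSums((idx - rep(sp, each = nrow(idx)))^2) /
                        (2 * 1.0^2))
  det <- detectFoci(ch, lab, method = "otsu")
  expect_equal(det$counts$n_foci, 1L)
  expect_lt(sqrt(sum((c(det$foci$z, det$foci$y, det$foci$x) - sp)^2)), 1)
  expect_true(det$foci$fitted)

  ## empty nucleus: 0 foci
  det0 <- detectFoci(array(5, dims), lab, method = "otsu")
  expect_equal(det0$counts$n_foci, 0L)

  ## two spots >= 6 sigma apart resolve as two foci
  sp2 <- c(8, 8, 8); sp3 <- c(13, 13, 13)
  ch2 <- array(0, dims)
  ch2[] <- 5 +
    200 * exp(-rowSums((idx - rep(sp2, each = nrow(idx)))^2) / 2) +
    180 * exp(-rowSums((idx - rep(sp3, each = nrow(idx)))^2) / 2)
  det2 <- detectFoci(ch2, lab, method = "otsu")
  expect_equal(det2$counts$n_foci, 2L)

  ## RAD-51 mode: nuclei outside the 1-6 um diameter gate are not scored
  det3 <- detectFoci(ch, lab, method = "yen", diameterRange = c(1, 6),
                     voxelSizeUm = c(0.5, 0.5, 0.5))
  expect_false(det3$counts$scored)  # 8-voxel radius at 0.5 um => 8 um
  det4 <- detectFoci(ch, lab, method = "yen", diameterRange = c(1, 6),
                     voxelSizeUm = c(0.2, 0.2, 0.2))
  expect_true(det4$counts$scored)
})

test_that("focus intensity CV uses the sample standard deviation", {
  expect_equal(focusIntensityCV(c(5, 5, 5)), 0)
  expect_equal(focusIntensityCV(c(1, 3)), sqrt(2) / 2)
  expect_true(is.na(focusIntensityCV(7)))
  expect_true(is.na(focusIntensityCV(numeric())))
})

test_that("a planted lognormal intensity CV of 0.4 is recovered from the
           fitted focus intensities", {
  cvs <- c(); truthCvs <- c(); pooled <- c()
  for (s in 1:4) {
    sim <- simulateGermlineStack(nNuclei = 50, fociPerNucleus = 6,
                                 intensityCV = 0.4, seed = 700 + s)
    det <- detectFoci(volumeChannels(sim$volume)$foci,
                      volumeLabels(sim$volume), method = "otsu",
                      voxelSizeUm = voxelSize(sim$volume))
    f <- det$foci[det$foci$fitted, ]
    cvs <- c(cvs, vapply(split(f$integrated, f$nucleus_id),
                         focusIntensityCV, numeric(1)))
    truthCvs <- c(truthCvs, vapply(sim$truth$nuclei, function(tn)
      focusIntensityCV(tn$focusAmplitudes), numeric(1)))
    pooled <- c(pooled, f$integrated / mean(f$integrated))
  }
  expect_gte(length(cvs), 200)
  ## per-nucleus CVs reproduce the planted per-nucleus sample CVs
  expect_lt(abs(mean(cvs, na.rm = TRUE) - mean(truthCvs)), 0.01)
  ## pooled over all foci, the generator CV of 0.4 is recovered
  expect_lt(abs(focusIntensityCV(pooled) - 0.4), 0.05)
})

test_that("histogram thresholds match the reference implementations", {
  ## expected values computed once with scikit-image 0.26
  ## (threshold_otsu / threshold_yen, nbins = 256) on this exact sample
  set.seed(31)
  x <- c(rnorm(3000, 30, 8), rnorm(300, 120, 15))
  binw <- diff(range(x)) / 256
  expect_lt(abs(meioquant:::.histThreshold(x, "otsu") - 53.40216),
            2 * binw)
  expect_lt(abs(meioquant:::.histThreshold(x, "yen") - 47.49038),
            2 * binw)
})

test_that("axis masks are subsets of nucleus masks on simulated stacks", {
  sim <- simulateGermlineStack(nNuclei = 4, seed = 14)
  lab <- volumeLabels(sim$volume)
  ch <- volumeChannels(sim$volume)$axis
  for (id in 1:4) {
    m <- lab == id
    am <- segmentAxis(ch, m)
    expect_true(all(m[am]))
  }
})

test_that("the genotype contrast recovers a planted hexanediol effect and
           respects the gonad structure", {
  rec0 <- simulateRatioRecords(genotypeMeans = c(WT = 0.6, mut = 0.6),
                               seed = 41)
  h0 <- hexanediolContrast(rec0, reference = "WT")
  expect_lt(abs(h0$estimate), 0.05)
  expect_gt(h0$p_value, 0.05)

  rec1 <- simulateRatioRecords(genotypeMeans = c(WT = 0.6, mut = 0.5),
                               gonadsPerGenotype = 6, seed = 42)
  h1 <- hexanediolContrast(rec1, reference = "WT")
  expect_lt(abs(h1$estimate - (-0.1)), 0.03)
  expect_lt(h1$p_value, 0.01)

  ## permuting genotype labels destroys the effect
  set.seed(43)
  recP <- rec1
  recP$genotype <- sample(recP$genotype)
  recP$gonad <- paste0(recP$gonad, "_", recP$genotype)
  hP <- hexanediolContrast(recP, reference = "WT")
  expect_gt(hP$p_value, 0.05)

  rec2 <- rec1[rec1$genotype == "WT" | rec1$gonad == "mut_gonad1", ]
  expect_error(hexanediolContrast(rec2), "single gonad")
})
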