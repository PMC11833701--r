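test_that("focus placement models obey their defining laws", {
  ## obligate_one: exactly one focus per chromosome
  sim <- simulateFocusPlacement("obligate_one", nNuclei = 100,
                                chromosomeLengths = c(a = 1, b = 2, c = 5,
                                                      d = 1, e = 3, f = 2),
                                seed = 2)
  expect_true(all(vapply(sim$focusSets, length, integer(1)) == 1L))

  ## poisson: empirical mean count matches the rate
  simP <- simulateFocusPlacement("poisson", nNuclei = 2000,
                                 chromosomeLengths = c(chr = 1),
                                 meanCount = 2, seed = 3)
  counts <- vapply(simP$focusSets, length, integer(1))
  expect_lt(abs(mean(counts) - 2), 0.1)

  ## gamma renewal: the fitted shape recovers the generating shape
  simG <- simulateFocusPlacement("gamma_renewal", nNuclei = 400,
                                 chromosomeLengths = c(chr = 1),
                                 shape = 10, meanCount = 4, seed = 4)
  fit <- fitGammaInterference(interfocusDistances(simG$focusSets))
  expect_lt(abs(interferenceShape(fit) - 10) / 10, 0.15)

  expect_error(simulateFocusPlacement("poisson", meanCount = -1), "positive")
  expect_error(simulateFocusPlacement("gamma_renewal", meanCount = 2),
               "shape")
})

test_that("identical seeds give identical synthetic data", {
  a <- simulateFocusPlacement("poisson", nNuclei = 20, meanCount = 3,
                              seed = 5)
  b <- simulateFocusPlacement("poisson", nNuclei = 20, meanCount = 3,
                              seed = 5)
  expect_identical(lapply(a$focusSets, focusPositions),
                   lapply(b$focusSets, focusPositions))
  c <- simulateFocusPlacement("poisson", nNuclei = 20, meanCount = 3,
                              seed = 6)
  expect_false(identical(lapply(a$focusSets, focusPositions),
                         lapply(c$focusSets, focusPositions)))

  e1 <- simulateF2Embryo(seed = 7)
  e2 <- simulateF2Embryo(seed = 7)
  expect_identical(windowCounts(e1$counts), windowCounts(e2$counts))
  expect_identical(windowDepth(e1$depth), windowDepth(e2$depth))

  s1 <- simulateGermlineStack(nNuclei = 3, seed = 8)
  s2 <- simulateGermlineStack(nNuclei = 3, seed = 8)
  expect_identical(volumeChannels(s1$volume), volumeChannels(s2$volume))
})

test_that("simulated embryos respect the backcross read model", {
  ## crossover-free heterozygous chromosome: gliding ratio around 0.5
  sim <- simulateF2Embryo(coModel = list(model = "none"),
                          chromosomeLengths = c(II = 15e6), coverage = 3,
                          seed = 9)
  if (sim$truth$chromosomes$II$startsBristol) {
    tr <- glidingRatio(sim$counts)
    expect_true(all(abs(tr$ratio - 0.5) < 0.15))
  }

  ## the depth of an absent X is about half the autosomal baseline
  found <- FALSE
  for (s in 10:20) {
    simX <- simulateF2Embryo(coverage = 3, seed = s)
    if (simX$truth$chromosomes$X$paternalCopies == 0L) {
      cn <- estimateCopyNumber(simX$depth)
      xcn <- cn$mean_copy_number[cn$chrom == "X"]
      expect_lt(abs(xcn - 1), 0.15)
      expect_equal(as.character(classifyPloidy(xcn)), "HAPLOID")
      found <- TRUE
      break
    }
  }
  expect_true(found)

  ## a planted crossover at 7.5 Mb is recovered by the caller
  simC <- simulateF2Embryo(coModel = list(model = "none"),
                           chromosomeLengths = c(IV = 15e6), coverage = 3,
                           seed = 21)
  cdf <- windowCounts(simC$counts)
  ## plant the breakpoint exactly: HET left of 7.5 Mb, hawaiian-hom right
  set.seed(22)
  half <- cdf$start < 7.5e6
  lam <- 3 / 2 * 5000 / 150 * 0.3
  cdf$bristol <- rpois(nrow(cdf), lam) * half
  cdf$hawaiian <- rpois(nrow(cdf), lam * 2)
  tb <- WindowCountTable(cdf)
  calls <- callCrossovers(glidingRatio(tb), tb)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$midpoint - 7.5e6), 250000)
})

test_that("generated window tables satisfy the container invariants", {
  for (s in 1:5) {
    sim <- simulateF2Embryo(coverage = 1.8 + 0.9 * s, seed = 30 + s,
                            nondisjunctionP = 0.1)
    expect_true(validObject(sim$counts))
    expect_true(validObject(sim$depth))
    cdf <- windowCounts(sim$counts)
    expect_true(all(cdf$bristol >= 0 & cdf$hawaiian >= 0))
    for (ch in unique(cdf$chrom)) {
      st <- cdf$start[cdf$chrom == ch]
      expect_true(all(diff(st) == 5000))
    }
    ## truth records the planted copy state for every chromosome
    expect_setequal(names(sim$truth$chromosomes), unique(cdf$chrom))
  }
})

test_that("germline stacks carry their planted truth", {
  sim <- simulateGermlineStack(nNuclei = 3, fociPerNucleus = 2,
                               noise = FALSE, seed = 35)
  vol <- sim$volume
  expect_s4_class(vol, "LabeledVolume")
  expect_equal(length(sim$truth$nuclei), 3L)
  ## labels are exactly the planted spheres
  lab <- volumeLabels(vol)
  for (k in 1:3) {
    expect_equal(sum(lab == k), sim$truth$nuclei[[k]]$nVoxels)
  }
  ## zero planted foci means zero detected foci
  sim0 <- simulateGermlineStack(nNuclei = 3, fociPerNucleus = 0,
                                noise = FALSE, seed = 36)
  det <- detectFoci(volumeChannels(sim0$volume)$foci,
                    volumeLabels(sim0$volume), method = "otsu",
                    voxelSizeUm = voxelSize(sim0$volume))
  expect_true(all(det$counts$n_foci == 0L))
})

test_that("round-trip tests can run from the serialized truth alone", {
  sim <- simulateFocusPlacement("gamma_renewal", nNuclei = 50,
                                chromosomeLengths = c(chr = 1),
                                shape = 5, meanCount = 3, seed = 40)
  path <- tempfile(fileext = ".json")
  writeTruth(sim$truth, path)
  tr <- readTruth(path)
  expect_equal(tr$model, "focus_placement")
  expect_equal(tr$params$shape, 5)
  expect_equal(tr$seed, 40)
  ## positions in the truth file reproduce the focus sets
  expect_equal(tr$foci[["n1_chr"]]$positions,
               focusPositions(sim$focusSets[["n1_chr"]]))
})
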