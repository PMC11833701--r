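makeCountTable <- function(bristol, hawaiian, chrom = "chrII",
                           windowSize = 5000) {
  WindowCountTable(data.frame(
    chrom = chrom, start = seq(0, by = windowSize,
                               length.out = length(bristol)),
    bristol = bristol, hawaiian = hawaiian), windowSize)
}

test_that("gliding ratio is a centered ratio of sums, truncated at ends", {
  tb <- makeCountTable(rep(5, 250), rep(5, 250))
  tr <- glidingRatio(tb, span = 100)
  expect_true(all(tr$ratio == 0.5))
  tb2 <- makeCountTable(rep(0, 250), rep(8, 250))
  expect_true(all(glidingRatio(tb2)$ratio == 0))
  set.seed(5)
  b <- rpois(300, 3); h <- rpois(300, 3)
  tr3 <- glidingRatio(makeCountTable(b, h), span = 100)
  expect_equal(tr3$ratio, loopGlidingRatio(b, h, 100))
  expect_error(glidingRatio(tb, span = 0), "span")
})

test_that("windows with an empty informative span are UNINFORMATIVE", {
  b <- c(rep(4, 50), rep(0, 200), rep(4, 50))
  h <- rep(0, 300)
  tr <- glidingRatio(makeCountTable(b, h), span = 21)
  expect_true(any(tr$class == "UNINFORMATIVE"))
  expect_true(all(is.na(tr$ratio[tr$class == "UNINFORMATIVE"])))
  expect_true(all(tr$informative[tr$class == "UNINFORMATIVE"] == 0))
})

test_that("genotype classification uses strict 0.9 / 0.25 thresholds", {
  expect_equal(as.character(classifyGenotype(0.95)), "BRISTOL_HOM")
  expect_equal(as.character(classifyGenotype(0.20)), "HAWAIIAN_HOM")
  expect_equal(as.character(classifyGenotype(0.25)), "HET")
  expect_equal(as.character(classifyGenotype(0.9)), "HET")
  expect_equal(as.character(classifyGenotype(0.90001)), "BRISTOL_HOM")
  expect_equal(as.character(classifyGenotype(0.24999)), "HAWAIIAN_HOM")
  expect_equal(as.character(classifyGenotype(NA)), "UNINFORMATIVE")
  expect_error(classifyGenotype(1.2), "\\[0, 1\\]")
  expect_error(classifyGenotype(-0.1), "\\[0, 1\\]")
})

test_that("crossover calling needs a transition, 15 kb flanks and >1500 reads", {
  tb <- makeCountTable(rep(3, 400), rep(3, 400))
  tr <- glidingRatio(tb)
  expect_equal(nrow(callCrossovers(tr, tb)), 0L)

  ## HET then HAWAIIAN_HOM at ample coverage: one call at the planted spot
  n <- 800; bkpt <- 400
  set.seed(21)
  b <- c(rpois(bkpt, 5), rep(0, n - bkpt))
  h <- rpois(n, 5)
  tb2 <- makeCountTable(b, h)
  calls <- callCrossovers(glidingRatio(tb2), tb2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$left_class, "HET")
  expect_equal(calls$right_class, "HAWAIIAN_HOM")
  expect_lte(abs(calls$midpoint - bkpt * 5000), 50 * 5000)

  ## a 10-kb consistent run on the right is too short
  b3 <- c(rep(40, 100), rep(0, 2))
  h3 <- rep(40, 102)
  tb3 <- makeCountTable(b3, h3)
  tr3 <- data.frame(chrom = "chrII",
                    start = seq(0, by = 5000, length.out = 102),
                    ratio = c(rep(0.5, 100), 0.2, 0.2),
                    informative = 80)
  tr3$class <- classifyGenotype(tr3$ratio)
  expect_equal(nrow(callCrossovers(tr3, tb3)), 0L)

  ## same geometry but with enough windows and too few reads
  b4 <- c(rep(1, 8), rep(0, 8))
  h4 <- rep(1, 16)
  tb4 <- makeCountTable(b4, h4)
  tr4 <- data.frame(chrom = "chrII",
                    start = seq(0, by = 5000, length.out = 16),
                    ratio = rep(c(0.5, 0.2), each = 8),
                    informative = 2)
  tr4$class <- classifyGenotype(tr4$ratio)
  expect_equal(nrow(callCrossovers(tr4, tb4)), 0L)
  ## support is strictly greater-than
  tr4$informative <- 100
  b5 <- c(rep(93, 8), rep(0, 8)); h5 <- rep(c(94, 94), each = 8)
  h5 <- rep(94, 16)
  tb5 <- makeCountTable(b5, h5)  # run sums: 8*187 + 8*94 = 2248 > 1500
  expect_equal(nrow(callCrossovers(tr4, tb5)), 1L)
  b6 <- c(rep(50, 8), rep(0, 8)); h6 <- rep(43, 16)
  tb6 <- makeCountTable(b6, h6)  # run sums: 8*93 + 8*43 = 1088 <= 1500
  expect_equal(nrow(callCrossovers(tr4, tb6)), 0L)
  expect_error(callCrossovers(tr4[1:4, ], tb4), "aligned")
})

test_that("copy number is twice the depth over the diploid baseline", {
  d <- data.frame(chrom = rep(c("I", "II", "X"), each = 20),
                  start = rep(seq(0, by = 50000, length.out = 20), 3),
                  depth = c(rep(100, 20), rep(100, 20), rep(50, 20)))
  cn <- estimateCopyNumber(WindowDepthTable(d))
  expect_equal(cn$mean_copy_number[cn$chrom == "I"], 2)
  expect_equal(cn$mean_copy_number[cn$chrom == "X"], 1)
  d$depth[d$chrom == "X"] <- 150
  cn2 <- estimateCopyNumber(WindowDepthTable(d))
  expect_equal(cn2$mean_copy_number[cn2$chrom == "X"], 3)
  expect_error(estimateCopyNumber(WindowDepthTable(d), baseline = 0),
               "baseline")
})

test_that("ploidy classes split at 1.45 and 2.5 with a closed diploid band", {
  expect_equal(as.character(classifyPloidy(2.0)), "DIPLOID")
  expect_equal(as.character(classifyPloidy(1.0)), "HAPLOID")
  expect_equal(as.character(classifyPloidy(3.0)), "TRIPLOID")
  expect_equal(as.character(classifyPloidy(1.45)), "DIPLOID")
  expect_equal(as.character(classifyPloidy(2.5)), "DIPLOID")
  expect_equal(as.character(classifyPloidy(1.4499)), "HAPLOID")
  expect_equal(as.character(classifyPloidy(2.5001)), "TRIPLOID")
  expect_error(classifyPloidy(-1), "non-negative")
})

test_that("embryo analysis classifies ploidy first and skips aneuploid
           chromosomes for crossover calling", {
  set.seed(9)
  sim <- simulateF2Embryo(coverage = 3, seed = 31)
  ## force a triploid X: set its depth to 1.5x the autosomal baseline
  d <- windowDepth(sim$depth)
  base <- median(d$depth[d$chrom != "X"])
  set.seed(1)
  d$depth[d$chrom == "X"] <- rpois(sum(d$chrom == "X"), 1.5 * base)
  rep1 <- analyzeEmbryo(sim$counts, WindowDepthTable(d))
  expect_equal(as.character(rep1$ploidy$class[rep1$ploidy$chrom == "X"]),
               "TRIPLOID")
  expect_false(rep1$ploidy$co_called[rep1$ploidy$chrom == "X"])
  expect_false("X" %in% rep1$calls$chrom)

  ## crossover-free diploid embryo: no calls anywhere
  sim0 <- simulateF2Embryo(coModel = list(model = "none"), coverage = 3,
                           seed = 32)
  rep0 <- analyzeEmbryo(sim0$counts, sim0$depth)
  expect_equal(nrow(rep0$calls), 0L)

  ## planted single crossover per autosome: all recovered within the
  ## smoothing half-span (250 kb)
  sim1 <- simulateF2Embryo(coModel = list(model = "obligate_one"),
                           coverage = 3, seed = 33)
  rep2 <- analyzeEmbryo(sim1$counts, sim1$depth)
  for (ch in setdiff(names(celegansChromosomes()), "X")) {
    if (!rep2$ploidy$co_called[rep2$ploidy$chrom == ch]) next
    truthBp <- sim1$truth$chromosomes[[ch]]$breakpoints
    got <- rep2$calls$midpoint[rep2$calls$chrom == ch]
    expect_equal(length(got), 1L)
    expect_lte(abs(got - truthBp), 250000)
  }

  ## a chromosome missing from the depth table is skipped with a warning
  d2 <- windowDepth(sim$depth)
  expect_warning(
    rep3 <- analyzeEmbryo(sim$counts,
                          WindowDepthTable(d2[d2$chrom != "V", ])),
    "skipped")
  expect_false("V" %in% rep3$ploidy$chrom)
})

test_that("homozygous Bristol never occurs on simulated diploid autosomes", {
  for (s in 1:5) {
    sim <- simulateF2Embryo(coverage = 3, seed = 60 + s)
    tr <- glidingRatio(sim$counts)
    auto <- tr$chrom != "X"
    expect_false(any(tr$class[auto] == "BRISTOL_HOM"))
  }
})

test_that("call count equals the number of retained run boundaries", {
  set.seed(71)
  for (r in 1:10) {
    n <- 600
    ## random genotype mosaic with long runs
    nseg <- sample(1:4, 1)
    cuts <- sort(sample(50:(n - 50), nseg))
    cls <- rep(sample(c("HET", "HAWAIIAN_HOM")), length.out = nseg + 1)
    lab <- rep(cls, diff(c(0, cuts, n)))
    b <- ifelse(lab == "HET", 5, 0) + rpois(n, 0.2)
    h <- rpois(n, 5)
    tb <- makeCountTable(b, h)
    tr <- glidingRatio(tb)
    calls <- callCrossovers(tr, tb)
    runs <- rle(as.character(tr$class[tr$class != "UNINFORMATIVE"]))
    nb <- sum(runs$lengths * 5000 >= 15000) - 1
    expect_lte(nrow(calls), max(nb, 0))
  }
})
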