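#' Chromosome lengths of the C. elegans genome (bp)
#'
#' Approximate lengths of the six C. elegans chromosomes, used as the
#' default genome for simulated F2 embryos.
#' @return Named numeric vector of lengths in bp.
#' @export
celegansChromosomes <- function() {
  c(I = 15070000, II = 15280000, III = 13780000,
    IV = 17490000, V = 20920000, X = 17720000)
}

.newTruth <- function(model, seed, params, ...) {
  structure(c(list(model = model, seed = seed, params = params),
              list(...)), class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", x$model, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Simulate focus placements under interference models
#'
#' Plants crossover-designation foci on chromosomes under three models:
#' `obligate_one` places exactly one uniformly positioned focus per
#' chromosome (the wild-type regime of one designated crossover per
#' synaptonemal complex); `poisson` places a homogeneous Poisson number of
#' foci (no interference); `gamma_renewal` draws inter-focus gaps from a
#' gamma distribution with the given shape (interference strength),
#' realized by running the renewal process over a long burn-in line and
#' windowing it to the chromosome, which approximates the stationary
#' process. Focus intensities are lognormal with the given mean and
#' coefficient of variation.
#'
#' @param model `"obligate_one"`, `"gamma_renewal"` or `"poisson"`.
#' @param nNuclei number of nuclei to simulate.
#' @param chromosomeLengths named numeric vector of chromosome (trace)
#'   lengths.
#' @param shape gamma shape for `gamma_renewal`.
#' @param meanCount mean focus count per chromosome for `poisson` and
#'   `gamma_renewal`.
#' @param intensityMean,intensityCV lognormal intensity parameters.
#' @param seed integer seed; the output is fully reproducible from it.
#' @return list with `focusSets` (list of [FocusSet-class], ids
#'   `"n<k>_<chrom>"`) and `truth` (a `SyntheticTruth` holding the planted
#'   positions and intensities).
#' @export
simulateFocusPlacement <- function(model = c("obligate_one",
                                             "gamma_renewal", "poisson"),
                                   nNuclei = 100,
                                   chromosomeLengths = c(chr1 = 1),
                                   shape = NULL, meanCount = NULL,
                                   intensityMean = 1, intensityCV = 0.3,
                                   seed = 1) {
  model <- match.arg(model)
  if (any(chromosomeLengths <= 0)) stop("chromosome lengths must be positive")
  if (model != "obligate_one") {
    if (is.null(meanCount) || meanCount <= 0)
      stop("meanCount must be positive for model ", model)
  }
  if (model == "gamma_renewal" && (is.null(shape) || shape <= 0))
    stop("shape must be positive for gamma_renewal")
  set.seed(seed)
  sdlog <- sqrt(log(1 + intensityCV^2))
  mulog <- log(intensityMean) - sdlog^2 / 2
  fs <- list()
  truthPos <- list()
  for (k in seq_len(nNuclei)) {
    for (ch in names(chromosomeLengths)) {
      L <- chromosomeLengths[[ch]]
      pos <- switch(model,
        obligate_one = runif(1, 0, L),
        poisson = sort(runif(rpois(1, meanCount), 0, L)),
        gamma_renewal = {
          meanGap <- L / meanCount
          burn <- 25 * meanGap
          ## draw enough gaps to cross burn-in plus the chromosome
          ng <- max(20, ceiling((burn + L) / meanGap * 2) + 10)
          pts <- -burn + cumsum(rgamma(ng, shape = shape,
                                       scale = meanGap / shape))
          while (max(pts) < L) {
            pts <- c(pts, max(pts) +
                     cumsum(rgamma(ng, shape = shape,
                                   scale = meanGap / shape)))
          }
          pts[pts >= 0 & pts <= L]
        })
      id <- paste0("n", k, "_", ch)
      fs[[id]] <- FocusSet(id, L, pos)
      truthPos[[id]] <- list(positions = as.numeric(pos),
                             intensities = rlnorm(length(pos), mulog, sdlog))
    }
  }
  truth <- .newTruth("focus_placement", seed,
                     list(model = model, nNuclei = nNuclei,
                          chromosomeLengths = as.list(chromosomeLengths),
                          shape = shape, meanCount = meanCount,
                          intensityMean = intensityMean,
                          intensityCV = intensityCV),
                     foci = truthPos)
  list(focusSets = fs, truth = truth)
}

## genotype of the maternal mosaic at positions `at`, given breakpoints
.mosaicIsBristol <- function(at, breakpoints, startsBristol) {
  nLeft <- findInterval(at, sort(breakpoints))
  (nLeft %% 2 == 0) == startsBristol
}

#' Simulate one backcross F2 embryo
#'
#' Emulates the sequencing readout of a single F2 embryo from a
#' Bristol/Hawaiian hybrid hermaphrodite backcrossed to a Hawaiian male.
#' Each maternal chromosome is a Bristol/Hawaiian mosaic whose breakpoints
#' are drawn from the crossover model; the paternal chromosome is always
#' Hawaiian. The X is transmitted by the sperm with probability 1/2
#' (Mendelian male X segregation), so roughly half the embryos are male
#' with a haploid X. Optional nondisjunction adds or removes one copy of
#' a chromosome. Read counts per 5-kb window and total depth per 50-kb
#' window are Poisson at the requested coverage, with strain-informative
#' reads a thinned fraction of the total.
#'
#' @param coModel list describing the crossover model for maternal
#'   breakpoints: `list(model = "obligate_one")`,
#'   `list(model = "poisson", meanCount = )`,
#'   `list(model = "gamma_renewal", shape = , meanCount = )` or
#'   `list(model = "none")` for crossover-free chromosomes.
#' @param chromosomeLengths named chromosome lengths in bp; names ending
#'   in `xChrom` mark the sex chromosome.
#' @param coverage mean genome coverage of the diploid genome (the study
#'   regime is roughly 1.8-6.7x).
#' @param windowSize,depthWindow 5-kb count and 50-kb depth window sizes.
#' @param informativeFraction fraction of reads that map exclusively to
#'   one strain.
#' @param readLength read length in bp used to convert coverage to read
#'   counts.
#' @param xChrom name of the sex chromosome.
#' @param nondisjunctionP per-chromosome probability of gaining or losing
#'   one copy.
#' @param seed integer seed.
#' @return list with `counts` ([WindowCountTable-class]), `depth`
#'   ([WindowDepthTable-class]) and `truth` (planted breakpoints, copy
#'   numbers and per-chromosome genotype structure).
#' @export
simulateF2Embryo <- function(coModel = list(model = "obligate_one"),
                             chromosomeLengths = celegansChromosomes(),
                             coverage = 3, windowSize = 5000,
                             depthWindow = 50000,
                             informativeFraction = 0.3, readLength = 150,
                             xChrom = "X", nondisjunctionP = 0, seed = 1) {
  if (coverage <= 0 || informativeFraction <= 0 || informativeFraction > 1)
    stop("invalid coverage or informativeFraction")
  set.seed(seed)
  muPerCopy <- coverage / 2 * windowSize / readLength
  muDepthPerCopy <- coverage / 2 * depthWindow / readLength
  countsL <- list(); depthL <- list(); truthCh <- list()
  for (ch in names(chromosomeLengths)) {
    L <- chromosomeLengths[[ch]]
    isX <- ch %in% xChrom
    bp <- switch(coModel$model,
      none = numeric(),
      obligate_one = runif(1, 0, L),
      poisson = sort(runif(rpois(1, coModel$meanCount), 0, L)),
      gamma_renewal = {
        meanGap <- L / coModel$meanCount
        burn <- 25 * meanGap
        ng <- max(20, ceiling((burn + L) / meanGap * 2) + 10)
        pts <- -burn + cumsum(rgamma(ng, shape = coModel$shape,
                                     scale = meanGap / coModel$shape))
        pts[pts >= 0 & pts <= L]
      },
      stop("unknown crossover model: ", coModel$model))
    startsBristol <- runif(1) < 0.5
    paternalPresent <- if (isX) runif(1) < 0.5 else TRUE
    ## copy multiplicities: maternal mosaic and (optionally) paternal H
    matCopies <- 1L
    patCopies <- as.integer(paternalPresent)
    if (nondisjunctionP > 0 && runif(1) < nondisjunctionP) {
      total <- matCopies + patCopies
      if (runif(1) < 0.5 || total == 0L) { # gain a copy
        if (runif(1) < matCopies / max(total, 1L)) matCopies <- matCopies + 1L
        else patCopies <- patCopies + 1L
      } else {                             # lose a copy
        if (runif(1) < matCopies / total) matCopies <- matCopies - 1L
        else patCopies <- patCopies - 1L
      }
    }
    starts <- seq(0, L - windowSize, by = windowSize)
    mids <- starts + windowSize / 2
    matB <- .mosaicIsBristol(mids, bp, startsBristol)
    nB <- matCopies * as.integer(matB)
    nH <- matCopies * as.integer(!matB) + patCopies
    bristol <- rpois(length(starts), muPerCopy * informativeFraction * nB)
    hawaiian <- rpois(length(starts), muPerCopy * informativeFraction * nH)
    countsL[[ch]] <- data.frame(chrom = ch, start = starts,
                                bristol = bristol, hawaiian = hawaiian)
    dstarts <- seq(0, L - depthWindow, by = depthWindow)
    copies <- matCopies + patCopies
    depthL[[ch]] <- data.frame(chrom = ch, start = dstarts,
                               depth = rpois(length(dstarts),
                                             muDepthPerCopy * copies))
    truthCh[[ch]] <- list(breakpoints = as.numeric(bp),
                          startsBristol = startsBristol,
                          maternalCopies = matCopies,
                          paternalCopies = patCopies,
                          copies = copies, isX = isX)
  }
  truth <- .newTruth("f2_embryo", seed,
                     list(coModel = coModel, coverage = coverage,
                          windowSize = windowSize,
                          depthWindow = depthWindow,
                          informativeFraction = informativeFraction,
                          readLength = readLength,
                          nondisjunctionP = nondisjunctionP,
                          chromosomeLengths = as.list(chromosomeLengths)),
                     chromosomes = truthCh)
  list(counts = WindowCountTable(do.call(rbind, countsL), windowSize),
       depth = WindowDepthTable(do.call(rbind, depthL), depthWindow),
       truth = truth)
}

## voxel-centre coordinate grids for a (z, y, x) array
.voxelCentres <- function(dims, vs) {
  list(z = ((seq_len(dims[1])) - 0.5) * vs[1],
       y = ((seq_len(dims[2])) - 0.5) * vs[2],
       x = ((seq_len(dims[3])) - 0.5) * vs[3])
}

#' Simulate a 3D germline stack with known ground truth
#'
#' Builds a labeled 3D stack emulating a gonad arm: spherical nuclei
#' placed along a gently curved row, an axis channel in which a smooth
#' random filament (the synaptonemal-complex/axis signal) inside each
#' nucleus carries a planted fraction `axisRatio` of the
#' background-corrected nuclear signal, and a focus channel with 3D
#' Gaussian spots of lognormal amplitude at planted positions. Noise is
#' Poisson shot noise plus Gaussian read noise; a finite `snr` adds
#' read noise so the peak contrast-to-noise ratio of each channel equals
#' `snr`, while `snr = Inf` leaves shot and baseline read noise only, and
#' `noise = FALSE` produces a noise-free stack.
#'
#' @param nNuclei number of nuclei.
#' @param nucleusRadius nucleus radius in um.
#' @param voxelSizeUm voxel size `(z, y, x)` in um.
#' @param axisRatio planted axis/nucleus intensity fraction.
#' @param fociPerNucleus planted focus count per nucleus.
#' @param focusSigmaUm isotropic Gaussian sigma of a focus, um.
#' @param focusAmplitude mean focus peak amplitude.
#' @param intensityCV lognormal CV of focus amplitudes.
#' @param nucleoplasmLevel mean nucleoplasmic intensity (axis channel).
#' @param focusBaseLevel nucleoplasmic intensity of the focus channel.
#' @param backgroundLevel intensity outside nuclei (both channels).
#' @param snr peak contrast-to-total-noise ratio per channel.
#' @param readNoiseSD baseline Gaussian read noise (camera noise floor).
#' @param noise set `FALSE` for a completely noise-free stack.
#' @param bendAmplitude amplitude (um) of the sinusoidal bend of the row.
#' @param seed integer seed.
#' @return list with `volume` (a [LabeledVolume-class] with channels
#'   `"axis"` and `"foci"`) and `truth` (planted nucleus centres, focus
#'   positions/amplitudes, filament voxel counts, axis ratio).
#' @export
simulateGermlineStack <- function(nNuclei = 20, nucleusRadius = 2,
                                  voxelSizeUm = c(0.25, 0.25, 0.25),
                                  axisRatio = 0.7, fociPerNucleus = 0,
                                  focusSigmaUm = 0.2,
                                  focusAmplitude = 500, intensityCV = 0.3,
                                  nucleoplasmLevel = 50,
                                  focusBaseLevel = 20,
                                  backgroundLevel = 10, snr = Inf,
                                  readNoiseSD = 5, noise = TRUE,
                                  bendAmplitude = 1, seed = 1) {
  stopifnot(nNuclei >= 1, nucleusRadius > 0, axisRatio > 0, axisRatio < 1)
  set.seed(seed)
  vs <- voxelSizeUm
  R <- nucleusRadius
  spacing <- 2 * R + 1
  marg <- R + 1
  ext <- c(2 * (R + 1) + 2 * bendAmplitude,
           2 * (R + 1) + 2 * bendAmplitude,
           2 * marg + (nNuclei - 1) * spacing)  # (z, y, x) um
  dims <- ceiling(ext / vs)
  grid <- .voxelCentres(dims, vs)
  labels <- array(0L, dims)
  axisCh <- array(backgroundLevel, dims)
  fociCh <- array(backgroundLevel, dims)
  centres <- matrix(NA_real_, nNuclei, 3,
                    dimnames = list(NULL, c("z", "y", "x")))
  truthNuc <- list()
  maxF <- 0
  for (k in seq_len(nNuclei)) {
    cx <- marg + (k - 1) * spacing
    cy <- ext[2] / 2 + bendAmplitude * sin(2 * pi * cx / (ext[3] + 1))
    cz <- ext[1] / 2
    centres[k, ] <- c(cz, cy, cx)
    ## bounding box in voxels
    lo <- pmax(floor((centres[k, ] - R) / vs), 1)
    hi <- pmin(ceiling((centres[k, ] + R) / vs), dims)
    zz <- grid$z[lo[1]:hi[1]]; yy <- grid$y[lo[2]:hi[2]]
    xx <- grid$x[lo[3]:hi[3]]
    dz2 <- (zz - cz)^2
    dy2 <- (yy - cy)^2
    dx2 <- (xx - cx)^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    inside <- d2 <= R^2
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (any(sub[inside] != 0L)) stop("nucleus placement overlap")
    sub[inside] <- k
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    ## filament: smooth closed Lissajous curve inside the nucleus
    ph <- runif(3, 0, 2 * pi)
    tt <- seq(0, 2 * pi, length.out = 400)
    amp <- 0.55 * R
    curve <- cbind(cz + amp * sin(2 * tt + ph[1]),
                   cy + amp * sin(3 * tt + ph[2]),
                   cx + amp * sin(5 * tt + ph[3]))
    boxIdx <- which(inside, arr.ind = TRUE)
    coords <- cbind(zz[boxIdx[, 1]], yy[boxIdx[, 2]], xx[boxIdx[, 3]])
    dmin2 <- .nearest(coords, curve)$dist^2
    filam <- dmin2 <= 0.3^2
    V <- nrow(coords)
    nAx <- sum(filam)
    if (axisRatio * V <= nAx)
      stop("axisRatio too small for the filament volume; increase it")
    u <- nucleoplasmLevel
    f <- u * (axisRatio * V - nAx) / (nAx * (1 - axisRatio))
    aSub <- axisCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    insIdx <- which(inside)
    aSub[insIdx] <- backgroundLevel + u
    aSub[insIdx[filam]] <- backgroundLevel + u + f
    axisCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- aSub
    ## foci: planted away from the nucleus boundary
    fpos <- NULL; famp <- numeric()
    if (fociPerNucleus > 0) {
      sdlog <- sqrt(log(1 + intensityCV^2))
      mulog <- log(focusAmplitude) - sdlog^2 / 2
      famp <- rlnorm(fociPerNucleus, mulog, sdlog)
      ## rejection-sample positions with a minimum mutual separation,
      ## relaxing the separation when the packing is too tight to find
      minSep <- 6 * focusSigmaUm
      restarts <- 0L
      repeat {
        fpos <- matrix(NA_real_, fociPerNucleus, 3)
        ok <- TRUE
        for (j in seq_len(fociPerNucleus)) {
          placed <- FALSE
          for (tries in 1:500) {
            cand <- centres[k, ] + runif(3, -0.8 * R, 0.8 * R)
            if (sum((cand - centres[k, ])^2) > (0.8 * R)^2) next
            if (j > 1L &&
                min(rowSums((fpos[seq_len(j - 1L), , drop = FALSE] -
                             rep(cand, each = j - 1L))^2)) < minSep^2) next
            fpos[j, ] <- cand
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) break
        restarts <- restarts + 1L
        if (restarts %% 10L == 0L) minSep <- 0.8 * minSep
      }
      fSub <- fociCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      fSub[insIdx] <- backgroundLevel + focusBaseLevel
      for (j in seq_len(fociPerNucleus)) {
        dd2 <- rowSums((coords - rep(fpos[j, ], each = V))^2)
        fSub[insIdx] <- fSub[insIdx] +
          famp[j] * exp(-dd2 / (2 * focusSigmaUm^2))
      }
      fociCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- fSub
      maxF <- max(maxF, famp)
    } else {
      fSub <- fociCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      fSub[insIdx] <- backgroundLevel + focusBaseLevel
      fociCh[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- fSub
    }
    truthNuc[[k]] <- list(centre = centres[k, ], nVoxels = V,
                          filamentVoxels = nAx,
                          focusPositions = fpos, focusAmplitudes = famp)
  }
  addNoise <- function(img, peakContrast) {
    if (!noise) return(img)
    extra2 <- if (is.finite(snr))
      max((peakContrast / snr)^2 - peakContrast - readNoiseSD^2, 0) else 0
    out <- array(rpois(length(img), lambda = img), dim(img))
    out + array(rnorm(length(img), 0, sqrt(readNoiseSD^2 + extra2)),
                dim(img))
  }
  ## snr is defined against the nominal planted contrast of each channel:
  ## the mean filament excess for the axis channel, the mean focus
  ## amplitude for the focus channel
  axisPeak <- max(axisCh) - backgroundLevel - nucleoplasmLevel
  axisCh <- addNoise(axisCh, max(axisPeak, 1))
  fociCh <- addNoise(fociCh, if (fociPerNucleus > 0) focusAmplitude else 1)
  vol <- LabeledVolume(list(axis = axisCh, foci = fociCh), labels, vs)
  truth <- .newTruth("germline_stack", seed,
                     list(nNuclei = nNuclei, nucleusRadius = R,
                          voxelSizeUm = as.numeric(vs),
                          axisRatio = axisRatio,
                          fociPerNucleus = fociPerNucleus,
                          focusSigmaUm = focusSigmaUm,
                          focusAmplitude = focusAmplitude,
                          intensityCV = intensityCV,
                          nucleoplasmLevel = nucleoplasmLevel,
                          focusBaseLevel = focusBaseLevel,
                          backgroundLevel = backgroundLevel,
                          snr = snr, readNoiseSD = readNoiseSD,
                          noise = noise),
                     nuclei = truthNuc)
  list(volume = vol, truth = truth)
}

#' Simulate per-nucleus axis-ratio records with gonad structure
#'
#' Convenience generator for testing the mixed-model genotype contrast:
#' per-nucleus axis/nucleus ratios with a planted genotype effect, a
#' random gonad-level intercept and residual noise.
#'
#' @param genotypeMeans named numeric vector: mean ratio per genotype.
#' @param gonadsPerGenotype number of gonads (animals) per genotype.
#' @param nucleiPerGonad nuclei measured per gonad.
#' @param gonadSD between-gonad standard deviation.
#' @param residSD within-gonad (residual) standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns `genotype`, `gonad`, `axis_ratio`.
#' @export
simulateRatioRecords <- function(genotypeMeans = c(WT = 0.6, mut = 0.5),
                                 gonadsPerGenotype = 6,
                                 nucleiPerGonad = 30, gonadSD = 0.02,
                                 residSD = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(genotypeMeans)) {
    for (a in seq_len(gonadsPerGenotype)) {
      mu <- genotypeMeans[[g]] + rnorm(1, 0, gonadSD)
      rows[[paste(g, a)]] <- data.frame(
        genotype = g, gonad = paste0(g, "_gonad", a),
        axis_ratio = mu + rnorm(nucleiPerGonad, 0, residSD))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
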