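.GENOTYPE_LEVELS <- c("BRISTOL_HOM", "HET", "HAWAIIAN_HOM", "UNINFORMATIVE")

#' Gliding allele-ratio track
#'
#' For every 5-kb window, computes the ratio of Bristol-specific reads to
#' all strain-specific (informative) reads over a centered span of `span`
#' windows, truncated at chromosome ends. The ratio is a ratio of sums
#' (not a mean of per-window ratios), which is robust to empty windows.
#' Windows whose whole span contains zero informative reads are marked
#' `UNINFORMATIVE`.
#'
#' @param table a [WindowCountTable-class].
#' @param span number of windows in the gliding span (default 100).
#' @return A data.frame (genotype track) with columns `chrom`, `start`,
#'   `ratio`, `informative` (informative reads in the span) and `class`
#'   (see [classifyGenotype()]).
#' @export
glidingRatio <- function(table, span = 100) {
  stopifnot(is(table, "WindowCountTable"))
  validObject(table)
  if (length(span) != 1L || is.na(span) || span < 1)
    stop("invalid parameter: 'span' must be >= 1")
  span <- as.integer(span)
  df <- windowCounts(table)
  halfL <- (span - 1L) %/% 2L
  halfR <- span - 1L - halfL
  res <- lapply(split(df, df$chrom), function(d) {
    n <- nrow(d)
    cb <- cumsum(c(0, d$bristol))
    ch <- cumsum(c(0, d$hawaiian))
    i <- seq_len(n)
    lo <- pmax(i - halfL, 1L)
    hi <- pmin(i + halfR, n)
    sb <- cb[hi + 1L] - cb[lo]
    sh <- ch[hi + 1L] - ch[lo]
    tot <- sb + sh
    r <- ifelse(tot > 0, sb / tot, NA_real_)
    data.frame(chrom = d$chrom, start = d$start, ratio = r,
               informative = tot)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$class <- classifyGenotype(out$ratio)
  out
}

#' Classify a smoothed allele ratio into a genotype
#'
#' Ratios above 0.9 are homozygous Bristol, ratios below 0.25 homozygous
#' Hawaiian (both strict inequalities), everything in between heterozygous.
#' `NA` ratios (no informative reads in the span) are `UNINFORMATIVE`.
#'
#' @param r numeric vector of ratios in `[0, 1]` (NA allowed).
#' @param bristolMin threshold above which a ratio is homozygous Bristol.
#' @param hawaiianMax threshold below which a ratio is homozygous Hawaiian.
#' @return Factor with levels `BRISTOL_HOM`, `HET`, `HAWAIIAN_HOM`,
#'   `UNINFORMATIVE`.
#' @export
classifyGenotype <- function(r, bristolMin = 0.9, hawaiianMax = 0.25) {
  r <- as.numeric(r)
  if (any(r < 0 | r > 1, na.rm = TRUE))
    stop("invalid input: ratios must lie in [0, 1]")
  cls <- rep("HET", length(r))
  cls[r > bristolMin] <- "BRISTOL_HOM"
  cls[r < hawaiianMax] <- "HAWAIIAN_HOM"
  cls[is.na(r)] <- "UNINFORMATIVE"
  factor(cls, levels = .GENOTYPE_LEVELS)
}

## Run-length encode the genotype classes of one chromosome, bridging
## UNINFORMATIVE stretches shorter than minFlank into the neighbouring
## run: a short uninformative run between two runs of the same class is
## absorbed into that class; between differing classes it is attached to
## the left run, so the reported breakpoint interval spans it. Long
## uninformative runs break continuity and no crossover is called across
## them.
.genotypeRuns <- function(cls, windowSize, minFlank) {
  r <- rle(as.character(cls))
  ends <- cumsum(r$lengths)
  runs <- data.frame(class = r$values, from = ends - r$lengths + 1L,
                     to = ends)
  repeat {
    short <- which(runs$class == "UNINFORMATIVE" &
                   (runs$to - runs$from + 1L) * windowSize < minFlank)
    if (!length(short)) break
    i <- short[1]
    if (i > 1L) {
      runs$to[i - 1L] <- runs$to[i]
      runs <- runs[-i, , drop = FALSE]
    } else if (nrow(runs) > 1L) {
      runs$from[2L] <- runs$from[1L]
      runs <- runs[-1L, , drop = FALSE]
    } else break
    ## merge neighbours that became identical
    r2 <- rle(runs$class)
    if (any(r2$lengths > 1L)) {
      e2 <- cumsum(r2$lengths)
      s2 <- e2 - r2$lengths + 1L
      runs <- data.frame(class = r2$values, from = runs$from[s2],
                         to = runs$to[e2])
    }
  }
  rownames(runs) <- NULL
  runs
}

#' Call crossovers from a genotype track
#'
#' Identifies crossovers as transitions between runs of different genotype
#' classes. A transition is retained only when the consistent genotype run
#' on each side spans at least `minFlank` bp and the informative
#' (strain-specific) reads summed over the two flanking runs exceed
#' `minReads`. The breakpoint is reported as the interval from the end of
#' the last window of the left run to the start of the first window of the
#' right run.
#'
#' @param track genotype track from [glidingRatio()].
#' @param table the matching [WindowCountTable-class] (raw counts supply
#'   the read support).
#' @param minReads support threshold; strictly more reads are required.
#' @param minFlank minimum consistent-genotype flank, in bp.
#' @return A data.frame of crossover calls with columns `chrom`, `left`,
#'   `right`, `left_class`, `right_class`, `support_reads`,
#'   `left_flank`, `right_flank` and `midpoint`.
#' @export
callCrossovers <- function(track, table, minReads = 1500, minFlank = 15000) {
  stopifnot(is(table, "WindowCountTable"))
  df <- windowCounts(table)
  if (nrow(track) != nrow(df) ||
      !all(track$chrom == df$chrom & track$start == df$start))
    stop("invalid input: track and count table are not aligned")
  ws <- windowSize(table)
  empty <- data.frame(chrom = character(), left = numeric(),
                      right = numeric(), left_class = character(),
                      right_class = character(), support_reads = numeric(),
                      left_flank = numeric(), right_flank = numeric(),
                      midpoint = numeric())
  res <- lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
    d <- df[idx, , drop = FALSE]
    cls <- track$class[idx]
    runs <- .genotypeRuns(cls, ws, minFlank)
    runs <- runs[runs$class != "UNINFORMATIVE" |
                 (runs$to - runs$from + 1L) * ws >= minFlank, , drop = FALSE]
    if (nrow(runs) < 2L) return(empty)
    inf <- d$bristol + d$hawaiian
    calls <- empty
    for (i in seq_len(nrow(runs) - 1L)) {
      a <- runs[i, ]; b <- runs[i + 1L, ]
      if (a$class == "UNINFORMATIVE" || b$class == "UNINFORMATIVE") next
      if (a$class == b$class) next
      flankL <- (a$to - a$from + 1L) * ws
      flankR <- (b$to - b$from + 1L) * ws
      if (flankL < minFlank || flankR < minFlank) next
      support <- sum(inf[a$from:a$to]) + sum(inf[b$from:b$to])
      if (support <= minReads) next
      left <- d$start[a$to] + ws
      right <- d$start[b$from]
      calls <- rbind(calls, data.frame(
        chrom = d$chrom[1], left = left, right = right,
        left_class = a$class, right_class = b$class,
        support_reads = support, left_flank = flankL,
        right_flank = flankR, midpoint = (left + right) / 2))
    }
    calls
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Depth-normalized copy number per chromosome
#'
#' Copy number per 50-kb window is `2 * depth / baseline`, with the
#' baseline the median per-window depth over chromosomes assumed diploid
#' (by default all autosomes, i.e. every chromosome except `xChrom`), so
#' that a chromosome at baseline depth has copy number 2.
#'
#' @param depthTable a [WindowDepthTable-class].
#' @param baseline optional externally supplied baseline depth (`> 0`).
#' @param xChrom name of the sex chromosome excluded from the default
#'   baseline (default `"X"`).
#' @return data.frame with columns `chrom` and `mean_copy_number`.
#' @export
estimateCopyNumber <- function(depthTable, baseline = NULL, xChrom = "X") {
  stopifnot(is(depthTable, "WindowDepthTable"))
  validObject(depthTable)
  d <- windowDepth(depthTable)
  if (is.null(baseline)) {
    auto <- d$depth[!(d$chrom %in% xChrom)]
    if (!length(auto)) stop("no autosomal windows to derive a baseline from")
    baseline <- median(auto)
  }
  if (!is.finite(baseline) || baseline <= 0)
    stop("invalid parameter: baseline depth must be positive")
  cn <- 2 * d$depth / baseline
  agg <- tapply(cn, d$chrom, mean)
  data.frame(chrom = names(agg), mean_copy_number = as.numeric(agg),
             row.names = NULL)
}

#' Classify chromosome ploidy from mean copy number
#'
#' Chromosomes with mean copy number between 1.45 and 2.5 (closed interval)
#' are diploid, below 1.45 haploid, above 2.5 triploid.
#'
#' @param meanCN numeric vector of non-negative mean copy numbers.
#' @param bounds haploid/diploid and diploid/triploid boundaries.
#' @return Factor with levels `HAPLOID`, `DIPLOID`, `TRIPLOID`.
#' @export
classifyPloidy <- function(meanCN, bounds = c(1.45, 2.5)) {
  meanCN <- as.numeric(meanCN)
  if (any(meanCN < 0, na.rm = TRUE))
    stop("invalid input: copy number must be non-negative")
  cls <- rep("DIPLOID", length(meanCN))
  cls[meanCN < bounds[1]] <- "HAPLOID"
  cls[meanCN > bounds[2]] <- "TRIPLOID"
  factor(cls, levels = c("HAPLOID", "DIPLOID", "TRIPLOID"))
}

#' Analyze one F2 embryo: ploidy first, then crossovers on diploid
#' chromosomes
#'
#' Classifies the ploidy of every chromosome from the 50-kb depth table and
#' calls crossovers only on chromosomes classified diploid; non-diploid
#' chromosomes are flagged and excluded from crossover calling, since a
#' genotype transition on an aneuploid chromosome is not interpretable as a
#' simple crossover. Chromosomes missing from either table are skipped
#' with a warning.
#'
#' @param countTable a [WindowCountTable-class] (5-kb windows).
#' @param depthTable a [WindowDepthTable-class] (50-kb windows).
#' @param span,minReads,minFlank see [glidingRatio()] and
#'   [callCrossovers()].
#' @param baseline,xChrom see [estimateCopyNumber()].
#' @param ploidyBounds see [classifyPloidy()].
#' @return A list of class `embryoReport` with elements `ploidy`
#'   (data.frame: chrom, mean_copy_number, class, co_called), `calls`
#'   (crossover calls on diploid chromosomes) and `skipped` (chromosome
#'   names absent from one of the tables).
#' @export
analyzeEmbryo <- function(countTable, depthTable, span = 100,
                          minReads = 1500, minFlank = 15000,
                          baseline = NULL, xChrom = "X",
                          ploidyBounds = c(1.45, 2.5)) {
  stopifnot(is(countTable, "WindowCountTable"),
            is(depthTable, "WindowDepthTable"))
  cc <- unique(windowCounts(countTable)$chrom)
  dc <- unique(windowDepth(depthTable)$chrom)
  skipped <- union(setdiff(cc, dc), setdiff(dc, cc))
  if (length(skipped))
    warning("chromosome(s) missing from one table, skipped: ",
            paste(skipped, collapse = ", "))
  keep <- intersect(cc, dc)
  cn <- estimateCopyNumber(depthTable, baseline = baseline, xChrom = xChrom)
  cn <- cn[cn$chrom %in% keep, , drop = FALSE]
  cn$class <- classifyPloidy(cn$mean_copy_number, bounds = ploidyBounds)
  cn$co_called <- cn$class == "DIPLOID"
  dip <- cn$chrom[cn$co_called]
  cdf <- windowCounts(countTable)
  sel <- cdf$chrom %in% dip
  if (any(sel)) {
    sub <- WindowCountTable(cdf[sel, , drop = FALSE],
                            windowSize = windowSize(countTable))
    track <- glidingRatio(sub, span = span)
    calls <- callCrossovers(track, sub, minReads = minReads,
                            minFlank = minFlank)
  } else {
    calls <- callCrossovers(glidingRatio(countTable, span = span),
                            countTable, minReads, minFlank)[0, ]
  }
  structure(list(ploidy = cn, calls = calls, skipped = skipped),
            class = "embryoReport")
}

#' @export
print.embryoReport <- function(x, ...) {
  cat("F2 embryo report:\n")
  print(x$ploidy)
  cat(sprintf("%d crossover call(s) on diploid chromosomes\n",
              nrow(x$calls)))
  if (length(x$skipped))
    cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
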