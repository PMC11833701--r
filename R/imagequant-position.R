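#' Normalized germline position by local-regression straightening
#'
#' The germline is a curved tube along which nuclei progress through
#' meiosis, so a nucleus's position along the tube encodes its meiotic
#' stage. The tube's centre line is recovered by locally weighted
#' regression (loess) of the transverse centroid coordinates against the
#' leading principal axis of all centroids; each nucleus is then assigned
#' the arc length of its projection onto the fitted curve, and arc length
#' is mapped linearly so the annotated start lands at 0 and the annotated
#' end at 1. Positions outside `[0, 1]` are kept but flagged.
#'
#' @param centroids numeric matrix or data.frame with three columns
#'   `(z, y, x)` in micrometres; at least 10 nuclei.
#' @param annotations list with elements `start` and `end`: row indices of
#'   the nuclei marking the annotated zone boundaries (e.g. beginning of
#'   the transition zone and end of pachytene). The orientation is taken
#'   from the annotations, so `start` may lie on either end of the curve.
#' @param span,degree loess span and degree for the centre line.
#' @return data.frame with columns `position` (normalized) and `flagged`
#'   (`TRUE` outside `[0, 1]`).
#' @export
straightenPositions <- function(centroids, annotations, span = 0.5,
                                degree = 2) {
  xyz <- as.matrix(centroids)
  if (ncol(xyz) != 3L) stop("centroids must have 3 columns (z, y, x)")
  if (nrow(xyz) < 10L) stop("need at least 10 nuclei to fit a centre line")
  if (all(apply(xyz, 2, function(v) max(v) - min(v)) < 1e-9))
    stop("degenerate input: all centroids coincide")
  ctr <- colMeans(xyz)
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  t0 <- pc$x[, 1]
  ## centre line: transverse coordinates regressed on the long axis
  fit2 <- loess(pc$x[, 2] ~ t0, span = span, degree = degree)
  fit3 <- loess(pc$x[, 3] ~ t0, span = span, degree = degree)
  tg <- seq(min(t0), max(t0), length.out = 512)
  curve <- cbind(tg, predict(fit2, data.frame(t0 = tg)),
                 predict(fit3, data.frame(t0 = tg)))
  seg <- sqrt(rowSums(diff(curve)^2))
  arcg <- c(0, cumsum(seg))
  arc <- approx(tg, arcg, xout = t0, rule = 2)$y
  a0 <- arc[annotations$start]
  a1 <- arc[annotations$end]
  if (length(a0) != 1L || length(a1) != 1L || a0 == a1)
    stop("annotations must give distinct start and end nuclei")
  pos <- (arc - a0) / (a1 - a0)
  data.frame(position = pos, flagged = pos < 0 | pos > 1)
}

#' Binned profile along the normalized germline axis
#'
#' Partitions `[0, 1]` into `nbins` equal-width bins and reports the mean,
#' standard error and count of `values` per bin (the 11-bin pachytene
#' profile presentation). Empty bins carry `NA` means and `n = 0`.
#'
#' @param positions normalized positions in `[0, 1]`.
#' @param values values to profile, same length.
#' @param nbins number of bins (default 11).
#' @return data.frame with `bin_lo`, `bin_hi`, `mid`, `mean`, `se`, `n`.
#' @export
profileBins <- function(positions, values, nbins = 11) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  if (any(positions < 0 | positions > 1, na.rm = TRUE))
    stop("positions must lie in [0, 1]")
  edges <- seq(0, 1, length.out = nbins + 1)
  bin <- findInterval(positions, edges, rightmost.closed = TRUE)
  out <- data.frame(bin_lo = edges[-(nbins + 1)], bin_hi = edges[-1])
  out$mid <- (out$bin_lo + out$bin_hi) / 2
  out$mean <- NA_real_
  out$se <- NA_real_
  out$n <- 0L
  for (b in seq_len(nbins)) {
    v <- values[bin == b & !is.na(values)]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$se[b] <- if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
    }
  }
  out
}

#' Genotype contrast of axis retention under hexanediol, with gonad as a
#' random effect
#'
#' Hexanediol sensitivity of the synaptonemal complex is read out as the
#' drop in the axis/nucleus intensity ratio. Because nuclei within one
#' gonad are not independent, the genotype contrast is fitted as a linear
#' mixed-effects model with genotype as fixed effect and gonad as a random
#' intercept, and the reported p-value uses Satterthwaite degrees of
#' freedom.
#'
#' @param records data.frame with one row per nucleus.
#' @param value column holding the axis/nucleus ratio.
#' @param genotype,gonad grouping columns; each genotype must contribute
#'   at least two gonads, otherwise the random effect is unidentifiable.
#' @param reference genotype treated as the baseline level.
#' @return data.frame with one row per non-reference genotype: `genotype`,
#'   `estimate`, `se`, `df`, `p_value`; the fitted model is attached as
#'   attribute `"model"`.
#' @export
hexanediolContrast <- function(records, value = "axis_ratio",
                               genotype = "genotype", gonad = "gonad",
                               reference = NULL) {
  for (cc in c(value, genotype, gonad))
    if (!cc %in% names(records)) stop("missing column: ", cc)
  d <- data.frame(y = records[[value]],
                  genotype = factor(records[[genotype]]),
                  gonad = factor(paste(records[[genotype]],
                                       records[[gonad]], sep = ":")))
  ng <- tapply(as.character(d$gonad), d$genotype,
               function(g) length(unique(g)))
  if (any(ng < 2))
    stop("genotype(s) with a single gonad: ",
         paste(names(ng)[ng < 2], collapse = ", "),
         " (random effect unidentifiable)")
  if (!is.null(reference)) d$genotype <- relevel(d$genotype, reference)
  m <- lmerTest::lmer(y ~ genotype + (1 | gonad), data = d)
  co <- summary(m)$coefficients
  rows <- grep("^genotype", rownames(co))
  out <- data.frame(genotype = sub("^genotype", "", rownames(co)[rows]),
                    estimate = co[rows, "Estimate"],
                    se = co[rows, "Std. Error"],
                    df = co[rows, "df"],
                    p_value = co[rows, "Pr(>|t|)"],
                    row.names = NULL)
  attr(out, "model") <- m
  out
}
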