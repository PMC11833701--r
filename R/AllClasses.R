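#' @import methods
NULL

#' FocusSet: ordered focus or crossover positions on one chromosome
#'
#' A `FocusSet` holds the ordered coordinates of crossover-associated foci
#' (e.g. COSA-1 foci along a synaptonemal-complex trace) or genetic crossover
#' midpoints along one physical chromosome. Coordinates are in the same unit
#' as `length` (micrometres for cytological traces, base pairs for genomic
#' chromosomes).
#'
#' @slot chromosomeId single character identifier; must be unique per
#'   physical chromosome (e.g. `"nucleus3_chrII"`), since inter-focus
#'   distances are formed within a `FocusSet` only.
#' @slot length positive chromosome (or trace) length.
#' @slot positions numeric vector, sorted ascending, all within
#'   `[0, length]`.
#'
#' @export
setClass("FocusSet",
  representation(chromosomeId = "character",
                 length = "numeric",
                 positions = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@chromosomeId) != 1L)
      msg <- c(msg, "chromosomeId must be a single string")
    if (length(object@length) != 1L || !is.finite(object@length) ||
        object@length <= 0)
      msg <- c(msg, "length must be a single positive number")
    p <- object@positions
    if (anyNA(p)) msg <- c(msg, "positions must not contain NA")
    if (is.unsorted(p)) msg <- c(msg, "positions must be sorted ascending")
    if (length(p) && (min(p) < 0 || max(p) > object@length))
      msg <- c(msg, "positions must lie within [0, length]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FocusSet
#'
#' @param chromosomeId chromosome identifier, unique per physical chromosome.
#' @param length chromosome length (same unit as `positions`).
#' @param positions numeric focus coordinates; sorted internally.
#' @return A [FocusSet-class] object.
#' @examples
#' FocusSet("nuc1_chrI", 15, c(3, 9))
#' @export
FocusSet <- function(chromosomeId, length, positions = numeric()) {
  new("FocusSet", chromosomeId = as.character(chromosomeId),
      length = as.numeric(length),
      positions = sort(as.numeric(positions)))
}

setMethod("show", "FocusSet", function(object) {
  cat("FocusSet", object@chromosomeId,
      sprintf("(length %g, %d foci)\n", object@length,
              length(object@positions)))
})

#' @describeIn FocusSet number of foci
#' @param x a `FocusSet`
#' @export
setMethod("length", "FocusSet", function(x) length(x@positions))

#' Accessors for FocusSet
#' @param object a [FocusSet-class]
#' @return `focusPositions` returns the numeric positions,
#'   `chromosomeLength` the chromosome length.
#' @export
focusPositions <- function(object) object@positions

#' @rdname focusPositions
#' @export
chromosomeLength <- function(object) object@length

#' InterferenceFit: maximum-likelihood gamma fit to inter-focus distances
#'
#' The strength of crossover interference is summarised by the shape factor
#' of a gamma distribution fitted to normalized inter-focus (or inter-CO)
#' distances. Shape 1 corresponds to no interference (memoryless placement);
#' larger shapes correspond to increasingly positive interference.
#'
#' @slot shape fitted gamma shape factor (dimensionless).
#' @slot scale fitted gamma scale on the normalized-distance axis.
#' @slot loglik maximized log-likelihood.
#' @slot shapeSE standard error of the shape from the observed Fisher
#'   information with the scale profiled out; `NA` when `capped`.
#' @slot n number of distances used.
#' @slot capped `TRUE` when the optimizer reached `shapeCap` (e.g. for
#'   zero-variance input).
#' @slot shapeCap the upper bound imposed on the shape.
#' @export
setClass("InterferenceFit",
  representation(shape = "numeric", scale = "numeric", loglik = "numeric",
                 shapeSE = "numeric", n = "integer", capped = "logical",
                 shapeCap = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@shape <= 0) msg <- c(msg, "shape must be positive")
    if (object@scale <= 0) msg <- c(msg, "scale must be positive")
    if (object@n < 2L) msg <- c(msg, "a fit requires n >= 2 distances")
    if (!object@capped && (!is.finite(object@shapeSE) || object@shapeSE <= 0))
      msg <- c(msg, "shapeSE must be positive unless the fit is capped")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "InterferenceFit", function(object) {
  cat(sprintf("InterferenceFit: shape %.3g", object@shape))
  if (object@capped) cat(" (capped)") else
    cat(sprintf(" +/- %.3g", object@shapeSE))
  cat(sprintf(", scale %.3g, n = %d, logLik %.2f\n",
              object@scale, object@n, object@loglik))
})

#' @rdname fitGammaInterference
#' @param object an [InterferenceFit-class]
#' @export
interferenceShape <- function(object) object@shape

.validWindows <- function(df, windowSize, valueCols) {
  msg <- NULL
  if (!is.data.frame(df)) return("window data must be a data.frame")
  need <- c("chrom", "start", valueCols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(windowSize) != 1L || windowSize <= 0)
    msg <- c(msg, "windowSize must be a single positive number")
  for (cc in valueCols)
    if (any(df[[cc]] < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("column '%s' must be non-negative", cc))
  for (ch in unique(df$chrom)) {
    s <- df$start[df$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, sprintf("windows on %s must be sorted and unique", ch))
    if (length(s) > 1L && any(diff(s) < windowSize))
      msg <- c(msg, sprintf("windows on %s overlap", ch))
  }
  if (is.null(msg)) TRUE else msg
}

#' WindowCountTable: strain-specific read counts in fixed genomic windows
#'
#' Per-window counts of reads mapping exclusively to the Bristol (N2) or
#' Hawaiian (CB4856) genome, the raw material for genotyping single F2
#' embryos. Windows are 0-based, half-open, non-overlapping and of constant
#' size (default 5 kb).
#'
#' @slot counts data.frame with columns `chrom`, `start` (bp, 0-based),
#'   `bristol`, `hawaiian` (read counts, `>= 0`).
#' @slot windowSize window width in bp.
#' @export
setClass("WindowCountTable",
  representation(counts = "data.frame", windowSize = "numeric"),
  validity = function(object)
    .validWindows(object@counts, object@windowSize,
                  c("bristol", "hawaiian")))

#' Construct a WindowCountTable
#' @param counts data.frame with columns `chrom`, `start`, `bristol`,
#'   `hawaiian`.
#' @param windowSize window width in bp (default 5000).
#' @return A [WindowCountTable-class].
#' @export
WindowCountTable <- function(counts, windowSize = 5000) {
  counts <- as.data.frame(counts)
  counts <- counts[order(counts$chrom, counts$start), , drop = FALSE]
  rownames(counts) <- NULL
  new("WindowCountTable", counts = counts, windowSize = as.numeric(windowSize))
}

setMethod("show", "WindowCountTable", function(object) {
  cat(sprintf("WindowCountTable: %d windows of %g bp on %d chromosome(s)\n",
              nrow(object@counts), object@windowSize,
              length(unique(object@counts$chrom))))
})

#' @rdname WindowCountTable
#' @param object a window table
#' @export
windowCounts <- function(object) object@counts

#' @rdname WindowCountTable
#' @export
windowSize <- function(object) object@windowSize

#' WindowDepthTable: total mapped-read depth in fixed genomic windows
#'
#' Per-window total read counts (all mapped reads, not only strain-specific
#' ones) used for copy-number and ploidy work; by convention 50-kb windows.
#'
#' @slot depth data.frame with columns `chrom`, `start`, `depth`.
#' @slot windowSize window width in bp.
#' @export
setClass("WindowDepthTable",
  representation(depth = "data.frame", windowSize = "numeric"),
  validity = function(object)
    .validWindows(object@depth, object@windowSize, "depth"))

#' Construct a WindowDepthTable
#' @param depth data.frame with columns `chrom`, `start`, `depth`.
#' @param windowSize window width in bp (default 50000).
#' @return A [WindowDepthTable-class].
#' @export
WindowDepthTable <- function(depth, windowSize = 50000) {
  depth <- as.data.frame(depth)
  depth <- depth[order(depth$chrom, depth$start), , drop = FALSE]
  rownames(depth) <- NULL
  new("WindowDepthTable", depth = depth, windowSize = as.numeric(windowSize))
}

setMethod("show", "WindowDepthTable", function(object) {
  cat(sprintf("WindowDepthTable: %d windows of %g bp on %d chromosome(s)\n",
              nrow(object@depth), object@windowSize,
              length(unique(object@depth$chrom))))
})

#' @rdname WindowDepthTable
#' @param object a depth table
#' @export
windowDepth <- function(object) object@depth

#' LabeledVolume: multi-channel 3D stack with a nucleus label volume
#'
#' Container for one field of view: intensity channels as 3D arrays in
#' `(z, y, x)` voxel order plus an integer label array of the same shape in
#' which 0 is background and positive integers identify segmented nuclei.
#'
#' @slot channels named list of numeric 3D arrays, all sharing one shape.
#' @slot labels integer 3D array of nucleus labels (0 = background).
#' @slot voxelSize numeric length-3 voxel size `(z, y, x)` in micrometres.
#' @export
setClass("LabeledVolume",
  representation(channels = "list", labels = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!length(object@channels) || is.null(names(object@channels)) ||
        any(!nzchar(names(object@channels))))
      msg <- c(msg, "channels must be a non-empty named list")
    dl <- dim(object@labels)
    if (length(dl) != 3L) msg <- c(msg, "labels must be a 3D array")
    for (nm in names(object@channels)) {
      d <- dim(object@channels[[nm]])
      if (length(d) != 3L || !all(d == dl))
        msg <- c(msg, sprintf("channel '%s' must share the label shape", nm))
    }
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive numbers (z, y, x)")
    if (any(object@labels < 0))
      msg <- c(msg, "labels must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a LabeledVolume
#' @param channels named list of 3D arrays in `(z, y, x)` order.
#' @param labels integer 3D array of the same shape; 0 = background.
#' @param voxelSize voxel size `(z, y, x)` in micrometres.
#' @return A [LabeledVolume-class].
#' @export
LabeledVolume <- function(channels, labels, voxelSize) {
  storage.mode(labels) <- "integer"
  new("LabeledVolume", channels = channels, labels = labels,
      voxelSize = as.numeric(voxelSize))
}

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "LabeledVolume: %d x %d x %d (z,y,x), %d channel(s) [%s], %d nuclei\n",
    d[1], d[2], d[3], length(object@channels),
    paste(names(object@channels), collapse = ", "),
    length(setdiff(unique(as.vector(object@labels)), 0L))))
})

#' @rdname LabeledVolume
#' @param object a `LabeledVolume`
#' @export
volumeChannels <- function(object) object@channels

#' @rdname LabeledVolume
#' @export
volumeLabels <- function(object) object@labels

#' @rdname LabeledVolume
#' @export
voxelSize <- function(object) object@voxelSize

#' ChromosomeTrace: an arc-length parametrized chromosome trace
#'
#' A polyline through a traced chromosome (synaptonemal complex), stored
#' with its original control points and an equidistant arc-length
#' resampling obtained by cubic-spline interpolation.
#'
#' @slot traceId single character trace identifier.
#' @slot nucleusId identifier of the nucleus the trace belongs to.
#' @slot controlPoints numeric matrix (n x 3), columns `(z, y, x)` in um.
#' @slot points equidistant resampled points, same layout.
#' @slot arc arc-length coordinate (um) of each resampled point.
#' @slot step target sample spacing in um.
#' @slot totalLength trace length in um.
#' @export
setClass("ChromosomeTrace",
  representation(traceId = "character", nucleusId = "character",
                 controlPoints = "matrix", points = "matrix",
                 arc = "numeric", step = "numeric", totalLength = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@controlPoints) < 2L)
      msg <- c(msg, "a trace needs at least 2 control points")
    if (object@totalLength <= 0) msg <- c(msg, "totalLength must be positive")
    if (nrow(object@points) != length(object@arc))
      msg <- c(msg, "points and arc must agree")
    if (length(object@arc) > 1L) {
      sp <- diff(object@arc)
      if (max(abs(sp - mean(sp))) > 0.01 * mean(sp))
        msg <- c(msg, "resampled spacing must be constant to within 1%")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ChromosomeTrace", function(object) {
  cat(sprintf(
    "ChromosomeTrace %s (nucleus %s): length %.2f um, %d samples @ %.3g um\n",
    object@traceId, object@nucleusId, object@totalLength,
    nrow(object@points), object@step))
})

#' @rdname resampleTrace
#' @param object a [ChromosomeTrace-class]
#' @export
traceLength <- function(object) object@totalLength

#' @rdname resampleTrace
#' @export
tracePoints <- function(object) object@points
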