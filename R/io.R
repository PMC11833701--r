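#' Default run configuration
#'
#' All tunable parameters of the pipelines with their standard defaults:
#' the genotype-ratio thresholds (0.9 / 0.25), the 100-window gliding
#' span over 5-kb windows, the >1500-read and 15-kb crossover support
#' rules, the 50-kb copy-number windows with the 1.45 / 2.5 ploidy
#' bounds, the 10-60 um^3 (exclusive) volume, 0.4 sphericity and 0.3-0.8
#' (inclusive) intensity-ratio nucleus filters, the 10-50 px background
#' annulus, the 11-bin germline profile, the 1-6 um RAD-51 nucleus
#' diameter gate, and the 0.05-um trace resampling step.
#'
#' @return Nested named list of parameters.
#' @export
defaultRunConfig <- function() {
  list(
    interference = list(shapeCap = 1000),
    comap = list(windowSize = 5000, depthWindow = 50000, span = 100,
                 bristolMin = 0.9, hawaiianMax = 0.25, minReads = 1500,
                 minFlank = 15000, ploidyBounds = c(1.45, 2.5),
                 xChrom = "X"),
    imagequant = list(annulus = c(10, 50), volumeBounds = c(10, 60),
                      minSphericity = 0.4, ratioBounds = c(0.3, 0.8),
                      nbins = 11, rad51DiameterRange = c(1, 6),
                      loessSpan = 0.5, loessDegree = 2,
                      thresholdBins = 256),
    tracing = list(step = 0.05, offsetTrim = 0.1),
    synthetic = list(informativeFraction = 0.3, readLength = 150,
                     coverage = 3)
  )
}

#' Read a run configuration from YAML
#'
#' Values given in the file override the defaults of
#' [defaultRunConfig()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Nested named list of parameters.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) { cfg[[sec]] <- user[[sec]]; next }
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  cfg
}

.checkSchema <- function(df, schema, path) {
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (cc in names(schema)) {
    if (schema[[cc]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]))
      if (length(bad))
        stop(path, ": column '", cc, "' is not numeric at row ", bad[1])
      if (anyNA(df[[cc]]))
        stop(path, ": column '", cc, "' has a missing value at row ",
             which(is.na(df[[cc]]))[1])
      df[[cc]] <- v
    } else df[[cc]] <- as.character(df[[cc]])
  }
  df
}

.readDelim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Read and write focus tables
#'
#' A focus table is TSV/CSV with columns `chromosome_id`, `length`,
#' `position`, one row per focus; zero-focus chromosomes may appear with
#' an `NA` position row omitted.
#'
#' @param path file path (TSV by default, CSV if the extension is .csv).
#' @return `readFocusTable` returns the validated data.frame.
#' @export
readFocusTable <- function(path) {
  .checkSchema(.readDelim(path),
               list(chromosome_id = "character", length = "numeric",
                    position = "numeric"), path)
}

#' @rdname readFocusTable
#' @param foci list of [FocusSet-class] or a focus data.frame.
#' @export
writeFocusTable <- function(foci, path) {
  if (!is.data.frame(foci)) {
    foci <- do.call(rbind, lapply(foci, function(fs)
      if (length(fs) == 0L) NULL else
      data.frame(chromosome_id = fs@chromosomeId, length = fs@length,
                 position = fs@positions)))
  }
  utils::write.table(foci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write window count and depth tables
#'
#' Window tables are TSV with columns `chrom`, `start`, `bristol`,
#' `hawaiian` (counts; 5-kb windows) or `chrom`, `start`, `depth`
#' (depth; 50-kb windows). Coordinates are 0-based half-open window
#' starts.
#'
#' @param path file path.
#' @param windowSize window size in bp.
#' @return The corresponding [WindowCountTable-class] or
#'   [WindowDepthTable-class].
#' @export
readWindowCounts <- function(path, windowSize = 5000) {
  df <- .checkSchema(.readDelim(path),
                     list(chrom = "character", start = "numeric",
                          bristol = "numeric", hawaiian = "numeric"), path)
  WindowCountTable(df, windowSize)
}

#' @rdname readWindowCounts
#' @param table a window table object.
#' @export
writeWindowCounts <- function(table, path) {
  utils::write.table(windowCounts(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readWindowCounts
#' @export
readWindowDepth <- function(path, windowSize = 50000) {
  df <- .checkSchema(.readDelim(path),
                     list(chrom = "character", start = "numeric",
                          depth = "numeric"), path)
  WindowDepthTable(df, windowSize)
}

#' @rdname readWindowCounts
#' @export
writeWindowDepth <- function(table, path) {
  utils::write.table(windowDepth(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write crossover calls (BED-like)
#'
#' Calls are written as a BED-like table `chrom left right left_class
#' right_class support_reads` with 0-based half-open intervals.
#'
#' @param calls crossover calls from [callCrossovers()].
#' @param path file path.
#' @export
writeCrossoverCalls <- function(calls, path) {
  utils::write.table(
    calls[, c("chrom", "left", "right", "left_class", "right_class",
              "support_reads")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCrossoverCalls
#' @export
readCrossoverCalls <- function(path) {
  .checkSchema(.readDelim(path),
               list(chrom = "character", left = "numeric",
                    right = "numeric", left_class = "character",
                    right_class = "character",
                    support_reads = "numeric"), path)
}

#' Read a chromosome-trace control-point table
#'
#' Control points exported by an interactive tracer: columns
#' `nucleus_id`, `trace_id`, `order`, `z`, `y`, `x` (um). Returns the
#' traces resampled at `step` via [resampleTrace()].
#'
#' @param path CSV/TSV path.
#' @param step resampling step in um.
#' @return Named list of [ChromosomeTrace-class] objects.
#' @export
readTraceTable <- function(path, step = 0.05) {
  df <- .checkSchema(.readDelim(path),
                     list(nucleus_id = "character", trace_id = "character",
                          order = "numeric", z = "numeric", y = "numeric",
                          x = "numeric"), path)
  out <- list()
  for (tid in unique(df$trace_id)) {
    d <- df[df$trace_id == tid, , drop = FALSE]
    d <- d[order(d$order), , drop = FALSE]
    out[[tid]] <- resampleTrace(as.matrix(d[, c("z", "y", "x")]),
                                step = step, traceId = tid,
                                nucleusId = d$nucleus_id[1])
  }
  out
}

#' Write and read synthetic ground truth as JSON
#'
#' Every generator returns a `SyntheticTruth`; serializing it next to the
#' generated data lets round-trip tests consume only the truth file.
#'
#' @param truth a `SyntheticTruth`.
#' @param path JSON file path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "SyntheticTruth")
}

#' Write an interference fit report as JSON
#'
#' @param fit an [InterferenceFit-class].
#' @param path JSON file path.
#' @export
writeFitReport <- function(fit, path) {
  jsonlite::write_json(
    list(shape = fit@shape, scale = fit@scale, shape_se = fit@shapeSE,
         loglik = fit@loglik, n = fit@n, capped = fit@capped,
         shape_cap = fit@shapeCap),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
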