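#' Run a named pipeline stage
#'
#' Thin umbrella over the module functions for scripted use: executes one
#' analysis stage on file or in-memory inputs with a single configuration
#' object, and (optionally) writes the stage outputs plus a
#' machine-readable JSON manifest (configuration echo, seed, package
#' version, timestamp) to an output directory.
#'
#' Stages:
#' \describe{
#'   \item{`interference`}{`inputs$foci` (focus table path, focus
#'     data.frame or list of [FocusSet-class]) -> interference fit.}
#'   \item{`comap`}{`inputs$counts` + `inputs$depth` (paths or table
#'     objects) -> per-embryo report via [analyzeEmbryo()].}
#'   \item{`imagequant`}{`inputs$volume` (a [LabeledVolume-class]) ->
#'     background, nucleus records, filters.}
#'   \item{`tracing`}{`inputs$traces` (path or trace list) +
#'     `inputs$foci` (focus data.frame) -> offset, mappings, per-trace
#'     stats.}
#' }
#'
#' @param stage stage name.
#' @param inputs named list of stage inputs (see Details).
#' @param config configuration list, see [defaultRunConfig()].
#' @param out optional output directory for result files and the
#'   manifest.
#' @param seed seed recorded in the manifest.
#' @return The stage result, invisibly when `out` is given.
#' @export
runPipeline <- function(stage = c("interference", "comap", "imagequant",
                                  "tracing"),
                        inputs = list(), config = defaultRunConfig(),
                        out = NULL, seed = NULL) {
  stage <- match.arg(stage)
  result <- switch(stage,
    interference = {
      foci <- inputs$foci
      if (is.character(foci)) foci <- readFocusTable(foci)
      d <- interfocusDistances(foci)
      fitGammaInterference(d, shapeCap = config$interference$shapeCap)
    },
    comap = {
      counts <- inputs$counts
      depth <- inputs$depth
      if (is.character(counts))
        counts <- readWindowCounts(counts, config$comap$windowSize)
      if (is.character(depth))
        depth <- readWindowDepth(depth, config$comap$depthWindow)
      analyzeEmbryo(counts, depth, span = config$comap$span,
                    minReads = config$comap$minReads,
                    minFlank = config$comap$minFlank,
                    xChrom = config$comap$xChrom,
                    ploidyBounds = config$comap$ploidyBounds)
    },
    imagequant = {
      vol <- inputs$volume
      stopifnot(is(vol, "LabeledVolume"))
      ann <- config$imagequant$annulus
      bg <- vapply(volumeChannels(vol), function(ch)
        backgroundAnnulus(ch, volumeLabels(vol), ann[1], ann[2]),
        numeric(1))
      rec <- nucleusMetrics(vol, backgrounds = bg,
                            axisChannel = inputs$axisChannel,
                            ratioChannel = inputs$ratioChannel %||%
                              inputs$axisChannel)
      list(backgrounds = bg, records = rec,
           kept = filterNuclei(rec,
                               volumeBounds = config$imagequant$volumeBounds,
                               minSphericity = config$imagequant$minSphericity,
                               ratioBounds = config$imagequant$ratioBounds))
    },
    tracing = {
      traces <- inputs$traces
      if (is.character(traces))
        traces <- readTraceTable(traces, step = config$tracing$step)
      foci <- inputs$foci
      if (is.character(foci)) foci <- .readDelim(foci)
      off <- estimateChannelOffset(as.matrix(foci[, c("z", "y", "x")]),
                                   traces,
                                   trim = config$tracing$offsetTrim)
      mp <- mapFoci(foci, traces, offset = off)
      c(list(offset = off, mappings = mp), perTraceFocusStats(mp, traces))
    })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(stage = stage, seed = seed,
                     package = as.character(utils::packageVersion("meioquant")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = config)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (stage == "interference")
      writeFitReport(result, file.path(out, "fit.json"))
    if (stage == "comap") {
      writeCrossoverCalls(result$calls, file.path(out, "calls.bed"))
      utils::write.table(result$ploidy, file.path(out, "ploidy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (stage == "imagequant")
      utils::write.table(result$records, file.path(out, "nuclei.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (stage == "tracing")
      utils::write.table(result$mappings, file.path(out, "mappings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(result))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
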