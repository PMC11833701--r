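#' Resample a chromosome trace as an equidistant spline
#'
#' Interpolates the ordered control points of a traced chromosome with a
#' natural cubic spline (chord-length parametrization; linear for two
#' distinct points) and resamples it at constant arc-length spacing close
#' to `step`, preserving both endpoints. Duplicate consecutive control
#' points are collapsed.
#'
#' @param controlPoints numeric matrix (n x 3), columns `(z, y, x)` um.
#' @param step target sample spacing in um (default 0.05, well below the
#'   width of a synaptonemal complex).
#' @param traceId,nucleusId identifiers carried on the result.
#' @return A [ChromosomeTrace-class].
#' @export
resampleTrace <- function(controlPoints, step = 0.05, traceId = "trace1",
                          nucleusId = "nucleus1") {
  cp <- as.matrix(controlPoints)
  if (ncol(cp) != 3L) stop("control points must have 3 columns (z, y, x)")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number")
  if (nrow(cp) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(cp))) == 0)
    cp <- cp[!dup, , drop = FALSE]
  }
  if (nrow(cp) < 2L) stop("need at least 2 distinct control points")
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  nDense <- max(512L, 16L * nrow(cp), 4L * ceiling(chord[length(chord)] / step))
  td <- seq(0, chord[length(chord)], length.out = nDense)
  dense <- if (nrow(cp) == 2L) {
    cbind(approx(chord, cp[, 1], td)$y, approx(chord, cp[, 2], td)$y,
          approx(chord, cp[, 3], td)$y)
  } else {
    cbind(spline(chord, cp[, 1], xout = td, method = "natural")$y,
          spline(chord, cp[, 2], xout = td, method = "natural")$y,
          spline(chord, cp[, 3], xout = td, method = "natural")$y)
  }
  arcd <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  L <- arcd[length(arcd)]
  n <- max(2L, round(L / step) + 1L)
  arcOut <- seq(0, L, length.out = n)
  tOut <- approx(arcd, td, xout = arcOut, rule = 2)$y
  pts <- if (nrow(cp) == 2L) {
    cbind(approx(chord, cp[, 1], tOut)$y, approx(chord, cp[, 2], tOut)$y,
          approx(chord, cp[, 3], tOut)$y)
  } else {
    cbind(spline(chord, cp[, 1], xout = tOut, method = "natural")$y,
          spline(chord, cp[, 2], xout = tOut, method = "natural")$y,
          spline(chord, cp[, 3], xout = tOut, method = "natural")$y)
  }
  pts[1, ] <- cp[1, ]
  pts[n, ] <- cp[nrow(cp), ]
  colnames(pts) <- c("z", "y", "x")
  new("ChromosomeTrace", traceId = as.character(traceId),
      nucleusId = as.character(nucleusId), controlPoints = cp,
      points = pts, arc = arcOut, step = as.numeric(step), totalLength = L)
}

.allTracePoints <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) tr@points))
}

## squared distance of each row of a to its nearest row of b,
## returning the index of that nearest row as well
.nearest <- function(a, b) {
  bb <- rowSums(b^2)
  d2 <- outer(rowSums(a^2), bb, "+") - 2 * (a %*% t(b))
  j <- max.col(-d2, ties.method = "first")
  list(index = j, dist = sqrt(pmax(d2[cbind(seq_len(nrow(a)), j)], 0)))
}

#' Estimate the global offset between the focus and trace channels
#'
#' Chromatic shift between the focus channel (e.g. COSA-1) and the
#' trace/SC channel (e.g. SYP-4) is modelled as a single 3D translation:
#' the translation minimizing the sum of squared distances from shifted
#' focus centroids to their nearest trace sample points. It is found by
#' alternating nearest-point assignment with a closed-form translation
#' update (coordinate descent starting from zero). With `trim` set, the
#' worst fraction of foci by residual distance is excluded from each
#' update, making the estimate robust to mis-mapped foci.
#'
#' @param foci numeric matrix (n x 3) of focus centroids `(z, y, x)` um;
#'   at least 3 foci.
#' @param traces list of [ChromosomeTrace-class] objects.
#' @param trim fraction of worst-fitting foci to ignore (default 0;
#'   robust option 0.1).
#' @param maxIter,tol iteration controls.
#' @return Numeric length-3 offset `(z, y, x)` to add to focus centroids.
#' @export
estimateChannelOffset <- function(foci, traces, trim = 0, maxIter = 100,
                                  tol = 1e-6) {
  f <- as.matrix(foci)
  if (ncol(f) != 3L) stop("foci must have 3 columns (z, y, x)")
  if (nrow(f) < 3L) stop("need at least 3 foci to estimate an offset")
  if (!length(traces)) stop("no traces supplied")
  ## work on a 5x linearly densified polyline so the discrete sampling
  ## step does not quantize the converged translation
  tp <- do.call(rbind, lapply(traces, function(tr) {
    a <- tr@arc
    if (length(a) < 2L) return(tr@points)
    ad <- seq(a[1], a[length(a)], length.out = 5L * length(a))
    cbind(approx(a, tr@points[, 1], ad)$y,
          approx(a, tr@points[, 2], ad)$y,
          approx(a, tr@points[, 3], ad)$y)
  }))
  descend <- function(off) {
    for (i in seq_len(maxIter)) {
      nn <- .nearest(f + rep(off, each = nrow(f)), tp)
      res <- tp[nn$index, , drop = FALSE] - (f + rep(off, each = nrow(f)))
      keep <- seq_len(nrow(f))
      if (trim > 0) {
        nKeep <- max(3L, ceiling((1 - trim) * nrow(f)))
        keep <- order(nn$dist)[seq_len(nKeep)]
      }
      delta <- colMeans(res[keep, , drop = FALSE])
      off <- off + delta
      if (sqrt(sum(delta^2)) < tol) break
    }
    nn <- .nearest(f + rep(off, each = nrow(f)), tp)
    d <- sort(nn$dist)
    if (trim > 0) d <- d[seq_len(max(3L, ceiling((1 - trim) * length(d))))]
    list(off = off, ssq = sum(d^2))
  }
  ## two starts: zero (small chromatic shifts) and the centroid
  ## difference (a coarse global alignment); keep the better optimum
  starts <- list(c(0, 0, 0), colMeans(tp) - colMeans(f))
  fits <- lapply(starts, descend)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ssq"))]]
  setNames(best$off, c("z", "y", "x"))
}

#' Map focus centroids onto their nearest chromosome trace
#'
#' Each offset-corrected focus centroid is assigned to the globally
#' nearest resampled point among the traces of its own nucleus; the focus
#' inherits that point's arc-length position (um and normalized by the
#' trace length). Ties are broken towards the lowest `traceId`, then the
#' smallest arc position. Foci whose nucleus has no trace are returned
#' unmapped and flagged.
#'
#' @param foci data.frame with columns `focus_id`, `nucleus_id`, `z`, `y`,
#'   `x` (um).
#' @param traces list of [ChromosomeTrace-class] objects (resampled).
#' @param offset length-3 channel offset added to the centroids
#'   (see [estimateChannelOffset()]).
#' @return data.frame: `focus_id`, `nucleus_id`, `trace_id`, `arc_um`,
#'   `arc_norm`, `distance_um`, `mapped`.
#' @export
mapFoci <- function(foci, traces, offset = c(0, 0, 0)) {
  need <- c("focus_id", "nucleus_id", "z", "y", "x")
  miss <- setdiff(need, names(foci))
  if (length(miss))
    stop("focus table is missing column(s): ", paste(miss, collapse = ", "))
  traceNuc <- vapply(traces, function(tr) tr@nucleusId, character(1))
  traceIds <- vapply(traces, function(tr) tr@traceId, character(1))
  n <- nrow(foci)
  out <- data.frame(focus_id = foci$focus_id,
                    nucleus_id = foci$nucleus_id,
                    trace_id = rep(NA_character_, n),
                    arc_um = rep(NA_real_, n),
                    arc_norm = rep(NA_real_, n),
                    distance_um = rep(NA_real_, n),
                    mapped = rep(FALSE, n))
  for (i in seq_len(nrow(foci))) {
    sel <- which(traceNuc == as.character(foci$nucleus_id[i]))
    if (!length(sel)) next
    p <- c(foci$z[i], foci$y[i], foci$x[i]) + offset
    best <- NULL
    for (k in sel[order(traceIds[sel])]) {
      tr <- traces[[k]]
      d <- sqrt(colSums((t(tr@points) - p)^2))
      j <- which.min(d) # first (smallest-arc) minimizer
      cand <- list(trace = tr@traceId, arc = tr@arc[j],
                   norm = tr@arc[j] / tr@totalLength, dist = d[j])
      if (is.null(best) || cand$dist < best$dist - 1e-12) best <- cand
    }
    out$trace_id[i] <- best$trace
    out$arc_um[i] <- best$arc
    out$arc_norm[i] <- best$norm
    out$distance_um[i] <- best$dist
    out$mapped[i] <- TRUE
  }
  out
}

#' Per-trace focus counts and normalized inter-focus distances
#'
#' Summarises mapped foci per chromosome trace: the focus count, and for
#' traces carrying two or more foci the consecutive arc-length gaps
#' normalized by the trace length. The returned `focusSets` feed directly
#' into [interfocusDistances()] and [fitGammaInterference()].
#'
#' @param mappings output of [mapFoci()].
#' @param traces the list of [ChromosomeTrace-class] objects.
#' @return list with `stats` (data.frame: `trace_id`, `nucleus_id`,
#'   `length_um`, `n_foci`) and `focusSets` (list of [FocusSet-class],
#'   one per trace, positions in um along the trace).
#' @export
perTraceFocusStats <- function(mappings, traces) {
  traceIds <- vapply(traces, function(tr) tr@traceId, character(1))
  stats <- data.frame(
    trace_id = traceIds,
    nucleus_id = vapply(traces, function(tr) tr@nucleusId, character(1)),
    length_um = vapply(traces, function(tr) tr@totalLength, numeric(1)),
    n_foci = 0L)
  fs <- vector("list", length(traces))
  m <- mappings[mappings$mapped, , drop = FALSE]
  for (k in seq_along(traces)) {
    arcs <- sort(m$arc_um[m$trace_id == traceIds[k]])
    stats$n_foci[k] <- length(arcs)
    fs[[k]] <- FocusSet(traceIds[k], stats$length_um[k], arcs)
  }
  names(fs) <- traceIds
  list(stats = stats, focusSets = fs)
}
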