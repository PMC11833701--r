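## separable Gaussian smoothing of a 3D array, zero-padded at edges
.gaussKernel <- function(sigma = 1, radius = 3) {
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

.smooth3d <- function(a, kernel) {
  d <- dim(a)
  r <- (length(kernel) - 1L) / 2L
  filt <- function(m) {
    n <- nrow(m)
    mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- stats::filter(mp, kernel, sides = 2)
    out[(r + 1):(r + n), , drop = FALSE]
  }
  a <- array(filt(matrix(a, d[1], d[2] * d[3])), d)
  a <- aperm(array(filt(matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3])),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(filt(matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2])),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

## Surface area of a binary 3D mask by the coarea formula: the mask is
## smoothed with a 1-voxel Gaussian and the gradient magnitude of the
## smoothed indicator is integrated over the volume. On digital balls of
## radius >= 5 voxels this is within ~5% of the analytic area, well inside
## the tolerance the sphericity filter needs.
.surfaceArea <- function(mask, vs) {
  u <- .smooth3d(mask * 1, .gaussKernel(1, 3))
  d <- dim(u)
  gz <- (u[c(2:d[1], d[1]), , ] - u[c(1, 1:(d[1] - 1)), , ]) / (2 * vs[1])
  gy <- (u[, c(2:d[2], d[2]), ] - u[, c(1, 1:(d[2] - 1)), ]) / (2 * vs[2])
  gx <- (u[, , c(2:d[3], d[3])] - u[, , c(1, 1:(d[3] - 1))]) / (2 * vs[3])
  sum(sqrt(gz^2 + gy^2 + gx^2)) * prod(vs)
}

## bounding box of a voxel index set, padded and clipped to the array
.bbox <- function(idx, dims, pad = 4L) {
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dims)
  list(lo = lo, hi = hi)
}

#' Background from an annulus around segmented objects
#'
#' The background of a channel is estimated as the mean intensity over all
#' voxels whose 2D (within-slice) pixel distance to the nearest labeled
#' voxel lies in `(rmin, rmax]`. All labeled objects (including those later
#' filtered out) exclude their surroundings, and the distance is computed
#' per z-slice in pixel units, matching anisotropic stacks where the
#' camera pixel is the natural lateral unit. Slices containing no labeled
#' voxel contribute nothing.
#'
#' @param channel 3D intensity array `(z, y, x)`.
#' @param labels 3D integer label array of the same shape.
#' @param rmin,rmax inner (exclusive) and outer (inclusive) annulus radii
#'   in pixels.
#' @param mode `"slice"` (default) for per-slice 2D distances, `"volume"`
#'   for full 3D voxel distances.
#' @return Scalar mean background intensity.
#' @export
backgroundAnnulus <- function(channel, labels, rmin = 10, rmax = 50,
                              mode = c("slice", "volume")) {
  mode <- match.arg(mode)
  if (!all(dim(channel) == dim(labels)))
    stop("channel and labels must share a shape")
  fg <- labels > 0
  if (!any(fg)) stop("invalid input: label volume is empty")
  if (mode == "slice") {
    ## EBImage::distmap computes, per 2D frame, the distance of each
    ## non-zero pixel to the nearest zero pixel; feeding 1 - foreground
    ## yields the distance of every unlabeled pixel to the nearest label.
    inv <- aperm(1 - fg, c(2, 3, 1)) # frames last for EBImage
    d <- EBImage::distmap(inv)
    d <- aperm(d, c(3, 1, 2))
  } else {
    d <- .distance3d(fg)
  }
  sel <- is.finite(d) & d > rmin & d <= rmax
  if (!any(sel)) stop("empty background annulus")
  mean(channel[sel])
}

## exact 3D Euclidean distance (in voxels) of every voxel to the nearest
## foreground voxel, via per-voxel nearest-neighbour search on the
## foreground set; adequate for the stack sizes this package targets
.distance3d <- function(fg) {
  dims <- dim(fg)
  fi <- which(fg, arr.ind = TRUE)
  bi <- which(!fg, arr.ind = TRUE)
  d <- array(0, dims)
  if (nrow(bi)) {
    block <- 2000L
    dist <- numeric(nrow(bi))
    for (s in seq(1L, nrow(bi), by = block)) {
      e <- min(s + block - 1L, nrow(bi))
      dz <- outer(bi[s:e, 1], fi[, 1], "-")
      dy <- outer(bi[s:e, 2], fi[, 2], "-")
      dx <- outer(bi[s:e, 3], fi[, 3], "-")
      dist[s:e] <- sqrt(apply(dz^2 + dy^2 + dx^2, 1, min))
    }
    d[!fg] <- dist
  }
  d
}

#' Segment the chromosome-axis signal within a nucleus
#'
#' Axis (HTP-3) voxels are those nucleus voxels whose intensity is strictly
#' greater than the mean intensity over the nucleus mask (mean
#' thresholding). A constant-intensity nucleus therefore yields an empty
#' axis mask.
#'
#' @param axisChannel 3D intensity array `(z, y, x)`.
#' @param nucleusMask logical 3D array of the same shape.
#' @return Logical 3D array: the axis mask (always a subset of the
#'   nucleus mask).
#' @export
segmentAxis <- function(axisChannel, nucleusMask) {
  if (!any(nucleusMask)) stop("invalid input: empty nucleus mask")
  if (!all(dim(axisChannel) == dim(nucleusMask)))
    stop("channel and mask must share a shape")
  thr <- mean(axisChannel[nucleusMask])
  nucleusMask & (axisChannel > thr)
}

#' Per-nucleus intensity metrics
#'
#' For every labeled nucleus computes its volume (voxel count times voxel
#' volume), centroid, sphericity, background-corrected total intensities
#' in the nucleus and on its chromosome-axis mask, and the axis-to-nucleus
#' intensity ratio. Background is subtracted per voxel and each voxel is
#' floored at zero before summing, so totals are non-negative. Sphericity
#' is `pi^(1/3) * (6 V)^(2/3) / A` with the surface area `A` estimated
#' from the gradient of the smoothed nucleus mask.
#'
#' @param volume a [LabeledVolume-class].
#' @param backgrounds named numeric vector of per-channel background
#'   levels (e.g. from [backgroundAnnulus()]); channels without an entry
#'   use background 0.
#' @param axisChannel name of the channel whose mean-threshold mask
#'   defines the chromosome axis (e.g. the HTP-3 stain).
#' @param ratioChannel channel whose axis/nucleus ratio is reported in the
#'   `axis_ratio` column (defaults to `axisChannel`).
#' @return A data.frame of nucleus records: `nucleus_id`, centroid
#'   (`centroid_z/y/x`, um), `volume_um3`, `sphericity`, per-channel
#'   totals `nuc_<channel>` and `axis_<channel>`, per-channel ratios
#'   `ratio_<channel>`, plus `axis_ratio`.
#' @export
nucleusMetrics <- function(volume, backgrounds = NULL, axisChannel = NULL,
                           ratioChannel = axisChannel) {
  stopifnot(is(volume, "LabeledVolume"))
  validObject(volume)
  labs <- volumeLabels(volume)
  chans <- volumeChannels(volume)
  vs <- voxelSize(volume)
  if (is.null(axisChannel)) axisChannel <- names(chans)[1]
  if (!axisChannel %in% names(chans))
    stop("unknown axis channel: ", axisChannel)
  bg <- setNames(rep(0, length(chans)), names(chans))
  if (!is.null(backgrounds)) bg[names(backgrounds)] <- backgrounds
  ids <- setdiff(sort(unique(as.vector(labs))), 0L)
  dims <- dim(labs)
  voxVol <- prod(vs)
  rows <- lapply(ids, function(id) {
    idx <- which(labs == id, arr.ind = TRUE)
    nvox <- nrow(idx)
    bb <- .bbox(idx, dims)
    sub <- labs[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                drop = FALSE]
    mask <- sub == id
    vol <- nvox * voxVol
    sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / .surfaceArea(mask, vs)
    axisChanSub <- chans[[axisChannel]][bb$lo[1]:bb$hi[1],
                                        bb$lo[2]:bb$hi[2],
                                        bb$lo[3]:bb$hi[3], drop = FALSE]
    amask <- segmentAxis(axisChanSub, mask)
    rec <- data.frame(nucleus_id = id,
                      centroid_z = mean(idx[, 1] - 0.5) * vs[1],
                      centroid_y = mean(idx[, 2] - 0.5) * vs[2],
                      centroid_x = mean(idx[, 3] - 0.5) * vs[3],
                      n_voxels = nvox, volume_um3 = vol, sphericity = sph)
    for (nm in names(chans)) {
      ch <- chans[[nm]][bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                        bb$lo[3]:bb$hi[3], drop = FALSE]
      corr <- pmax(ch - bg[[nm]], 0)
      nuc <- sum(corr[mask])
      ax <- sum(corr[amask])
      rec[[paste0("nuc_", nm)]] <- nuc
      rec[[paste0("axis_", nm)]] <- ax
      rec[[paste0("ratio_", nm)]] <- if (nuc > 0) ax / nuc else NA_real_
    }
    rec$axis_ratio <- rec[[paste0("ratio_", ratioChannel)]]
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter nucleus records
#'
#' Removes fragmented, apoptotic or somatic nuclei: a record passes when
#' its volume is strictly between the volume bounds (10-60 um^3,
#' exclusive), its sphericity is strictly greater than `minSphericity`,
#' and its axis/nucleus intensity ratio lies within `ratioBounds`
#' (inclusive). The decision depends only on the record itself.
#'
#' @param records nucleus records from [nucleusMetrics()].
#' @param volumeBounds exclusive volume bounds in um^3.
#' @param minSphericity strict lower sphericity bound.
#' @param ratioBounds inclusive bounds on the `ratioMetric` column.
#' @param ratioMetric column used for the intensity-ratio filter
#'   (default `"axis_ratio"`).
#' @param keep `"pass"` returns the passing subset; `"all"` returns every
#'   record with a `passed_filters` column added.
#' @return Filtered (or annotated) nucleus records.
#' @export
filterNuclei <- function(records, volumeBounds = c(10, 60),
                         minSphericity = 0.4, ratioBounds = c(0.3, 0.8),
                         ratioMetric = "axis_ratio",
                         keep = c("pass", "all")) {
  keep <- match.arg(keep)
  r <- records[[ratioMetric]]
  pass <- records$volume_um3 > volumeBounds[1] &
    records$volume_um3 < volumeBounds[2] &
    records$sphericity > minSphericity &
    !is.na(r) & r >= ratioBounds[1] & r <= ratioBounds[2]
  records$passed_filters <- pass
  if (keep == "pass") records[pass, , drop = FALSE] else records
}

#' Normalize axis loading to the wild-type mean of the same slide
#'
#' Each nucleus's axis total is divided by the mean axis total of
#' wild-type nuclei on the same slide, removing slide-to-slide staining
#' variability. The wild-type group itself therefore has mean 1 on every
#' slide.
#'
#' @param records data.frame of nucleus records.
#' @param value column to normalize (e.g. `"axis_syp4"`).
#' @param slide,genotype names of the grouping columns.
#' @param wildtype the genotype label of the reference group.
#' @return `records` with an added `<value>_norm` column.
#' @export
normalizeToSlideWT <- function(records, value, slide = "slide",
                               genotype = "genotype", wildtype = "WT") {
  for (cc in c(value, slide, genotype))
    if (!cc %in% names(records)) stop("missing column: ", cc)
  out <- lapply(split(records, records[[slide]]), function(d) {
    wt <- d[[value]][d[[genotype]] == wildtype]
    if (!length(wt))
      stop("slide '", d[[slide]][1], "' has no wild-type reference nuclei")
    d[[paste0(value, "_norm")]] <- d[[value]] / mean(wt)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
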