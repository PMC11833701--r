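## Histogram thresholds on the voxel intensities of one nucleus. Both
## methods use the standard 256-bin formulation: Otsu maximizes the
## between-class variance, Yen maximizes the entropic correlation
## criterion. They operate on a plain intensity vector because the
## thresholding is restricted to the voxels inside one segmentation mask.
.histThreshold <- function(x, method = c("otsu", "yen"), nbins = 256L) {
  method <- match.arg(method)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nbins),
                nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w <- cumsum(p)
  if (method == "otsu") {
    mu <- cumsum(p * mids)
    muT <- mu[nbins]
    sb <- (muT * w - mu)^2 / (w * (1 - w))
    sb[!is.finite(sb)] <- -Inf
    k <- which.max(sb)
  } else {
    p2 <- cumsum(p^2)
    tot2 <- p2[nbins]
    crit <- -log(pmax(p2 * (tot2 - p2), .Machine$double.xmin)) +
      2 * log(pmax(w * (1 - w), .Machine$double.xmin))
    crit[!is.finite(crit)] <- -Inf
    k <- which.max(crit)
  }
  br[k + 1L] # upper edge of the selected bin: foreground is > threshold
}

## 6-connected components of a logical 3D array, via the graph of
## face-adjacent foreground voxels
.components3d <- function(mask) {
  dims <- dim(mask)
  id <- array(0L, dims)
  vox <- which(mask)
  if (!length(vox)) return(id)
  lin <- array(0L, dims)
  lin[vox] <- seq_along(vox)
  idx <- which(mask, arr.ind = TRUE)
  edges <- list()
  for (ax in 1:3) {
    ok <- idx[, ax] < dims[ax]
    nb <- idx[ok, , drop = FALSE]
    nb[, ax] <- nb[, ax] + 1L
    nbl <- lin[nb]
    sel <- nbl > 0L
    edges[[ax]] <- cbind(lin[idx[ok, , drop = FALSE]][sel], nbl[sel])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  id[vox] <- as.integer(comp)
  id
}

## Tolerance watershed on the voxels of one candidate component: voxels
## are flooded in order of decreasing intensity; a new peak founds a
## region, and when the flood reaches a saddle, regions whose peak rises
## less than `tolerance` above the saddle are merged into their higher
## neighbour. Returns an integer membership vector over the rows of cidx.
.watershedSplit <- function(vals, cidx, tolerance) {
  n <- length(vals)
  ord <- order(vals, decreasing = TRUE)
  key <- cidx[, 1] + 4096 * (cidx[, 2] + 4096 * cidx[, 3])
  lookup <- new.env(hash = TRUE, size = n)
  parent <- seq_len(n)
  peak <- rep(-Inf, n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offKey <- offs[, 1] + 4096 * (offs[, 2] + 4096 * offs[, 3])
  for (i in ord) {
    v <- vals[i]
    roots <- integer()
    for (ok in offKey) {
      j <- lookup[[as.character(key[i] + ok)]]
      if (!is.null(j)) roots <- c(roots, find(j))
    }
    roots <- unique(roots)
    if (!length(roots)) {
      peak[i] <- v
    } else {
      main <- roots[which.max(peak[roots])]
      for (r in roots) {
        if (r != main && peak[r] - v < tolerance) parent[r] <- main
      }
      parent[i] <- main
    }
    lookup[[as.character(key[i])]] <- i
  }
  vapply(seq_len(n), find, integer(1))
}

## 3D Gaussian + offset fit to one candidate spot; coordinates in voxels.
## Sigmas are bounded by the neighbourhood extent so a flat plateau
## cannot drive them off to infinity. Returns NULL when the nonlinear
## fit fails or lands on an implausible solution.
.fitGaussian3d <- function(coords, vals) {
  w <- pmax(vals - min(vals), 0)
  if (sum(w) == 0) w <- rep(1, length(vals))
  c0 <- colSums(coords * w) / sum(w)
  s0 <- sqrt(pmax(colSums((coords - rep(c0, each = nrow(coords)))^2 * w) /
                  sum(w), 0.25))
  ext <- apply(coords, 2, function(v) diff(range(v))) + 1
  sMax <- pmax(ext, 2)
  s0 <- pmin(s0, sMax - 0.1)
  st <- list(A = max(vals) - min(vals), b = min(vals),
             z0 = c0[1], y0 = c0[2], x0 = c0[3],
             sz = s0[1], sy = s0[2], sx = s0[3])
  df <- data.frame(v = vals, z = coords[, 1], y = coords[, 2],
                   x = coords[, 3])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-0.5 * ((z - z0)^2 / sz^2 + (y - y0)^2 / sy^2 +
                              (x - x0)^2 / sx^2)),
      data = df, start = st,
      lower = c(A = 0, b = -Inf, z0 = min(coords[, 1]) - 1,
                y0 = min(coords[, 2]) - 1, x0 = min(coords[, 3]) - 1,
                sz = 0.2, sy = 0.2, sx = 0.2),
      upper = c(A = Inf, b = Inf, z0 = max(coords[, 1]) + 1,
                y0 = max(coords[, 2]) + 1, x0 = max(coords[, 3]) + 1,
                sz = sMax[1], sy = sMax[2], sx = sMax[3]),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  out <- as.list(coef(fit))
  if (out$A <= 0 || out$sz >= sMax[1] - 1e-6 || out$sy >= sMax[2] - 1e-6 ||
      out$sx >= sMax[3] - 1e-6) return(NULL)
  out
}

#' Detect fluorescent foci inside segmented nuclei
#'
#' Per nucleus, voxel intensities inside the segmentation mask are
#' thresholded (Otsu for bright, sparse COSA-1-like foci; Yen for
#' RAD-51-like foci), connected components of the suprathreshold voxels
#' become candidate spots, and each candidate is refined by a 3D Gaussian
#' fit giving a subvoxel centroid, per-axis sigmas and an integrated
#' intensity (`A * (2*pi)^(3/2) * sz*sy*sx` in intensity-voxel units).
#' Candidates whose Gaussian fit fails are kept with their
#' intensity-weighted centroid and flagged `fitted = FALSE`. When
#' `diameterRange` is given (RAD-51 mode), only nuclei whose
#' equivalent-sphere diameter falls inside it are scored at all.
#'
#' @param channel 3D intensity array `(z, y, x)`.
#' @param labels 3D integer label array.
#' @param method thresholding method, `"otsu"` or `"yen"`.
#' @param minVoxels smallest candidate size kept, in voxels.
#' @param smoothSigma sigma (voxels) of the Gaussian prefilter applied
#'   before thresholding and labeling, suppressing single-voxel noise;
#'   the Gaussian refinement always fits the raw intensities. Set 0 to
#'   threshold the raw image.
#' @param splitTolerance connected candidates whose smoothed profile has
#'   several peaks separated by valleys deeper than this fraction of the
#'   peak contrast are split into separate spots by an intensity
#'   watershed.
#' @param diameterRange optional inclusive bounds (um) on the
#'   equivalent-sphere nucleus diameter; nuclei outside are not scored.
#' @param voxelSizeUm voxel size `(z, y, x)` in um (needed for
#'   `diameterRange` and um-scale centroids).
#' @return A list with `foci` (data.frame: `nucleus_id`, voxel-space and
#'   um-space centroids, `amplitude`, `sigma_z/y/x` in voxels,
#'   `integrated`, `fitted`) and `counts` (data.frame: `nucleus_id`,
#'   `n_foci`, `scored`).
#' @export
detectFoci <- function(channel, labels, method = c("otsu", "yen"),
                       minVoxels = 3, diameterRange = NULL,
                       voxelSizeUm = c(1, 1, 1), smoothSigma = 0.75,
                       splitTolerance = 0.3) {
  method <- match.arg(method)
  if (!all(dim(channel) == dim(labels)))
    stop("channel and labels must share a shape")
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(ids)) stop("invalid input: label volume is empty")
  dims <- dim(labels)
  voxVol <- prod(voxelSizeUm)
  fociRows <- list()
  countRows <- list()
  for (id in ids) {
    idx <- which(labels == id, arr.ind = TRUE)
    scored <- TRUE
    if (!is.null(diameterRange)) {
      dia <- (6 * nrow(idx) * voxVol / pi)^(1 / 3)
      scored <- dia >= diameterRange[1] && dia <= diameterRange[2]
    }
    if (!scored) {
      countRows[[length(countRows) + 1L]] <-
        data.frame(nucleus_id = id, n_foci = NA_integer_, scored = FALSE)
      next
    }
    bb <- .bbox(idx, dims, pad = 3L)
    sub <- channel[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                   drop = FALSE]
    mask <- labels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                   bb$lo[3]:bb$hi[3], drop = FALSE] == id
    det <- if (smoothSigma > 0)
      .smooth3d(sub, .gaussKernel(smoothSigma, max(3L, ceiling(3 * smoothSigma))))
    else sub
    ## a nucleus with no intensity contrast carries no spots; without
    ## this guard, histogram thresholding of a constant channel would
    ## promote smoothing edge effects into one giant candidate
    if (diff(range(sub[mask])) == 0) {
      countRows[[length(countRows) + 1L]] <-
        data.frame(nucleus_id = id, n_foci = 0L, scored = TRUE)
      next
    }
    thr <- .histThreshold(det[mask], method)
    cand <- .components3d(mask & det > thr)
    ncomp <- max(cand)
    maxVox <- max(minVoxels, floor(0.25 * sum(mask)))
    ## split touching spots: a component whose smoothed profile has
    ## several peaks separated by valleys deeper than `splitTolerance`
    ## times its peak contrast is divided by an intensity watershed
    candIdx <- list()
    for (ci in seq_len(ncomp)) {
      cidx <- which(cand == ci, arr.ind = TRUE)
      if (nrow(cidx) < minVoxels) next
      ## a candidate covering a large fraction of the nucleus is diffuse
      ## signal, not a focus
      if (nrow(cidx) > maxVox) next
      vals <- det[cidx]
      peak <- max(vals) - thr
      if (nrow(cidx) >= 2L * minVoxels && peak > 0) {
        memb <- .watershedSplit(vals, cidx, splitTolerance * peak)
        for (wi in unique(memb)) {
          widx <- cidx[memb == wi, , drop = FALSE]
          if (nrow(widx) >= minVoxels)
            candIdx[[length(candIdx) + 1L]] <- widx
        }
      } else {
        candIdx[[length(candIdx) + 1L]] <- cidx
      }
    }
    nfoci <- 0L
    for (cidx in candIdx) {
      ## fit on a padded neighbourhood, restricted to this nucleus
      nb <- .bbox(cidx, dim(sub), pad = 2L)
      nmask <- mask[nb$lo[1]:nb$hi[1], nb$lo[2]:nb$hi[2],
                    nb$lo[3]:nb$hi[3], drop = FALSE]
      nsub <- sub[nb$lo[1]:nb$hi[1], nb$lo[2]:nb$hi[2],
                  nb$lo[3]:nb$hi[3], drop = FALSE]
      ncoord <- which(nmask, arr.ind = TRUE)
      ncoord <- ncoord + rep(nb$lo - 1L, each = nrow(ncoord))
      vals <- nsub[nmask]
      wC <- pmax(sub[cidx] - thr, 0)
      if (sum(wC) == 0) wC <- rep(1, nrow(cidx))
      compCen <- colSums(cidx * wC) / sum(wC)
      fit <- .fitGaussian3d(ncoord, vals)
      ## the refinement must stay on the candidate it refines: fits that
      ## drift away from the component core are local optima of the
      ## noisy offset and are discarded in favour of the plain centroid
      if (!is.null(fit) &&
          sum((c(fit$z0, fit$y0, fit$x0) - compCen)^2) > 4) fit <- NULL
      if (!is.null(fit) &&
          fit$z0 >= nb$lo[1] - 1 && fit$z0 <= nb$hi[1] + 1 &&
          fit$y0 >= nb$lo[2] - 1 && fit$y0 <= nb$hi[2] + 1 &&
          fit$x0 >= nb$lo[3] - 1 && fit$x0 <= nb$hi[3] + 1) {
        cen <- c(fit$z0, fit$y0, fit$x0)
        amp <- fit$A
        sig <- c(fit$sz, fit$sy, fit$sx)
        integ <- amp * (2 * pi)^1.5 * prod(sig)
        fitted <- TRUE
      } else {
        cen <- compCen
        amp <- max(sub[cidx]) - thr
        sig <- rep(NA_real_, 3)
        integ <- sum(sub[cidx] - thr)
        fitted <- FALSE
      }
      cenG <- cen + (bb$lo - 1L) # back to full-volume voxel coordinates
      nfoci <- nfoci + 1L
      fociRows[[length(fociRows) + 1L]] <- data.frame(
        nucleus_id = id, z = cenG[1], y = cenG[2], x = cenG[3],
        z_um = (cenG[1] - 0.5) * voxelSizeUm[1],
        y_um = (cenG[2] - 0.5) * voxelSizeUm[2],
        x_um = (cenG[3] - 0.5) * voxelSizeUm[3],
        amplitude = amp, sigma_z = sig[1], sigma_y = sig[2],
        sigma_x = sig[3], integrated = integ, fitted = fitted)
    }
    countRows[[length(countRows) + 1L]] <-
      data.frame(nucleus_id = id, n_foci = nfoci, scored = TRUE)
  }
  foci <- if (length(fociRows)) do.call(rbind, fociRows) else
    data.frame(nucleus_id = integer(), z = numeric(), y = numeric(),
               x = numeric(), z_um = numeric(), y_um = numeric(),
               x_um = numeric(), amplitude = numeric(),
               sigma_z = numeric(), sigma_y = numeric(),
               sigma_x = numeric(), integrated = numeric(),
               fitted = logical())
  list(foci = foci, counts = do.call(rbind, countRows))
}

#' Coefficient of variation of focus intensities within a nucleus
#'
#' Sample standard deviation of the integrated focus intensities divided
#' by their mean; undefined (NA) for fewer than two foci.
#'
#' @param intensities integrated intensities of the foci of one nucleus.
#' @return Scalar CV, or `NA` when fewer than 2 foci are available.
#' @export
focusIntensityCV <- function(intensities) {
  x <- as.numeric(intensities)
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / mean(x)
}
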