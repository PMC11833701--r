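# Independent oracles used to pin expected values. Each one is a direct,
# unoptimized restatement of the quantity being checked, sharing no code
# with the implementation paths it verifies.

# Gamma MLE by zooming 2D grid search over (shape, scale). The zoom
# window keeps a generous margin around the best grid point because the
# likelihood ridge runs diagonally in (shape, scale).
gridSearchGammaMLE <- function(x, rounds = 7, width = 41, margin = 6) {
  ll <- function(k, th) sum(dgamma(x, shape = k, scale = th, log = TRUE))
  kLo <- 1e-3; kHi <- 500
  tLo <- mean(x) / 500; tHi <- mean(x) * 10
  for (r in seq_len(rounds)) {
    ks <- exp(seq(log(kLo), log(kHi), length.out = width))
    ts <- exp(seq(log(tLo), log(tHi), length.out = width))
    vals <- outer(ks, ts, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    i <- best[1]; j <- best[2]
    kLo <- ks[max(i - margin, 1)]; kHi <- ks[min(i + margin, width)]
    tLo <- ts[max(j - margin, 1)]; tHi <- ts[min(j + margin, width)]
  }
  list(shape = ks[i], scale = ts[j],
       loglik = ll(ks[i], ts[j]))
}

# Per-window centered gliding ratio by explicit looping
loopGlidingRatio <- function(bristol, hawaiian, span) {
  n <- length(bristol)
  halfL <- (span - 1) %/% 2
  halfR <- span - 1 - halfL
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - halfL); hi <- min(n, i + halfR)
    sb <- sum(bristol[lo:hi]); sh <- sum(hawaiian[lo:hi])
    out[i] <- if (sb + sh > 0) sb / (sb + sh) else NA_real_
  }
  out
}

# Exhaustive per-voxel per-slice annulus background
bruteForceAnnulus <- function(channel, labels, rmin, rmax) {
  vals <- c()
  for (z in seq_len(dim(labels)[1])) {
    sl <- labels[z, , ]
    fg <- which(sl > 0, arr.ind = TRUE)
    if (!nrow(fg)) next
    bg <- which(sl == 0, arr.ind = TRUE)
    dmin <- numeric(nrow(bg))
    for (i in seq_len(nrow(bg)))
      dmin[i] <- sqrt(min((bg[i, 1] - fg[, 1])^2 + (bg[i, 2] - fg[, 2])^2))
    sel <- dmin > rmin & dmin <= rmax
    vals <- c(vals, channel[z, , ][sl == 0][sel])
  }
  mean(vals)
}

# Hand-rolled group-by for the binned profile
groupbyProfile <- function(positions, values, nbins) {
  edges <- seq(0, 1, length.out = nbins + 1)
  out <- data.frame(mean = rep(NA_real_, nbins), se = NA_real_, n = 0L)
  for (b in seq_len(nbins)) {
    sel <- if (b < nbins)
      positions >= edges[b] & positions < edges[b + 1]
    else positions >= edges[b] & positions <= edges[b + 1]
    v <- values[sel]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$se[b] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    }
  }
  out
}

# Small synthetic nucleus: a digital ball with a planted bright filament
makeFilamentNucleus <- function(radius = 8, base = 10, axisExtra = 40) {
  n <- 2 * radius + 7
  c0 <- (n + 1) / 2
  idx <- as.matrix(expand.grid(z = 1:n, y = 1:n, x = 1:n))
  ball <- array(rowSums((idx - c0)^2) <= radius^2, c(n, n, n))
  tt <- seq(0, 2 * pi, length.out = 200)
  curve <- cbind(c0 + 0.5 * radius * sin(2 * tt),
                 c0 + 0.5 * radius * sin(3 * tt + 1),
                 c0 + 0.5 * radius * cos(2 * tt))
  fil <- array(FALSE, c(n, n, n))
  bi <- which(ball, arr.ind = TRUE)
  for (i in seq_len(nrow(bi))) {
    d2 <- min(colSums((t(curve) - bi[i, ])^2))
    if (d2 <= 1.2^2) fil[bi[i, 1], bi[i, 2], bi[i, 3]] <- TRUE
  }
  ch <- array(0, c(n, n, n))
  ch[ball] <- base
  ch[fil] <- base + axisExtra
  list(channel = ch, nucleus = ball, filament = fil)
}
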