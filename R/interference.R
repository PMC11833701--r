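#' Normalized inter-focus distances
#'
#' Computes the consecutive gaps between foci (or crossover midpoints) on
#' each chromosome, divided by that chromosome's length. Chromosomes with
#' fewer than two foci contribute nothing; distances from all chromosomes
#' are pooled so a single per-genotype gamma fit can be made.
#'
#' @param foci either a list of [FocusSet-class] objects or a data.frame
#'   with columns `chromosome_id`, `length`, `position` (one row per focus;
#'   `chromosome_id` must be unique per physical chromosome).
#' @return Numeric vector of normalized gaps, each in `(0, 1]`.
#' @examples
#' interfocusDistances(list(FocusSet("c1", 1, c(0.2, 0.7))))
#' @export
interfocusDistances <- function(foci) {
  if (is.data.frame(foci)) {
    need <- c("chromosome_id", "length", "position")
    miss <- setdiff(need, names(foci))
    if (length(miss))
      stop("focus table is missing column(s): ", paste(miss, collapse = ", "))
    foci <- lapply(split(foci, foci$chromosome_id), function(d) {
      if (length(unique(d$length)) != 1L)
        stop("chromosome ", d$chromosome_id[1], " has inconsistent lengths")
      FocusSet(d$chromosome_id[1], d$length[1], d$position)
    })
  }
  if (!is.list(foci) || !all(vapply(foci, is, logical(1), "FocusSet")))
    stop("'foci' must be a list of FocusSet objects or a focus data.frame")
  out <- lapply(foci, function(fs) {
    validObject(fs)
    p <- focusPositions(fs)
    if (length(p) < 2L) return(numeric())
    diff(p) / chromosomeLength(fs)
  })
  unlist(out, use.names = FALSE)
}

## Profile log-likelihood machinery: for gamma data the scale has the
## closed form theta(k) = mean(x)/k, so the MLE reduces to solving
##   log(k) - digamma(k) = log(mean(x)) - mean(log(x))
## in the shape k alone. The right-hand side s is >= 0 (Jensen), and the
## left-hand side decreases monotonically from +Inf to 0, so the root is
## unique. Newton steps with the analytic gradient 1/k - trigamma(k)
## converge in a handful of iterations from the classical starting value;
## uniroot is the bounded fallback.
.gammaShapeMLE <- function(s, cap) {
  if (s <= 0) return(list(shape = cap, capped = TRUE))
  g <- function(k) log(k) - digamma(k) - s
  if (g(cap) > 0) return(list(shape = cap, capped = TRUE))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  k <- min(max(k, 1e-8), cap)
  ok <- FALSE
  for (i in 1:50) {
    step <- g(k) / (1 / k - trigamma(k))
    knew <- k - step
    if (!is.finite(knew) || knew <= 0 || knew > cap) break
    if (abs(knew - k) < 1e-12 * max(1, k)) { k <- knew; ok <- TRUE; break }
    k <- knew
  }
  if (!ok)
    k <- uniroot(g, lower = 1e-8, upper = cap, tol = 1e-12)$root
  list(shape = k, capped = FALSE)
}

#' Fit the crossover-interference gamma model
#'
#' Maximum-likelihood fit of a two-parameter gamma distribution to pooled
#' normalized inter-focus (or inter-CO) distances. The fitted shape factor
#' is the interference statistic: a shape of 1 corresponds to no
#' interference (memoryless crossover placement) and larger shapes to
#' increasingly positive interference. The standard error of the shape is
#' taken from the observed Fisher information with the scale profiled out,
#' `SE = 1 / sqrt(n * (trigamma(shape) - 1/shape))`.
#'
#' @param distances numeric vector of normalized distances, all `> 0`,
#'   `n >= 2`.
#' @param shapeCap upper bound for the shape; when the optimizer reaches it
#'   (e.g. zero-variance distances) the fit is flagged `capped` and the
#'   standard error is undefined.
#' @return An [InterferenceFit-class].
#' @seealso [interfocusDistances()], [gammaFitCurve()]
#' @examples
#' set.seed(1)
#' fitGammaInterference(rgamma(500, shape = 10, scale = 0.02))
#' @export
fitGammaInterference <- function(distances, shapeCap = 1000) {
  x <- as.numeric(distances)
  if (anyNA(x)) stop("distances must not contain NA")
  if (length(x) < 2L)
    stop("insufficient data: a gamma fit requires at least 2 distances")
  if (any(x <= 0)) stop("all distances must be positive")
  if (shapeCap <= 0) stop("shapeCap must be positive")
  n <- length(x)
  s <- log(mean(x)) - mean(log(x))
  ml <- .gammaShapeMLE(s, shapeCap)
  shape <- ml$shape
  scale <- mean(x) / shape
  ll <- sum(dgamma(x, shape = shape, scale = scale, log = TRUE))
  se <- if (ml$capped) NA_real_ else
    1 / sqrt(n * (trigamma(shape) - 1 / shape))
  new("InterferenceFit", shape = shape, scale = scale, loglik = ll,
      shapeSE = se, n = n, capped = ml$capped,
      shapeCap = as.numeric(shapeCap))
}

#' Gamma model CDF for ECDF overlays
#'
#' Evaluates the fitted gamma cumulative distribution function on a grid of
#' normalized distances, for overlaying the model on the empirical CDF of
#' the data (the standard presentation of interference fits).
#'
#' @param fit an [InterferenceFit-class].
#' @param grid numeric vector of non-negative distances.
#' @return Numeric vector of cumulative probabilities.
#' @export
gammaFitCurve <- function(fit, grid) {
  if (!is(fit, "InterferenceFit")) stop("'fit' must be an InterferenceFit")
  g <- as.numeric(grid)
  if (any(g < 0)) stop("grid values must be non-negative")
  pgamma(g, shape = fit@shape, scale = fit@scale)
}

#' Plot an interference fit over the empirical CDF
#'
#' @param fit an [InterferenceFit-class].
#' @param distances the normalized distances the fit was made on.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotInterferenceFit <- function(fit, distances, ...) {
  x <- sort(as.numeric(distances))
  plot(x, seq_along(x) / length(x), xlab = "normalized inter-focus distance",
       ylab = "cumulative probability", ...)
  g <- seq(0, max(x), length.out = 200)
  lines(g, gammaFitCurve(fit, g), col = "red")
  legend("bottomright", bty = "n",
         legend = sprintf("gamma shape = %.2f", fit@shape))
  invisible(NULL)
}
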