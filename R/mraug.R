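#' @include geometry.R
NULL

#' Configuration of MR acquisition-variability augmentations
#'
#' Three intensity-only augmentations emulate between-session MR
#' acquisition variability: a random monotone histogram shift, a random
#' global intensity scaling, and random Gibbs (k-space truncation) ringing.
#' None of them alters geometry or labels.
#'
#' @param histShiftControlPoints number of control points of the piecewise
#'   linear histogram curve (>= 2; endpoints are pinned to the intensity
#'   range).
#' @param histShiftStrength maximum perturbation of interior control
#'   points, as a fraction of the intensity range; 0 disables the shift.
#' @param intensityScaleRange length-2 multiplicative factor range
#'   (lo <= hi); \code{c(1, 1)} disables scaling.
#' @param gibbsAlphaRange length-2 range of the k-space truncation fraction
#'   alpha, within [0, 1); alpha = 0 leaves the image untouched.
#' @param probabilities per-augmentation apply probabilities, named
#'   \code{histogram}, \code{scale}, \code{gibbs} (default all 1).
#' @return an \code{MrAugConfig} (validated list).
#' @export
mrAugConfig <- function(histShiftControlPoints = 5L,
                        histShiftStrength = 0.1,
                        intensityScaleRange = c(0.9, 1.1),
                        gibbsAlphaRange = c(0, 0.4),
                        probabilities = c(histogram = 1, scale = 1,
                                          gibbs = 1)) {
  if (histShiftControlPoints < 2)
    stop("histShiftControlPoints must be >= 2", call. = FALSE)
  if (histShiftStrength < 0)
    stop("histShiftStrength must be >= 0", call. = FALSE)
  if (length(intensityScaleRange) != 2 || diff(intensityScaleRange) < 0)
    stop("intensityScaleRange must be an ordered (lo, hi) pair",
         call. = FALSE)
  if (length(gibbsAlphaRange) != 2 || diff(gibbsAlphaRange) < 0 ||
      gibbsAlphaRange[1] < 0 || gibbsAlphaRange[2] >= 1)
    stop("gibbsAlphaRange must be an ordered pair within [0, 1)",
         call. = FALSE)
  pr <- c(histogram = 1, scale = 1, gibbs = 1)
  pr[names(probabilities)] <- probabilities
  structure(list(histShiftControlPoints = as.integer(histShiftControlPoints),
                 histShiftStrength = histShiftStrength,
                 intensityScaleRange = intensityScaleRange,
                 gibbsAlphaRange = gibbsAlphaRange, probabilities = pr),
            class = "MrAugConfig")
}

.identityConfig <- function() {
  mrAugConfig(histShiftStrength = 0, intensityScaleRange = c(1, 1),
              gibbsAlphaRange = c(0, 0))
}

#' Random monotone histogram shift
#'
#' Remaps intensities through a monotone non-decreasing piecewise-linear
#' curve: control points are placed evenly over the intensity range, the
#' interior ones are perturbed by uniform draws within
#' \code{histShiftStrength} of the range and re-sorted, and the endpoints
#' stay pinned, so the output range equals the input range and the rank
#' order of any two voxels is preserved. Strength 0 is an exact identity.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param config an \code{\link{mrAugConfig}}.
#' @param seed optional integer seed.
#' @return the remapped \linkS4class{ImageVolume} (same geometry).
#' @export
randomHistogramShift <- function(image, config = mrAugConfig(),
                                 seed = NULL) {
  stopifnot(is(image, "ImageVolume"), inherits(config, "MrAugConfig"))
  if (config$histShiftStrength == 0) return(image)
  v <- voxels(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(image)
  k <- config$histShiftControlPoints
  pert <- .withSeed(seed, stats::runif(max(k - 2, 0), -1, 1)) *
    config$histShiftStrength * (hi - lo)
  cx <- seq(lo, hi, length.out = k)
  cy <- cx
  if (k > 2) {
    cy[2:(k - 1)] <- pmin(hi, pmax(lo, cy[2:(k - 1)] + pert))
    cy <- sort(cy)
  }
  out <- stats::approx(cx, cy, xout = as.vector(v), rule = 2)$y
  ImageVolume(array(out, dim(v)), spacing = spacing(image),
              origin = origin(image))
}

#' Random global intensity scaling
#'
#' Multiplies every voxel by one factor drawn uniformly from
#' \code{intensityScaleRange}. The range \code{c(1, 1)} is an exact
#' identity.
#'
#' @inheritParams randomHistogramShift
#' @return the scaled \linkS4class{ImageVolume}.
#' @export
randomIntensityScale <- function(image, config = mrAugConfig(),
                                 seed = NULL) {
  stopifnot(is(image, "ImageVolume"), inherits(config, "MrAugConfig"))
  r <- config$intensityScaleRange
  f <- .withSeed(seed, stats::runif(1, r[1], r[2]))
  if (r[1] == r[2]) f <- r[1]
  if (f == 1) return(image)
  ImageVolume(voxels(image) * f, spacing = spacing(image),
              origin = origin(image))
}

# centered box k-space mask: keep per-axis centered index |k| <= cutoff
.gibbsKeep <- function(n, alpha) {
  k <- 0:(n - 1)
  kc <- ifelse(k <= n %/% 2, k, k - n)
  cutoff <- floor((1 - alpha) * (n / 2))
  abs(kc) <= cutoff
}

#' Random Gibbs (k-space truncation) ringing
#'
#' Forward 3D Fourier transform, zeroing of the fraction alpha of highest
#' spatial frequencies per axis (a centered box mask in k-space), inverse
#' transform, real part. alpha = 0 reproduces the input up to floating
#' round-off; the DC component is always retained, so constant images stay
#' constant. alpha is drawn uniformly from \code{gibbsAlphaRange}.
#'
#' @inheritParams randomHistogramShift
#' @return the \linkS4class{ImageVolume} with truncation ringing.
#' @export
randomGibbsNoise <- function(image, config = mrAugConfig(), seed = NULL) {
  stopifnot(is(image, "ImageVolume"), inherits(config, "MrAugConfig"))
  r <- config$gibbsAlphaRange
  alpha <- .withSeed(seed, stats::runif(1, r[1], r[2]))
  if (r[1] == r[2]) alpha <- r[1]
  if (alpha == 0) return(image)
  v <- voxels(image)
  d <- dim(v)
  keep <- outer(outer(.gibbsKeep(d[1], alpha), .gibbsKeep(d[2], alpha)),
                .gibbsKeep(d[3], alpha))
  ksp <- stats::fft(v)
  ksp[!keep] <- 0
  out <- Re(stats::fft(ksp, inverse = TRUE)) / prod(d)
  ImageVolume(array(out, d), spacing = spacing(image),
              origin = origin(image))
}

#' Apply all MR augmentations in the fixed order
#'
#' Applies histogram shift, then intensity scaling, then Gibbs ringing,
#' each gated by its own apply-probability draw. The order and the gate
#' draws are recorded in the \code{"mrAugLog"} attribute of the result.
#'
#' @inheritParams randomHistogramShift
#' @return the augmented \linkS4class{ImageVolume}.
#' @export
#' @examples
#' p <- makePhantom(phantomSpec(gridShape = c(24, 24, 16)))
#' a <- applyMrAugmentations(p$image, mrAugConfig(), seed = 3)
#' attr(a, "mrAugLog")$order
applyMrAugmentations <- function(image, config = mrAugConfig(),
                                 seed = NULL) {
  stopifnot(is(image, "ImageVolume"), inherits(config, "MrAugConfig"))
  .withSeed(seed, {
    gates <- stats::runif(3) <= config$probabilities
    names(gates) <- c("histogram", "scale", "gibbs")
    out <- image
    if (gates[["histogram"]]) out <- randomHistogramShift(out, config)
    if (gates[["scale"]]) out <- randomIntensityScale(out, config)
    if (gates[["gibbs"]]) out <- randomGibbsNoise(out, config)
    attr(out, "mrAugLog") <- list(order = c("histogram", "scale", "gibbs"),
                                  applied = gates)
    out
  })
}
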