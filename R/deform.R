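#' @include geometry.R
NULL

#' Bounds of the per-organ random deformation
#'
#' Each organ receives an independent random similarity-type motion:
#' translation, isotropic expansion/shrinkage and rotation about its
#' centroid, each component drawn uniformly within these bounds. The two
#' scale parameters control how the dense field is built from the motion:
#' the label's influence decays with a Gaussian of the distance to the
#' organ, and the resulting field is Gaussian-smoothed.
#'
#' @param maxDisplacementMm maximum translation magnitude per axis, mm.
#' @param maxExpansion maximum fractional expansion (scale up to
#'   \code{1 + maxExpansion}).
#' @param maxShrinkage maximum fractional shrinkage (scale down to
#'   \code{1 - maxShrinkage}); must be < 1.
#' @param maxRotationDeg maximum rotation angle about the organ centroid,
#'   degrees, per Euler axis.
#' @param fieldSmoothingMm Gaussian smoothing scale of the dense field, mm.
#' @param influenceDecayMm decay scale of the organ's influence region, mm.
#' @return a \code{DeformParams} (validated list).
#' @export
#' @examples
#' deformParams(maxDisplacementMm = 5, maxRotationDeg = 0)
deformParams <- function(maxDisplacementMm = 8, maxExpansion = 0.15,
                         maxShrinkage = 0.15, maxRotationDeg = 8,
                         fieldSmoothingMm = 4, influenceDecayMm = 15) {
  if (any(c(maxDisplacementMm, maxExpansion, maxShrinkage,
            maxRotationDeg) < 0))
    stop("deformation bounds must be >= 0", call. = FALSE)
  if (maxShrinkage >= 1)
    stop("maxShrinkage must be < 1", call. = FALSE)
  if (fieldSmoothingMm <= 0 || influenceDecayMm <= 0)
    stop("smoothing and decay scales must be > 0", call. = FALSE)
  structure(list(maxDisplacementMm = maxDisplacementMm,
                 maxExpansion = maxExpansion, maxShrinkage = maxShrinkage,
                 maxRotationDeg = maxRotationDeg,
                 fieldSmoothingMm = fieldSmoothingMm,
                 influenceDecayMm = influenceDecayMm),
            class = "DeformParams")
}

#' Draw one random similarity motion
#'
#' Samples each motion component independently and uniformly within the
#' bounds of \code{params}: translation per axis in
#' \code{[-maxDisplacementMm, maxDisplacementMm]}, scale in
#' \code{[1 - maxShrinkage, 1 + maxExpansion]}, Euler angles in
#' \code{[-maxRotationDeg, maxRotationDeg]}. Uses (and advances) R's global
#' RNG stream, so successive calls with identical bounds yield distinct
#' draws; pass \code{seed} for an isolated reproducible draw.
#'
#' @param params a \code{\link{deformParams}}.
#' @param seed optional integer; when given, the draw is made under this
#'   seed without disturbing the global RNG stream.
#' @return a \code{PhiDraw}: list with \code{translationMm} (numeric 3),
#'   \code{scaleFactor} (scalar) and \code{rotationDeg} (numeric 3).
#' @export
samplePhiDraw <- function(params, seed = NULL) {
  stopifnot(inherits(params, "DeformParams"))
  .withSeed(seed, {
    draw <- list(
      translationMm = stats::runif(3, -params$maxDisplacementMm,
                                   params$maxDisplacementMm),
      scaleFactor = stats::runif(1, 1 - params$maxShrinkage,
                                 1 + params$maxExpansion),
      rotationDeg = stats::runif(3, -params$maxRotationDeg,
                                 params$maxRotationDeg))
    # degenerate bounds: runif(n, a, a) is a; force exactness
    if (params$maxDisplacementMm == 0) draw$translationMm <- c(0, 0, 0)
    if (params$maxExpansion == 0 && params$maxShrinkage == 0)
      draw$scaleFactor <- 1
    if (params$maxRotationDeg == 0) draw$rotationDeg <- c(0, 0, 0)
    structure(draw, class = "PhiDraw")
  })
}

.isIdentityDraw <- function(draw) {
  all(draw$translationMm == 0) && draw$scaleFactor == 1 &&
    all(draw$rotationDeg == 0)
}

.rotationMatrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Build the dense displacement field of one organ's random motion
#'
#' Realizes a drawn similarity motion (translate, scale and rotate about the
#' organ centroid) as a dense backward-warping displacement field that is
#' exact wherever the sampled position falls inside the organ, decays to
#' zero away from it with Gaussian scale \code{influenceDecayMm} of the
#' Euclidean distance to the mask, and is finally Gaussian-smoothed at
#' \code{fieldSmoothingMm}. An identity draw yields an exactly zero field.
#'
#' @param mask a nonempty \linkS4class{BinaryMask} (single organ).
#' @param draw a \code{\link{samplePhiDraw}} result.
#' @param params a \code{\link{deformParams}} (for the two scales).
#' @param organ organ name used in error messages.
#' @return a \linkS4class{DisplacementField} on the mask geometry, mm.
#' @export
generateLabelField <- function(mask, draw, params, organ = "organ") {
  stopifnot(is(mask, "BinaryMask"), inherits(draw, "PhiDraw"),
            inherits(params, "DeformParams"))
  d <- .gridDim(mask)
  if (!any(voxels(mask) != 0))
    stop("empty label for '", organ, "': cannot build a deformation field",
         call. = FALSE)
  if (.isIdentityDraw(draw))
    return(DisplacementField(array(0, c(d, 3)), spacing = spacing(mask),
                             origin = origin(mask)))
  w <- .worldGrid(mask)
  inside <- as.vector(voxels(mask) != 0)
  centroid <- colMeans(w[inside, , drop = FALSE])
  rot <- .rotationMatrix(draw$rotationDeg)
  s <- draw$scaleFactor
  # forward motion A(x) = R s (x - c) + c + t ; backward field samples A^-1
  pre <- sweep(w, 2, centroid + draw$translationMm, "-") %*% rot / s
  pre <- sweep(pre, 2, centroid, "+")
  disp <- pre - w
  # influence weight evaluated at the sampled (pre-image) position, so the
  # motion is exact wherever the sampled point lies in or near the organ
  distMm <- distanceToMask(mask)
  wgt <- exp(-distMm^2 / (2 * params$influenceDecayMm^2))
  preIdx <- .worldToIndex(pre, spacing(mask), origin(mask))
  wAtPre <- .sampleTrilinear(as.numeric(wgt), as.integer(d), preIdx)
  u <- disp * wAtPre
  field <- array(u, c(d, 3))
  for (k in 1:3)
    field[, , , k] <- gaussianSmooth(field[, , , k], params$fieldSmoothingMm,
                                     spacing(mask))
  DisplacementField(field, spacing = spacing(mask), origin = origin(mask))
}

#' Compose two displacement fields
#'
#' Returns the single field equivalent to warping by \code{first} and then
#' warping the result by \code{second} under the backward-warping
#' convention: \code{u(x) = second(x) + first(x + second(x))}, with the
#' off-grid lookup of \code{first} linearly interpolated (edge-clamped).
#' Composing with a zero field returns the other field unchanged.
#'
#' @param first,second \linkS4class{DisplacementField}s on one geometry;
#'   \code{first} is the warp applied first.
#' @return the composed \linkS4class{DisplacementField}.
#' @export
composeFields <- function(first, second) {
  stopifnot(is(first, "DisplacementField"), is(second, "DisplacementField"))
  .stopGeometry(first, second, "displacement fields")
  d <- .gridDim(first)
  n <- prod(d)
  spc <- spacing(first)
  u2 <- matrix(voxels(second), ncol = 3)
  idx <- .indexGrid(d)
  pts <- idx + sweep(u2, 2, spc, "/")
  u1v <- voxels(first)
  out <- u2
  for (k in 1:3)
    out[, k] <- out[, k] +
      .sampleTrilinear(as.numeric(u1v[, , , k]), as.integer(d), pts)
  DisplacementField(array(out, c(d, 3)), spacing = spc,
                    origin = origin(first))
}

.warpArray <- function(arr, field, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  spc <- spacing(field)
  u <- matrix(voxels(field), ncol = 3)
  pts <- .indexGrid(d) + sweep(u, 2, spc, "/")
  fun <- if (method == "linear") .sampleTrilinear else .sampleNearest
  array(fun(as.numeric(arr), as.integer(d), pts), d)
}

#' Warp an image with a displacement field
#'
#' Backward warping: the output at voxel position x samples the input at
#' \code{T(x) = x + u(x)} with linear interpolation; out-of-domain samples
#' take the nearest-edge value. The output geometry equals the input
#' geometry, and warped intensities never exceed the input extrema.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param field a \linkS4class{DisplacementField} on the same geometry.
#' @return the warped \linkS4class{ImageVolume}.
#' @export
warpImage <- function(image, field) {
  stopifnot(is(image, "ImageVolume"), is(field, "DisplacementField"))
  .stopGeometry(image, field, "image and field")
  ImageVolume(.warpArray(voxels(image), field, "linear"),
              spacing = spacing(image), origin = origin(image))
}

#' Warp a label map with a displacement field
#'
#' As \code{\link{warpImage}} but with nearest-neighbour interpolation, so
#' the output code set is always a subset of the input code set.
#'
#' @param labels a \linkS4class{LabelVolume} (or \linkS4class{BinaryMask}).
#' @param field a \linkS4class{DisplacementField} on the same geometry.
#' @return the warped labels, same class as the input.
#' @export
warpLabels <- function(labels, field) {
  stopifnot(is(field, "DisplacementField"))
  .stopGeometry(labels, field, "labels and field")
  out <- .warpArray(voxels(labels), field, "nearest")
  if (is(labels, "BinaryMask"))
    BinaryMask(out, spacing = spacing(labels), origin = origin(labels))
  else
    LabelVolume(out, organTable = organTable(labels),
                spacing = spacing(labels), origin = origin(labels))
}

#' Simulate one inter-fraction session by structure-guided deformation
#'
#' Iterates over the organs in ascending label-code order; for organ k the
#' current label channel is first warped by the already-composed field of
#' organs 1..k-1, a fresh random similarity motion is drawn and converted
#' into organ k's dense field from that warped mask, and the composition is
#' updated. Finally the image (linear) and all labels (nearest) are warped
#' once with the total field, which is also returned for quality assurance.
#'
#' @param image session \linkS4class{ImageVolume}.
#' @param labels paired \linkS4class{LabelVolume}.
#' @param params \code{\link{deformParams}} bounds.
#' @param seed optional integer seed for the random draws.
#' @param organOrder optional character vector overriding the iteration
#'   order (default: ascending label code); the order is recorded in the
#'   result since it affects the composed field.
#' @param strict if \code{TRUE}, reject fields whose minimum Jacobian
#'   determinant is <= 0 (folding) with an error; otherwise only warn.
#' @return list with \code{image}, \code{labels}, \code{field} (the total
#'   \linkS4class{DisplacementField}), \code{draws} (per-organ motions) and
#'   \code{organOrder}.
#' @export
#' @examples
#' p <- makePhantom(phantomSpec(gridShape = c(32, 32, 24)))
#' s <- simulateSession(p$image, p$labels,
#'                      deformParams(maxDisplacementMm = 4), seed = 1)
#' jacobianMin(s$field)
simulateSession <- function(image, labels, params, seed = NULL,
                            organOrder = NULL, strict = FALSE) {
  stopifnot(is(image, "ImageVolume"), is(labels, "LabelVolume"),
            inherits(params, "DeformParams"))
  .stopGeometry(image, labels, "image and labels")
  if (!any(voxels(labels) != 0))
    stop("label map is all background; nothing to deform", call. = FALSE)
  tab <- organTable(labels)
  present <- names(tab)[vapply(tab, function(k) any(voxels(labels) == k),
                               logical(1))]
  if (is.null(organOrder)) {
    organOrder <- present[order(tab[present])]
  } else {
    stopifnot(all(organOrder %in% names(tab)))
    organOrder <- intersect(organOrder, present)
  }
  d <- .gridDim(image)
  run <- function() {
    uAcc <- DisplacementField(array(0, c(d, 3)), spacing = spacing(image),
                              origin = origin(image))
    draws <- list()
    for (organ in organOrder) {
      mask <- organMask(labels, organ)
      warpedMask <- warpLabels(mask, uAcc)
      draw <- samplePhiDraw(params)
      draws[[organ]] <- draw
      if (!any(voxels(warpedMask) != 0)) {
        warning("organ '", organ,
                "' vanished under the accumulated field; skipping its draw",
                call. = FALSE)
        next
      }
      uk <- generateLabelField(warpedMask, draw, params, organ = organ)
      uAcc <- composeFields(uk, uAcc)
    }
    jmin <- jacobianMin(uAcc, warn = !strict)
    if (strict && jmin <= 0)
      stop(sprintf("composed field folds (min Jacobian %.3g <= 0)", jmin),
           call. = FALSE)
    list(image = warpImage(image, uAcc),
         labels = warpLabels(labels, uAcc),
         field = uAcc, draws = draws, organOrder = organOrder,
         jacobianMin = jmin)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

.gradAxis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  idxAll <- function(i) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- i
    ix
  }
  g <- array(0, d)
  if (n >= 3) {
    hi <- do.call(`[`, c(list(arr), idxAll(3:n), list(drop = FALSE)))
    lo <- do.call(`[`, c(list(arr), idxAll(1:(n - 2)), list(drop = FALSE)))
    g <- do.call(`[<-`, c(list(g), idxAll(2:(n - 1)),
                          list(value = (hi - lo) / (2 * h))))
  }
  first <- (do.call(`[`, c(list(arr), idxAll(2), list(drop = FALSE))) -
            do.call(`[`, c(list(arr), idxAll(1), list(drop = FALSE)))) / h
  last <- (do.call(`[`, c(list(arr), idxAll(n), list(drop = FALSE))) -
           do.call(`[`, c(list(arr), idxAll(n - 1), list(drop = FALSE)))) / h
  g <- do.call(`[<-`, c(list(g), idxAll(1), list(value = first)))
  do.call(`[<-`, c(list(g), idxAll(n), list(value = last)))
}

#' Minimum Jacobian determinant of a displacement field's transform
#'
#' Computes the spatial Jacobian of \code{T(x) = x + u(x)} by central
#' differences in physical units (one-sided at the grid edges) and returns
#' the minimum determinant over the grid. A value <= 0 indicates folding
#' (a non-injective transform); a warning is emitted in that case.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param warn emit a warning when folding is detected.
#' @return scalar minimum Jacobian determinant (1 for the identity).
#' @export
jacobianMin <- function(field, warn = TRUE) {
  stopifnot(is(field, "DisplacementField"))
  u <- voxels(field)
  spc <- spacing(field)
  d <- dim(u)[1:3]
  J <- vector("list", 9)
  for (comp in 1:3)
    for (axis in 1:3) {
      g <- .gradAxis(array(u[, , , comp], d), axis, spc[axis])
      if (comp == axis) g <- g + 1
      J[[(comp - 1) * 3 + axis]] <- as.vector(g)
    }
  # det of [a b c; d e f; g h i] with row = component, col = axis
  a <- J[[1]]; b <- J[[2]]; cc <- J[[3]]
  dd <- J[[4]]; e <- J[[5]]; f <- J[[6]]
  g <- J[[7]]; h <- J[[8]]; i <- J[[9]]
  det <- a * (e * i - f * h) - b * (dd * i - f * g) + cc * (dd * h - e * g)
  jmin <- min(det)
  if (warn && jmin <= 0)
    warning(sprintf("displacement field folds: min Jacobian %.3g <= 0",
                    jmin), call. = FALSE)
  jmin
}
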