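#' @include AllClasses.R
NULL

.gridDim <- function(x) dim(voxels(x))[1:3]

#' Test whether two volumes share one grid geometry
#'
#' @param a,b volume objects (image, labels, mask, dose or field).
#' @param tol numeric tolerance on spacing/origin in mm.
#' @return logical scalar.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  all(.gridDim(a) == .gridDim(b)) &&
    all(abs(spacing(a) - spacing(b)) < tol) &&
    all(abs(origin(a) - origin(b)) < tol)
}

.stopGeometry <- function(a, b, what = "inputs") {
  if (!sameGeometry(a, b))
    stop(what, " do not share the same grid geometry ",
         "(shape, spacing and origin must match)", call. = FALSE)
  invisible(TRUE)
}

# n x 3 matrix of 1-based voxel indices for every voxel, column-major order
.indexGrid <- function(d) {
  cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
        rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

# world (mm) coordinates of every voxel center, n x 3
.worldGrid <- function(x) {
  d <- .gridDim(x)
  idx <- .indexGrid(d)
  sweep(sweep(idx - 1, 2, spacing(x), "*"), 2, origin(x), "+")
}

.worldToIndex <- function(pts, spc, org) {
  sweep(sweep(pts, 2, org, "-"), 2, spc, "/") + 1
}

#' Extract a single-organ binary mask from a label volume
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param organ organ name (must be in \code{organTable(labels)}) or an
#'   integer code.
#' @return a \linkS4class{BinaryMask} on the same geometry.
#' @export
#' @examples
#' p <- makePhantom(phantomSpec(gridShape = c(32, 32, 24)))
#' m <- organMask(p$labels, "liver")
#' sum(voxels(m))
organMask <- function(labels, organ) {
  stopifnot(is(labels, "LabelVolume"))
  tab <- organTable(labels)
  code <- if (is.character(organ)) {
    if (!organ %in% names(tab))
      stop("unknown organ '", organ, "'", call. = FALSE)
    tab[[organ]]
  } else as.integer(organ)
  BinaryMask(array(as.numeric(voxels(labels) == code), .gridDim(labels)),
             spacing = spacing(labels), origin = origin(labels))
}

#' Euclidean distance to a mask, in mm
#'
#' Distance from each voxel center to the nearest voxel center belonging to
#' the mask (0 inside the mask), computed by a separable exact distance
#' transform honouring anisotropic spacing.
#'
#' @param mask a \linkS4class{BinaryMask} or a logical/0-1 array.
#' @param spacing voxel spacing in mm (ignored when \code{mask} is a
#'   \code{BinaryMask}).
#' @return 3D numeric array of distances in mm.
#' @export
distanceToMask <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "BinaryMask")) {
    spacing <- spacing(mask)
    mask <- voxels(mask)
  }
  m <- array(as.logical(mask != 0), dim(mask))
  if (!any(m)) stop("mask is empty; distance is undefined", call. = FALSE)
  sq <- .edtSquared(as.vector(m), as.integer(dim(m)), as.numeric(spacing))
  array(sqrt(sq), dim(m))
}

#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian blur with replicate-edge padding; \code{sigma} is given
#' in mm and converted to voxels through \code{spacing}. \code{sigma = 0}
#' returns the input unchanged.
#'
#' @param arr 3D numeric array.
#' @param sigmaMm Gaussian standard deviation in mm (scalar or length 3).
#' @param spacing voxel spacing in mm.
#' @return smoothed array of the same dimension.
#' @export
gaussianSmooth <- function(arr, sigmaMm, spacing = c(1, 1, 1)) {
  sig <- rep_len(as.numeric(sigmaMm), 3) / as.numeric(spacing)
  if (all(sig <= 0)) return(arr)
  out <- .gaussBlur3d(as.numeric(arr), as.integer(dim(arr)), sig)
  array(out, dim(arr))
}

# deterministic per-stage child seed below 2^31
.deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
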