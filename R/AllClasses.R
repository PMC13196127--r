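#' @include AllGenerics.R
NULL

.checkGeometrySlots <- function(object, ncomp = NULL) {
  msg <- character()
  d <- dim(object@voxels)
  want <- if (is.null(ncomp)) 3L else 4L
  if (length(d) != want)
    msg <- c(msg, sprintf("voxel array must be %d-dimensional", want))
  if (!is.null(ncomp) && length(d) == 4L && d[4] != ncomp)
    msg <- c(msg, sprintf("last axis must have %d components", ncomp))
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  msg
}

#' ImageVolume: a 3D scalar grid with physical geometry
#'
#' The basic session-image container: a 3D array of intensities plus voxel
#' spacing and world origin in mm. World coordinates follow
#' \code{origin + (index - 1) * spacing} on a fixed right-handed axis order
#' (x: right, y: anterior, z: superior).
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric(3), voxel size in mm, all > 0.
#' @slot origin numeric(3), world coordinate of voxel (1,1,1) in mm.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of the first voxel, mm.
#' @return an \code{ImageVolume}.
#' @export
#' @examples
#' iv <- ImageVolume(array(rnorm(64), c(4, 4, 4)), spacing = c(2, 2, 2))
#' iv
setClass("ImageVolume",
         representation(voxels = "array", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           msg <- .checkGeometrySlots(object)
           if (any(!is.finite(object@voxels)))
             msg <- c(msg, "all voxel values must be finite")
           if (length(msg)) msg else TRUE
         })

#' @rdname ImageVolume-class
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LabelVolume: an integer-coded multi-organ map
#'
#' Voxel codes are 0 (background) or one of the codes in \code{organTable},
#' a named integer vector mapping organ name to code. Codes are assigned
#' 1..N in the listed organ order.
#'
#' @slot voxels 3D array of integer codes (stored as numeric).
#' @slot spacing,origin geometry as in \linkS4class{ImageVolume}.
#' @slot organTable named integer vector, organ name -> code.
#'
#' @param voxels 3D array of integer codes.
#' @param organTable named integer vector mapping organ names to codes.
#' @param spacing,origin geometry in mm.
#' @return a \code{LabelVolume}.
#' @export
setClass("LabelVolume",
         representation(voxels = "array", spacing = "numeric",
                        origin = "numeric", organTable = "integer"),
         validity = function(object) {
           msg <- .checkGeometrySlots(object)
           v <- object@voxels
           if (any(v != round(v)) || any(v < 0))
             msg <- c(msg, "label codes must be non-negative integers")
           tab <- object@organTable
           if (is.null(names(tab)) || anyDuplicated(names(tab)) ||
               anyDuplicated(tab))
             msg <- c(msg, "organTable must map unique names to unique codes")
           extra <- setdiff(unique(v[v != 0]), tab)
           if (length(extra))
             msg <- c(msg, paste("codes not in organTable:",
                                 paste(extra, collapse = ", ")))
           if (length(msg)) msg else TRUE
         })

#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(voxels, organTable, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  tab <- as.integer(organTable)
  names(tab) <- names(organTable)
  new("LabelVolume", voxels = voxels, organTable = tab,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' BinaryMask: a single-structure 0/1 mask
#'
#' An \linkS4class{ImageVolume} whose voxels are restricted to \{0, 1\};
#' used for single-organ channels and all metric computations.
#'
#' @param voxels 3D array with values in \{0, 1\} (logical accepted).
#' @param spacing,origin geometry in mm.
#' @return a \code{BinaryMask}.
#' @export
setClass("BinaryMask", contains = "ImageVolume",
         validity = function(object) {
           if (!all(object@voxels %in% c(0, 1)))
             "mask voxels must be 0 or 1" else TRUE
         })

#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.numeric(voxels), dim(voxels))
  new("BinaryMask", voxels = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' DoseGrid: absorbed dose with its prescription
#'
#' A non-negative dose distribution in Gy on an image grid, carrying the
#' prescribed dose PD (Gy) used to express DVH discrepancies as percentages
#' of PD.
#'
#' @slot prescription positive scalar, the prescribed dose PD in Gy.
#'
#' @param voxels 3D array of dose in Gy, all >= 0.
#' @param prescription prescribed dose PD in Gy (> 0).
#' @param spacing,origin geometry in mm.
#' @return a \code{DoseGrid}.
#' @export
setClass("DoseGrid", contains = "ImageVolume",
         representation(prescription = "numeric"),
         validity = function(object) {
           msg <- character()
           if (any(object@voxels < 0)) msg <- c(msg, "dose must be >= 0 Gy")
           if (length(object@prescription) != 1L ||
               !is.finite(object@prescription) || object@prescription <= 0)
             msg <- c(msg, "prescription must be a positive scalar (Gy)")
           if (length(msg)) msg else TRUE
         })

#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(voxels, prescription, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
  new("DoseGrid", voxels = voxels, prescription = as.numeric(prescription),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' DisplacementField: a dense per-voxel displacement in mm
#'
#' A 4D array (nx, ny, nz, 3) of displacement vectors u(x) in mm on an image
#' grid. The associated transform is backward-warping:
#' \code{T(x) = x + u(x)}; warping samples the source volume at \code{T(x)}.
#'
#' @slot vectors 4D numeric array, last axis = (x, y, z) components in mm.
#' @slot spacing,origin geometry as in \linkS4class{ImageVolume}.
#'
#' @param vectors 4D numeric array (nx, ny, nz, 3), mm.
#' @param spacing,origin geometry in mm.
#' @return a \code{DisplacementField}.
#' @export
setClass("DisplacementField",
         representation(vectors = "array", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           msg <- character()
           d <- dim(object@vectors)
           if (length(d) != 4L || d[4] != 3L)
             msg <- c(msg, "vectors must be a 4D array with 3 components")
           if (any(!is.finite(object@vectors)))
             msg <- c(msg, "all displacement components must be finite")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             msg <- c(msg, "spacing must be 3 positive values (mm)")
           if (length(object@origin) != 3L || any(!is.finite(object@origin)))
             msg <- c(msg, "origin must be 3 finite values (mm)")
           if (length(msg)) msg else TRUE
         })

#' @rdname DisplacementField-class
#' @export
DisplacementField <- function(vectors, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' DVHCurve: a cumulative dose-volume histogram
#'
#' For a structure, \code{volumeFraction[i]} is the fraction of the
#' structure's volume receiving at least \code{doseEdges[i]} Gy; the curve
#' starts at 1 for dose 0 and is non-increasing.
#'
#' @slot doseEdges ascending dose levels in Gy, starting at 0.
#' @slot volumeFraction cumulative volume fractions in [0, 1].
#' @export
setClass("DVHCurve",
         representation(doseEdges = "numeric", volumeFraction = "numeric"),
         validity = function(object) {
           msg <- character()
           if (length(object@doseEdges) != length(object@volumeFraction))
             msg <- c(msg, "doseEdges and volumeFraction lengths differ")
           if (is.unsorted(object@doseEdges))
             msg <- c(msg, "doseEdges must be ascending")
           if (any(diff(object@volumeFraction) > 1e-12))
             msg <- c(msg, "volumeFraction must be non-increasing")
           if (length(object@volumeFraction) &&
               abs(object@volumeFraction[1] - 1) > 1e-12)
             msg <- c(msg, "volumeFraction must start at 1 for dose 0")
           if (length(msg)) msg else TRUE
         })

## accessors ----------------------------------------------------------------

#' @rdname volume-accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)
#' @rdname volume-accessors
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)
#' @rdname volume-accessors
#' @export
setMethod("voxels", "DisplacementField", function(x) x@vectors)

#' @rdname volume-accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' @rdname LabelVolume-class
#' @param x a \code{LabelVolume}.
#' @export
setMethod("organTable", "LabelVolume", function(x) x@organTable)

#' @rdname DoseGrid-class
#' @param x a \code{DoseGrid}.
#' @export
setMethod("prescription", "DoseGrid", function(x) x@prescription)

#' @rdname DVHCurve-class
#' @param x a \code{DVHCurve}.
#' @export
doseEdges <- function(x) x@doseEdges

#' @rdname DVHCurve-class
#' @export
volumeFraction <- function(x) x@volumeFraction

## show methods -------------------------------------------------------------

.showGeom <- function(x) {
  d <- dim(voxels(x))[1:3]
  cat(sprintf("  grid %s | spacing %s mm | origin %s mm\n",
              paste(d, collapse = "x"),
              paste(format(spacing(x), trim = TRUE), collapse = "x"),
              paste(format(origin(x), trim = TRUE), collapse = ", ")))
}

setMethod("show", "ImageVolume", function(object) {
  cat(class(object), "\n")
  .showGeom(object)
  v <- object@voxels
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume\n")
  .showGeom(object)
  tab <- object@organTable
  present <- vapply(tab, function(k) sum(object@voxels == k), numeric(1))
  cat(sprintf("  %d organs (%d present): %s\n", length(tab),
              sum(present > 0),
              paste(names(tab)[present > 0], collapse = ", ")))
})

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid\n")
  .showGeom(object)
  cat(sprintf("  dose range [%.3g, %.3g] Gy | prescription %.3g Gy\n",
              min(object@voxels), max(object@voxels), object@prescription))
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField\n")
  .showGeom(object)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat(sprintf("  |u| max %.3g mm, mean %.3g mm\n", max(mag), mean(mag)))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve: %d dose levels in [%.3g, %.3g] Gy\n",
              length(object@doseEdges), min(object@doseEdges),
              max(object@doseEdges)))
})
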