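#' @include RcppExports.R
NULL

#' Accessors for spatial volumes
#'
#' All volume classes (\linkS4class{ImageVolume}, \linkS4class{LabelVolume},
#' \linkS4class{BinaryMask}, \linkS4class{DoseGrid},
#' \linkS4class{DisplacementField}) share one geometry model: a regular grid
#' whose world coordinate (mm) of 1-based voxel index \code{(i, j, k)} is
#' \code{origin + (c(i, j, k) - 1) * spacing} in a fixed right-handed axis
#' order.
#'
#' @param x a volume object.
#' @return \code{voxels()} returns the underlying array (3D, or 4D with a
#'   trailing component axis for displacement fields); \code{spacing()} and
#'   \code{origin()} return numeric length-3 vectors in mm.
#' @name volume-accessors
#' @aliases voxels spacing origin
#' @examples
#' iv <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(voxels(iv))
#' spacing(iv)
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname volume-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname volume-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname LabelVolume-class
#' @export
setGeneric("organTable", function(x) standardGeneric("organTable"))

#' @rdname DoseGrid-class
#' @export
setGeneric("prescription", function(x) standardGeneric("prescription"))
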