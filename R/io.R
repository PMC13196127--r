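#' @include geometry.R
NULL

.asNiftiWithGeom <- function(arr, spc, org) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spc, rep(1, nd - 3L))
  m <- diag(4)
  m[1:3, 1:3] <- diag(spc)
  m[1:3, 4] <- org
  m <- structure(m, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  img
}

#' Read and write volumes as NIfTI
#'
#' Images and dose grids are stored as 64-bit floats so that write/read
#' round-trips are bit-exact; label maps as 16-bit integers; displacement
#' fields as 4D volumes whose last axis holds the (x, y, z) components in
#' mm. Spacing is carried in \code{pixdim} and the origin in an axis-aligned
#' qform/sform.
#'
#' @param x the volume to write.
#' @param path file path, conventionally ending in \code{.nii.gz}.
#' @return \code{writeVolume} returns \code{path} invisibly;
#'   \code{readVolume} returns an object of the class selected by
#'   \code{type}.
#' @name volume-io
#' @export
writeVolume <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is(x, "DisplacementField")) {
    img <- .asNiftiWithGeom(voxels(x), spacing(x), origin(x))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (is(x, "LabelVolume")) {
    img <- .asNiftiWithGeom(voxels(x), spacing(x), origin(x))
    RNifti::writeNifti(img, path, datatype = "int16")
  } else if (is(x, "ImageVolume")) {  # includes BinaryMask, DoseGrid
    img <- .asNiftiWithGeom(voxels(x), spacing(x), origin(x))
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop("cannot write object of class ", class(x), call. = FALSE)
  invisible(path)
}

#' @rdname volume-io
#' @param type one of \code{"image"}, \code{"labels"}, \code{"mask"},
#'   \code{"dose"}, \code{"field"}.
#' @param organTable named integer vector for \code{type = "labels"}; when
#'   \code{NULL}, codes present in the file are named \code{organ<code>}.
#' @param prescriptionGy prescribed dose for \code{type = "dose"}.
#' @export
readVolume <- function(path, type = c("image", "labels", "mask", "dose",
                                      "field"),
                       organTable = NULL, prescriptionGy = NULL) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop("file does not exist: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(nii)[1:3]
  hdr <- RNifti::niftiHeader(nii)
  org <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  arr <- array(as.numeric(nii), dim(nii))
  switch(type,
    image = ImageVolume(arr, spacing = spc, origin = org),
    mask = BinaryMask(arr, spacing = spc, origin = org),
    labels = {
      if (is.null(organTable)) {
        codes <- sort(unique(arr[arr != 0]))
        organTable <- structure(as.integer(codes),
                                names = paste0("organ", codes))
      }
      LabelVolume(arr, organTable = organTable, spacing = spc, origin = org)
    },
    dose = {
      if (is.null(prescriptionGy))
        stop("prescriptionGy is required to read a dose grid", call. = FALSE)
      DoseGrid(arr, prescription = prescriptionGy, spacing = spc,
               origin = org)
    },
    field = DisplacementField(arr, spacing = spc, origin = org))
}

#' Cohort registries
#'
#' A cohort registry maps each patient to its ordered list of sessions
#' (image path, label path, optional displacement-field path). It is the
#' interchange object between the phantom generator, the conditioning
#' module and the evaluation tools, and is serialized as JSON.
#'
#' @param patients named list; one element per patient, each a data.frame
#'   with columns \code{session}, \code{image}, \code{labels} and optionally
#'   \code{field}.
#' @param root directory that relative paths are resolved against.
#' @param organTable named integer vector shared by all label maps.
#' @return a \code{CohortRegistry}.
#' @export
CohortRegistry <- function(patients, root = ".", organTable = integer()) {
  tab <- as.integer(organTable)
  names(tab) <- names(organTable)
  new("CohortRegistry", patients = patients, root = root, organTable = tab)
}

#' @rdname CohortRegistry
#' @slot patients named list of per-patient session data.frames.
#' @slot root base directory for relative paths.
#' @slot organTable named integer vector, organ name -> label code.
#' @export
setClass("CohortRegistry",
         representation(patients = "list", root = "character",
                        organTable = "integer"),
         validity = function(object) {
           msg <- character()
           if (is.null(names(object@patients)) ||
               anyDuplicated(names(object@patients)))
             msg <- c(msg, "patient ids must be unique and named")
           for (pid in names(object@patients)) {
             s <- object@patients[[pid]]
             if (!is.data.frame(s) ||
                 !all(c("session", "image", "labels") %in% names(s)))
               msg <- c(msg, sprintf(
                 "patient %s: sessions need columns session/image/labels",
                 pid))
             else if (anyDuplicated(s$session) || is.unsorted(s$session))
               msg <- c(msg, sprintf(
                 "patient %s: session indices must be unique and ordered",
                 pid))
           }
           if (length(msg)) msg else TRUE
         })

setMethod("show", "CohortRegistry", function(object) {
  ns <- vapply(object@patients, nrow, integer(1))
  cat(sprintf("CohortRegistry: %d patients, %d images (root: %s)\n",
              length(ns), sum(ns), object@root))
  for (pid in names(object@patients))
    cat(sprintf("  %s: %d sessions\n", pid, ns[[pid]]))
})

#' @rdname CohortRegistry
#' @param registry a \code{CohortRegistry}.
#' @param x a \code{CohortRegistry}.
#' @export
registryPatients <- function(x) x@patients

#' Number of session images in a registry
#' @param x a \code{CohortRegistry}.
#' @return integer count of all sessions over all patients.
#' @export
registryImageCount <- function(x) {
  sum(vapply(x@patients, nrow, integer(1)))
}

#' @rdname CohortRegistry
#' @param path JSON file path.
#' @export
writeRegistry <- function(registry, path) {
  obj <- list(
    organ_table = as.list(registry@organTable),
    patients = lapply(registry@patients, function(s)
      lapply(seq_len(nrow(s)), function(i) as.list(s[i, , drop = FALSE])))
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname CohortRegistry
#' @export
readRegistry <- function(path) {
  obj <- jsonlite::read_json(path)
  tab <- unlist(obj$organ_table)
  patients <- lapply(obj$patients, function(ss)
    do.call(rbind, lapply(ss, function(s)
      data.frame(session = as.integer(s$session), image = s$image,
                 labels = s$labels,
                 field = if (is.null(s$field)) NA_character_ else s$field,
                 stringsAsFactors = FALSE))))
  CohortRegistry(patients, root = dirname(path),
                 organTable = structure(as.integer(tab), names = names(tab)))
}

.resolvePath <- function(registry, path) {
  ifelse(grepl("^(/|[A-Za-z]:)", path), path,
         file.path(registry@root, path))
}
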