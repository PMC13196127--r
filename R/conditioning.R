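#' @include io.R deform.R
NULL

#' Enumerate ordered within-patient session pairs
#'
#' Every ordered pair (m, n) with m != n of a patient's sessions is a
#' candidate conditioning pair: the source session m contributes the prior
#' image and organ mask, the target session n the image to segment. A
#' patient with k sessions contributes k(k-1) ordered pairs under
#' \code{scope = "all_ordered"}, and k-1 pairs under
#' \code{scope = "first_to_rest"} (deployment: the first session is always
#' the source).
#'
#' @param registry a \linkS4class{CohortRegistry}.
#' @param patientSubset optional character vector of patient ids.
#' @param scope \code{"all_ordered"} (training arrangement; all ordered
#'   pairs) or \code{"first_to_rest"} (deployment: session 1 is always the
#'   source).
#' @return data.frame with columns \code{patient}, \code{m}, \code{n},
#'   ordered by patient then m then n. Patients with fewer than two
#'   sessions contribute zero pairs (with a warning).
#' @export
#' @examples
#' reg <- CohortRegistry(list(
#'   A = data.frame(session = 1:2, image = c("a1", "a2"),
#'                  labels = c("l1", "l2"))))
#' enumeratePairs(reg)
enumeratePairs <- function(registry, patientSubset = NULL,
                           scope = c("all_ordered", "first_to_rest")) {
  stopifnot(is(registry, "CohortRegistry"))
  scope <- match.arg(scope)
  pids <- names(registry@patients)
  if (!is.null(patientSubset)) {
    missing <- setdiff(patientSubset, pids)
    if (length(missing))
      stop("unknown patients: ", paste(missing, collapse = ", "),
           call. = FALSE)
    pids <- pids[pids %in% patientSubset]
  }
  out <- list()
  for (pid in pids) {
    ses <- registry@patients[[pid]]$session
    if (length(ses) < 2) {
      warning("patient '", pid, "' has fewer than 2 sessions; no pairs",
              call. = FALSE)
      next
    }
    grid <- expand.grid(n = ses, m = if (scope == "first_to_rest")
      ses[1] else ses)
    grid <- grid[grid$m != grid$n, c("m", "n")]
    grid <- grid[order(grid$m, grid$n), ]
    out[[pid]] <- data.frame(patient = pid, m = grid$m, n = grid$n,
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(patient = character(), m = integer(), n = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build single-organ three-channel conditioned cases
#'
#' For each (source m, target n) pair and each organ o, a conditioned case
#' concatenates three channels: the source image, the source label
#' binarized to organ o, and the target image. Organs absent from a source
#' label map (for example a missing kidney) are skipped with a notice, so
#' the case count is |pairs| x (number of organs present per source).
#'
#' @param registry a \linkS4class{CohortRegistry}.
#' @param pairs data.frame from \code{\link{enumeratePairs}}.
#' @param organs organ names to condition on (default: the registry's full
#'   organ table).
#' @return data.frame of case metadata with columns \code{caseId},
#'   \code{patient}, \code{m}, \code{n}, \code{organ}; case ids follow
#'   \code{P<patient>_s<m>to<n>_<organ>}.
#' @export
buildConditionedCases <- function(registry, pairs, organs = NULL) {
  stopifnot(is(registry, "CohortRegistry"), is.data.frame(pairs))
  tab <- registry@organTable
  if (is.null(organs)) organs <- names(tab)
  unknown <- setdiff(organs, names(tab))
  if (length(unknown))
    stop("organs not in the registry organ table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # organs actually present per (patient, source session)
  presence <- new.env(parent = emptyenv())
  presentOrgans <- function(pid, m) {
    key <- paste(pid, m, sep = "\r")
    if (!is.null(presence[[key]])) return(presence[[key]])
    row <- registry@patients[[pid]]
    lab <- readVolume(.resolvePath(registry, row$labels[row$session == m]),
                      "labels", organTable = tab)
    codes <- unique(as.vector(voxels(lab)))
    pres <- organs[tab[organs] %in% codes]
    presence[[key]] <- pres
    pres
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$patient[i]; m <- pairs$m[i]; n <- pairs$n[i]
    pres <- presentOrgans(pid, m)
    absent <- setdiff(organs, pres)
    if (length(absent))
      message("patient ", pid, " session ", m, ": skipping absent organ(s) ",
              paste(absent, collapse = ", "))
    if (!length(pres)) next
    out[[i]] <- data.frame(
      caseId = sprintf("P%s_s%dto%d_%s", pid, m, n, pres),
      patient = pid, m = m, n = n, organ = pres, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(caseId = character(), patient = character(),
                      m = integer(), n = integer(), organ = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyDuplicated(res$caseId))
    stop("case id collision; pairs must be unique", call. = FALSE)
  res
}

#' Resample an image/label pair onto a reference grid
#'
#' Maps every reference voxel center into the moving volume's continuous
#' index space through world coordinates and samples the image with linear
#' interpolation and the labels with nearest-neighbour, so the label code
#' set never grows. The output geometry equals the reference geometry
#' exactly. Used to reassign an offline source session to the target
#' session geometry so all channels share one grid.
#'
#' @param movingImage \linkS4class{ImageVolume} to resample (or NULL).
#' @param movingLabels \linkS4class{LabelVolume} to resample (or NULL).
#' @param reference any volume supplying the target geometry.
#' @return list with resampled \code{image} and \code{labels}.
#' @export
resampleToGrid <- function(movingImage, movingLabels, reference) {
  refD <- .gridDim(reference)
  world <- .worldGrid(reference)
  resampleOne <- function(vol, method) {
    lo <- origin(vol)
    hi <- origin(vol) + (.gridDim(vol) - 1) * spacing(vol)
    if (any(apply(world, 2, max) < lo) || any(apply(world, 2, min) > hi))
      stop("moving and reference grids do not overlap", call. = FALSE)
    pts <- .worldToIndex(world, spacing(vol), origin(vol))
    fun <- if (method == "linear") .sampleTrilinear else .sampleNearest
    array(fun(as.numeric(voxels(vol)), as.integer(.gridDim(vol)), pts),
          refD)
  }
  out <- list(image = NULL, labels = NULL)
  if (!is.null(movingImage))
    out$image <- ImageVolume(resampleOne(movingImage, "linear"),
                             spacing = spacing(reference),
                             origin = origin(reference))
  if (!is.null(movingLabels))
    out$labels <- LabelVolume(resampleOne(movingLabels, "nearest"),
                              organTable = organTable(movingLabels),
                              spacing = spacing(reference),
                              origin = origin(reference))
  out
}

#' Patient-level leave-one-out cross-validation folds
#'
#' One fold per training/validation patient: that patient is the validation
#' case, all other training/validation patients form the training set, and
#' any remaining registry patients are the held-out test set. All sessions
#' of a patient stay in the same partition, preventing leakage.
#'
#' @param registry a \linkS4class{CohortRegistry} (or character vector of
#'   patient ids).
#' @param trainvalPatients patient ids taking part in cross-validation
#'   (>= 2).
#' @return list of folds; each fold is a list with \code{foldId},
#'   \code{trainPatients}, \code{validationPatient}, \code{testPatients}.
#' @export
makeLoocvFolds <- function(registry, trainvalPatients = NULL) {
  pids <- if (is.character(registry)) registry else names(registry@patients)
  if (is.null(trainvalPatients)) trainvalPatients <- pids
  missing <- setdiff(trainvalPatients, pids)
  if (length(missing))
    stop("unknown patients: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(trainvalPatients) < 2)
    stop("leave-one-out needs at least 2 training/validation patients",
         call. = FALSE)
  test <- setdiff(pids, trainvalPatients)
  lapply(seq_along(trainvalPatients), function(i) {
    list(foldId = i,
         trainPatients = setdiff(trainvalPatients, trainvalPatients[i]),
         validationPatient = trainvalPatients[i],
         testPatients = test)
  })
}

#' Foreground z-score intensity normalization
#'
#' Standardizes an image using the mean and standard deviation of its
#' foreground voxels (those above a low-percentile floor of the intensity
#' distribution), so the foreground has mean 0 and unit standard deviation.
#' Invariant under positive affine intensity transforms of the input.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param floorPercentile percentile (0-100) below which voxels are treated
#'   as background when estimating the statistics.
#' @return the normalized \linkS4class{ImageVolume}.
#' @export
normalizeIntensity <- function(image, floorPercentile = 5) {
  stopifnot(is(image, "ImageVolume"))
  v <- as.vector(voxels(image))
  if (max(v) - min(v) <= 0)
    stop("constant image cannot be normalized (zero variance)",
         call. = FALSE)
  floorVal <- stats::quantile(v, floorPercentile / 100, names = FALSE)
  fg <- v > floorVal
  mu <- mean(v[fg])
  sd <- stats::sd(v[fg])
  if (!is.finite(sd) || sd == 0)
    stop("foreground is constant; cannot normalize", call. = FALSE)
  ImageVolume(array((v - mu) / sd, dim(voxels(image))),
              spacing = spacing(image), origin = origin(image))
}

#' Majority-vote ensembling of predicted masks
#'
#' Combines single-organ predictions obtained from several prior (source)
#' sessions into one mask: a voxel is foreground when at least half of the
#' sources mark it (ties count as foreground).
#'
#' @param masks list of \linkS4class{BinaryMask}s on one geometry.
#' @return the consensus \linkS4class{BinaryMask}.
#' @export
ensembleVote <- function(masks) {
  stopifnot(length(masks) >= 1)
  ref <- masks[[1]]
  acc <- array(0, .gridDim(ref))
  for (m in masks) {
    .stopGeometry(ref, m, "ensemble masks")
    acc <- acc + voxels(m)
  }
  BinaryMask(array(as.numeric(acc * 2 >= length(masks)), dim(acc)),
             spacing = spacing(ref), origin = origin(ref))
}

#' Write a conditioned dataset in a raw three-channel layout
#'
#' Emits the standard raw layout a segmentation trainer consumes:
#' \code{imagesTr/<caseId>_0000.nii.gz} (source image, resampled to the
#' target grid), \code{_0001} (source organ mask, binary) and \code{_0002}
#' (target image); \code{labelsTr/<caseId>.nii.gz} (binary target organ
#' label); a \code{dataset.json} descriptor (channel names, one foreground
#' class) and a \code{manifest.csv} mapping case ids to (patient, m, n,
#' organ, fold). The layout round-trips losslessly through
#' \code{\link{readDataset}}.
#'
#' @param registry a \linkS4class{CohortRegistry}.
#' @param cases data.frame from \code{\link{buildConditionedCases}}.
#' @param outputRoot output directory.
#' @param folds optional result of \code{\link{makeLoocvFolds}} used to tag
#'   each case with the fold whose validation patient it belongs to (NA for
#'   test patients).
#' @return the manifest data.frame, invisibly.
#' @export
writeDataset <- function(registry, cases, outputRoot, folds = NULL) {
  stopifnot(is(registry, "CohortRegistry"), is.data.frame(cases))
  if (anyDuplicated(cases$caseId))
    stop("case id collision in 'cases'", call. = FALSE)
  imgDir <- file.path(outputRoot, "imagesTr")
  labDir <- file.path(outputRoot, "labelsTr")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(labDir, recursive = TRUE, showWarnings = FALSE)
  tab <- registry@organTable
  foldOf <- rep(NA_integer_, nrow(cases))
  if (!is.null(folds)) {
    vmap <- vapply(folds, function(f) f$validationPatient, character(1))
    foldOf <- vapply(cases$patient, function(p) {
      i <- match(p, vmap)
      if (is.na(i)) NA_integer_ else folds[[i]]$foldId
    }, integer(1))
  }
  cache <- new.env(parent = emptyenv())
  loadSession <- function(pid, s) {
    key <- paste(pid, s, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    row <- registry@patients[[pid]]
    r <- row[row$session == s, ]
    if (nrow(r) != 1)
      stop("patient ", pid, " has no session ", s, call. = FALSE)
    val <- list(
      image = readVolume(.resolvePath(registry, r$image), "image"),
      labels = readVolume(.resolvePath(registry, r$labels), "labels",
                          organTable = tab))
    cache[[key]] <- val
    val
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    src <- loadSession(cs$patient, cs$m)
    tgt <- loadSession(cs$patient, cs$n)
    if (!sameGeometry(src$image, tgt$image)) {
      res <- resampleToGrid(src$image, src$labels, tgt$image)
      src <- list(image = res$image, labels = res$labels)
    }
    srcMask <- organMask(src$labels, cs$organ)
    if (!any(voxels(srcMask) != 0))
      stop("organ '", cs$organ, "' empty in source labels of case ",
           cs$caseId, call. = FALSE)
    tgtMask <- organMask(tgt$labels, cs$organ)
    writeVolume(src$image,
                file.path(imgDir, paste0(cs$caseId, "_0000.nii.gz")))
    writeVolume(srcMask,
                file.path(imgDir, paste0(cs$caseId, "_0001.nii.gz")))
    writeVolume(tgt$image,
                file.path(imgDir, paste0(cs$caseId, "_0002.nii.gz")))
    writeVolume(tgtMask, file.path(labDir, paste0(cs$caseId, ".nii.gz")))
  }
  descriptor <- list(
    name = "conditioned-single-organ-segmentation",
    channel_names = list(`0` = "source image", `1` = "source organ mask",
                         `2` = "target image"),
    labels = list(background = 0, organ = 1),
    numTraining = nrow(cases),
    file_ending = ".nii.gz")
  jsonlite::write_json(descriptor, file.path(outputRoot, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- data.frame(caseId = cases$caseId, patient = cases$patient,
                         m = cases$m, n = cases$n, organ = cases$organ,
                         fold = foldOf, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outputRoot, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeDataset
#' @param root a directory previously written by \code{writeDataset}.
#' @return \code{readDataset}: list with \code{manifest},
#'   \code{descriptor}, and a \code{loadCase(caseId)} closure returning the
#'   three channels plus the target label as volumes.
#' @export
readDataset <- function(root) {
  manifest <- utils::read.csv(file.path(root, "manifest.csv"),
                              stringsAsFactors = FALSE)
  descriptor <- jsonlite::read_json(file.path(root, "dataset.json"))
  loadCase <- function(caseId) {
    stopifnot(caseId %in% manifest$caseId)
    list(
      sourceImage = readVolume(
        file.path(root, "imagesTr", paste0(caseId, "_0000.nii.gz")),
        "image"),
      sourceMask = readVolume(
        file.path(root, "imagesTr", paste0(caseId, "_0001.nii.gz")),
        "mask"),
      targetImage = readVolume(
        file.path(root, "imagesTr", paste0(caseId, "_0002.nii.gz")),
        "image"),
      targetLabel = readVolume(
        file.path(root, "labelsTr", paste0(caseId, ".nii.gz")), "mask"))
  }
  list(manifest = manifest, descriptor = descriptor, loadCase = loadCase)
}
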