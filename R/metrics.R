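#' @include deform.R
NULL

.maskArray <- function(m) {
  if (is(m, "ImageVolume")) voxels(m) != 0 else m != 0
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks: \code{2|A intersect B| / (|A| + |B|)}.
#' Two empty masks are defined to agree perfectly (1.0); exactly one empty
#' mask scores 0.
#'
#' @param a,b \linkS4class{BinaryMask}s on one geometry.
#' @return scalar in [0, 1].
#' @export
#' @examples
#' m <- array(0, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- 1
#' dice(BinaryMask(m), BinaryMask(m))
dice <- function(a, b) {
  .stopGeometry(a, b, "masks")
  va <- .maskArray(a); vb <- .maskArray(b)
  na <- sum(va); nb <- sum(vb)
  if (na + nb == 0) return(1)
  2 * sum(va & vb) / (na + nb)
}

# 6-connected erosion boundary: mask voxels with any face neighbour outside
.surfaceVoxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  er <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  m & !er
}

#' Directed surface-to-surface distances between two masks
#'
#' Surface voxels are a mask minus its 6-connected erosion. The directed
#' distances from each surface voxel of \code{a} to the nearest surface
#' voxel of \code{b} (voxel center to voxel center, physical mm, via an
#' exact Euclidean distance transform) are returned together with the
#' opposite direction.
#'
#' @param a,b nonempty \linkS4class{BinaryMask}s on one geometry.
#' @return list with numeric vectors \code{ab} and \code{ba} (mm).
#' @export
surfaceDistances <- function(a, b) {
  .stopGeometry(a, b, "masks")
  va <- .maskArray(a); vb <- .maskArray(b)
  if (!any(va) || !any(vb))
    stop("surface distances are undefined for an empty mask; ",
         "report the sentinel instead (see evaluateContours)",
         call. = FALSE)
  sa <- .surfaceVoxels(va); sb <- .surfaceVoxels(vb)
  spc <- spacing(a)
  dToB <- sqrt(.edtSquared(as.vector(sb), as.integer(dim(vb)), spc))
  dToA <- sqrt(.edtSquared(as.vector(sa), as.integer(dim(va)), spc))
  list(ab = dToB[as.vector(sa)], ba = dToA[as.vector(sb)])
}

#' Average surface distance (mm)
#'
#' Mean of the pooled bidirectional surface distances (symmetric by
#' construction).
#'
#' @inheritParams surfaceDistances
#' @return scalar mm.
#' @export
asd <- function(a, b) {
  sd <- surfaceDistances(a, b)
  mean(c(sd$ab, sd$ba))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' 95th percentile (linear interpolation between order statistics) of the
#' pooled bidirectional surface distances; bounded above by the exact
#' Hausdorff distance.
#'
#' @inheritParams surfaceDistances
#' @param probs percentile in [0, 1] (default 0.95).
#' @return scalar mm.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  sd <- surfaceDistances(a, b)
  stats::quantile(c(sd$ab, sd$ba), probs, names = FALSE, type = 7)
}

#' Cumulative dose-volume histogram of a structure
#'
#' For each dose edge, the fraction of the structure's volume receiving at
#' least that dose. The curve starts at 1.0 for dose 0 and is
#' non-increasing.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{BinaryMask} on the dose geometry.
#' @param edges ascending dose levels in Gy starting at 0 (default: 201
#'   levels from 0 to the maximum structure dose).
#' @return a \linkS4class{DVHCurve}.
#' @export
dvh <- function(dose, mask, edges = NULL) {
  stopifnot(is(dose, "DoseGrid"), is(mask, "BinaryMask"))
  .stopGeometry(dose, mask, "dose and mask")
  dvals <- voxels(dose)[.maskArray(mask)]
  if (!length(dvals)) stop("mask is empty; DVH undefined", call. = FALSE)
  if (is.null(edges))
    edges <- seq(0, max(dvals), length.out = 201)
  frac <- vapply(edges, function(e) mean(dvals >= e), numeric(1))
  new("DVHCurve", doseEdges = edges, volumeFraction = frac)
}

#' Minimum dose to the hottest requested volume
#'
#' Sorts the structure's voxel doses in descending order and returns the
#' dose at the requested cumulative volume (absolute \code{cc} or
#' percentage \code{pct} of the structure volume), linearly interpolating
#' between neighbouring voxels' doses on the cumulative-volume axis (voxel
#' centers at (k - 1/2) voxel volumes). D0.1cc is the near-maximum dose;
#' D50\% the median dose.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask a nonempty \linkS4class{BinaryMask} on the dose geometry.
#' @param cc requested hottest volume in cm^3 (exclusive with \code{pct}).
#' @param pct requested volume as a percentage of the structure volume.
#' @return dose in Gy.
#' @export
#' @examples
#' d <- array(10, c(4, 4, 4)); m <- array(1, c(4, 4, 4))
#' doseAtVolume(DoseGrid(d, 40, spacing = c(5, 5, 5)),
#'              BinaryMask(m, spacing = c(5, 5, 5)), pct = 50)
doseAtVolume <- function(dose, mask, cc = NULL, pct = NULL) {
  stopifnot(is(dose, "DoseGrid"), is(mask, "BinaryMask"))
  .stopGeometry(dose, mask, "dose and mask")
  if (is.null(cc) == is.null(pct))
    stop("give exactly one of 'cc' or 'pct'", call. = FALSE)
  dvals <- voxels(dose)[.maskArray(mask)]
  n <- length(dvals)
  if (!n) stop("mask is empty", call. = FALSE)
  voxCc <- prod(spacing(dose)) / 1000
  totalCc <- n * voxCc
  vReq <- if (!is.null(cc)) cc else pct / 100 * totalCc
  if (vReq <= 0) stop("requested volume must be positive", call. = FALSE)
  if (!is.null(cc) && cc > totalCc)
    stop(sprintf("mask volume %.3g cc is smaller than requested %.3g cc",
                 totalCc, cc), call. = FALSE)
  sorted <- sort(dvals, decreasing = TRUE)
  centers <- (seq_len(n) - 0.5) * voxCc
  vReq <- min(max(vReq, centers[1]), centers[n])
  stats::approx(centers, sorted, xout = vReq, ties = "ordered")$y
}

#' Dose discrepancy as a percentage of the prescribed dose
#'
#' \code{|method - groundTruth| / PD * 100}; set \code{signed = TRUE} to
#' keep the sign of (method - groundTruth).
#'
#' @param methodGy dose statistic of the evaluated contour, Gy.
#' @param gtGy same statistic on the ground-truth contour, Gy.
#' @param pdGy prescribed dose, Gy.
#' @param signed keep the sign instead of the absolute value.
#' @return percentage of PD.
#' @export
dpd <- function(methodGy, gtGy, pdGy, signed = FALSE) {
  stopifnot(pdGy > 0)
  d <- (methodGy - gtGy) / pdGy * 100
  if (signed) d else abs(d)
}

#' Dose-gradient-weighted Dice
#'
#' Dice with per-voxel weight \code{w(x) = ||grad dose(x)||} (central
#' differences, Gy/mm): \code{2 sum_{A^B} w / (sum_A w + sum_B w)}. Regions
#' where the dose changes fastest dominate, so agreement near steep dose
#' gradients (next to the target) counts most. Under a spatially constant
#' gradient magnitude this reduces exactly to the unweighted Dice; if the
#' total weight over the union is zero the unweighted Dice is returned with
#' a notice.
#'
#' @param a,b \linkS4class{BinaryMask}s on one geometry.
#' @param dose a \linkS4class{DoseGrid} on the same geometry.
#' @return scalar in [0, 1].
#' @export
mdice <- function(a, b, dose) {
  stopifnot(is(dose, "DoseGrid"))
  .stopGeometry(a, b, "masks")
  .stopGeometry(a, dose, "mask and dose")
  va <- .maskArray(a); vb <- .maskArray(b)
  if (sum(va) + sum(vb) == 0) return(1)
  dv <- voxels(dose)
  spc <- spacing(dose)
  d <- dim(dv)
  w <- sqrt(.gradAxis(dv, 1, spc[1])^2 + .gradAxis(dv, 2, spc[2])^2 +
            .gradAxis(dv, 3, spc[3])^2)
  if (sum(w[va | vb]) == 0) {
    message("zero dose-gradient weight over the union; ",
            "falling back to unweighted Dice")
    return(dice(a, b))
  }
  2 * sum(w[va & vb]) / (sum(w[va]) + sum(w[vb]))
}

#' Evaluate predicted contours against ground truth
#'
#' Per organ present in the ground truth: Dice, average surface distance
#' and 95th-percentile Hausdorff distance; when a dose grid is supplied,
#' additionally D0.1cc and D50\% for the predicted and ground-truth masks,
#' their discrepancies as a percentage of the prescription (dPD), and the
#' dose-gradient-weighted Dice. Organs empty in the prediction but present
#' in the ground truth are reported with Dice 0 and undefined (NA, flagged)
#' distances rather than dropped, so cohort evaluation never aborts.
#'
#' @param pred predicted \linkS4class{LabelVolume} (same coding as
#'   \code{gt}).
#' @param gt ground-truth \linkS4class{LabelVolume}.
#' @param dose optional \linkS4class{DoseGrid} on the same geometry.
#' @param signedDpd report signed dPD values instead of absolute.
#' @return data.frame with one row per ground-truth organ; the pooled
#'   bidirectional distance convention is recorded in the
#'   \code{"conventions"} attribute.
#' @export
#' @examples
#' p <- makePhantom(phantomSpec(gridShape = c(32, 32, 24)))
#' evaluateContours(p$labels, p$labels)
evaluateContours <- function(pred, gt, dose = NULL, signedDpd = FALSE) {
  stopifnot(is(pred, "LabelVolume"), is(gt, "LabelVolume"))
  .stopGeometry(pred, gt, "prediction and ground truth")
  if (!is.null(dose)) .stopGeometry(gt, dose, "labels and dose")
  tab <- organTable(gt)
  present <- names(tab)[vapply(tab, function(k) any(voxels(gt) == k),
                               logical(1))]
  rows <- lapply(present, function(organ) {
    gm <- organMask(gt, organ)
    pm <- BinaryMask(array(as.numeric(voxels(pred) == tab[[organ]]),
                           .gridDim(pred)),
                     spacing = spacing(pred), origin = origin(pred))
    empty <- !any(voxels(pm) != 0)
    row <- data.frame(organ = organ, dsc = dice(pm, gm),
                      asd_mm = NA_real_, hd95_mm = NA_real_,
                      distance_undefined = empty,
                      stringsAsFactors = FALSE)
    if (!empty) {
      sdist <- surfaceDistances(pm, gm)
      pooled <- c(sdist$ab, sdist$ba)
      row$asd_mm <- mean(pooled)
      row$hd95_mm <- stats::quantile(pooled, 0.95, names = FALSE)
    }
    if (!is.null(dose)) {
      safeDose <- function(mask, ...) {
        tryCatch(doseAtVolume(dose, mask, ...), error = function(e) NA_real_)
      }
      gt01 <- safeDose(gm, cc = 0.1)
      gt50 <- safeDose(gm, pct = 50)
      pd01 <- if (empty) NA_real_ else safeDose(pm, cc = 0.1)
      pd50 <- if (empty) NA_real_ else safeDose(pm, pct = 50)
      pdGy <- prescription(dose)
      row$d01cc_pred_Gy <- pd01
      row$d01cc_gt_Gy <- gt01
      row$d01cc_dpd_pct <- if (is.na(pd01) || is.na(gt01)) NA_real_ else
        dpd(pd01, gt01, pdGy, signed = signedDpd)
      row$d50_pred_Gy <- pd50
      row$d50_gt_Gy <- gt50
      row$d50_dpd_pct <- if (is.na(pd50) || is.na(gt50)) NA_real_ else
        dpd(pd50, gt50, pdGy, signed = signedDpd)
      row$mdice <- mdice(pm, gm, dose)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "conventions") <- paste(
    "surface distances: pooled bidirectional, 6-connectivity erosion",
    "boundary, voxel-center to voxel-center, mm; dPD:",
    if (signedDpd) "signed" else "absolute")
  out
}

#' Aggregate per-case evaluation reports over a cohort
#'
#' Binds per-case reports and summarizes mean and standard deviation per
#' organ for every numeric metric column.
#'
#' @param reports list of data.frames from \code{\link{evaluateContours}}.
#' @return list with \code{perCase} (bound rows, with a \code{case}
#'   column) and \code{summary} (mean and sd per organ).
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports)))
    names(reports) <- paste0("case", seq_along(reports))
  perCase <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(case = nm, reports[[nm]], stringsAsFactors = FALSE)
  }))
  rownames(perCase) <- NULL
  metricCols <- names(perCase)[vapply(perCase, is.numeric, logical(1))]
  summary <- do.call(rbind, lapply(split(perCase, perCase$organ),
    function(g) {
      row <- data.frame(organ = g$organ[1], n = nrow(g),
                        stringsAsFactors = FALSE)
      for (mc in metricCols) {
        row[[paste0(mc, "_mean")]] <- mean(g[[mc]], na.rm = TRUE)
        row[[paste0(mc, "_sd")]] <- stats::sd(g[[mc]], na.rm = TRUE)
      }
      row
    }))
  rownames(summary) <- NULL
  list(perCase = perCase, summary = summary)
}
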