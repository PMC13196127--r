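#' @include io.R
NULL

#' The default abdominal organ roster
#'
#' Nine organs of interest for abdominal MR-guided adaptive radiotherapy,
#' in the fixed order that assigns label codes 1..9.
#'
#' @return character vector of organ names.
#' @export
abdominalOrgans <- function() {
  c("duodenum", "large_bowel", "small_bowel", "liver", "left_kidney",
    "right_kidney", "spleen", "stomach", "spinal_canal")
}

.defaultIntensityModel <- function(organs) {
  means <- c(duodenum = 55, large_bowel = 45, small_bowel = 50, liver = 95,
             left_kidney = 70, right_kidney = 70, spleen = 80, stomach = 40,
             spinal_canal = 110)
  missing <- setdiff(organs, names(means))
  if (length(missing)) {
    extra <- 40 + 10 * seq_along(missing)
    names(extra) <- missing
    means <- c(means, extra)
  }
  list(background = 20, means = means[organs], noiseSd = 4,
       biasAmplitude = 0.08)
}

#' Specification of a synthetic abdominal phantom
#'
#' Describes the grid, the organ roster and the intensity model of one
#' synthetic session image. Organ label codes are assigned 1..N in the
#' order of \code{organs}; code 0 is background. The layout is a fixed
#' stylized abdominal template (liver right-superior, kidneys
#' posterior-lateral, spinal canal posterior-midline, bowel loops anterior,
#' duodenum adjacent to the stomach), scaled to the grid.
#'
#' @param gridShape integer(3), voxels per axis, all >= 16.
#' @param spacingMm numeric(3), voxel size in mm, all > 0.
#' @param organs ordered character vector of unique organ names.
#' @param includeRightKidney if \code{FALSE} the right kidney is omitted
#'   from the label map (single-kidney anatomy); its code stays reserved in
#'   the organ table.
#' @param intensityModel list with \code{background}, per-organ
#'   \code{means}, \code{noiseSd} (additive Gaussian noise, intensity
#'   units) and \code{biasAmplitude} (relative amplitude of a smooth
#'   multiplicative shading field; 0 disables it).
#' @param seed integer seed controlling noise and bias.
#' @return a \code{PhantomSpec} (validated list).
#' @export
#' @examples
#' spec <- phantomSpec(gridShape = c(32, 32, 24), seed = 7)
#' p <- makePhantom(spec)
#' p$labels
phantomSpec <- function(gridShape = c(64, 64, 48), spacingMm = c(2, 2, 2),
                        organs = abdominalOrgans(),
                        includeRightKidney = TRUE,
                        intensityModel = NULL, seed = 1L) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3)
  if (any(gridShape < 16))
    stop("gridShape must be at least 16 voxels per axis", call. = FALSE)
  if (any(spacingMm <= 0)) stop("spacingMm must be > 0", call. = FALSE)
  if (anyDuplicated(organs)) stop("organ names must be unique", call. = FALSE)
  if (is.null(intensityModel)) intensityModel <- .defaultIntensityModel(organs)
  structure(list(gridShape = gridShape, spacingMm = as.numeric(spacingMm),
                 organs = organs, includeRightKidney = includeRightKidney,
                 intensityModel = intensityModel, seed = as.integer(seed)),
            class = "PhantomSpec")
}

## shape primitives on fractional coordinates -------------------------------

# fractional coordinate arrays (voxel centers mapped to (0,1))
.fracCoords <- function(d) {
  fx <- (seq_len(d[1]) - 0.5) / d[1]
  fy <- (seq_len(d[2]) - 0.5) / d[2]
  fz <- (seq_len(d[3]) - 0.5) / d[3]
  list(x = array(rep.int(fx, d[2] * d[3]), d),
       y = array(rep.int(rep(fy, each = d[1]), d[3]), d),
       z = array(rep(fz, each = d[1] * d[2]), d))
}

.ellipsoid <- function(fc, center, radii) {
  ((fc$x - center[1]) / radii[1])^2 + ((fc$y - center[2]) / radii[2])^2 +
    ((fc$z - center[3]) / radii[3])^2 <= 1
}

.cylinderZ <- function(fc, center_xy, radius, zRange) {
  ((fc$x - center_xy[1]) / radius)^2 + ((fc$y - center_xy[2]) / radius)^2 <= 1 &
    fc$z >= zRange[1] & fc$z <= zRange[2]
}

# paint a tube of fractional radius around a polyline of fractional points
.tube <- function(fc, pts, radius) {
  d <- dim(fc$x)
  out <- array(FALSE, d)
  # densify the polyline so consecutive samples are < radius/2 apart
  dens <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (radius / 2)))
    tt <- seq(0, 1, length.out = n)
    dens[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                       a[3] + tt * (b[3] - a[3]))
  }
  dens <- do.call(rbind, dens)
  rx <- ceiling(radius * d[1]) + 1L
  ry <- ceiling(radius * d[2]) + 1L
  rz <- ceiling(radius * d[3]) + 1L
  for (i in seq_len(nrow(dens))) {
    p <- dens[i, ]
    ci <- round(p * d + 0.5)
    xs <- max(1, ci[1] - rx):min(d[1], ci[1] + rx)
    ys <- max(1, ci[2] - ry):min(d[2], ci[2] + ry)
    zs <- max(1, ci[3] - rz):min(d[3], ci[3] + rz)
    sub <- expand.grid(x = xs, y = ys, z = zs)
    fr <- cbind((sub$x - 0.5) / d[1], (sub$y - 0.5) / d[2],
                (sub$z - 0.5) / d[3])
    inside <- rowSums(sweep(fr, 2, p, "-")^2) <= radius^2
    idx <- (sub$z[inside] - 1) * d[1] * d[2] + (sub$y[inside] - 1) * d[1] +
      sub$x[inside]
    out[idx] <- TRUE
  }
  out
}

.duodenumCurve <- function() {
  th <- seq(90, 330, by = 12) * pi / 180
  cbind(0.48 + 0.10 * cos(th), 0.56, 0.50 + 0.10 * sin(th))
}

.smallBowelCurve <- function() {
  tt <- seq(0, 1, length.out = 40)
  cbind(0.30 + 0.40 * tt, 0.68, 0.30 + 0.06 * sin(4 * pi * tt))
}

.largeBowelCurve <- function() {
  rbind(cbind(0.78, 0.72, seq(0.18, 0.50, by = 0.04)),
        cbind(seq(0.78, 0.22, by = -0.04), 0.72, 0.50),
        cbind(0.22, 0.72, seq(0.50, 0.18, by = -0.04)))
}

# organ name -> logical shape on the grid (fixed stylized template)
.organShape <- function(name, fc) {
  switch(name,
    liver        = .ellipsoid(fc, c(0.72, 0.50, 0.74), c(0.18, 0.18, 0.14)),
    left_kidney  = .ellipsoid(fc, c(0.28, 0.30, 0.38), c(0.08, 0.08, 0.13)),
    right_kidney = .ellipsoid(fc, c(0.72, 0.30, 0.38), c(0.08, 0.08, 0.13)),
    spleen       = .ellipsoid(fc, c(0.24, 0.40, 0.68), c(0.10, 0.09, 0.09)),
    stomach      = .ellipsoid(fc, c(0.38, 0.62, 0.68), c(0.13, 0.10, 0.09)),
    spinal_canal = .cylinderZ(fc, c(0.50, 0.14), 0.045, c(0.02, 0.98)),
    duodenum     = .tube(fc, .duodenumCurve(), 0.035),
    small_bowel  = .tube(fc, .smallBowelCurve(), 0.040),
    large_bowel  = .tube(fc, .largeBowelCurve(), 0.045),
    stop("no shape template for organ '", name, "'", call. = FALSE))
}

# painting priority: solid organs first, then tubes threaded between them
.paintOrder <- function(organs) {
  pref <- c("spinal_canal", "liver", "left_kidney", "right_kidney", "spleen",
            "stomach", "duodenum", "small_bowel", "large_bowel")
  c(intersect(pref, organs), setdiff(organs, pref))
}

#' Generate a synthetic abdominal phantom
#'
#' Builds a multi-organ label map from the stylized template (ellipsoids for
#' solid organs, bent tubes for bowel and duodenum, a cylinder for the
#' spinal canal) and a matching session-like image: per-organ mean
#' intensities, additive Gaussian noise and an optional smooth multiplicative
#' bias field mimicking MR shading. Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{image} (\linkS4class{ImageVolume}) and
#'   \code{labels} (\linkS4class{LabelVolume}).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$gridShape
  fc <- .fracCoords(d)
  organs <- spec$organs
  codes <- seq_along(organs)
  names(codes) <- organs
  placed <- organs
  if (!spec$includeRightKidney)
    placed <- setdiff(placed, "right_kidney")
  lab <- array(0, d)
  for (name in .paintOrder(placed)) {
    shape <- .organShape(name, fc) & lab == 0
    if (!any(shape))
      stop("grid too small to place organ '", name, "'", call. = FALSE)
    lab[shape] <- codes[[name]]
  }
  for (name in placed)
    if (!any(lab == codes[[name]]))
      stop("grid too small to place organ '", name, "'", call. = FALSE)

  im <- spec$intensityModel
  img <- array(im$background, d)
  for (name in placed) img[lab == codes[[name]]] <- im$means[[name]]
  .withSeed(spec$seed, {
    if (im$noiseSd > 0)
      img <- img + array(stats::rnorm(prod(d), 0, im$noiseSd), d)
    if (im$biasAmplitude > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      bias <- 1 + im$biasAmplitude *
        cos(2 * pi * fc$x * 0.7 + ph[1]) *
        cos(2 * pi * fc$y * 0.7 + ph[2]) *
        cos(2 * pi * fc$z * 0.7 + ph[3])
      img <- img * bias
    }
  })
  tab <- as.integer(codes)
  names(tab) <- organs
  list(image = ImageVolume(img, spacing = spec$spacingMm),
       labels = LabelVolume(lab, organTable = tab,
                            spacing = spec$spacingMm))
}

#' Generate a synthetic dose grid peaked near a target
#'
#' The dose is an isotropic Gaussian peak: maximal at \code{targetCenterMm},
#' monotonically non-increasing with radial distance along any ray, and at
#' least the prescription inside a small target sphere. By default the
#' target sits at the duodenum centroid, emulating a pancreatic target
#' abutting the duodenum.
#'
#' @param labels a \linkS4class{LabelVolume} providing the geometry (and the
#'   default target position).
#' @param targetCenterMm numeric(3) world position of the dose peak, mm;
#'   default: centroid of the duodenum (or the grid center if absent).
#' @param prescriptionGy prescribed dose PD in Gy (> 0); the peak is set to
#'   1.1 PD so the target sphere receives at least PD.
#' @param falloffMm Gaussian falloff scale of the dose in mm.
#' @return a \linkS4class{DoseGrid} with \code{prescription(x) ==
#'   prescriptionGy}.
#' @export
makeDosePhantom <- function(labels, targetCenterMm = NULL,
                            prescriptionGy = 40, falloffMm = 12) {
  stopifnot(is(labels, "LabelVolume"))
  if (prescriptionGy <= 0)
    stop("prescription must be positive (Gy)", call. = FALSE)
  d <- .gridDim(labels)
  spc <- spacing(labels)
  org <- origin(labels)
  if (is.null(targetCenterMm)) {
    tab <- organTable(labels)
    if ("duodenum" %in% names(tab) &&
        any(voxels(labels) == tab[["duodenum"]])) {
      w <- .worldGrid(labels)
      inside <- as.vector(voxels(labels) == tab[["duodenum"]])
      targetCenterMm <- colMeans(w[inside, , drop = FALSE])
    } else {
      targetCenterMm <- org + (d - 1) / 2 * spc
    }
  }
  lo <- org
  hi <- org + (d - 1) * spc
  if (any(targetCenterMm < lo) || any(targetCenterMm > hi))
    stop("target center lies outside the image grid", call. = FALSE)
  w <- .worldGrid(labels)
  r2 <- rowSums(sweep(w, 2, targetCenterMm, "-")^2)
  dose <- 1.1 * prescriptionGy * exp(-r2 / (2 * falloffMm^2))
  DoseGrid(array(dose, d), prescription = prescriptionGy, spacing = spc,
           origin = org)
}

#' Specification of a synthetic multi-session cohort
#'
#' @param patients data.frame with columns \code{patient_id} and
#'   \code{n_sessions}, or a named integer vector (names = patient ids,
#'   values = session counts, all >= 1).
#' @param deformParams \code{\link{deformParams}} used to simulate sessions
#'   2..n from session 1.
#' @param phantom \code{\link{phantomSpec}} template shared by all patients
#'   (each patient gets a derived seed).
#' @param missingKidneyPatients patient ids generated with a single (left)
#'   kidney.
#' @param seed integer root seed.
#' @return a \code{CohortSpec} (validated list).
#' @export
cohortSpec <- function(patients, deformParams = DefAug::deformParams(),
                       phantom = phantomSpec(),
                       missingKidneyPatients = character(), seed = 1L) {
  if (!is.data.frame(patients))
    patients <- data.frame(patient_id = names(patients),
                           n_sessions = as.integer(patients),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "n_sessions") %in% names(patients)))
  if (anyDuplicated(patients$patient_id))
    stop("patient ids must be unique", call. = FALSE)
  if (any(patients$n_sessions < 1))
    stop("each patient needs at least one session", call. = FALSE)
  structure(list(patients = patients, deformParams = deformParams,
                 phantom = phantom,
                 missingKidneyPatients = missingKidneyPatients,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic cohort on disk
#'
#' For each patient, session 1 is a fresh phantom; sessions 2..n are
#' deformation-simulated variants of session 1 (see
#' \code{\link{simulateSession}}), written together with their ground-truth
#' labels and displacement fields. A JSON registry listing each patient's
#' ordered sessions is written to \code{file.path(dir, "registry.json")}.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param dir output directory (created if needed).
#' @param mrAug optional \code{\link{mrAugConfig}}; when given, simulated
#'   sessions additionally receive the MR acquisition-variability
#'   augmentations.
#' @return the \linkS4class{CohortRegistry} (also written as JSON).
#' @export
makeCohort <- function(spec, dir, mrAug = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop("cannot create output directory: ", dir, call. = FALSE)
  patients <- list()
  tab <- NULL
  for (i in seq_len(nrow(spec$patients))) {
    pid <- spec$patients$patient_id[i]
    nses <- spec$patients$n_sessions[i]
    pspec <- spec$phantom
    pspec$seed <- .deriveSeed(spec$seed, paste0("phantom:", pid))
    pspec$includeRightKidney <- !(pid %in% spec$missingKidneyPatients)
    ph <- makePhantom(pspec)
    tab <- organTable(ph$labels)
    rows <- list()
    img <- ph$image
    lab <- ph$labels
    for (s in seq_len(nses)) {
      stem <- sprintf("%s_s%02d", pid, s)
      if (s == 1L) {
        simg <- img; slab <- lab; sfield <- NULL
      } else {
        sim <- simulateSession(img, lab, spec$deformParams,
                               seed = .deriveSeed(pspec$seed,
                                                  paste0("session:", s)))
        simg <- sim$image; slab <- sim$labels; sfield <- sim$field
        if (!is.null(mrAug))
          simg <- applyMrAugmentations(simg, mrAug,
                                       seed = .deriveSeed(pspec$seed,
                                                          paste0("mraug:", s)))
      }
      imgPath <- paste0(stem, "_image.nii.gz")
      labPath <- paste0(stem, "_labels.nii.gz")
      writeVolume(simg, file.path(dir, imgPath))
      writeVolume(slab, file.path(dir, labPath))
      fieldPath <- NA_character_
      if (!is.null(sfield)) {
        fieldPath <- paste0(stem, "_dvf.nii.gz")
        writeVolume(sfield, file.path(dir, fieldPath))
      }
      rows[[s]] <- data.frame(session = s, image = imgPath,
                              labels = labPath, field = fieldPath,
                              stringsAsFactors = FALSE)
    }
    patients[[pid]] <- do.call(rbind, rows)
  }
  reg <- CohortRegistry(patients, root = dir, organTable = tab)
  writeRegistry(reg, file.path(dir, "registry.json"))
  reg
}
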