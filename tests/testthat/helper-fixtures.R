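# Fixtures and independent oracles used across the suite. Oracles here are
# deliberately naive (loops, brute-force sorting) and never share code with
# the package internals they check.

# axis-aligned ellipsoid mask centered at `center` (1-based voxel indices)
ellipsoidMask <- function(dims, center, radii, spacing = c(2, 2, 2)) {
  arr <- array(0, dims)
  idx <- which(arr == 0, arr.ind = TRUE)
  inside <- ((idx[, 1] - center[1]) / radii[1])^2 +
    ((idx[, 2] - center[2]) / radii[2])^2 +
    ((idx[, 3] - center[3]) / radii[3])^2 <= 1
  arr[idx[inside, , drop = FALSE]] <- 1
  BinaryMask(arr, spacing = spacing)
}

cubeMask <- function(dims, from, size, spacing = c(1, 1, 1)) {
  arr <- array(0, dims)
  arr[from[1]:(from[1] + size - 1), from[2]:(from[2] + size - 1),
      from[3]:(from[3] + size - 1)] <- 1
  BinaryMask(arr, spacing = spacing)
}

# unit-thickness z-slab covering the full xy extent
slabMask <- function(dims, z, spacing = c(1, 1, 1)) {
  arr <- array(0, dims)
  arr[, , z] <- 1
  BinaryMask(arr, spacing = spacing)
}

phiDraw <- function(translation = c(0, 0, 0), scale = 1,
                    rotation = c(0, 0, 0)) {
  structure(list(translationMm = translation, scaleFactor = scale,
                 rotationDeg = rotation), class = "PhiDraw")
}

zeroField <- function(dims, spacing = c(2, 2, 2)) {
  DisplacementField(array(0, c(dims, 3)), spacing = spacing)
}

constantField <- function(dims, u, spacing = c(2, 2, 2)) {
  arr <- array(0, c(dims, 3))
  for (k in 1:3) arr[, , , k] <- u[k]
  DisplacementField(arr, spacing = spacing)
}

smoothRandomImage <- function(dims, seed, sigma = 4) {
  set.seed(seed)
  ImageVolume(gaussianSmooth(array(rnorm(prod(dims)), dims), sigma,
                             c(1, 1, 1)))
}

smoothRandomField <- function(dims, seed, sd = 2, sigma = 5) {
  set.seed(seed)
  u <- array(rnorm(prod(dims) * 3, 0, sd), c(dims, 3))
  for (k in 1:3) u[, , , k] <- gaussianSmooth(u[, , , k], sigma, c(1, 1, 1))
  DisplacementField(u)
}

maskCentroidMm <- function(mask) {
  idx <- which(voxels(mask) != 0, arr.ind = TRUE)
  colMeans(sweep(idx - 1, 2, spacing(mask), "*"))
}

# 6-connected flood fill: TRUE when all mask voxels are one component
isConnected6 <- function(arr) {
  m <- arr != 0
  if (!any(m)) return(FALSE)
  seedIdx <- which(m, arr.ind = TRUE)[1, , drop = FALSE]
  reached <- array(FALSE, dim(m))
  reached[seedIdx] <- TRUE
  d <- dim(m)
  repeat {
    grown <- reached
    grown[-1, , ] <- grown[-1, , ] | reached[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reached[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reached[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reached[, -1, ]
    grown[, , -1] <- grown[, , -1] | reached[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reached[, , -1]
    grown <- grown & m
    if (identical(grown, reached)) break
    reached <- grown
  }
  all(reached[m])
}

# brute-force "minimum dose to the hottest volume": explicit cumulative
# volume walk with manual interpolation at voxel centers
oracleDoseAtVolume <- function(doseVals, voxCc, vReq) {
  srt <- sort(doseVals, decreasing = TRUE)
  n <- length(srt)
  centers <- ((1:n) - 0.5) * voxCc
  if (vReq <= centers[1]) return(srt[1])
  if (vReq >= centers[n]) return(srt[n])
  k <- max(which(centers <= vReq))
  f <- (vReq - centers[k]) / (centers[k + 1] - centers[k])
  srt[k] + f * (srt[k + 1] - srt[k])
}

# brute-force directed surface distance via full pairwise search
oracleSurfaceDistances <- function(surfA, surfB, spacing) {
  pa <- sweep(which(surfA, arr.ind = TRUE) - 1, 2, spacing, "*")
  pb <- sweep(which(surfB, arr.ind = TRUE) - 1, 2, spacing, "*")
  vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min(colSums((t(pb) - pa[i, ])^2)))
  }, numeric(1))
}

smallPhantom <- function(seed = 1, dims = c(32, 32, 24)) {
  makePhantom(phantomSpec(gridShape = dims, seed = seed))
}
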