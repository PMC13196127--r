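test_that("phi draws respect degenerate and uniform bounds", {
  zero <- deformParams(maxDisplacementMm = 0, maxExpansion = 0,
                       maxShrinkage = 0, maxRotationDeg = 0)
  d <- samplePhiDraw(zero, seed = 1)
  expect_identical(d$translationMm, c(0, 0, 0))
  expect_identical(d$scaleFactor, 1)
  expect_identical(d$rotationDeg, c(0, 0, 0))

  # Monte-Carlo check of the uniform law: mean within 3 standard errors
  p <- deformParams(maxDisplacementMm = 5)
  draws <- DefAug:::.withSeed(202, {
    replicate(1e4, samplePhiDraw(p)$translationMm)
  })
  expect_true(all(abs(draws) <= 5))
  se <- (10 / sqrt(12)) / sqrt(1e4)
  expect_true(all(abs(rowMeans(draws)) < 3 * se))

  # same seed, same params -> identical draw sequence
  s1 <- lapply(1:3, function(i) samplePhiDraw(p, seed = 7))
  expect_identical(s1[[1]], s1[[3]])
  set.seed(9); a <- list(samplePhiDraw(p), samplePhiDraw(p))
  set.seed(9); b <- list(samplePhiDraw(p), samplePhiDraw(p))
  expect_identical(a, b)
  # successive draws differ (rng advances between labels)
  expect_false(identical(a[[1]], a[[2]]))
})

test_that("an identity draw produces an exactly zero field", {
  m <- ellipsoidMask(c(32, 32, 32), c(16, 16, 16), c(6, 8, 5))
  f <- generateLabelField(m, phiDraw(), deformParams())
  expect_true(all(voxels(f) == 0))
  expect_error(
    generateLabelField(BinaryMask(array(0, c(8, 8, 8))), phiDraw(),
                       deformParams(), organ = "spleen"),
    "spleen")
})

test_that("a pure translation moves the label centroid by the drawn amount", {
  m <- ellipsoidMask(c(48, 48, 48), c(24, 24, 24), c(8, 10, 6),
                     spacing = c(2, 2, 2))
  tr <- c(5.3, -3.1, 2.7)  # mm, deliberately off half-voxel multiples
  f <- generateLabelField(m, phiDraw(translation = tr), deformParams())
  w <- warpLabels(m, f)
  shift <- maskCentroidMm(w) - maskCentroidMm(m)
  expect_true(all(abs(shift - tr) <= 0.5 * spacing(m)),
              label = paste("centroid shift", toString(round(shift, 2))))
})

test_that("a pure scaling changes label volume like the cube of the factor", {
  m <- ellipsoidMask(c(48, 48, 48), c(24, 24, 24), c(8, 10, 6),
                     spacing = c(2, 2, 2))
  for (s in c(1.12, 0.88)) {
    f <- generateLabelField(m, phiDraw(scale = s), deformParams())
    w <- warpLabels(m, f)
    ratio <- sum(voxels(w)) / sum(voxels(m))
    expect_lt(abs(ratio - s^3) / s^3, 0.10)
  }
})

test_that("composing with a zero field is the identity element", {
  u <- smoothRandomField(c(24, 24, 20), seed = 5)
  z <- zeroField(c(24, 24, 20), spacing = spacing(u))
  expect_equal(voxels(composeFields(z, u)), voxels(u))
  expect_equal(voxels(composeFields(u, z)), voxels(u))
})

test_that("warping by a composed field matches sequential warping on smooth images", {
  img <- smoothRandomImage(c(32, 32, 32), seed = 1)
  u1 <- smoothRandomField(c(32, 32, 32), seed = 2)
  u2 <- smoothRandomField(c(32, 32, 32), seed = 3)
  sequential <- warpImage(warpImage(img, u1), u2)
  oneShot <- warpImage(img, composeFields(u1, u2))
  dynRange <- diff(range(voxels(img)))
  expect_lt(max(abs(voxels(sequential) - voxels(oneShot))),
            0.02 * dynRange)
})

test_that("two pure translations compose additively", {
  t1 <- c(1.5, -2.25, 0.5); t2 <- c(-0.75, 1.0, 2.0)
  f1 <- constantField(c(24, 24, 24), t1, spacing = c(1, 1, 1))
  f2 <- constantField(c(24, 24, 24), t2, spacing = c(1, 1, 1))
  comp <- voxels(composeFields(f1, f2))
  for (k in 1:3)
    expect_lt(max(abs(comp[, , , k] - (t1[k] + t2[k]))), 1e-3)
})

test_that("warping with a zero field is the exact identity", {
  p <- smallPhantom(seed = 1)
  z <- zeroField(dim(voxels(p$image)), spacing = spacing(p$image))
  expect_identical(voxels(warpImage(p$image, z)), voxels(p$image))
  expect_identical(voxels(warpLabels(p$labels, z)), voxels(p$labels))
})

test_that("a one-voxel constant shift reproduces the integer-shift oracle", {
  img <- smoothRandomImage(c(20, 20, 20), seed = 4)
  f <- constantField(c(20, 20, 20), c(1, 0, 0), spacing = c(1, 1, 1))
  w <- voxels(warpImage(img, f))
  v <- voxels(img)
  # interior: output[i] = input[i + 1]
  expect_equal(w[1:19, , ], v[2:20, , ])
})

test_that("warped intensities stay within the source extrema and codes never grow", {
  p <- smallPhantom(seed = 2)
  u <- smoothRandomField(dim(voxels(p$image)), seed = 6, sd = 3)
  u@spacing <- spacing(p$image)
  w <- warpImage(p$image, u)
  expect_gte(min(voxels(w)), min(voxels(p$image)))
  expect_lte(max(voxels(w)), max(voxels(p$image)))
  lw <- warpLabels(p$labels, u)
  expect_true(all(unique(as.vector(voxels(lw))) %in%
                  c(0, organTable(p$labels))))
})

test_that("zero deformation bounds make simulateSession an exact fixed point", {
  p <- smallPhantom(seed = 3)
  zero <- deformParams(maxDisplacementMm = 0, maxExpansion = 0,
                       maxShrinkage = 0, maxRotationDeg = 0)
  s <- simulateSession(p$image, p$labels, zero, seed = 1)
  expect_identical(voxels(s$image), voxels(p$image))
  expect_identical(voxels(s$labels), voxels(p$labels))
  expect_true(all(voxels(s$field) == 0))
})

test_that("simulated sessions deform at least one organ and are reproducible", {
  p <- smallPhantom(seed = 3)
  s1 <- simulateSession(p$image, p$labels, deformParams(), seed = 21)
  s2 <- simulateSession(p$image, p$labels, deformParams(), seed = 21)
  expect_identical(voxels(s1$image), voxels(s2$image))
  expect_identical(voxels(s1$labels), voxels(s2$labels))
  tab <- organTable(p$labels)
  dscs <- vapply(names(tab), function(o) {
    dice(organMask(p$labels, o), organMask(s1$labels, o))
  }, numeric(1))
  expect_true(any(dscs < 1))
  s3 <- simulateSession(p$image, p$labels, deformParams(), seed = 22)
  expect_false(identical(voxels(s1$labels), voxels(s3$labels)))
})

test_that("a single-organ map reduces simulateSession to one field generation", {
  m <- ellipsoidMask(c(32, 32, 32), c(16, 16, 16), c(6, 7, 5))
  lab <- LabelVolume(voxels(m), organTable = c(liver = 1L),
                     spacing = spacing(m))
  img <- ImageVolume(voxels(m) * 50 + 10, spacing = spacing(m))
  params <- deformParams()
  s <- simulateSession(img, lab, params, seed = 31)
  draw <- samplePhiDraw(params, seed = 31)
  f <- generateLabelField(m, draw, params)
  expect_equal(voxels(s$field), voxels(f))
  expect_identical(voxels(s$labels),
                   voxels(warpLabels(lab, f)))
})

test_that("labels warped with their image keep each organ under its intensity", {
  spec <- phantomSpec(gridShape = c(48, 48, 32), seed = 8)
  spec$intensityModel$biasAmplitude <- 0
  p <- makePhantom(spec)
  s <- simulateSession(p$image, p$labels, deformParams(maxDisplacementMm = 5),
                       seed = 9)
  tab <- organTable(p$labels)
  means <- spec$intensityModel$means
  for (organ in c("liver", "spleen", "left_kidney", "right_kidney")) {
    inOrgan <- voxels(s$image)[voxels(s$labels) == tab[[organ]]]
    expect_lt(abs(mean(inOrgan) - means[[organ]]), 10,
              label = paste(organ, "mean intensity under warped label"))
  }
})

test_that("the Jacobian determinant flags identity, translation and folding correctly", {
  z <- zeroField(c(16, 16, 16), spacing = c(1.5, 2, 1))
  expect_equal(jacobianMin(z), 1.0)
  tf <- constantField(c(16, 16, 16), c(3, -2, 1), spacing = c(1.5, 2, 1))
  expect_equal(jacobianMin(tf), 1.0)
  # a strong compressive gradient along x folds the transform
  d <- c(16, 16, 16)
  u <- array(0, c(d, 3))
  u[, , , 1] <- -2 * ((1:16) - 1)  # du/dx = -2 with unit spacing
  fold <- DisplacementField(u, spacing = c(1, 1, 1))
  expect_warning(j <- jacobianMin(fold), "fold")
  expect_lte(j, 0)
})

test_that("geometry mismatches are rejected with a validation error", {
  img <- smoothRandomImage(c(16, 16, 16), seed = 1)
  f <- zeroField(c(16, 16, 12), spacing = c(1, 1, 1))
  expect_error(warpImage(img, f), "geometry")
  expect_error(composeFields(f, zeroField(c(16, 16, 16),
                                          spacing = c(1, 1, 1))),
               "geometry")
})
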