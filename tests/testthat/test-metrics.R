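test_that("Dice matches hand-computed fixtures and the empty-mask convention", {
  a <- cubeMask(c(10, 10, 10), c(3, 3, 3), 2)
  expect_equal(dice(a, a), 1)
  b <- cubeMask(c(10, 10, 10), c(4, 3, 3), 2)  # shifted 1 voxel along x
  expect_equal(dice(a, b), 0.5)                # 2*4 / (8 + 8)
  disjoint <- cubeMask(c(10, 10, 10), c(7, 7, 7), 2)
  expect_equal(dice(a, disjoint), 0)
  empty <- BinaryMask(array(0, c(10, 10, 10)))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(a, empty), 0)
  wrong <- cubeMask(c(8, 8, 8), c(3, 3, 3), 2)
  expect_error(dice(a, wrong), "geometry")
})

test_that("surface distances match slab geometry and a brute-force oracle", {
  s1 <- slabMask(c(12, 12, 31), z = 10)
  s2 <- slabMask(c(12, 12, 31), z = 20)
  sd <- surfaceDistances(s1, s2)
  expect_true(all(sd$ab == 10))
  expect_true(all(sd$ba == 10))
  expect_equal(asd(s1, s2), 10)
  expect_equal(hd95(s1, s2), 10)
  expect_equal(asd(s1, s1), 0)
  expect_equal(hd95(s1, s1), 0)
  # multiset symmetry under swapping
  a <- ellipsoidMask(c(20, 20, 20), c(9, 10, 10), c(4, 5, 3),
                     spacing = c(1, 2, 1.5))
  b <- ellipsoidMask(c(20, 20, 20), c(12, 10, 11), c(5, 4, 4),
                     spacing = c(1, 2, 1.5))
  fwd <- surfaceDistances(a, b)
  rev <- surfaceDistances(b, a)
  expect_equal(fwd$ab, rev$ba)
  expect_equal(fwd$ba, rev$ab)
  # EDT-based distances equal the naive pairwise search
  surfOf <- function(m) {
    v <- voxels(m) != 0
    DefAug:::.surfaceVoxels(v)
  }
  oracle <- oracleSurfaceDistances(surfOf(a), surfOf(b), spacing(a))
  expect_equal(sort(fwd$ab), sort(oracle), tolerance = 1e-10)
  expect_lte(hd95(a, b), max(c(fwd$ab, fwd$ba)))
  expect_lte(asd(a, b), max(c(fwd$ab, fwd$ba)))
  expect_error(surfaceDistances(a, BinaryMask(array(0, c(20, 20, 20)),
                                              spacing = spacing(a))),
               "empty")
})

test_that("DVH curves are cumulative, start at 1 and step for uniform dose", {
  d <- c(10, 10, 10)
  mask <- cubeMask(d, c(3, 3, 3), 4, spacing = c(2, 2, 2))
  doseArr <- array(0, d); doseArr[voxels(mask) != 0] <- 25
  dose <- DoseGrid(doseArr, prescription = 40, spacing = c(2, 2, 2))
  curve <- dvh(dose, mask, edges = seq(0, 30, by = 1))
  vf <- volumeFraction(curve)
  expect_equal(vf[1], 1)
  expect_true(all(diff(vf) <= 1e-12))
  expect_true(all(vf[doseEdges(curve) <= 25] == 1))
  expect_true(all(vf[doseEdges(curve) > 25] == 0))
  # random dose/mask: still non-increasing, still starts at 1
  set.seed(5)
  rndDose <- DoseGrid(array(runif(1000, 0, 50), d), prescription = 40,
                      spacing = c(2, 2, 2))
  rc <- dvh(rndDose, mask)
  expect_equal(volumeFraction(rc)[1], 1)
  expect_true(all(diff(volumeFraction(rc)) <= 1e-12))
})

test_that("dose-at-volume handles uniform dose, the two-plateau median and bounds", {
  d <- c(10, 10, 10)
  mask <- BinaryMask(array(1, d), spacing = c(5, 5, 5))
  uni <- DoseGrid(array(12.5, d), prescription = 40, spacing = c(5, 5, 5))
  expect_equal(doseAtVolume(uni, mask, cc = 0.1), 12.5)
  expect_equal(doseAtVolume(uni, mask, pct = 50), 12.5)
  # half the voxels at 10 Gy, half at 20 Gy -> D50% is the interpolated median
  half <- array(10, d); half[1:5, , ] <- 20
  hd <- DoseGrid(half, prescription = 40, spacing = c(5, 5, 5))
  expect_equal(doseAtVolume(hd, mask, pct = 50), 15)
  # monotone non-increasing as the requested volume grows
  set.seed(8)
  rnd <- DoseGrid(array(runif(1000, 0, 45), d), prescription = 40,
                  spacing = c(5, 5, 5))
  ccs <- c(0.2, 1, 5, 20, 60)
  vals <- vapply(ccs, function(cc) doseAtVolume(rnd, mask, cc = cc),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(doseAtVolume(rnd, mask, cc = 1e6), "smaller")
  expect_error(doseAtVolume(rnd, mask), "exactly one")
})

test_that("dose-at-volume agrees with the brute-force sort oracle on random masks", {
  set.seed(99)
  for (i in 1:200) {
    d <- c(sample(4:10, 1), sample(4:10, 1), sample(4:10, 1))
    spc <- runif(3, 1, 4)
    maskArr <- array(stats::rbinom(prod(d), 1, 0.5), d)
    if (!any(maskArr == 1)) maskArr[1] <- 1
    doseArr <- array(runif(prod(d), 0, 60), d)
    mask <- BinaryMask(maskArr, spacing = spc)
    dose <- DoseGrid(doseArr, prescription = 40, spacing = spc)
    voxCc <- prod(spc) / 1000
    n <- sum(maskArr)
    vReq <- runif(1, 0.01, 1) * n * voxCc
    got <- doseAtVolume(dose, mask, cc = vReq)
    want <- oracleDoseAtVolume(doseArr[maskArr == 1], voxCc, vReq)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("dPD is the absolute discrepancy as a percentage of the prescription", {
  expect_equal(dpd(32, 32, 40), 0)
  expect_equal(dpd(36, 32, 40), 10)
  expect_equal(dpd(32, 36, 40), 10)     # symmetric under swap
  expect_equal(dpd(32, 36, 40, signed = TRUE), -10)
})

test_that("gradient-weighted Dice reduces to Dice under constant gradient", {
  d <- c(12, 12, 12)
  a <- cubeMask(d, c(3, 3, 3), 4, spacing = c(2, 2, 2))
  b <- cubeMask(d, c(4, 3, 3), 4, spacing = c(2, 2, 2))
  # linear ramp: gradient magnitude exactly constant everywhere
  ramp <- array(rep(0.5 * 2 * ((1:12) - 1), times = 144), d)
  dose <- DoseGrid(ramp, prescription = 40, spacing = c(2, 2, 2))
  expect_equal(mdice(a, b, dose), dice(a, b), tolerance = 1e-12)
  expect_equal(mdice(a, a, dose), 1)
  # zero gradient -> fall back to plain Dice with a notice
  flat <- DoseGrid(array(5, d), prescription = 40, spacing = c(2, 2, 2))
  expect_message(md <- mdice(a, b, flat), "unweighted")
  expect_equal(md, dice(a, b))
})

test_that("mdice exceeds Dice when disagreement sits in a flat dose region", {
  d <- c(20, 20, 8)
  # agreement region near a steep dose blob, disagreement far away
  a <- array(0, d); a[4:6, 4:6, 3:5] <- 1; a[14:16, 14:16, 3:5] <- 1
  b <- array(0, d); b[4:6, 4:6, 3:5] <- 1; b[17:19, 14:16, 3:5] <- 1
  doseArr <- array(0, d)
  idx <- which(doseArr == 0, arr.ind = TRUE)
  r2 <- (idx[, 1] - 5)^2 + (idx[, 2] - 5)^2 + (idx[, 3] - 4)^2
  doseArr[idx] <- 40 * exp(-r2 / 8)
  am <- BinaryMask(a); bm <- BinaryMask(b)
  dose <- DoseGrid(doseArr, prescription = 40)
  expect_gt(mdice(am, bm, dose), dice(am, bm))
  # brute-force weighted sums reproduce the value
  spc <- c(1, 1, 1)
  g <- array(0, d)
  w <- sqrt(DefAug:::.gradAxis(doseArr, 1, 1)^2 +
            DefAug:::.gradAxis(doseArr, 2, 1)^2 +
            DefAug:::.gradAxis(doseArr, 3, 1)^2)
  want <- 2 * sum(w[a == 1 & b == 1]) / (sum(w[a == 1]) + sum(w[b == 1]))
  expect_equal(mdice(am, bm, dose), want)
})

test_that("contour evaluation reports every ground-truth organ with sensible values", {
  p <- smallPhantom(seed = 13)
  perfect <- evaluateContours(p$labels, p$labels)
  expect_equal(nrow(perfect), 9L)
  expect_true(all(perfect$dsc == 1))
  expect_true(all(perfect$asd_mm == 0))
  expect_true(all(perfect$hd95_mm == 0))
  dose <- makeDosePhantom(p$labels, prescriptionGy = 40)
  withDose <- evaluateContours(p$labels, p$labels, dose = dose)
  expect_true(all(withDose$mdice == 1))
  expect_true(all(withDose$d01cc_dpd_pct[!is.na(withDose$d01cc_dpd_pct)]
                  == 0))
  expect_true(all(withDose$d50_dpd_pct[!is.na(withDose$d50_dpd_pct)] == 0))

  s <- simulateSession(p$image, p$labels, deformParams(maxDisplacementMm = 4),
                       seed = 14)
  rep <- evaluateContours(s$labels, p$labels, dose = dose)
  expect_equal(sort(rep$organ), sort(names(organTable(p$labels))))
  expect_true(all(rep$dsc > 0 & rep$dsc <= 1))
  expect_true(all(rep$mdice >= 0 & rep$mdice <= 1))
  expect_true(all(rep$asd_mm >= 0))
})

test_that("missing and empty organs are reported, never dropped", {
  pk <- makePhantom(phantomSpec(gridShape = c(32, 32, 24),
                                includeRightKidney = FALSE, seed = 15))
  rep <- evaluateContours(pk$labels, pk$labels)
  expect_equal(nrow(rep), 8L)
  expect_false("right_kidney" %in% rep$organ)
  # organ present in gt, absent in pred -> DSC 0, flagged sentinel distances
  full <- smallPhantom(seed = 15)
  predArr <- voxels(full$labels)
  predArr[predArr == organTable(full$labels)[["spleen"]]] <- 0
  pred <- LabelVolume(predArr, organTable = organTable(full$labels),
                      spacing = spacing(full$labels))
  rep2 <- evaluateContours(pred, full$labels)
  spleenRow <- rep2[rep2$organ == "spleen", ]
  expect_equal(spleenRow$dsc, 0)
  expect_true(spleenRow$distance_undefined)
  expect_true(is.na(spleenRow$asd_mm))
  expect_equal(nrow(rep2), 9L)
})

test_that("metrics are invariant under background padding of all inputs", {
  a <- cubeMask(c(10, 10, 10), c(3, 3, 3), 3, spacing = c(2, 2, 2))
  b <- cubeMask(c(10, 10, 10), c(4, 4, 3), 3, spacing = c(2, 2, 2))
  pad <- function(m, extra = 4) {
    arr <- array(0, dim(voxels(m)) + extra)
    arr[seq_len(10), seq_len(10), seq_len(10)] <- voxels(m)
    BinaryMask(arr, spacing = spacing(m))
  }
  expect_equal(dice(pad(a), pad(b)), dice(a, b))
  expect_equal(asd(pad(a), pad(b)), asd(a, b))
  expect_equal(hd95(pad(a), pad(b)), hd95(a, b))
})

test_that("cohort aggregation summarizes per-organ means and sds", {
  p <- smallPhantom(seed = 16)
  r1 <- evaluateContours(p$labels, p$labels)
  s <- simulateSession(p$image, p$labels, deformParams(maxDisplacementMm = 3),
                       seed = 17)
  r2 <- evaluateContours(s$labels, p$labels)
  agg <- aggregateReports(list(caseA = r1, caseB = r2))
  expect_equal(nrow(agg$perCase), 18L)
  expect_equal(nrow(agg$summary), 9L)
  liver <- agg$summary[agg$summary$organ == "liver", ]
  liverCases <- agg$perCase$dsc[agg$perCase$organ == "liver"]
  expect_equal(liver$dsc_mean, mean(liverCases))
  expect_equal(liver$dsc_sd, stats::sd(liverCases))
})
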