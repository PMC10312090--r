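## Small hand-built label geometries; voxel size defaults to the
## anisotropic 1.3 x 1.3 x 5 mm acquisition grid.

makeLabels <- function(dims, fill = 0L, voxelSize = c(1.3, 1.3, 5)) {
  LabelVolume(array(as.integer(fill), dims), voxelSize)
}

test_that("scaled distance transform equals the brute-force distance", {
  set.seed(21)
  for (rep in 1:3) {
    dims <- c(10, 9, 6)
    target <- array(runif(prod(dims)) < 0.06, dims)
    if (!any(target)) target[5, 5, 3] <- TRUE
    radii <- c(1, 1, 5)
    got <- scaledSquaredDistance(target, c(1.3, 1.3, 5), radii)
    want <- bruteScaledDistSq(target, c(1.3, 1.3, 5), radii)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("one-voxel-thick in-plane structures vanish under 1 mm erosion", {
  dims <- c(12, 12, 4)
  lab <- array(0L, dims)
  lab[6, 3:10, 2] <- 2L        # cortex sheet 1 voxel thick in x
  lab[3, 3, 2] <- 4L           # a far-away ventricle voxel (CSF present)
  lv <- LabelVolume(lab, c(1.3, 1.3, 5))
  suppressWarnings(rois <- erodeRois(lv, erosionSpec(stage1Mm = 1,
                                                     inPlaneMm = 0,
                                                     throughPlaneMm = 0)))
  expect_equal(sum(roiMask(rois, "cortex")), 0)
})

test_that("a tissue voxel one slice from the ventricle is removed", {
  dims <- c(9, 9, 7)
  lab <- array(0L, dims)
  lab[, , ] <- 1L              # all WM
  lab[5, 5, 4] <- 4L           # single ventricle voxel
  lab[1, 1, 1] <- 5L           # subarachnoid corner so both CSF labels exist
  lv <- LabelVolume(lab, c(1.3, 1.3, 5))
  rois <- erodeRois(lv, erosionSpec(stage1Mm = 0, inPlaneMm = 1,
                                    throughPlaneMm = 5))
  wm <- roiMask(rois, "wm")
  ## directly above the ventricle: center distance exactly 5 mm -> removed
  expect_false(wm[5, 5, 5])
  expect_false(wm[5, 5, 3])
  ## in-plane neighbor: 1.3 mm >= 1 mm in-plane -> kept
  expect_true(wm[6, 5, 4])
  ## and the brute-force criterion agrees everywhere
  csf <- array(lab %in% c(4L, 5L), dims)
  dsq <- bruteScaledDistSq(csf, c(1.3, 1.3, 5), c(1, 1, 5))
  expect_identical(wm, array(lab == 1L, dims) & (dsq > 1 + 1e-12))
})

test_that("tissue far from CSF in every axis is untouched by stage 2", {
  dims <- c(20, 20, 8)
  lab <- array(0L, dims)
  lab[9:12, 9:12, 4:5] <- 1L     # WM block
  lab[1, 1, 1] <- 4L             # CSF at the far corner (> 10 mm away)
  lab[20, 20, 8] <- 5L
  lv <- LabelVolume(lab, c(1.3, 1.3, 5))
  rois <- erodeRois(lv, erosionSpec(stage1Mm = 0))
  expect_identical(roiMask(rois, "wm"), array(lab == 1L, dims))
})

test_that("erosion masks form a nested chain and stay disjoint", {
  lv <- buildLabelVolume(c(32, 32, 16), c(1.3, 1.3, 5), seed = 3)
  raw <- lapply(c(wm = 1L, cortex = 2L, deepgm = 3L), function(l)
    array(labelData(lv) == l, dim(labelData(lv))))
  prev <- NULL
  for (tp in c(1, 3, 5)) {
    rois <- suppressWarnings(
      erodeRois(lv, erosionSpec(stage1Mm = 1, inPlaneMm = 1,
                                throughPlaneMm = tp)))
    cur <- lapply(c("wm", "cortex", "deepgm"), roiMask, x = rois)
    names(cur) <- c("wm", "cortex", "deepgm")
    for (rn in names(cur)) {
      expect_true(all(raw[[rn]][cur[[rn]]]))          # subset of label
      if (!is.null(prev)) expect_true(all(prev[[rn]][cur[[rn]]]))
    }
    expect_false(any(cur$wm & cur$cortex))
    expect_false(any(cur$wm & cur$deepgm))
    expect_false(any(cur$cortex & cur$deepgm))
    prev <- cur
  }
})

test_that("center and boundary distance modes agree on their ordering", {
  dims <- c(8, 8, 5)
  lab <- array(0L, dims)
  lab[, , ] <- 1L
  lab[4, 4, 3] <- 4L
  lab[1, 1, 1] <- 5L
  lv <- LabelVolume(lab, c(1.3, 1.3, 5))
  center <- erodeRois(lv, erosionSpec(stage1Mm = 0))
  boundary <- erodeRois(lv, erosionSpec(stage1Mm = 0,
                                        distanceMode = "boundary"))
  ## boundary distances are shorter, so the boundary-mode mask is a subset
  cb <- roiMask(boundary, "wm"); cc <- roiMask(center, "wm")
  expect_true(all(cc[cb]))
  expect_lte(sum(cb), sum(cc))
})

test_that("erosion sweep voxel counts shrink and contamination falls", {
  ## masks live on a 1 mm isotropic segmentation grid, where the 1..7 mm
  ## through-plane sweep is meaningful
  lv <- buildLabelVolume(c(32, 32, 32), c(1, 1, 1), seed = 5)
  lab <- labelData(lv)
  dims <- dim(lab)
  ## synthetic CSFF map: baseline 0.02 plus CSF contamination decaying with
  ## physical distance to CSF (partial-volume mixing at the rim)
  csf <- array(lab %in% c(4L, 5L), dims)
  dmm <- sqrt(scaledSquaredDistance(csf, c(1, 1, 1), c(1, 1, 1)))
  csffMap <- 0.02 + 0.30 * exp(-dmm / 3)
  defined <- array(lab %in% 1:3, dims)
  csffMap[!defined] <- NA
  mwfMap <- ifelse(is.na(csffMap), NA, 0.1)
  iewfMap <- 1 - csffMap - mwfMap
  wf <- new("WFMaps", mwf = mwfMap, iewf = iewfMap, csff = csffMap,
            defined = defined, voxelSize = c(1, 1, 1))
  sweep <- erosionSweep(lv, wf, throughPlaneMm = c(1, 3, 5, 7))
  expect_equal(sweep$level[1], "uneroded")
  expect_equal(which.max(sweep$n_voxels), 1L)
  expect_true(all(diff(sweep$n_voxels) <= 0))
  ok <- !is.na(sweep$mean_csff)
  expect_true(all(diff(sweep$mean_csff[ok]) < 0))
})

test_that("aggressive erosion warns instead of failing silently", {
  dims <- c(16, 16, 4)
  lab <- array(0L, dims)
  lab[4:13, 4:13, 2:3] <- 2L
  lab[8, 8, 2] <- 4L
  lab[4, 4, 3] <- 5L
  lv <- LabelVolume(lab, c(1.3, 1.3, 5))
  expect_warning(erodeRois(lv, erosionSpec(stage1Mm = 0, inPlaneMm = 30,
                                           throughPlaneMm = 30)),
                 "empty")
  noCsf <- makeLabels(c(16, 16, 8), 1L)
  expect_error(erodeRois(noCsf), "CSF")
})

test_that("regional means equal direct averages over mask indices", {
  dims <- c(6, 6, 4)
  set.seed(12)
  csffMap <- array(runif(prod(dims), 0, 0.2), dims)
  mwfMap <- array(runif(prod(dims), 0, 0.2), dims)
  iewfMap <- 1 - csffMap - mwfMap
  defined <- array(TRUE, dims); defined[1, 1, 1] <- FALSE
  csffMap[1, 1, 1] <- NA; mwfMap[1, 1, 1] <- NA; iewfMap[1, 1, 1] <- NA
  wf <- new("WFMaps", mwf = mwfMap, iewf = iewfMap, csff = csffMap,
            defined = defined, voxelSize = c(1.3, 1.3, 5))
  masks <- list(wm = array(FALSE, dims), cortex = array(FALSE, dims),
                deepgm = array(FALSE, dims))
  masks$wm[2:4, 2:4, 2] <- TRUE
  masks$cortex[5, 5:6, 3] <- TRUE
  masks$deepgm[1, 1, 1] <- TRUE   # only the undefined voxel
  rois <- new("RoiMaskSet", masks = masks, spec = list(),
              voxelSize = c(1.3, 1.3, 5))
  expect_warning(rm <- regionalMeans(wf, rois), "deepgm")
  expect_equal(rm$csff[rm$roi == "wm"], mean(csffMap[masks$wm]))
  expect_equal(rm$mwf[rm$roi == "cortex"], mean(mwfMap[masks$cortex]))
  expect_true(is.na(rm$csff[rm$roi == "deepgm"]))
  expect_equal(rm$n_voxels, c(9L, 2L, 0L))

  ## constant and half/half sanity cases
  csffMap[] <- 0.05; iewfMap <- 1 - csffMap - mwfMap
  csffMap[1, 1, 1] <- NA; iewfMap[1, 1, 1] <- NA
  wf2 <- new("WFMaps", mwf = mwfMap, iewf = iewfMap, csff = csffMap,
             defined = defined, voxelSize = c(1.3, 1.3, 5))
  expect_warning(rm2 <- regionalMeans(wf2, rois))
  expect_equal(rm2$csff[1], 0.05)
  half <- csffMap; half[masks$wm][1:4] <- 0.04; half[masks$wm][6:9] <- 0.06
  ## direct check of the arithmetic-mean contract
  expect_equal(mean(half[masks$wm]), 0.05, tolerance = 1e-12)
})

test_that("volume normalization is a guarded product", {
  expect_equal(normalizeVolume(100, 1), 100)
  expect_equal(normalizeVolume(100, 1.2), 120)
  expect_error(normalizeVolume(100, 0), "> 0")
  expect_error(normalizeVolume(100, -2), "> 0")
  ## monotone within subject: ordering preserved
  raw <- c(10, 20, 30)
  expect_identical(order(normalizeVolume(raw, 1.3)), order(raw))
})
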