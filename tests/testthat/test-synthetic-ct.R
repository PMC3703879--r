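test_that("HU threshold segmentation follows the printed window bounds", {
  v <- new("HUVolume", voxels = array(c(150, 150.5, 750, 751, 0, -10), c(6, 1, 1)),
           spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0))
  lab <- segmentHU(v)@labels[, 1, 1]
  expect_equal(lab, c("soft", "trabecular", "trabecular", "cortical",
                      "soft", "soft"))
  ## all-zero volume is all soft tissue
  z <- new("HUVolume", voxels = array(0, c(3, 3, 3)), spacing_mm = rep(1, 3),
           origin_mm = rep(0, 3))
  expect_true(all(segmentHU(z)@labels == "soft"))
  expect_error(segmentHU(z, soft_max = 800, trabecular_max = 750))
})

test_that("segmentation is idempotent and threshold-monotone", {
  set.seed(11)
  v <- new("HUVolume", voxels = array(runif(400, -100, 1500), c(10, 10, 4)),
           spacing_mm = rep(1, 3), origin_mm = rep(0, 3))
  s1 <- segmentHU(v)
  ## raising soft_max never converts soft -> bone
  for (sm in c(200, 400, 700)) {
    s2 <- segmentHU(v, soft_max = sm)
    expect_true(all(s2@labels[s1@labels == "soft"] == "soft"))
  }
})

test_that("the noiseless generated volume reproduces the bone model exactly", {
  bone <- boneSegmentSpec()
  vol <- generateHUVolume(bone, noise_sd = 0, spacing_mm = 1)
  seg <- segmentHU(vol)
  ## recompute the generating masks at the voxel centres
  solid <- buildBoneSegment(bone)
  g <- osseoFEM:::.voxelGrid(bone, 1)
  dims <- dim(vol@voxels)
  xx <- rep(g$x, times = dims[2] * dims[3])
  yy <- rep(rep(g$y, each = dims[1]), times = dims[3])
  zz <- rep(g$z, each = dims[1] * dims[2])
  tis <- solid@tissueFun(xx, yy, zz)
  want <- ifelse(tis == "outside", "soft", tis)
  expect_identical(as.vector(seg@labels), unname(want))
})

test_that("the cortical voxel fraction matches the analytic shell fraction", {
  bone <- boneSegmentSpec()
  vol <- generateHUVolume(bone, noise_sd = 0, spacing_mm = 0.4)
  seg <- segmentHU(vol)
  solid <- buildBoneSegment(bone)
  nvox <- prod(dim(vol@voxels))
  vox_vol <- prod(vol@spacing_mm)
  cort_frac_vox <- labelFraction(seg, "cortical") * nvox * vox_vol
  expect_equal(cort_frac_vox, solid@cortical_volume_mm3, tolerance = 0.02)
})

test_that("generation with noise is deterministic per seed", {
  bone <- boneSegmentSpec()
  v1 <- generateHUVolume(bone, noise_sd = 30, seed = 42, spacing_mm = 1.5)
  v2 <- generateHUVolume(bone, noise_sd = 30, seed = 42, spacing_mm = 1.5)
  v3 <- generateHUVolume(bone, noise_sd = 30, seed = 43, spacing_mm = 1.5)
  expect_identical(v1@voxels, v2@voxels)
  expect_false(identical(v1@voxels, v3@voxels))
  expect_warning(generateHUVolume(bone, noise_sd = 0, spacing_mm = 2.5),
                 "alias")
})
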