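test_that("threshold bounds are inclusive and sub-threshold voxels are excluded", {
  vox <- array(c(100, 225, 3070, 3071, 224, 1000), c(3, 2, 1))
  vol <- ct_volume(vox, 1)
  mask <- segment_hu(vol, 225, 3070)
  expect_identical(as.vector(mask), c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_error(segment_hu(vol, 500, 100), "hu_low < hu_high")
})

test_that("exclusion masks remove voxels and must match shape", {
  vol <- generate_hu_volume(c(10, 10, 10), 0.5,
                            list(list(type = "box", lower = c(2, 2, 2),
                                      upper = c(5, 5, 5), hu = 800)))
  all_excl <- array(TRUE, dim(vol$voxels))
  expect_identical(sum(segment_hu(vol, exclusion = all_excl)), 0L)
  expect_error(segment_hu(vol, exclusion = array(TRUE, c(2, 2, 2))),
               "shape")
  # partial exclusion removes exactly the covered voxels
  half <- array(FALSE, dim(vol$voxels)); half[1:3, , ] <- TRUE
  m_full <- segment_hu(vol); m_half <- segment_hu(vol, exclusion = half)
  expect_identical(sum(m_half), sum(m_full & !half))
})

test_that("measured volume is count times voxel volume", {
  expect_equal(measure_volume(array(FALSE, c(4, 4, 4)), 0.5), 0)
  mask <- array(FALSE, c(10, 10, 10)); mask[seq_len(1000)] <- TRUE
  expect_equal(measure_volume(mask, 0.5), 125)
  expect_equal(measure_volume(mask, c(0.5, 1, 2)), 1000)
})

test_that("a rasterized sphere recovers its analytic volume within 2%", {
  vol <- generate_hu_volume(c(25, 25, 25), 0.5,
                            list(list(type = "sphere", center = c(13, 13, 13),
                                      radius = 10, hu = 800)))
  truth <- attr(vol, "truth")
  expect_equal(truth, 4 / 3 * pi * 5^3)
  measured <- measure_volume(segment_hu(vol), vol)
  expect_lt(abs(measured - truth) / truth, 0.02)
})

test_that("inclusions below the bone window are excluded entirely", {
  vol <- generate_hu_volume(c(12, 12, 12), 0.5,
                            list(list(type = "sphere", center = c(6, 6, 6),
                                      radius = 4, hu = 100)))
  expect_equal(measure_volume(segment_hu(vol), vol), 0)
  empty <- generate_hu_volume(c(8, 8, 8), 0.5)
  expect_equal(measure_volume(segment_hu(empty), empty), 0)
})

test_that("volume is additive over disjoint masks and monotone in the window", {
  vol <- generate_hu_volume(c(16, 16, 16), 1,
                            list(list(type = "box", lower = c(1, 1, 1),
                                      upper = c(4, 4, 4), hu = 500),
                                 list(type = "box", lower = c(9, 9, 9),
                                      upper = c(14, 14, 14), hu = 2000)))
  m_all <- segment_hu(vol, 225, 3070)
  m_lo <- segment_hu(vol, 225, 1000)
  m_hi <- segment_hu(vol, 1001, 3070)
  expect_identical(sum(m_lo & m_hi), 0L)
  expect_equal(measure_volume(m_all, vol),
               measure_volume(m_lo, vol) + measure_volume(m_hi, vol))
  expect_gte(measure_volume(segment_hu(vol, 100, 4000), vol),
             measure_volume(m_all, vol))
})

test_that("NIfTI round trip preserves voxels and spacing", {
  vol <- generate_hu_volume(c(9, 8, 7), c(0.5, 0.5, 1),
                            list(list(type = "box", lower = c(2, 2, 2),
                                      upper = c(4, 4, 4), hu = 700)))
  path <- file.path(tempdir(), "vol.nii.gz")
  write_ct_nifti(vol, path)
  back <- read_ct_nifti(path)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
})
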