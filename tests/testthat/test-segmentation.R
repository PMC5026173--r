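test_that("background ROI selection is seeded and handles flat images", {
  img <- magnitude_image(matrix(0, 32, 32))
  roi <- select_background_roi(img, seed = 1)
  expect_equal(roi$mean, 0)
  expect_equal(roi$sd, 0)

  ph <- make_phantom(control_phantom_spec(seed = 2))
  im <- sim_frame(ph, 0, seed = 3)
  r1 <- select_background_roi(im, seed = 10)
  r2 <- select_background_roi(im, seed = 10)
  expect_identical(r1, r2)

  # an image saturated with signal leaves no candidate position
  hot <- magnitude_image(matrix(stats::rchisq(32 * 32, 3) + 50, 32, 32))
  expect_error(select_background_roi(hot, seed = 1, fg_cut = 1), "saturated")
})

test_that("random ROI placement avoids the true lung", {
  ph <- make_phantom(control_phantom_spec(seed = 4))
  im <- sim_frame(ph, 0, seed = 5)
  hits <- vapply(1:100, function(s) {
    roi <- select_background_roi(im, seed = s)
    block <- ph$lung_mask_true[roi$origin[1] + 0:(roi$size[1] - 1),
                               roi$origin[2] + 0:(roi$size[2] - 1)]
    any(block)
  }, logical(1))
  expect_gte(sum(!hits), 99)
})

test_that("mean + 3 SD thresholding follows the rule with inclusive boundary", {
  roi0 <- structure(list(origin = c(1L, 1L), size = c(10L, 10L), mean = 5, sd = 0),
                    class = "background_roi")
  img <- magnitude_image(matrix(6, 16, 16))
  expect_equal(threshold_and_mask(img, roi0)$threshold_value, 5)

  roi <- structure(list(origin = c(1L, 1L), size = c(10L, 10L), mean = 2, sd = 1),
                   class = "background_roi")
  vals <- matrix(c(4.9, 5.0, 5.1, 0), 2, 2)
  m <- threshold_and_mask(magnitude_image(vals), roi)
  expect_equal(m$threshold_value, 5)
  expect_identical(as.vector(m$mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(m$n_voxels, 2L)
})

test_that("threshold is translation-equivariant and mask monotone", {
  set.seed(42)
  base <- matrix(abs(stats::rnorm(40 * 40, 10, 3)), 40, 40)
  img <- magnitude_image(base)
  roi <- background_roi_at(img, c(1, 1))
  m0 <- threshold_and_mask(img, roi)

  cshift <- 7.5
  img_c <- magnitude_image(base + cshift)
  roi_c <- background_roi_at(img_c, c(1, 1))
  m1 <- threshold_and_mask(img_c, roi_c)
  expect_equal(m1$threshold_value, m0$threshold_value + cshift)
  expect_identical(m1$mask, m0$mask)

  # voxel count is non-increasing in the threshold
  counts <- vapply(seq(0, 20, by = 2), function(thr) {
    roi_t <- structure(list(origin = c(1L, 1L), size = c(10L, 10L),
                            mean = thr, sd = 0), class = "background_roi")
    threshold_and_mask(img, roi_t)$n_voxels
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline frames segment to the true lung up to boundary voxels", {
  # the 3-SD threshold sits a few percent of the lung signal above zero, so
  # the mask contains the full lung plus a 1-2 voxel point-spread halo
  ph <- make_phantom(control_phantom_spec(seed = 6))
  band2 <- xeventmap:::dilate_box(ph$lung_mask_true, 2)
  for (s in 1:5) {
    im <- sim_frame(ph, 0, seed = s)
    roi <- select_background_roi(im, seed = s)
    m <- threshold_and_mask(im, roi)
    expect_equal(sum(ph$lung_mask_true & !m$mask), 0)      # no lung missed
    expect_lt(sum(m$mask & !band2) / m$n_voxels, 0.05)     # stray voxels rare
    expect_gte(dice(m$mask, ph$lung_mask_true), 0.90)
  }
})

test_that("whole-lung SNR is mean in-mask signal over background SD", {
  img <- magnitude_image(matrix(70, 16, 16))
  mask <- matrix(TRUE, 16, 16)
  roi <- structure(list(origin = c(1L, 1L), size = c(10L, 10L), mean = 0, sd = 1),
                   class = "background_roi")
  expect_equal(whole_lung_snr(img, mask, roi), 70)

  img2 <- magnitude_image(matrix(c(10, 30, 0, 0), 2, 2))
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  roi2 <- structure(list(origin = c(1L, 1L), size = c(1L, 1L), mean = 0, sd = 2),
                    class = "background_roi")
  expect_equal(whole_lung_snr(img2, mask2, roi2), 10)

  expect_error(whole_lung_snr(img2, matrix(FALSE, 2, 2), roi2), "empty")
  roi_bad <- structure(list(origin = c(1L, 1L), size = c(1L, 1L), mean = 0, sd = 0),
                       class = "background_roi")
  expect_error(whole_lung_snr(img2, mask2, roi_bad), "SD")
})
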