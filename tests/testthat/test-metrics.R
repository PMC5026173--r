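test_that("cumulative dose bookkeeping reproduces the dosing protocol", {
  expect_equal(cumulative_doses(c(10, 25, 50, 75, 100, 200, 400)),
               c(10, 35, 85, 160, 260, 460, 860))
  expect_equal(cumulative_doses(c(10, 25, 50)), c(10, 35, 85))
  expect_equal(cumulative_doses(numeric(0)), numeric(0))
  expect_error(cumulative_doses(c(10, -5)), ">= 0")
})

test_that("global signal intensity is a sum ratio with the expected algebra", {
  B <- matrix(c(2, 2, 2, 4), 2, 2)
  M <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(global_signal(B, B), 1)
  expect_equal(global_signal(0.5 * B, B), 0.5)
  expect_equal(global_signal(M, B), 1)  # 10 / 10

  # multiplicativity across a chain of frames
  C <- matrix(stats::runif(4, 1, 2), 2, 2)
  expect_equal(global_signal(M, B) * global_signal(B, C), global_signal(M, C),
               tolerance = 1e-12)

  expect_error(global_signal(M, matrix(0, 2, 2)), "> 0")
})

test_that("global signal curve supports both normalization conventions", {
  mk <- function(v, role, lab, dose = 0)
    magnitude_image(matrix(v, 2, 2), label = lab, role = role,
                    cumulative_dose_ug = dose)
  # voxel sums 10, 10, 10, 10, 5
  ser <- challenge_series(list(
    mk(2.5, "baseline", "b1"), mk(2.5, "baseline", "b2"),
    mk(2.5, "fluid", "fluid"),
    mk(2.5, "dose", "d10", 10), mk(1.25, "dose", "d35", 35)))
  gs_avg <- global_signal_curve(ser, reference_mode = "averaged_reference")
  expect_equal(gs_avg$gs, c(1, 1, 1, 1, 0.5))
  expect_equal(attr(gs_avg, "reference_frames"), 1:4)
  gs_first <- global_signal_curve(ser)
  expect_equal(gs_first$gs, c(1, 1, 1, 1, 0.5))
})

test_that("noise-free OVA series has strictly decreasing GS across doses", {
  sp <- ova_phantom_spec(seed = 8, noise_sd = 0,
                         grid_shape = c(64L, 32L), fov = c(23.65, 15.75))
  ser <- generate_challenge_series(sp)
  gs <- global_signal_curve(ser)
  dose_gs <- gs$gs[gs$role == "dose"]
  expect_true(all(diff(dose_gs) < 0))
})

test_that("absolute difference map is a plain antisymmetric subtraction", {
  M <- matrix(c(3, 1), 1, 2); B <- matrix(c(1, 2), 1, 2)
  expect_equal(absolute_difference_map(M, B), matrix(c(2, -1), 1, 2))
  expect_equal(absolute_difference_map(M, M), matrix(0, 1, 2))
  expect_equal(absolute_difference_map(M, B), -absolute_difference_map(B, M))

  set.seed(1)
  M2 <- matrix(stats::runif(64), 8, 8); B2 <- matrix(stats::runif(64), 8, 8)
  expect_equal(sum(absolute_difference_map(M2, B2)), sum(M2) - sum(B2),
               tolerance = 1e-12)
})

test_that("relative difference map measures share redistribution in percent", {
  M <- matrix(c(2, 2, 4, 4), 1, 4)
  B <- matrix(1, 1, 4)
  dr <- relative_difference_map(M, B, gs = 3)
  expect_equal(as.vector(dr), c(-100 / 9, -100 / 9, 100 / 9, 100 / 9),
               tolerance = 1e-9)
  expect_equal(dr, brute_force_relative_diff(M, B, 3), tolerance = 1e-12)

  # proportional images have identical shares
  expect_true(all(relative_difference_map(3.7 * B, B) == 0))

  # scaling law: c * M multiplies the map by 1/c (shares unchanged, GS scales)
  set.seed(2)
  M2 <- matrix(stats::runif(36, 1, 2), 6, 6)
  B2 <- matrix(stats::runif(36, 1, 2), 6, 6)
  d1 <- relative_difference_map(M2, B2)
  d4 <- relative_difference_map(4 * M2, B2)
  expect_equal(d4, d1 / 4, tolerance = 1e-10)

  # zero mean over the full domain, by construction
  expect_lt(abs(mean(d1)), 1e-10)
})

test_that("difference summaries use the population SD", {
  dR <- matrix(c(-10, 10), 1, 2)
  dA <- matrix(c(2, -1), 1, 2)
  res <- summarize_difference(dA, dR)
  expect_equal(res$sigma_RID, 10)

  dA3 <- matrix(c(2, -1, -1, 0), 2, 2)
  mask3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  res3 <- summarize_difference(dA3, dA3, mask3)
  expect_equal(res3$mean_difference, 0)
  expect_equal(res3$n_voxels, 3L)

  const <- matrix(5, 3, 3)
  expect_equal(summarize_difference(const, const)$sigma_RID, 0)

  expect_error(summarize_difference(dA, dR, matrix(FALSE, 1, 2)), "empty")
})

test_that("noise consistency flags fluctuations of 20% or more", {
  mk_roi <- function(m) structure(list(origin = c(1L, 1L), size = c(10L, 10L),
                                       mean = m, sd = 1),
                                  class = "background_roi")
  mk_img <- function(lab) magnitude_image(matrix(1, 16, 16), label = lab,
                                          role = "baseline")
  ser <- challenge_series(list(mk_img("a"), mk_img("b"), mk_img("c")))

  rep0 <- noise_consistency(ser, rois = lapply(c(10, 10, 10), mk_roi))
  expect_equal(rep0$fluctuation, 0)
  expect_false(rep0$flagged)

  rep1 <- noise_consistency(ser, rois = lapply(c(10, 11, 12.5), mk_roi))
  expect_equal(rep1$fluctuation, 0.25)
  expect_true(rep1$flagged)

  ser2 <- challenge_series(list(mk_img("a"), mk_img("b")))
  rep2 <- noise_consistency(ser2, rois = lapply(c(10, 11.9), mk_roi))
  expect_equal(rep2$fluctuation, 0.19)
  expect_false(rep2$flagged)

  expect_error(noise_consistency(ser2, rois = lapply(c(0, 1), mk_roi)), "> 0")
})

test_that("regional summaries agree with the global ones and order defects", {
  # phantom with one deep programmed defect region
  sp <- small_spec(seed = 11, heterogeneity = 0, noise_sd = 0)
  ph <- make_phantom(sp)
  ph$region_params$emax <- rep(0.05, nrow(ph$region_params))
  ph$region_params$ec50 <- rep(100, nrow(ph$region_params))
  ph$region_params$hill <- rep(2, nrow(ph$region_params))
  defect_region <- which.max(tabulate(ph$region_labels[ph$region_labels > 0]))
  ph$region_params$emax[defect_region] <- 0.9

  B <- sim_frame(ph, 0, noise_sd = 0, seed = 1)
  M <- sim_frame(ph, 400, noise_sd = 0, seed = 2)
  dA <- absolute_difference_map(M, B)
  dR <- relative_difference_map(M, B)
  res <- summarize_difference(dA, dR)

  # box inside the defect vs a box inside a spared region
  centroid_box <- function(region) {
    idx <- which(ph$region_labels == region, arr.ind = TRUE)
    c(row = round(mean(idx[, 1])) - 1, col = round(mean(idx[, 2])) - 1,
      height = 3, width = 3)
  }
  spared <- which(ph$region_params$emax == 0.05)[1]
  tab <- regional_summary(res, list(centroid_box(defect_region),
                                    centroid_box(spared)))
  expect_lt(tab$mean_dA[1], tab$mean_dA[2])

  # a full-image box reproduces the whole-domain mean
  full <- regional_summary(res, data.frame(row = 1, col = 1,
                                           height = nrow(dA), width = ncol(dA)))
  expect_equal(full$mean_dA, res$mean_difference, tolerance = 1e-12)

  # a box covering a constant region has zero spread
  flat <- summarize_difference(matrix(2, 4, 4), matrix(-1, 4, 4))
  const_box <- regional_summary(flat, data.frame(row = 1, col = 1,
                                                 height = 4, width = 4))
  expect_equal(const_box$sd_dA, 0)
  expect_equal(const_box$sd_dR, 0)

  expect_error(regional_summary(res, data.frame(row = 1, col = 1,
                                                height = 1000, width = 2)),
               "out of bounds")
})

test_that("defect masks mark voxels at or below the negative cut", {
  expect_false(any(defect_mask(matrix(0, 3, 3), 1)))
  m <- defect_mask(matrix(c(-5, -1, 3), 1, 3), 2)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))
  m2 <- defect_mask(matrix(c(-2, NA), 1, 2), 2)
  expect_identical(as.vector(m2), c(TRUE, FALSE))
})

test_that("NA voxels are excluded from sums and counted", {
  M <- matrix(c(1, 2, NA, 4), 2, 2)
  B <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(global_signal(M, B), 7 / 3)
  dA <- absolute_difference_map(M, B)
  expect_true(is.na(dA[1, 2]))
  res <- summarize_difference(dA, dA)
  expect_equal(res$n_voxels, 3L)
  expect_equal(res$n_excluded, 1L)
})
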