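#' Cumulative dose bookkeeping
#'
#' Running sums of per-step methacholine dose increments. The standard
#' protocol 10, 25, 50, 75, 100, 200, 400 ug yields cumulative doses
#' 10, 35, 85, 160, 260, 460, 860 ug.
#'
#' @param increments per-step dose increments in ug (all >= 0).
#' @return Cumulative doses, same length as `increments`.
#' @export
cumulative_doses <- function(increments) {
  .assert(is.numeric(increments), "increments must be numeric")
  .assert(all(increments >= 0), "dose increments must be >= 0")
  cumsum(increments)
}

# Resolve the voxel domain shared by two frames: non-NA in both, optionally
# restricted to a mask.
common_domain <- function(M, B, domain = c("whole_image", "mask"), mask = NULL) {
  domain <- match.arg(domain)
  .assert(all(dim(M) == dim(B)), "image shapes must match")
  ok <- !is.na(M) & !is.na(B)
  if (domain == "mask") {
    .assert(!is.null(mask), "domain = 'mask' requires a mask")
    m <- if (inherits(mask, "lung_mask")) mask$mask else mask
    .assert(is.logical(m) && all(dim(m) == dim(M)), "mask shape must match the images")
    ok <- ok & m
  }
  ok
}

#' Normalized global signal intensity
#'
#' The ratio of the voxel-value sum of a challenge image to that of the
#' baseline image, `GS = sum(M_i) / sum(B_i)`, computed by default over all
#' voxels of the image. Voxels that are `NA` in either frame are excluded
#' from both sums.
#'
#' @param M challenge-step [magnitude_image()] or matrix.
#' @param B baseline image or matrix, same shape.
#' @param domain `"whole_image"` (default) or `"mask"`.
#' @param mask logical matrix or [threshold_and_mask()] result when
#'   `domain = "mask"`.
#' @return Dimensionless GS.
#' @export
global_signal <- function(M, B, domain = c("whole_image", "mask"), mask = NULL) {
  M <- as_values(M); B <- as_values(B)
  ok <- common_domain(M, B, domain, mask)
  denom <- sum(B[ok])
  .assert(is.finite(denom) && denom > 0, "baseline voxel sum must be > 0")
  sum(M[ok]) / denom
}

#' Global signal curve across a challenge series
#'
#' Computes per-frame normalized global signal intensity against either the
#' first baseline frame (`reference_mode = "first_baseline"`) or the mean
#' voxel-sum of a designated reference set (`"averaged_reference"`). The
#' averaged-reference default is the convention used to compensate for
#' shot-to-shot polarization fluctuations: all baseline frames, any fluid
#' frame, and the first (lowest-dose) challenge frame.
#'
#' @param series a [challenge_series()].
#' @param reference_mode `"first_baseline"` or `"averaged_reference"`.
#' @param reference_frames integer frame indices overriding the default
#'   averaged-reference set.
#' @param domain,mask as in [global_signal()].
#' @return An object of class `global_signal_curve`: a data frame with
#'   columns `label`, `role`, `cumulative_dose_ug`, `gs`, plus attributes
#'   `reference_mode` and `reference_frames`.
#' @export
global_signal_curve <- function(series,
                                reference_mode = c("first_baseline", "averaged_reference"),
                                reference_frames = NULL,
                                domain = c("whole_image", "mask"), mask = NULL) {
  .assert(inherits(series, "challenge_series"), "series must be a challenge_series")
  reference_mode <- match.arg(reference_mode)
  domain <- match.arg(domain)
  sums <- vapply(series$frames, function(f) {
    v <- f$values
    ok <- common_domain(v, v, domain, mask)
    sum(v[ok])
  }, numeric(1))
  if (reference_mode == "first_baseline") {
    ref_idx <- which(series$role == "baseline")[1]
  } else if (is.null(reference_frames)) {
    first_dose <- which(series$role == "dose")[1]
    ref_idx <- c(which(series$role %in% c("baseline", "fluid")),
                 if (!is.na(first_dose)) first_dose)
  } else {
    ref_idx <- as.integer(reference_frames)
    .assert(all(ref_idx >= 1L & ref_idx <= length(series$frames)),
            "reference_frames out of range")
  }
  .assert(length(ref_idx) >= 1L && !anyNA(ref_idx), "designated reference frames missing")
  ref <- mean(sums[ref_idx])
  .assert(is.finite(ref) && ref > 0, "reference voxel sum must be > 0")
  out <- data.frame(
    label = vapply(series$frames, function(f) f$label %||% "", character(1)),
    role = series$role,
    cumulative_dose_ug = series$cumulative_dose_ug,
    gs = sums / ref,
    stringsAsFactors = FALSE)
  structure(out, reference_mode = reference_mode, reference_frames = ref_idx,
            class = c("global_signal_curve", "data.frame"))
}

#' Absolute intensity difference map
#'
#' Voxel-wise `M - B`. For reversal frames the convention is to subtract
#' the final-dose (maximum cumulative dose) image from the reversal image,
#' i.e. pass that frame as `B`.
#'
#' @param M challenge (or reversal) image or matrix.
#' @param B baseline (or final-dose) image or matrix, same shape.
#' @return 2D difference map in signal units (`NA` where either input is `NA`).
#' @export
absolute_difference_map <- function(M, B) {
  M <- as_values(M); B <- as_values(B)
  .assert(all(dim(M) == dim(B)), "image shapes must match")
  M - B
}

#' Relative intensity difference map
#'
#' Voxel-wise difference of mean-normalized signal shares, scaled by the
#' normalized global signal intensity:
#' `dR_i = (M_i / mean(M) - B_i / mean(B)) * 100% / GS`,
#' with the means taken over the `k` voxels of the chosen domain. The map
#' captures redistribution of inhaled gas independent of the global signal
#' loss; values below -100% are possible when baseline voxels exceed the
#' baseline mean. Its mean over the full domain is exactly zero.
#'
#' @param M,B images or matrices, same shape.
#' @param gs normalized global signal intensity; computed from the same
#'   domain via [global_signal()] when `NULL`.
#' @param domain,mask as in [global_signal()].
#' @return 2D map in percent.
#' @export
relative_difference_map <- function(M, B, gs = NULL,
                                    domain = c("whole_image", "mask"), mask = NULL) {
  M <- as_values(M); B <- as_values(B)
  domain <- match.arg(domain)
  ok <- common_domain(M, B, domain, mask)
  mM <- mean(M[ok]); mB <- mean(B[ok])
  .assert(is.finite(mM) && mM > 0 && is.finite(mB) && mB > 0,
          "voxel means must be > 0")
  if (is.null(gs)) gs <- global_signal(M, B, domain = domain, mask = mask)
  .assert(is.finite(gs) && gs > 0, "gs must be > 0")
  out <- (M / mM - B / mB) * 100 / gs
  out[!ok] <- NA_real_
  out
}

#' Summarize a pair of difference maps
#'
#' Scalar descriptors of a challenge step: the mean absolute intensity
#' difference over the analysis mask and the heterogeneity index sigma_RID,
#' the population (n-divisor) standard deviation of the relative intensity
#' difference map over the mask.
#'
#' @param delta_A absolute difference map (signal units).
#' @param delta_R relative difference map (percent).
#' @param analysis_mask logical matrix (default: all voxels); voxels `NA`
#'   in either map are excluded and counted.
#' @return An object of class `difference_result` with fields `delta_A`,
#'   `delta_R`, `analysis_mask`, `mean_difference`, `sigma_RID`, `n_voxels`
#'   and `n_excluded`.
#' @export
summarize_difference <- function(delta_A, delta_R, analysis_mask = NULL) {
  .assert(all(dim(delta_A) == dim(delta_R)), "map shapes must match")
  if (is.null(analysis_mask)) analysis_mask <- array(TRUE, dim(delta_A))
  m <- if (inherits(analysis_mask, "lung_mask")) analysis_mask$mask else analysis_mask
  .assert(is.logical(m) && all(dim(m) == dim(delta_A)),
          "analysis_mask shape must match the maps")
  ok <- m & !is.na(delta_A) & !is.na(delta_R)
  .assert(sum(ok) > 0L, "analysis mask is empty")
  structure(list(delta_A = delta_A, delta_R = delta_R, analysis_mask = m,
                 mean_difference = mean(delta_A[ok]),
                 sigma_RID = pop_sd(delta_R[ok]),
                 n_voxels = sum(ok), n_excluded = sum(m) - sum(ok)),
            class = "difference_result")
}

#' Monitor background-noise consistency across a series
#'
#' Global signal curves are only meaningful if the background noise level
#' is stable across the challenge sequence. This report compares per-frame
#' background ROI means against the first frame:
#' `fluctuation = max |mean_f - mean_1| / mean_1`, flagged when it reaches
#' 20%.
#'
#' @param series a [challenge_series()].
#' @param rois list of [background_roi_at()] / [select_background_roi()]
#'   results, one per frame; computed with seeds derived from `seed` when
#'   omitted.
#' @param seed master seed for automatic per-frame ROI selection.
#' @param tol flag threshold on the fluctuation (default 0.2).
#' @return A list with `per_frame` (data frame of label and noise mean),
#'   `fluctuation`, and logical `flagged`.
#' @export
noise_consistency <- function(series, rois = NULL, seed = 1L, tol = 0.2) {
  .assert(inherits(series, "challenge_series"), "series must be a challenge_series")
  n <- length(series$frames)
  if (is.null(rois)) {
    seeds <- derive_seeds(seed, n)
    rois <- lapply(seq_len(n), function(i)
      select_background_roi(series$frames[[i]], seed = seeds[i]))
  }
  .assert(length(rois) == n, "one background ROI per frame is required")
  means <- vapply(rois, function(r) r$mean, numeric(1))
  .assert(is.finite(means[1]) && means[1] >= 0, "reference noise mean must be finite")
  if (means[1] == 0) {
    # noise-free frames: consistent iff every frame is also noise-free
    .assert(all(means == 0), "reference noise mean must be > 0")
    fluct <- 0
  } else {
    fluct <- max(abs(means - means[1]) / means[1])
  }
  list(per_frame = data.frame(
         label = vapply(series$frames, function(f) f$label %||% "", character(1)),
         noise_mean = means, stringsAsFactors = FALSE),
       fluctuation = fluct,
       flagged = fluct >= tol)
}

#' Regional summaries of difference maps
#'
#' Per-box mean and (population) SD of the absolute and relative intensity
#' difference maps over rectangular regions of interest, supporting e.g.
#' apical-versus-basal comparisons of regional lung response.
#'
#' @param result a [summarize_difference()] result.
#' @param boxes data frame (or list of length-4 vectors) with columns
#'   `row`, `col`, `height`, `width` giving top-left corner and size.
#' @return Data frame with one row per box: bounds, voxel count, and
#'   mean/SD of `delta_A` and `delta_R`.
#' @export
regional_summary <- function(result, boxes) {
  .assert(inherits(result, "difference_result"), "result must be a difference_result")
  if (is.list(boxes) && !is.data.frame(boxes))
    boxes <- as.data.frame(do.call(rbind, boxes)) |>
      stats::setNames(c("row", "col", "height", "width"))
  .assert(all(c("row", "col", "height", "width") %in% names(boxes)),
          "boxes must have columns row, col, height, width")
  nr <- nrow(result$delta_A); nc <- ncol(result$delta_A)
  out <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    .assert(b$height >= 1 && b$width >= 1, "box must be nonempty")
    .assert(b$row >= 1 && b$col >= 1 && b$row + b$height - 1 <= nr &&
              b$col + b$width - 1 <= nc, "box out of bounds")
    ri <- b$row + seq_len(b$height) - 1L
    ci <- b$col + seq_len(b$width) - 1L
    dA <- result$delta_A[ri, ci]; dR <- result$delta_R[ri, ci]
    data.frame(box = i, row = b$row, col = b$col, height = b$height,
               width = b$width, n = sum(!is.na(dA)),
               mean_dA = mean(dA, na.rm = TRUE), sd_dA = pop_sd(dA),
               mean_dR = mean(dR, na.rm = TRUE), sd_dR = pop_sd(dR))
  })
  do.call(rbind, out)
}

#' Threshold a difference map into a ventilation-defect mask
#'
#' Marks voxels whose signal change falls at or below `-cut`, flagging
#' regions of reduced gas entry before they become visually apparent on
#' the spin-density images.
#'
#' @param delta a difference map (signal units for `delta_A`, percent for
#'   `delta_R`).
#' @param cut positive defect depth in the map's units.
#' @return Logical matrix (`NA` voxels are `FALSE`).
#' @export
defect_mask <- function(delta, cut) {
  .assert(is.numeric(cut) && length(cut) == 1L, "cut must be a single number")
  (!is.na(delta)) & (delta <= -cut)
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf("<difference_result> %d voxels: mean difference %.4g, sigma_RID %.4g%%\n",
              x$n_voxels, x$mean_difference, x$sigma_RID))
  invisible(x)
}
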