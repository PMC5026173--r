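#' Select a background noise ROI outside the lung
#'
#' Emulates the operator's random placement of a 10 x 10 voxel noise region
#' "far removed from the lung": a provisional foreground estimate (Otsu's
#' bimodal threshold on the image histogram, or an explicit `fg_cut`) marks
#' candidate lung voxels, and the ROI is drawn uniformly (seeded) among all
#' positions whose voxels are all at or below that cut and at least
#' `margin` voxels away from any provisional-foreground voxel (keeping the
#' region clear of point-spread-function tails at the lung boundary). The
#' ROI's mean and (sample) standard deviation are recorded.
#'
#' @param image a [magnitude_image()] (or matrix) at least `size` big.
#' @param seed RNG seed for the placement draw.
#' @param size ROI size in voxels (default `c(10, 10)`).
#' @param fg_cut optional explicit signal cut overriding the Otsu estimate;
#'   voxels strictly above it are provisional foreground.
#' @param margin exclusion margin (voxels, Chebyshev) around the
#'   provisional foreground.
#' @return An object of class `background_roi` with fields `origin`
#'   (top-left voxel index), `size`, `mean` and `sd`.
#' @export
select_background_roi <- function(image, seed = NULL, size = c(10L, 10L),
                                  fg_cut = NULL, margin = 5L) {
  vals <- as_values(image)
  size <- as.integer(size)
  nr <- nrow(vals); nc <- ncol(vals)
  .assert(nr >= size[1] && nc >= size[2],
          sprintf("image must be at least %dx%d", size[1], size[2]))
  cut <- if (is.null(fg_cut)) otsu_threshold(vals) else fg_cut
  fg <- (!is.na(vals)) & (vals > cut)
  if (margin > 0L && any(fg)) fg <- dilate_box(fg, margin)
  below <- !fg & !is.na(vals)
  # integral image of `below`: candidate origins are blocks entirely clear
  s <- apply(below, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[-1L, -1L] <- s
  oi <- seq_len(nr - size[1] + 1L)
  oj <- seq_len(nc - size[2] + 1L)
  blocksum <- pad[oi + size[1], oj + size[2], drop = FALSE] -
    pad[oi, oj + size[2], drop = FALSE] -
    pad[oi + size[1], oj, drop = FALSE] + pad[oi, oj, drop = FALSE]
  cand <- which(blocksum == prod(size), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop("no background region found: image is saturated with signal", call. = FALSE)
  pick <- cand[with_seed(seed, sample.int(nrow(cand), 1L)), ]
  block <- vals[pick[1] + seq_len(size[1]) - 1L, pick[2] + seq_len(size[2]) - 1L]
  structure(list(origin = as.integer(pick), size = size,
                 mean = mean(block, na.rm = TRUE),
                 sd = stats::sd(as.vector(block), na.rm = TRUE)),
            class = "background_roi")
}

# Box dilation of a logical mask by `m` voxels (Chebyshev ball), via the
# integral-image trick.
dilate_box <- function(mask, m) {
  nr <- nrow(mask); nc <- ncol(mask)
  s <- apply(mask, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[-1L, -1L] <- s
  i1 <- pmax(0L, seq_len(nr) - m - 1L); i2 <- pmin(nr, seq_len(nr) + m)
  j1 <- pmax(0L, seq_len(nc) - m - 1L); j2 <- pmin(nc, seq_len(nc) + m)
  tot <- pad[i2 + 1L, j2 + 1L] - pad[i1 + 1L, j2 + 1L] -
    pad[i2 + 1L, j1 + 1L] + pad[i1 + 1L, j1 + 1L]
  tot > 0
}

# Otsu's threshold on a 256-bin histogram: the cut maximizing between-class
# variance. Constant images return their maximum so every position counts as
# background.
otsu_threshold <- function(vals, n_bins = 256L) {
  v <- vals[!is.na(vals)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[2])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  h$mids[which.max(sigma_b2)]
}

#' Construct a background ROI at a fixed position
#'
#' For workflows where the noise region is chosen by hand (or must match a
#' previous analysis) rather than drawn at random.
#'
#' @param image a [magnitude_image()] or matrix.
#' @param origin top-left voxel index pair.
#' @param size ROI size in voxels.
#' @return A `background_roi`.
#' @export
background_roi_at <- function(image, origin, size = c(10L, 10L)) {
  vals <- as_values(image)
  origin <- as.integer(origin); size <- as.integer(size)
  .assert(all(origin >= 1L) && origin[1] + size[1] - 1L <= nrow(vals) &&
            origin[2] + size[2] - 1L <= ncol(vals),
          "ROI must lie fully inside the image")
  block <- vals[origin[1] + seq_len(size[1]) - 1L,
                origin[2] + seq_len(size[2]) - 1L]
  structure(list(origin = origin, size = size,
                 mean = mean(block, na.rm = TRUE),
                 sd = stats::sd(as.vector(block), na.rm = TRUE)),
            class = "background_roi")
}

#' Threshold an image into a lung mask
#'
#' The lower threshold is the background ROI mean plus three times its
#' standard deviation; a voxel is lung when its value is greater than or
#' equal to the threshold (inclusive comparison for deterministic boundary
#' behaviour). `NA` voxels are excluded from the mask.
#'
#' @param image a [magnitude_image()] or matrix.
#' @param roi a [select_background_roi()] result.
#' @return An object of class `lung_mask` with fields `mask`,
#'   `threshold_value` and `n_voxels`.
#' @export
threshold_and_mask <- function(image, roi) {
  vals <- as_values(image)
  .assert(inherits(roi, "background_roi"), "roi must be a background_roi")
  thr <- roi$mean + 3 * roi$sd
  mask <- (!is.na(vals)) & (vals >= thr)
  structure(list(mask = mask, threshold_value = thr, n_voxels = sum(mask)),
            class = "lung_mask")
}

#' Whole-lung signal-to-noise ratio
#'
#' Mean in-mask voxel value divided by the background ROI standard
#' deviation. No Rician bias correction is applied to the background SD.
#'
#' @param image a [magnitude_image()] or matrix.
#' @param mask a [threshold_and_mask()] result (or logical matrix).
#' @param roi the background ROI whose SD estimates the noise level.
#' @return Dimensionless SNR.
#' @export
whole_lung_snr <- function(image, mask, roi) {
  vals <- as_values(image)
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  .assert(is.logical(m) && all(dim(m) == dim(vals)),
          "mask must be a logical matrix matching the image")
  .assert(sum(m, na.rm = TRUE) > 0L, "mask is empty")
  .assert(inherits(roi, "background_roi"), "roi must be a background_roi")
  .assert(is.finite(roi$sd) && roi$sd > 0, "background ROI SD must be > 0")
  mean(vals[m], na.rm = TRUE) / roi$sd
}

#' @export
print.background_roi <- function(x, ...) {
  cat(sprintf("<background_roi> %dx%d at (%d, %d): mean %.4g, sd %.4g\n",
              x$size[1], x$size[2], x$origin[1], x$origin[2], x$mean, x$sd))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d voxels at threshold %.4g\n",
              x$n_voxels, x$threshold_value))
  invisible(x)
}
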