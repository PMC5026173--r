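#' Construct a magnitude image
#'
#' Lightweight container for a reconstructed (or externally supplied)
#' nonnegative 2D voxel array with its in-plane voxel size and challenge
#' annotations.
#'
#' @param values nonnegative 2D numeric array (`NA` allowed and excluded
#'   from downstream sums).
#' @param voxel_mm in-plane voxel size (read, phase) in mm.
#' @param slice_thickness_mm slice thickness in mm or `NULL`.
#' @param label free-text step identifier.
#' @param cumulative_dose_ug cumulative MCh dose in ug or `NULL`.
#' @param role one of `"baseline"`, `"fluid"`, `"dose"`, `"reversal"` or `NULL`.
#' @return An object of class `magnitude_image`.
#' @export
magnitude_image <- function(values, voxel_mm = c(NA_real_, NA_real_),
                            slice_thickness_mm = NULL, label = NULL,
                            cumulative_dose_ug = NULL, role = NULL) {
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  .assert(all(values >= 0, na.rm = TRUE), "magnitude values must be >= 0")
  if (!is.null(role))
    .assert(role %in% c("baseline", "fluid", "dose", "reversal"),
            "role must be baseline/fluid/dose/reversal")
  structure(list(values = values, voxel_mm = as.numeric(voxel_mm),
                 slice_thickness_mm = slice_thickness_mm, label = label,
                 cumulative_dose_ug = cumulative_dose_ug, role = role),
            class = "magnitude_image")
}

#' Sine-bell squared apodization window
#'
#' Sample-centered discretization `w[n] = sin^2(pi * (n + 1/2) / N)` for
#' `n = 0..N-1`: symmetric (`w[n] = w[N-1-n]`), maximal at the matrix
#' center and approaching zero at the edges without exact zeros at the
#' edge samples.
#'
#' @param n window length.
#' @return Numeric weight vector of length `n`.
#' @export
sine_bell_squared_window <- function(n) {
  .assert(is.numeric(n) && length(n) == 1L && n >= 1, "n must be a single integer >= 1")
  n <- as.integer(n)
  sin(pi * (seq_len(n) - 0.5) / n)^2
}

#' Apply sine-bell squared apodization to a k-space frame
#'
#' Multiplies the DC-centered raw data by the separable window
#' `w[a] * w[b]` before Fourier reconstruction. The input frame is not
#' modified; a new frame is returned.
#'
#' @param kspace a [simulate_acquisition()] frame (or any `kspace_frame`).
#' @return A new `kspace_frame` with apodized data.
#' @export
sine_bell_squared <- function(kspace) {
  .assert(inherits(kspace, "kspace_frame"), "kspace must be a kspace_frame")
  .assert(length(kspace$data) > 0, "k-space data must be nonempty")
  w <- outer(sine_bell_squared_window(nrow(kspace$data)),
             sine_bell_squared_window(ncol(kspace$data)))
  out <- kspace
  out$data <- kspace$data * w
  out
}

# Complex image-space reconstruction (pre-magnitude); used internally and
# for linearity checks.
reconstruct_complex <- function(kspace, apodize = TRUE) {
  .assert(inherits(kspace, "kspace_frame"), "kspace must be a kspace_frame")
  .assert(all(dim(kspace$data) == kspace$config$matrix),
          "k-space data shape must equal config$matrix")
  if (apodize) kspace <- sine_bell_squared(kspace)
  inverse_ft(kspace$data)
}

#' Reconstruct a magnitude image from k-space
#'
#' Optionally applies the sine-bell squared window to the raw data, then
#' takes the magnitude of the centered 2D inverse discrete Fourier
#' transform. K-space is stored DC-centered and shifted before/after the
#' transform so images are not quadrant-swapped. No zero-filling is applied;
#' the image keeps the acquisition matrix size. Voxel size is derived from
#' the acquisition geometry (`fov / matrix` per axis).
#'
#' @param kspace a `kspace_frame`.
#' @param apodize apply the sine-bell squared window first (default `TRUE`).
#' @return A [magnitude_image()] carrying the frame's label, role and
#'   cumulative dose.
#' @export
reconstruct <- function(kspace, apodize = TRUE) {
  img <- Mod(reconstruct_complex(kspace, apodize = apodize))
  magnitude_image(img, voxel_mm = kspace$config$voxel_mm,
                  slice_thickness_mm = kspace$config$slice_thickness_mm,
                  label = kspace$label,
                  cumulative_dose_ug = kspace$cumulative_dose_ug,
                  role = kspace$role)
}

#' @export
print.magnitude_image <- function(x, ...) {
  cat(sprintf("<magnitude_image> %dx%d, voxel %.2f x %.2f mm%s%s\n",
              nrow(x$values), ncol(x$values), x$voxel_mm[1], x$voxel_mm[2],
              if (!is.null(x$label)) paste0(", '", x$label, "'") else "",
              if (!is.null(x$cumulative_dose_ug))
                sprintf(" (%g ug)", x$cumulative_dose_ug) else ""))
  invisible(x)
}
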