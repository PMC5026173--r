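#' Write a magnitude image to NIfTI
#'
#' Voxel dimensions are taken from the image's in-plane voxel size (and
#' slice thickness when present).
#'
#' @param image a [magnitude_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_magnitude_nifti <- function(image, path) {
  .assert(inherits(image, "magnitude_image"), "image must be a magnitude_image")
  nii <- RNifti::asNifti(image$values)
  vx <- ifelse(is.na(image$voxel_mm), 1, image$voxel_mm)
  RNifti::pixdim(nii) <- vx
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a lung mask to NIfTI (uint8)
#'
#' @param mask a [threshold_and_mask()] result or logical matrix.
#' @param path output path.
#' @param voxel_mm in-plane voxel size in mm.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path, voxel_mm = c(1, 1)) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  .assert(is.logical(m) && is.matrix(m), "mask must be a logical matrix")
  nii <- RNifti::asNifti(matrix(as.integer(m), nrow(m), ncol(m)))
  RNifti::pixdim(nii) <- voxel_mm
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}

#' Read a challenge series from NIfTI files and a metadata table
#'
#' The metadata CSV must have columns `path`, `label`, `role` and
#' `dose_increment_ug`; cumulative doses are the running sums over the
#' dose frames. Relative paths are resolved against the CSV's directory.
#'
#' @param metadata_csv path to the metadata table.
#' @return A [challenge_series()].
#' @export
read_image_series <- function(metadata_csv) {
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  .assert(all(c("path", "label", "role", "dose_increment_ug") %in% names(meta)),
          "metadata needs columns path, label, role, dose_increment_ug")
  base <- dirname(metadata_csv)
  cum <- 0
  frames <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    nii <- RNifti::readNifti(p)
    vals <- as.matrix(drop(as.array(nii)))
    pd <- RNifti::pixdim(nii)
    if (meta$role[i] == "dose") cum <- cum + meta$dose_increment_ug[i]
    frames[[i]] <- magnitude_image(vals, voxel_mm = pd[1:2],
                                   label = meta$label[i],
                                   cumulative_dose_ug = if (meta$role[i] %in% c("dose", "reversal")) cum else 0,
                                   role = meta$role[i])
  }
  challenge_series(frames, dose_increments_ug = meta$dose_increment_ug)
}

#' Write or read a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `write_phantom_spec` the path invisibly; `read_phantom_spec`
#'   a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(phantom_spec, x)
}

#' Write the ground-truth region parameter table
#'
#' @param phantom a [make_phantom()] result.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_region_params <- function(phantom, path) {
  .assert(inherits(phantom, "ventilation_phantom"),
          "phantom must be a ventilation_phantom")
  utils::write.csv(phantom$region_params, path, row.names = FALSE)
  invisible(path)
}

# Signed difference maps go out as float NIfTI.
write_map_nifti <- function(map, path, voxel_mm = c(1, 1)) {
  nii <- RNifti::asNifti(map)
  RNifti::pixdim(nii) <- voxel_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# Render a signed map to PNG with a diverging colormap, symmetric about 0.
# palette "blue_red": negative blue, positive red (absolute differences);
# palette "magenta_green": negative magenta, positive green (relative
# differences), matching the map display conventions.
render_map_png <- function(map, path, palette = c("blue_red", "magenta_green"),
                           limit = NULL) {
  palette <- match.arg(palette)
  if (is.null(limit)) limit <- max(abs(map), na.rm = TRUE)
  if (!is.finite(limit) || limit == 0) limit <- 1
  x <- pmin(1, pmax(-1, map / limit))
  x[is.na(x)] <- 0
  ends <- switch(palette,
                 blue_red = c("#2166AC", "#B2182B"),
                 magenta_green = c("#C51B8A", "#1B7837"))
  ramp <- grDevices::colorRamp(c(ends[1], "#FFFFFF", ends[2]))
  rgb <- ramp((as.vector(x) + 1) / 2) / 255
  img <- array(0, dim = c(nrow(map), ncol(map), 3L))
  img[, , 1] <- matrix(rgb[, 1], nrow(map)); img[, , 2] <- matrix(rgb[, 2], nrow(map))
  img[, , 3] <- matrix(rgb[, 3], nrow(map))
  png::writePNG(img, path)
  invisible(path)
}
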