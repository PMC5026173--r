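#' Configure an end-to-end analysis run
#'
#' Exactly one input mode must be supplied: `spec` (simulate a challenge
#' series from a phantom specification), `kspace` (a list of
#' `kspace_frame` objects or the path to an RDS file holding one), or
#' `images` (path to a NIfTI metadata CSV, see [read_image_series()]).
#'
#' @param spec a [phantom_spec()] for simulation mode.
#' @param kspace k-space frames (list or RDS path).
#' @param images metadata CSV path for magnitude-image mode.
#' @param dose_schedule per-step dose increments (simulation mode).
#' @param n_baseline baseline frames to simulate.
#' @param include_fluid,reversal,reversal_restore simulation options, see
#'   [generate_challenge_series()].
#' @param reference_mode global-signal normalization, see
#'   [global_signal_curve()].
#' @param map_domain analysis mask for difference-map summaries:
#'   `"lung_union"` (union of baseline and current lung masks; default,
#'   since background voxels would dilute the heterogeneity statistics) or
#'   `"whole_image"`.
#' @param apodize reconstruct with the sine-bell squared window.
#' @param seed master seed for simulation noise.
#' @param roi_seed master seed for background-ROI placement.
#' @param strict treat a >= 20% noise fluctuation as an error instead of a
#'   warning.
#' @param out_dir output directory (`NULL`: nothing is written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = NULL, kspace = NULL, images = NULL,
                       dose_schedule = c(10, 25, 50, 75, 100, 200, 400),
                       n_baseline = 2L, include_fluid = FALSE,
                       reversal = FALSE, reversal_restore = 0.5,
                       reference_mode = c("first_baseline", "averaged_reference"),
                       map_domain = c("lung_union", "whole_image"),
                       apodize = TRUE, seed = 1L, roi_seed = 1L,
                       strict = FALSE, out_dir = NULL) {
  reference_mode <- match.arg(reference_mode)
  map_domain <- match.arg(map_domain)
  n_modes <- sum(!is.null(spec), !is.null(kspace), !is.null(images))
  .assert(n_modes == 1L, "exactly one of spec, kspace, images must be given")
  mode <- if (!is.null(spec)) "simulate" else if (!is.null(kspace)) "kspace" else "images"
  if (mode == "simulate")
    .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  structure(list(mode = mode, spec = spec, kspace = kspace, images = images,
                 dose_schedule = dose_schedule, n_baseline = as.integer(n_baseline),
                 include_fluid = include_fluid, reversal = reversal,
                 reversal_restore = reversal_restore,
                 reference_mode = reference_mode, map_domain = map_domain,
                 apodize = apodize, seed = as.integer(seed),
                 roi_seed = as.integer(roi_seed), strict = strict,
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s | %s] %s", name, label, conditionMessage(e)), call. = FALSE))
}

#' Run the full challenge-imaging analysis pipeline
#'
#' Simulates or ingests a challenge series, segments every frame
#' (background ROI, mean + 3 SD threshold, whole-lung SNR), computes the
#' global signal curve, per-step absolute and relative intensity
#' difference maps with mean-difference and sigma_RID summaries, and a
#' noise-consistency report. Difference maps use the first baseline frame
#' as the subtraction reference; a reversal frame is compared against the
#' final (maximum cumulative dose) frame instead. When `out_dir` is set,
#' per-frame images and masks (NIfTI), difference maps (NIfTI + PNG), the
#' metrics tables (CSV) and a machine-readable YAML run manifest are
#' written. No inter-frame registration is performed; a warning is emitted
#' when the background noise fluctuates by 20% or more (an error under
#' `strict`).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `series`, `segmentation` (per-frame ROI,
#'   mask, SNR), `gs_curve`, `differences` (per-step `difference_result`),
#'   `metrics` (per-frame summary table), `noise` and `manifest`.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")

  series <- switch(config$mode,
    simulate = stage("simulate", "series",
      generate_challenge_series(config$spec, dose_schedule = config$dose_schedule,
                                n_baseline = config$n_baseline,
                                seed = config$seed,
                                include_fluid = config$include_fluid,
                                reversal = config$reversal,
                                reversal_restore = config$reversal_restore,
                                apodize = config$apodize)),
    kspace = stage("reconstruct", "series", {
      ks <- config$kspace
      if (is.character(ks)) ks <- readRDS(ks)
      .assert(is.list(ks) && all(vapply(ks, inherits, logical(1), "kspace_frame")),
              "kspace must be a list of kspace_frame objects")
      challenge_series(lapply(ks, reconstruct, apodize = config$apodize))
    }),
    images = stage("ingest", "series", read_image_series(config$images)))

  n <- length(series$frames)
  labels <- vapply(seq_len(n), function(i)
    series$frames[[i]]$label %||% sprintf("frame%d", i), character(1))
  # one noise-region position per series (chosen on the first frame and
  # reused), so the frame-to-frame noise comparison reflects the noise
  # level, not the placement
  roi0 <- stage("segment", labels[1],
                select_background_roi(series$frames[[1]], seed = config$roi_seed))
  seg <- lapply(seq_len(n), function(i) stage("segment", labels[i], {
    roi <- background_roi_at(series$frames[[i]], roi0$origin, roi0$size)
    mask <- threshold_and_mask(series$frames[[i]], roi)
    snr <- if (mask$n_voxels > 0 && roi$sd > 0)
      whole_lung_snr(series$frames[[i]], mask, roi) else NA_real_
    list(roi = roi, mask = mask, snr = snr)
  }))

  gs_curve <- stage("metrics", "gs_curve",
                    global_signal_curve(series, reference_mode = config$reference_mode))

  noise <- stage("metrics", "noise",
                 noise_consistency(series, rois = lapply(seg, `[[`, "roi")))
  if (noise$flagged) {
    msg <- sprintf("background noise fluctuation %.1f%% exceeds the 20%% consistency bound",
                   100 * noise$fluctuation)
    if (config$strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  base_idx <- which(series$role == "baseline")[1]
  dose_like <- which(series$role %in% c("fluid", "dose", "reversal"))
  max_dose_idx <- {
    di <- which(series$role == "dose")
    if (length(di)) di[which.max(series$cumulative_dose_ug[di])] else base_idx
  }
  differences <- lapply(dose_like, function(i) stage("maps", labels[i], {
    ref_idx <- if (series$role[i] == "reversal") max_dose_idx else base_idx
    M <- series$frames[[i]]; B <- series$frames[[ref_idx]]
    gs <- global_signal(M, B)
    dA <- absolute_difference_map(M, B)
    dR <- relative_difference_map(M, B, gs = gs)
    amask <- if (config$map_domain == "lung_union")
      seg[[i]]$mask$mask | seg[[ref_idx]]$mask$mask
    else array(TRUE, dim(dA))
    res <- summarize_difference(dA, dR, amask)
    res$label <- labels[i]
    res$reference_label <- labels[ref_idx]
    res
  }))
  names(differences) <- labels[dose_like]

  metrics <- data.frame(
    label = labels,
    role = series$role,
    cumulative_dose_ug = series$cumulative_dose_ug,
    gs = gs_curve$gs,
    snr = vapply(seg, `[[`, numeric(1), "snr"),
    noise_mean = noise$per_frame$noise_mean,
    mask_voxels = vapply(seg, function(s) s$mask$n_voxels, numeric(1)),
    mean_difference = NA_real_, sigma_RID = NA_real_,
    flagged = noise$flagged, stringsAsFactors = FALSE)
  for (nm in names(differences)) {
    j <- match(nm, metrics$label)
    metrics$mean_difference[j] <- differences[[nm]]$mean_difference
    metrics$sigma_RID[j] <- differences[[nm]]$sigma_RID
  }

  manifest <- list(
    package = "xeventmap",
    version = as.character(utils::packageVersion("xeventmap")),
    mode = config$mode,
    reference_mode = config$reference_mode,
    map_domain = config$map_domain,
    apodize = config$apodize,
    seed = config$seed, roi_seed = config$roi_seed,
    dose_schedule = config$dose_schedule,
    n_baseline = config$n_baseline,
    spec = if (config$mode == "simulate") unclass(config$spec))

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    for (d in file.path(out, c("images", "masks", "maps")))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_magnitude_nifti(series$frames[[i]],
                            file.path(out, "images", paste0(labels[i], ".nii.gz")))
      write_mask_nifti(seg[[i]]$mask,
                       file.path(out, "masks", paste0(labels[i], "_mask.nii.gz")),
                       voxel_mm = series$frames[[i]]$voxel_mm)
    }
    for (nm in names(differences)) {
      d <- differences[[nm]]
      vx <- series$frames[[base_idx]]$voxel_mm
      write_map_nifti(d$delta_A, file.path(out, "maps", paste0(nm, "_dA.nii.gz")), vx)
      write_map_nifti(d$delta_R, file.path(out, "maps", paste0(nm, "_dR.nii.gz")), vx)
      render_map_png(d$delta_A, file.path(out, "maps", paste0(nm, "_dA.png")),
                     palette = "blue_red")
      render_map_png(d$delta_R, file.path(out, "maps", paste0(nm, "_dR.png")),
                     palette = "magenta_green")
    }
    utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(gs_curve), file.path(out, "gs_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(noise$per_frame, file.path(out, "noise.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  }

  invisible(list(series = series, segmentation = seg, gs_curve = gs_curve,
                 differences = differences, metrics = metrics, noise = noise,
                 manifest = manifest))
}
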