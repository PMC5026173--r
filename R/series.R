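#' Assemble a challenge series from magnitude images
#'
#' An ordered baseline / fluid / dose / reversal image sequence with
#' per-step and cumulative methacholine dose bookkeeping. All frames must
#' share the grid shape; cumulative doses must be non-decreasing. At least
#' one baseline frame is required (two are recommended, mirroring the
#' acquisition protocol's repeated baseline imaging).
#'
#' @param frames list of [magnitude_image()] objects with `role` set.
#' @param dose_increments_ug per-frame dose increment in ug (0 for
#'   baseline/fluid/reversal frames); defaults to increments consistent
#'   with the frames' `cumulative_dose_ug` fields.
#' @return An object of class `challenge_series`.
#' @export
challenge_series <- function(frames, dose_increments_ug = NULL) {
  .assert(is.list(frames) && length(frames) >= 1L, "frames must be a nonempty list")
  .assert(all(vapply(frames, inherits, logical(1), "magnitude_image")),
          "all frames must be magnitude_image objects")
  roles <- vapply(frames, function(f) f$role %||% NA_character_, character(1))
  .assert(!anyNA(roles), "every frame must have a role")
  .assert(sum(roles == "baseline") >= 1L, "at least one baseline frame is required")
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  .assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
          "all frames must share the same grid shape")
  cum <- vapply(frames, function(f) f$cumulative_dose_ug %||% 0, numeric(1))
  dose_idx <- which(roles == "dose")
  .assert(all(diff(cum[dose_idx]) >= 0), "cumulative doses must be non-decreasing")
  if (is.null(dose_increments_ug)) {
    dose_increments_ug <- rep(0, length(frames))
    dose_increments_ug[dose_idx] <- diff(c(0, cum[dose_idx]))
  }
  .assert(length(dose_increments_ug) == length(frames),
          "dose_increments_ug must have one entry per frame")
  structure(list(frames = frames, role = roles,
                 dose_increments_ug = dose_increments_ug,
                 cumulative_dose_ug = cum),
            class = "challenge_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full methacholine challenge series
#'
#' Builds the phantom, then simulates one independently noised acquisition
#' per step: `n_baseline` baseline frames, an optional fluid
#' (Hartmann's-solution) frame, one frame per cumulative dose of the
#' schedule, and an optional reversal frame in which a configurable
#' fraction of the dose effect is restored (emulating partial
#' bronchodilator reversal; default restores half of the constriction at
#' the final cumulative dose). Per-frame noise seeds are derived
#' deterministically from `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param dose_schedule per-step MCh dose increments in ug (nonempty,
#'   nonnegative); default is the 10, 25, 50, 75, 100, 200, 400 ug protocol
#'   (cumulative maximum 860 ug).
#' @param n_baseline number of baseline frames (>= 1, default 2).
#' @param config an [acquisition_config()] matching `spec$grid_shape`.
#' @param seed master seed for the per-frame noise draws (default
#'   `spec$seed`).
#' @param include_fluid insert a fluid frame after the baselines.
#' @param reversal append a reversal frame.
#' @param reversal_restore fraction of the final-dose constriction restored
#'   on reversal, in `[0, 1]`.
#' @param apodize reconstruct with the sine-bell squared window.
#' @param keep_kspace also return the raw `kspace_frame` list.
#' @return A `challenge_series`; the generating phantom is attached as
#'   attribute `"phantom"` (ground truth for validation), and the k-space
#'   frames as attribute `"kspace"` when `keep_kspace = TRUE`.
#' @export
generate_challenge_series <- function(spec,
                                      dose_schedule = c(10, 25, 50, 75, 100, 200, 400),
                                      n_baseline = 2L,
                                      config = NULL,
                                      seed = spec$seed,
                                      include_fluid = FALSE,
                                      reversal = FALSE,
                                      reversal_restore = 0.5,
                                      apodize = TRUE,
                                      keep_kspace = FALSE) {
  .assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  .assert(length(dose_schedule) >= 1L, "dose_schedule must be nonempty")
  .assert(all(dose_schedule >= 0), "dose increments must be >= 0")
  .assert(n_baseline >= 1L, "n_baseline must be >= 1")
  .assert(reversal_restore >= 0 && reversal_restore <= 1,
          "reversal_restore must lie in [0, 1]")
  if (is.null(config))
    config <- acquisition_config(matrix = spec$grid_shape, fov_mm = spec$fov)
  .assert(all(config$matrix == spec$grid_shape),
          "config$matrix must equal spec$grid_shape")

  phantom <- make_phantom(spec)
  cum <- cumulative_doses(dose_schedule)
  max_cum <- cum[length(cum)]

  steps <- data.frame(
    role = c(rep("baseline", n_baseline),
             if (include_fluid) "fluid",
             rep("dose", length(cum)),
             if (reversal) "reversal"),
    stringsAsFactors = FALSE)
  steps$cum <- 0
  steps$cum[steps$role == "dose"] <- cum
  steps$cum[steps$role == "reversal"] <- max_cum
  steps$label <- character(nrow(steps))
  steps$label[steps$role == "baseline"] <- paste0("baseline", seq_len(n_baseline))
  steps$label[steps$role == "fluid"] <- "fluid"
  steps$label[steps$role == "dose"] <- sprintf("mch_%gug", cum)
  steps$label[steps$role == "reversal"] <- "reversal"

  frame_seeds <- derive_seeds(seed, nrow(steps))
  kspace <- vector("list", nrow(steps))
  frames <- vector("list", nrow(steps))
  for (i in seq_len(nrow(steps))) {
    amp <- switch(steps$role[i],
      baseline = ,
      fluid = phantom$amplitude_map,
      dose = apply_dose(phantom, steps$cum[i]),
      reversal = {
        v <- region_response(phantom$region_params, max_cum)
        v_rev <- 1 - (1 - v) * (1 - reversal_restore)
        phantom$amplitude_map * region_factor_map(phantom, v_rev)
      })
    kspace[[i]] <- simulate_acquisition(amp, config, noise_sd = spec$noise_sd,
                                        seed = frame_seeds[i],
                                        label = steps$label[i],
                                        cumulative_dose_ug = steps$cum[i],
                                        role = steps$role[i])
    frames[[i]] <- reconstruct(kspace[[i]], apodize = apodize)
  }

  incr <- rep(0, nrow(steps))
  incr[steps$role == "dose"] <- dose_schedule
  series <- challenge_series(frames, dose_increments_ug = incr)
  attr(series, "phantom") <- phantom
  if (keep_kspace) attr(series, "kspace") <- kspace
  series
}

#' @export
print.challenge_series <- function(x, ...) {
  cat(sprintf("<challenge_series> %d frames (%d baseline, %d dose%s%s), max cumulative %g ug\n",
              length(x$frames), sum(x$role == "baseline"), sum(x$role == "dose"),
              if (any(x$role == "fluid")) ", fluid" else "",
              if (any(x$role == "reversal")) ", reversal" else "",
              max(x$cumulative_dose_ug)))
  invisible(x)
}
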