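#' Acquisition geometry and timing for the simulated FLASH sequence
#'
#' Defaults follow the coronal protocol used throughout: a 128 x 64 matrix
#' (read x phase) over a 47.3 x 31.5 mm field of view, TE 1.27 ms, TR
#' 67.5 ms, non-slice-selective by default, and the constant-signal
#' variable-flip-angle schedule over the phase-encode lines.
#'
#' @param matrix integer pair, read x phase matrix size (even entries).
#' @param fov_mm numeric pair, field of view in mm.
#' @param slice_thickness_mm slice thickness in mm for slice-selective mode,
#'   or `NULL` when non-slice-selective.
#' @param te_ms,tr_ms echo and repetition time (ms).
#' @param flip_schedule per-phase-encode flip angles in radians; defaults to
#'   [vfa_flip_schedule()] over the phase lines.
#' @param mode `"nonslice"` or `"slice"` (labelled acquisition mode only).
#' @return An object of class `acquisition_config`; `$voxel_mm` holds the
#'   derived in-plane voxel size `fov_mm / matrix`.
#' @export
acquisition_config <- function(matrix = c(128L, 64L),
                               fov_mm = c(47.3, 31.5),
                               slice_thickness_mm = NULL,
                               te_ms = 1.27, tr_ms = 67.5,
                               flip_schedule = NULL,
                               mode = c("nonslice", "slice")) {
  mode <- match.arg(mode)
  matrix <- as.integer(matrix)
  .assert(length(matrix) == 2L && all(matrix > 0L), "matrix entries must be > 0")
  .assert(all(matrix %% 2L == 0L), "matrix entries must be even")
  .assert(length(fov_mm) == 2L && all(fov_mm > 0), "fov_mm must be two positive lengths")
  if (mode == "slice") {
    if (is.null(slice_thickness_mm)) slice_thickness_mm <- 4
    .assert(slice_thickness_mm > 0, "slice_thickness_mm must be > 0")
  } else {
    slice_thickness_mm <- NULL
  }
  if (is.null(flip_schedule)) flip_schedule <- vfa_flip_schedule(matrix[2])
  .assert(length(flip_schedule) == matrix[2],
          "flip_schedule must have one angle per phase-encode line")
  structure(list(matrix = matrix, fov_mm = as.numeric(fov_mm),
                 slice_thickness_mm = slice_thickness_mm,
                 te_ms = te_ms, tr_ms = tr_ms,
                 flip_schedule = flip_schedule, mode = mode,
                 voxel_mm = as.numeric(fov_mm) / matrix),
            class = "acquisition_config")
}

#' Constant-signal variable flip angle schedule
#'
#' Hyperpolarized magnetization is nonrenewable: every excitation consumes
#' polarization, so a constant flip angle yields decaying signal across
#' phase-encode lines. The schedule `theta_j = arctan(1 / sqrt(n - j))`
#' for `j = 1..n` (ending at 90 degrees) spends the longitudinal
#' magnetization so that the transverse signal is identical on every line
#' (`1/sqrt(n)` of the initial magnetization), to machine precision.
#'
#' @param n_lines number of phase-encode lines (>= 1).
#' @return Flip angles in radians, length `n_lines`.
#' @export
vfa_flip_schedule <- function(n_lines) {
  .assert(is.numeric(n_lines) && length(n_lines) == 1L && n_lines >= 1,
          "n_lines must be a single integer >= 1")
  n <- as.integer(n_lines)
  atan(1 / sqrt(n - seq_len(n)))
}

#' Transverse signal per line for a flip schedule
#'
#' Sequentially depletes a unit longitudinal magnetization: line `j` yields
#' `Mz_j * sin(theta_j)` and leaves `Mz_j * cos(theta_j)` for the next line
#' (no T1 recovery, as for a hyperpolarized gas during a single breath-hold).
#'
#' @param flip_schedule flip angles in radians.
#' @return Transverse signal per line (initial magnetization = 1).
#' @export
flip_signal <- function(flip_schedule) {
  .assert(length(flip_schedule) >= 1L, "flip_schedule must be nonempty")
  mz <- c(1, cumprod(cos(flip_schedule)))[seq_along(flip_schedule)]
  mz * sin(flip_schedule)
}

#' Simulate a k-space acquisition of an amplitude map
#'
#' Forward model: the 2D DFT of the amplitude map (stored DC-centered), each
#' phase-encode line scaled by the flip-schedule transverse-signal factor
#' relative to the first line (so the constant-signal VFA schedule leaves
#' k-space unscaled), plus independent complex Gaussian noise with standard
#' deviation `noise_sd` per real/imaginary channel. Complex k-space noise
#' makes the reconstructed magnitude background Rician, as in scanner data.
#'
#' @param amplitude 2D amplitude map sized to `config$matrix`.
#' @param config an [acquisition_config()].
#' @param noise_sd k-space noise standard deviation per channel.
#' @param seed RNG seed for the noise draw (`NULL` = current stream).
#' @param label,cumulative_dose_ug,role frame annotations carried through.
#' @return An object of class `kspace_frame`.
#' @export
simulate_acquisition <- function(amplitude, config = acquisition_config(),
                                 noise_sd = 0, seed = NULL,
                                 label = NULL, cumulative_dose_ug = NULL,
                                 role = NULL) {
  .assert(inherits(config, "acquisition_config"), "config must be an acquisition_config")
  .assert(is.matrix(amplitude), "amplitude must be a matrix")
  .assert(all(dim(amplitude) == config$matrix),
          "amplitude shape must equal config$matrix")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  s <- flip_signal(config$flip_schedule)
  factors <- s / s[1]
  k <- forward_ft(amplitude)
  k <- sweep(k, 2L, factors, `*`)
  if (noise_sd > 0) {
    n <- length(k)
    noise <- with_seed(seed, complex(real = stats::rnorm(n, 0, noise_sd),
                                     imaginary = stats::rnorm(n, 0, noise_sd)))
    k <- k + matrix(noise, nrow(k), ncol(k))
  }
  structure(list(data = k, config = config, label = label,
                 cumulative_dose_ug = cumulative_dose_ug, role = role),
            class = "kspace_frame")
}

#' @export
print.kspace_frame <- function(x, ...) {
  cat(sprintf("<kspace_frame> %dx%d complex, %s mode%s%s\n",
              nrow(x$data), ncol(x$data), x$config$mode,
              if (!is.null(x$label)) paste0(", label '", x$label, "'") else "",
              if (!is.null(x$cumulative_dose_ug))
                sprintf(", %g ug cumulative", x$cumulative_dose_ug) else ""))
  invisible(x)
}
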