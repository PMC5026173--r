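# Shared fixtures: everything is generated in code at test time.

# Small, fast phantom for unit tests that do not need the full acquisition
# geometry.
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(64L, 32L), fov = c(47.3 / 2, 31.5 / 2),
         n_regions = 6L, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# Simulate one reconstructed frame of a phantom at a cumulative dose.
sim_frame <- function(phantom, dose = 0, noise_sd = phantom$spec$noise_sd,
                      seed = 1, apodize = TRUE, config = NULL) {
  if (is.null(config))
    config <- acquisition_config(matrix = phantom$spec$grid_shape,
                                 fov_mm = phantom$spec$fov)
  amp <- apply_dose(phantom, dose)
  k <- simulate_acquisition(amp, config, noise_sd = noise_sd, seed = seed,
                            cumulative_dose_ug = dose,
                            role = if (dose > 0) "dose" else "baseline")
  reconstruct(k, apodize = apodize)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Independent brute-force evaluation of the relative-difference formula,
# written loop-wise so it shares no code path with the implementation.
brute_force_relative_diff <- function(M, B, gs) {
  k <- length(M)
  mM <- sum(M) / k
  mB <- sum(B) / k
  out <- M
  for (i in seq_along(M)) out[i] <- (M[i] / mM - B[i] / mB) * 100 / gs
  out
}
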