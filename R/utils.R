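# Internal helpers shared across modules.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent per-item seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# DC-centering half swap for even-sized matrices (self-inverse).
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  .assert(nr %% 2L == 0L && nc %% 2L == 0L,
          "fftshift2 requires even matrix dimensions")
  x[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2)), drop = FALSE]
}

# Forward 2D DFT of an image, returned DC-centered.
forward_ft <- function(x) {
  fftshift2(stats::fft(fftshift2(x)))
}

# Inverse 2D DFT of DC-centered k-space back to (complex) image space.
inverse_ft <- function(k) {
  fftshift2(stats::fft(fftshift2(k), inverse = TRUE)) / length(k)
}

# Population (n-divisor) standard deviation; descriptive map statistic.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

as_values <- function(x) {
  if (inherits(x, "magnitude_image")) return(x$values)
  .assert(is.matrix(x) && is.numeric(x), "expected a magnitude_image or numeric matrix")
  x
}
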