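## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

## Numerically safe logistic; plogis never overflows and saturates cleanly.
sigmoid <- function(x) stats::plogis(x)

## Min-max rescale to [0, 1]; a constant input maps to all zeros.
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    array(0, dim = dim(x) %||% length(x))
  } else {
    (x - rng[1]) / (rng[2] - rng[1])
  }
}

## Quantize [0,1] intensities to the 8-bit grid (values remain in [0,1]).
quantize8 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 255) / 255
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

## Standardized low-frequency random field on an nr x nc grid: a sum of
## random 2-D sinusoids, rescaled to zero mean and unit RMS. Used for
## smooth intra-lesion texture and background inhomogeneity.
smooth_field <- function(nr, nc, n_waves = 4L, max_freq = 4) {
  rows <- matrix(seq_len(nr) / nr, nr, nc)
  cols <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_waves)) {
    kr <- stats::runif(1, 0.5, max_freq)
    kc <- stats::runif(1, 0.5, max_freq)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * sin(2 * pi * (kr * rows + kc * cols) + ph)
  }
  f <- f - mean(f)
  rms <- sqrt(mean(f^2))
  if (rms > 0) f / rms else f
}
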