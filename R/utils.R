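#' @importFrom stats fft quantile median rnorm runif rpois sd cor
#' @importFrom utils head tail read.csv write.csv
NULL

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used when quoting percentages:
#' `round_half_up(98.86, 0)` is 99, where [round()] would give 99 too but
#' rounds halves to even in general (e.g. 0.5 -> 0).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# FFT sample frequencies (cycles per unit), matching numpy.fft.fftfreq layout.
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Block-average a matrix by an integer factor in both dimensions.
block_average <- function(m, factor) {
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # sum over factor x factor blocks
  a <- array(m, dim = c(factor, nr, factor, nc))
  out <- apply(a, c(2, 4), sum) / factor^2
  out
}

# Mean squared centered-difference gradient magnitude; zero for constants.
tenengrad <- function(a) {
  if (!is.matrix(a) || length(a) == 0) stop("focus_score: need a non-empty 2D array")
  if (all(is.na(a))) stop("focus_score: all-NaN input")
  n <- nrow(a); m <- ncol(a)
  if (n < 3 || m < 3) return(0)
  gx <- (a[, 3:m, drop = FALSE] - a[, 1:(m - 2), drop = FALSE]) / 2
  gy <- (a[3:n, , drop = FALSE] - a[1:(n - 2), , drop = FALSE]) / 2
  mean(gx^2) + mean(gy^2)
}

# Circular difference in degrees, result in [-180, 180).
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

# Circular mean of angles in degrees.
circ_mean_deg <- function(theta, w = NULL) {
  r <- theta * pi / 180
  if (is.null(w)) w <- rep(1, length(r))
  ang <- atan2(sum(w * sin(r)), sum(w * cos(r))) * 180 / pi
  ang %% 360
}

# Circular dispersion (1 - mean resultant length) in [0, 1].
circ_dispersion <- function(theta) {
  r <- theta * pi / 180
  1 - sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
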