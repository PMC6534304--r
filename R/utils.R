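#' @useDynLib vocemark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd var median quantile fft mvfft
#'   nextn wilcox.test predict setNames
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population variance and standard deviation
#'
#' Perturbation and summary statistics throughout the package use the
#' population (divide by n) convention, matching the usual definitions of
#' voice-report software.
#' @param x numeric vector
#' @return a single number; 0 for vectors of length < 2
#' @keywords internal
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

## mean that maps empty input to 0 (degenerate feature convention)
mean0 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) 0 else mean(x)
}

max0 <- function(x) if (length(x) == 0) 0 else max(x)

#' Deterministic seed derivation
#'
#' Derives a child seed from a parent seed and an index with a Lehmer step so
#' every recording/fold gets an independent, reproducible substream. Result is
#' always a positive integer below 2^31.
#' @keywords internal
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.numeric(i) * 16807) %% 2147483647
  as.integer(v + 1)
}

## evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## 1-based start indices of analysis frames fully inside a signal of length n
frame_starts <- function(n, frame_n, hop_n) {
  if (n < frame_n) return(integer(0))
  seq.int(1L, n - frame_n + 1L, by = hop_n)
}

## gather frames into a frame_n x nframes matrix
frame_matrix <- function(x, starts, frame_n) {
  idx <- rep(starts, each = frame_n) + seq_len(frame_n) - 1L
  matrix(x[idx], nrow = frame_n)
}

## truncated normal draw (by resampling the tail mass via clamping at bound)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}
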