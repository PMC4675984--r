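# Orthogonal periodic Daubechies-4 (8-tap, 4 vanishing moments) discrete
# wavelet transform. The signal is reflected up to a multiple of 2^level,
# transformed with periodic boundary handling (exact perfect
# reconstruction for orthonormal filters), and truncated back.

DB4_LO <- c(-0.010597401785069032, 0.032883011666885206,
            0.030841381835560764, -0.187034811718093090,
            -0.027983769416859854, 0.630880767929858910,
            0.714846570552915700, 0.230377813308896500)
DB4_HI <- (-1)^(seq_along(DB4_LO) - 1) * rev(DB4_LO)

# one analysis step: x (even length) -> list(approx, detail), periodic
dwt_step <- function(x) {
  n <- length(x)
  half <- n / 2
  a <- numeric(half)
  d <- numeric(half)
  k2 <- 2 * (seq_len(half) - 1)
  for (m in seq_along(DB4_LO)) {
    idx <- (k2 + (m - 1)) %% n + 1
    a <- a + DB4_LO[m] * x[idx]
    d <- d + DB4_HI[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# inverse of dwt_step (transpose of the orthogonal analysis operator)
idwt_step <- function(approx, detail) {
  half <- length(approx)
  n <- 2 * half
  x <- numeric(n)
  k2 <- 2 * (seq_len(half) - 1)
  for (m in seq_along(DB4_LO)) {
    idx <- (k2 + (m - 1)) %% n + 1
    x[idx] <- x[idx] + DB4_LO[m] * approx + DB4_HI[m] * detail
  }
  x
}

dwt_periodic <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a)
    a <- s$approx
    details[[j]] <- s$detail
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]])
  }
  a
}

max_dwt_level <- function(n) max(0L, floor(log2(n)))

#' Wavelet denoising of a binned signal
#'
#' Decomposes the series with a periodic orthogonal Daubechies-4 transform
#' (the input is reflected out to a transformable length first),
#' soft-thresholds every detail coefficient at the universal threshold
#' `sigma * sqrt(2 * log(n))` — with `sigma` estimated from the median
#' absolute deviation of the finest-scale details — reconstructs, and
#' clamps the result at zero (binned read counts are non-negative).
#'
#' @param series numeric vector, length >= 2.
#' @param level decomposition depth, or `NULL` to choose
#'   `min(4, floor(log2(n)))` automatically.
#' @return A smoothed vector the same length as the input.
#' @examples
#' set.seed(1)
#' x <- pmax(0, 10 + 3 * sin((1:256) / 10) + rnorm(256))
#' var(wavelet_smooth(x)) < var(x)
#' @export
wavelet_smooth <- function(series, level = NULL) {
  n <- length(series)
  assert_that(n >= 2, "`series` must have length >= 2")
  assert_that(all(is.finite(series)), "`series` must be finite")
  auto <- min(4L, max_dwt_level(n))
  level <- level %||% auto
  if (level > max_dwt_level(n)) {
    abort(sprintf("level %d exceeds maximum decomposition depth %d",
                  level, max_dwt_level(n)))
  }
  # reflect-pad to a multiple of 2^level
  block <- 2^level
  npad <- ceiling(n / block) * block - n
  x <- c(series, rev(series)[seq_len(min(npad, n))])
  while (length(x) < n + npad) {   # very short series may need repeats
    x <- c(x, rev(x)[seq_len(min(n + npad - length(x), length(x)))])
  }
  dec <- dwt_periodic(x, level)
  finest <- dec$details[[1]]
  sigma <- mad(finest, center = 0)
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- purrr::map(dec$details, function(d) {
    sign(d) * pmax(abs(d) - thr, 0)
  })
  out <- idwt_periodic(dec)[seq_len(n)]
  pmax(out, 0)
}

#' @rdname wavelet_smooth
#' @param track a [bruuv_track()].
#' @export
smooth_track <- function(track, level = NULL) {
  for (chr in names(chrom_sizes(track))) {
    v <- track_counts(track, chr)
    if (length(v) >= 2) {
      track <- set_track_counts(track, chr, wavelet_smooth(v, level = level))
    }
  }
  track
}
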