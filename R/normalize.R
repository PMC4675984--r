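#' Quantile-normalize a window matrix across regions
#'
#' Forces every row (one TSS window per row) to share the same value
#' distribution: the reference is the per-rank mean of the row-sorted
#' values, within-row rank order is preserved, and ties receive the mean of
#' the reference values they span. This makes emission parameters trained
#' on different gene windows comparable. A single row is returned
#' unchanged, and the operation is idempotent.
#'
#' @param mat numeric matrix, one row per window.
#' @return A matrix of the same shape.
#' @examples
#' quantile_normalize(rbind(c(1, 2, 3), c(6, 4, 2)))
#' @export
quantile_normalize <- function(mat) {
  assert_that(is.matrix(mat) && nrow(mat) >= 1,
              "`mat` must be a matrix with at least one row")
  if (ncol(mat) == 1) return(matrix(mean(mat), nrow(mat), 1,
                                    dimnames = dimnames(mat)))
  ref <- rowMeans(apply(mat, 1, sort))
  out <- t(apply(mat, 1, function(r) {
    o <- order(r)
    grp <- cumsum(c(1, diff(r[o]) != 0))
    gm <- tapply(ref, grp, mean)    # mean of the reference ranks a tie spans
    res <- numeric(length(r))
    res[o] <- gm[grp]
    res
  }))
  dimnames(out) <- dimnames(mat)
  out
}

#' Gamma-equivalent z-score transform
#'
#' Maps non-negative signal onto a standard-normal scale through the
#' probability-integral transform of a gamma distribution fitted to the
#' values by the method of moments (`shape = m^2/v`, `scale = v/m`). A
#' pseudocount of half the smallest positive value (1e-6 when there is
#' none) shifts zeros onto the positive support before fitting. The fitted
#' CDF is clamped to `[1e-6, 1 - 1e-6]` before the normal quantile is
#' taken, so the output is strictly increasing in the input except deep in
#' the clamped tails. `mode = "plain_z"` substitutes an ordinary z-score.
#'
#' @param values non-negative numeric vector, length >= 3.
#' @param mode `"gamma_z"` (default) or `"plain_z"`.
#' @return Numeric vector of z-scores.
#' @examples
#' set.seed(1)
#' z <- gamma_z_transform(rgamma(1000, shape = 2, scale = 1))
#' @export
gamma_z_transform <- function(values, mode = c("gamma_z", "plain_z")) {
  mode <- match.arg(mode)
  assert_that(length(values) >= 3, "need at least 3 values")
  assert_that(all(values >= 0), "values must be non-negative")
  if (mode == "plain_z") {
    s <- sd(values)
    if (s == 0) abort("degenerate window: zero variance")
    return((values - mean(values)) / s)
  }
  pos <- values[values > 0]
  eps <- if (length(pos) > 0) min(pos) / 2 else 1e-6
  x <- values + eps
  m <- mean(x)
  v <- var(x)
  if (v == 0) abort("degenerate window: zero variance")
  shape <- m^2 / v
  scale <- v / m
  p <- pgamma(x, shape = shape, scale = scale)
  qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6))
}

#' Scale a mock/UV track pair to a common sequencing depth
#'
#' Both tracks are multiplied by `min(totals) / own total`, so the smaller
#' library is untouched and the pair ends up at equal effective depth. The
#' baseline probability that a read at an unchanged location comes from
#' the UV sample is then `p0 = 0.5` by construction; it is returned
#' explicitly because it anchors the Bernoulli-trial reading of the
#' per-bin UV read fraction.
#'
#' @param mock,uv [bruuv_track()]s with positive `total_reads`.
#' @return List with elements `mock`, `uv` (scaled tracks) and `p0`.
#' @export
scale_pair_to_common_depth <- function(mock, uv) {
  tm <- total_reads(mock)
  tu <- total_reads(uv)
  assert_that(tm > 0 && tu > 0, "both tracks need positive `total_reads`")
  lo <- min(tm, tu)
  mock <- scale_track(mock, lo / tm)
  uv <- scale_track(uv, lo / tu)
  list(mock = mock, uv = uv,
       p0 = total_reads(uv) / (total_reads(uv) + total_reads(mock)))
}
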