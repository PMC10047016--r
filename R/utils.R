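#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (0.05 -> 0.1), the
#' convention used for reported percentages. Base `round()` rounds ties to
#' even, which would print 40.25% as 40.2%.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Smooth low-frequency random field
#'
#' Draws an i.i.d. Gaussian field on a coarse grid and bilinearly upsamples it
#' to `size x size`. Used as additive background texture (fibroglandular
#' structure on the density channel, parenchymal enhancement on the contrast
#' channel). Mean 0, marginal SD ~= 1 at the coarse knots.
#'
#' @param size output side length in pixels
#' @param knots coarse grid side length (>= 2)
#' @return size x size numeric matrix
#' @keywords internal
low_freq_field <- function(size, knots = 8) {
  stopifnot(size >= 2, knots >= 2)
  g <- matrix(stats::rnorm(knots * knots), knots, knots)
  # map pixel index 1..size onto knot coordinate 1..knots
  u <- seq(1, knots, length.out = size)
  i0 <- pmin(floor(u), knots - 1)
  fi <- u - i0
  # bilinear blend of the four surrounding knots, vectorized by outer products
  a <- g[i0, i0, drop = FALSE]
  b <- g[i0 + 1, i0, drop = FALSE]
  d <- g[i0, i0 + 1, drop = FALSE]
  e <- g[i0 + 1, i0 + 1, drop = FALSE]
  w1 <- outer(1 - fi, 1 - fi)
  w2 <- outer(fi, 1 - fi)
  w3 <- outer(1 - fi, fi)
  w4 <- outer(fi, fi)
  a * w1 + b * w2 + d * w3 + e * w4
}

# intensity scale: images live on the 16-bit unsigned range as integer counts
FULL_SCALE <- 65535

FINDING_CLASSES <- c("benign", "high_risk", "atypia", "malignant")

`%||%` <- function(a, b) if (is.null(a)) b else a
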