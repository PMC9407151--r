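# Convolution backbone.
#
# All filters use cross-correlation semantics (kernel not flipped) with
# reflect padding: the border is mirrored with the edge pixel duplicated,
# so filters see plausible tissue rather than zeros outside the frame.
# Separable (Gaussian / Gaussian-derivative) kernels run through
# stats::filter, which is C-backed; general 2-D kernels (membrane line
# kernels, Gabor) run through an FFT product on a padded grid.

#' Reflect-pad a matrix
#'
#' Pads `x` by `rr` rows and `rc` columns on each side, mirroring with the
#' edge duplicated (`a b c` -> `b a | a b c | c b`).
#'
#' @param x numeric matrix.
#' @param rr,rc non-negative pad widths in rows / columns.
#' @return padded matrix.
#' @keywords internal
pad_reflect <- function(x, rr, rc = rr) {
  nr <- nrow(x); nc <- ncol(x)
  assert_that(rr < nr && rc < nc || (rr <= nr && rc <= nc), "parameter",
              "pad width exceeds image size")
  ri <- c(rev(seq_len(min(rr, nr))), seq_len(nr), nr + 1 - seq_len(min(rr, nr)))
  ci <- c(rev(seq_len(min(rc, nc))), seq_len(nc), nc + 1 - seq_len(min(rc, nc)))
  x[ri, ci, drop = FALSE]
}

# 1-D cross-correlation along columns, valid region only after padding.
# stats::filter(x, f, sides = 2) computes y[i] = sum_j f[j] x[i + c - j]
# with c = p %/% 2 + 1, i.e. convolution; passing rev(k) yields correlation
# with k centred on its middle element (k must have odd length).
filter_cols <- function(x, k) {
  y <- stats::filter(x, rev(k), method = "convolution", sides = 2)
  matrix(as.numeric(y), nrow(x), ncol(x))
}

#' Separable cross-correlation with reflect padding
#'
#' Applies `ky` down the rows and `kx` across the columns (both odd-length),
#' returning a matrix of the input size.
#'
#' @keywords internal
correlate_sep <- function(img, ky, kx) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- pad_reflect(img, ry, rx)
  p <- filter_cols(p, ky)         # along rows dimension (column vectors)
  p <- t(filter_cols(t(p), kx))   # along columns dimension
  p[(ry + 1):(ry + nrow(img)), (rx + 1):(rx + ncol(img)), drop = FALSE]
}

#' 2-D cross-correlation with reflect padding (FFT)
#'
#' @param img numeric matrix.
#' @param kern odd-dimension numeric matrix.
#' @return matrix of the input size.
#' @keywords internal
correlate2 <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  p <- pad_reflect(img, kr, kc)
  nr <- nrow(p); nc <- ncol(p)
  # circular convolution of the padded image with the *flipped* kernel
  # equals cross-correlation; embed kernel top-left, compensate the shift.
  fr <- stats::nextn(nr + nrow(kern) - 1L, c(2, 3, 5))
  fc <- stats::nextn(nc + ncol(kern) - 1L, c(2, 3, 5))
  P <- matrix(0, fr, fc); P[1:nr, 1:nc] <- p
  K <- matrix(0, fr, fc)
  K[1:nrow(kern), 1:ncol(kern)] <- kern[nrow(kern):1, ncol(kern):1, drop = FALSE]
  full <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) / (fr * fc)
  # centre of the flipped kernel lands at offset (2*kr, 2*kc) in `full`;
  # valid output for original pixel (i,j) is full[i + 2*kr, j + 2*kc].
  full[(2L * kr + 1L):(2L * kr + nrow(img)),
       (2L * kc + 1L):(2L * kc + ncol(img)), drop = FALSE]
}

#' Sampled Gaussian (derivative) kernel
#'
#' @param sigma scale in pixels (> 0).
#' @param order derivative order 0..4.
#' @param radius half-width; default `max(1, ceiling(3.5 * sigma))`.
#' @return numeric vector of odd length. Order 0 sums to 1; higher orders
#'   have the moment normalization of sampled Gaussian derivatives.
#' @keywords internal
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
              "parameter", "sigma must be a positive number")
  assert_that(order %in% 0:4, "parameter", "derivative order must be 0..4")
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  s2 <- sigma^2
  # signs chosen for *correlation* semantics: a ramp I(x)=x yields +1 under
  # the order-1 kernel, I(x)=x^2 yields +2 under order 2, etc.
  h <- switch(as.character(order),
    "0" = g,
    "1" = x / s2 * g,
    "2" = (x^2 - s2) / s2^2 * g,
    "3" = (x^3 - 3 * s2 * x) / s2^3 * g,
    "4" = (x^4 - 6 * s2 * x^2 + 3 * s2^2) / s2^4 * g
  )
  if (order > 0) {
    # kill the residual DC component of the sampled derivative so constant
    # images map to exactly zero
    h <- h - mean(h)
  }
  # moment normalization so low-order polynomials respond exactly
  # (truncation of the sampled kernel otherwise biases the scale)
  if (order == 1) h <- h / sum(h * x)
  if (order == 2) h <- h * 2 / sum(h * x^2)
  h
}

#' Gaussian blur with reflect borders
#' @keywords internal
gauss_blur <- function(img, sigma) {
  k <- gauss_kernel(sigma, 0L)
  correlate_sep(img, k, k)
}

# Gaussian partial derivative d^(oy+ox) I / dy^oy dx^ox (y = rows downward,
# x = columns rightward).
gauss_deriv <- function(img, sigma, oy, ox) {
  correlate_sep(img, gauss_kernel(sigma, oy), gauss_kernel(sigma, ox))
}
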