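# The single-filter dispatch behind the feature stack.
#
# Every filter returns one or more named planes of the source dimensions,
# is deterministic, and handles borders by reflection (see conv.R).

.filter_kinds <- c("gaussian", "sobel", "dog", "hessian", "membrane",
                   "local_stats", "aniso_diffusion", "bilateral",
                   "lipschitz", "gabor", "derivatives", "structure", "shift")

#' Apply one filter kind to an image
#'
#' @param img a [gray_image()] or plain numeric matrix.
#' @param kind one of `"gaussian"`, `"sobel"`, `"dog"`, `"hessian"`,
#'   `"membrane"`, `"local_stats"`, `"aniso_diffusion"`, `"bilateral"`,
#'   `"lipschitz"`, `"gabor"`, `"derivatives"`, `"structure"`, `"shift"`.
#' @param ... parameters for the kind; most take `sigma` (scale in px).
#'   `dog` takes `sigma_a`, `sigma_b`; `membrane` takes `thickness`,
#'   `patch_size`; `hessian` takes `sigma`, `t`, and `orientation_form`.
#' @return a named list of numeric planes.
#' @export
apply_filter <- function(img, kind, ...) {
  assert_that(length(kind) == 1 && kind %in% .filter_kinds, "parameter",
              sprintf("unknown filter kind: '%s'", paste(kind, collapse = ",")))
  x <- unclass(img)
  attr(x, "pixels_per_mm") <- NULL
  switch(kind,
    gaussian        = filt_gaussian(x, ...),
    sobel           = filt_sobel(x, ...),
    dog             = filt_dog(x, ...),
    hessian         = hessian_planes(x, ...),
    membrane        = membrane_projections(x, ...),
    local_stats     = filt_local_stats(x, ...),
    aniso_diffusion = filt_aniso(x, ...),
    bilateral       = filt_bilateral(x, ...),
    lipschitz       = filt_lipschitz(x, ...),
    gabor           = filt_gabor(x, ...),
    derivatives     = filt_derivatives(x, ...),
    structure       = filt_structure(x, ...),
    shift           = filt_shift(x, ...)
  )
}

filt_gaussian <- function(x, sigma) {
  stats::setNames(list(gauss_blur(x, sigma)), sprintf("gaussian_s%g", sigma))
}

# Gradient magnitude of the sigma-smoothed image, via 3x3 Sobel kernels.
filt_sobel <- function(x, sigma) {
  s <- gauss_blur(x, sigma)
  gx <- correlate_sep(s, c(1, 2, 1), c(-1, 0, 1))
  gy <- correlate_sep(s, c(-1, 0, 1), c(1, 2, 1))
  stats::setNames(list(sqrt(gx^2 + gy^2)), sprintf("sobel_s%g", sigma))
}

filt_dog <- function(x, sigma_a, sigma_b) {
  stats::setNames(list(gauss_blur(x, sigma_a) - gauss_blur(x, sigma_b)),
                  sprintf("dog_s%g_s%g", sigma_a, sigma_b))
}

# Mean / min / max / variance / median over a disc of radius sigma.
# Implemented by enumerating the disc offsets (shift-and-aggregate), which
# is exact and fine for the radii in the default scale ladder.
filt_local_stats <- function(x, sigma) {
  r <- max(1L, as.integer(round(sigma)))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  p <- pad_reflect(x, r, r)
  nr <- nrow(x); nc <- ncol(x)
  stack <- vapply(seq_len(nrow(off)), function(i) {
    p[(r + 1 + off$dy[i]):(r + off$dy[i] + nr),
      (r + 1 + off$dx[i]):(r + off$dx[i] + nc)]
  }, matrix(0, nr, nc))
  m <- apply(stack, c(1, 2), mean)
  v <- apply(stack, c(1, 2), stats::var)
  stats::setNames(
    list(m,
         apply(stack, c(1, 2), min),
         apply(stack, c(1, 2), max),
         v,
         apply(stack, c(1, 2), stats::median)),
    sprintf("local_%s_s%g", c("mean", "min", "max", "var", "median"), sigma))
}

# Perona-Malik edge-preserving diffusion with the exponential conduction
# function; classic defaults (20 iterations, kappa = 20/255, step 0.2).
filt_aniso <- function(x, sigma = NULL, n_iter = 20L, kappa = 20 / 255,
                       lambda = 0.2) {
  u <- x
  for (it in seq_len(n_iter)) {
    p <- pad_reflect(u, 1, 1)
    n <- nrow(u); m <- ncol(u)
    dN <- p[1:n, 2:(m + 1)] - u
    dS <- p[3:(n + 2), 2:(m + 1)] - u
    dW <- p[2:(n + 1), 1:m] - u
    dE <- p[2:(n + 1), 3:(m + 2)] - u
    u <- u + lambda * (exp(-(dN / kappa)^2) * dN + exp(-(dS / kappa)^2) * dS +
                       exp(-(dW / kappa)^2) * dW + exp(-(dE / kappa)^2) * dE)
  }
  nm <- if (is.null(sigma)) "aniso" else sprintf("aniso_s%g", sigma)
  stats::setNames(list(u), nm)
}

# Bilateral filter over a disc of radius ceiling(2*sigma): spatial Gaussian
# of scale sigma, range Gaussian of scale sigma_r in intensity units.
filt_bilateral <- function(x, sigma, sigma_r = 0.1) {
  r <- max(1L, as.integer(ceiling(2 * sigma)))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  w_sp <- exp(-(off$dy^2 + off$dx^2) / (2 * sigma^2))
  p <- pad_reflect(x, r, r)
  nr <- nrow(x); nc <- ncol(x)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    nb <- p[(r + 1 + off$dy[i]):(r + off$dy[i] + nr),
            (r + 1 + off$dx[i]):(r + off$dx[i] + nc)]
    w <- w_sp[i] * exp(-(nb - x)^2 / (2 * sigma_r^2))
    num <- num + w * nb
    den <- den + w
  }
  stats::setNames(list(num / den), sprintf("bilateral_s%g", sigma))
}

# Lipschitz covers by chamfer-style raster sweeps: the lower cover is the
# largest function below the image whose slope is bounded by `slope` per
# pixel step; the returned plane is the top-hat residual image - cover
# (and symmetrically for the upper cover).
lipschitz_cover <- function(x, slope, lower = TRUE) {
  f <- if (lower) x else -x
  n <- nrow(f); m <- ncol(f)
  # forward then backward sweep, repeated until stable (2 passes suffice
  # for a 4-neighbour cone)
  for (pass in 1:2) {
    for (i in seq_len(n)) {
      if (i > 1) f[i, ] <- pmax(f[i, ], f[i - 1, ] - slope)
      r <- f[i, ]
      for (j in 2:m) if (r[j] < r[j - 1] - slope) r[j] <- r[j - 1] - slope
      f[i, ] <- r
    }
    for (i in rev(seq_len(n))) {
      if (i < n) f[i, ] <- pmax(f[i, ], f[i + 1, ] - slope)
      r <- f[i, ]
      for (j in rev(seq_len(m - 1))) if (r[j] < r[j + 1] - slope) r[j] <- r[j + 1] - slope
      f[i, ] <- r
    }
  }
  if (lower) f else -f
}

filt_lipschitz <- function(x, slope = 5 / 255, sigma = NULL) {
  lo <- lipschitz_cover(x, slope, lower = TRUE)
  hi <- lipschitz_cover(x, slope, lower = FALSE)
  suffix <- if (is.null(sigma)) "" else sprintf("_s%g", sigma)
  stats::setNames(list(x - hi, lo - x),
                  paste0(c("lipschitz_top", "lipschitz_bottom"), suffix))
}

# Gabor magnitude responses: per scale, 4 orientations x 2 wavelengths
# (lambda = 4*sigma and 8*sigma), even/odd quadrature pair.
filt_gabor <- function(x, sigma, n_orient = 4L, wavelengths = c(4, 8)) {
  out <- list()
  r <- max(2L, as.integer(ceiling(2.5 * sigma)))
  grid <- expand.grid(gy = -r:r, gx = -r:r)
  env <- exp(-(grid$gy^2 + grid$gx^2) / (2 * sigma^2))
  for (oi in seq_len(n_orient)) {
    th <- (oi - 1) * pi / n_orient
    u <- grid$gx * cos(th) + grid$gy * sin(th)
    for (wl in wavelengths * sigma) {
      phase <- 2 * pi * u / wl
      ke <- matrix(env * cos(phase), 2 * r + 1)
      ko <- matrix(env * sin(phase), 2 * r + 1)
      ke <- ke - mean(ke)   # zero-DC so flat regions respond 0
      re <- correlate2(x, ke)
      im <- correlate2(x, ko)
      out[[sprintf("gabor_s%g_o%d_w%g", sigma, oi - 1L, wl)]] <- sqrt(re^2 + im^2)
    }
  }
  out
}

# Gaussian derivatives of orders 2..4 along each axis.
filt_derivatives <- function(x, sigma, orders = 2:4) {
  out <- list()
  for (o in orders) {
    out[[sprintf("deriv_dx%d_s%g", o, sigma)]] <- gauss_deriv(x, sigma, 0L, o)
    out[[sprintf("deriv_dy%d_s%g", o, sigma)]] <- gauss_deriv(x, sigma, o, 0L)
  }
  out
}

# Eigenvalues of the sigma-smoothed gradient structure tensor.
filt_structure <- function(x, sigma, rho = NULL) {
  if (is.null(rho)) rho <- sigma
  gx <- gauss_deriv(x, sigma, 0L, 1L)
  gy <- gauss_deriv(x, sigma, 1L, 0L)
  jxx <- gauss_blur(gx * gx, rho)
  jxy <- gauss_blur(gx * gy, rho)
  jyy <- gauss_blur(gy * gy, rho)
  tr <- jxx + jyy
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  stats::setNames(list((tr + disc) / 2, (tr - disc) / 2),
                  sprintf("structure_e%d_s%g", 1:2, sigma))
}

# Image translated by +/- round(sigma) pixels in the 4 axis directions,
# reflect-filled at the vacated border.
filt_shift <- function(x, sigma) {
  d <- max(1L, as.integer(round(sigma)))
  p <- pad_reflect(x, d, d)
  nr <- nrow(x); nc <- ncol(x)
  take <- function(dy, dx) {
    p[(d + 1 + dy):(d + dy + nr), (d + 1 + dx):(d + dx + nc)]
  }
  stats::setNames(
    list(take(-d, 0), take(d, 0), take(0, -d), take(0, d)),
    sprintf("shift_%s_s%g", c("up", "down", "left", "right"), sigma))
}
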