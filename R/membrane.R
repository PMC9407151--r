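# Membrane projections: a thin line kernel rotated over 30 orientations
# (6 degree steps); the 30 responses are aggregated per pixel.  These
# respond to elongated, membrane-like structures regardless of direction.

#' Membrane projection feature planes
#'
#' A normalized line kernel of length `patch_size` and width `thickness`
#' is rotated through 30 orientations in 6-degree steps, each rotation is
#' correlated with the image, and the per-pixel responses across the 30
#' orientations are aggregated by sum, mean, standard deviation, median,
#' maximum, and minimum.
#'
#' @param img numeric matrix or [gray_image()].
#' @param thickness line width in pixels (>= 1).
#' @param patch_size kernel side length in pixels; must be odd.
#' @return named list of 6 planes
#'   (`membrane_{sum,mean,sd,median,max,min}_t<thickness>_p<patch_size>`).
#' @export
membrane_projections <- function(img, thickness = 1, patch_size = 19) {
  assert_that(patch_size %% 2 == 1, "parameter", "patch_size must be odd")
  assert_that(thickness >= 1, "parameter", "thickness must be >= 1")
  assert_that(patch_size >= thickness, "parameter",
              "patch_size must be >= thickness")
  x <- unclass(img)
  attr(x, "pixels_per_mm") <- NULL
  nr <- nrow(x); nc <- ncol(x)
  resp <- array(0, c(nr, nc, 30L))
  for (a in 0:29) {
    k <- membrane_kernel(thickness, patch_size, a * 6)
    resp[, , a + 1L] <- correlate2(x, k)
  }
  sum_p <- apply(resp, c(1, 2), sum)
  mean_p <- sum_p / 30
  sq <- apply(resp^2, c(1, 2), sum)
  sd_p <- sqrt(pmax(sq / 30 - mean_p^2, 0) * 30 / 29)
  stats::setNames(
    list(sum_p, mean_p, sd_p,
         apply(resp, c(1, 2), stats::median),
         apply(resp, c(1, 2), max),
         apply(resp, c(1, 2), min)),
    sprintf("membrane_%s_t%g_p%d",
            c("sum", "mean", "sd", "median", "max", "min"),
            thickness, as.integer(patch_size)))
}

# Rasterized rotated line kernel: distance-to-line thresholded at
# thickness/2 (with a half-pixel soft margin), normalized to sum 1.
membrane_kernel <- function(thickness, patch_size, angle_deg) {
  r <- (patch_size - 1) / 2
  g <- expand.grid(gy = -r:r, gx = -r:r)
  th <- angle_deg * pi / 180
  # signed distance from the line through the origin at angle th
  d <- abs(-sin(th) * g$gx + cos(th) * g$gy)
  w <- pmin(pmax(thickness / 2 + 0.5 - d, 0), 1)
  k <- matrix(w, patch_size, patch_size)
  k / sum(k)
}
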