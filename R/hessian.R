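# Multiscale Hessian features.
#
# The Hessian of the sigma-smoothed intensity,
#
#     H = | h1 h2 |      h1 = Ixx, h2 = h3 = Ixy, h4 = Iyy,
#         | h3 h4 |
#
# is summarized per pixel by its trace, determinant, eigenvalues
# (fe >= se), orientation of the maximal second derivative, and two
# gamma-normalized ridge-strength measures controlled by a constant `t`.
#
# Two determinant conventions are kept side by side:
#   det_standard = h1*h4 - h2*h3   (the algebraic 2x2 determinant; feeds
#                                   the eigenvalue identities)
#   det_printed  = h1^2 + h2*h3 + h4^2  (an alternative quadratic form some
#                                   implementations report; the default
#                                   stack feature)
# Similarly the orientation is atan2-based by default,
#     or = 1/2 * atan2(2*h2, h1 - h4),
# with an arccos form 1/2 * arccos(4*h2^2 + (h1-h4)^2) selectable; its
# argument is clamped to [-1, 1] because it is not intrinsically bounded.

#' Hessian feature planes at one scale
#'
#' @param img numeric matrix or [gray_image()].
#' @param sigma smoothing scale in pixels (> 0).
#' @param t constant of the gamma measures; default `13 / 4`.
#' @param orientation_form `"atan2"` (default) or `"arccos"` (clamped).
#' @return an object of class `hessian_features`: a named list of planes
#'   `h1, h2, h3, h4, trace, det_standard, det_printed, fe, se,
#'   orientation, gamma, square_gamma`, plus `sigma` and `t`.
#' @details
#' The eigenvalues are
#'   `fe, se = (h1 + h4)/2 +/- sqrt(4*h2^2 + (h1 - h4)^2)/2`
#' so that `fe + se == trace` and `fe * se == det_standard` hold exactly
#' (up to round-off).  The ridge measures are
#'   `gamma = t^4 * (h1 - h4)^2 * ((h1 - h4)^2 + 4*h2^2)` and
#'   `square_gamma = t^2 * ((h1 - h4)^2 + 4*h2^2)`.
#' @export
hessian_features <- function(img, sigma, t = 13 / 4,
                             orientation_form = c("atan2", "arccos")) {
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
              "parameter", "sigma must be positive")
  orientation_form <- match.arg(orientation_form)
  x <- unclass(img)
  attr(x, "pixels_per_mm") <- NULL
  h1 <- gauss_deriv(x, sigma, 0L, 2L)   # Ixx
  h2 <- gauss_deriv(x, sigma, 1L, 1L)   # Ixy
  h3 <- h2                              # mixed partials commute
  h4 <- gauss_deriv(x, sigma, 2L, 0L)   # Iyy
  dif <- h1 - h4
  disc <- 4 * h2^2 + dif^2
  root <- sqrt(pmax(disc, 0))
  or <- if (orientation_form == "atan2") {
    0.5 * atan2(2 * h2, dif)
  } else {
    0.5 * acos(pmin(pmax(disc, -1), 1))
  }
  structure(list(
    h1 = h1, h2 = h2, h3 = h3, h4 = h4,
    trace = h1 + h4,
    det_standard = h1 * h4 - h2 * h3,
    det_printed = h1^2 + h2 * h3 + h4^2,
    fe = (h1 + h4) / 2 + root / 2,
    se = (h1 + h4) / 2 - root / 2,
    orientation = or,
    gamma = t^4 * dif^2 * disc,
    square_gamma = t^2 * disc,
    sigma = sigma, t = t
  ), class = "hessian_features")
}

# The subset of Hessian planes that enters the feature stack.
hessian_planes <- function(x, sigma, t = 13 / 4, det = c("printed", "standard"),
                           orientation_form = "atan2") {
  det <- match.arg(det)
  hf <- hessian_features(x, sigma, t = t, orientation_form = orientation_form)
  det_plane <- if (det == "printed") hf$det_printed else hf$det_standard
  stats::setNames(
    list(hf$trace, det_plane, hf$fe, hf$se, hf$orientation,
         hf$gamma, hf$square_gamma),
    sprintf("hessian_%s_s%g",
            c("trace", "det", "fe", "se", "orient", "gamma", "sqgamma"),
            sigma))
}
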