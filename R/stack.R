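# Feature-stack construction: the configured filters evaluated across the
# scale ladder, plus the raw intensity plane.

#' Filter-bank configuration
#'
#' Defaults follow the optimized segmentation settings: Gaussian blur,
#' Hessian features, and membrane projections, with membrane thickness 1,
#' membrane patch size 19, minimum sigma 1 and maximum sigma 16.  Scales
#' form a powers-of-two ladder `sigma_min * 2^k <= sigma_max`, i.e.
#' `{1, 2, 4, 8, 16}` under the defaults.
#'
#' @param enabled_filters character vector of filter kinds (see
#'   [apply_filter()]); `"membrane"` is scale-free and controlled by
#'   `membrane_thickness` / `membrane_patch_size`.
#' @param sigma_min,sigma_max scale ladder bounds in pixels
#'   (`sigma_min >= 0.5`).
#' @param membrane_thickness,membrane_patch_size membrane kernel geometry
#'   (patch size odd, `>= thickness`).
#' @param hessian_t constant of the Hessian gamma measures.
#' @param hessian_det `"printed"` or `"standard"` determinant convention
#'   for the stack's determinant plane.
#' @param orientation_form `"atan2"` or `"arccos"` (see
#'   [hessian_features()]).
#' @param extra named list of extra per-kind parameters (e.g.
#'   `list(lipschitz = list(slope = 5/255))`).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(enabled_filters = c("gaussian", "hessian", "membrane"),
                          sigma_min = 1, sigma_max = 16,
                          membrane_thickness = 1, membrane_patch_size = 19,
                          hessian_t = 13 / 4,
                          hessian_det = "printed",
                          orientation_form = "atan2",
                          extra = list()) {
  assert_that(length(enabled_filters) >= 1, "config",
              "at least one filter must be enabled")
  bad <- setdiff(enabled_filters, .filter_kinds)
  assert_that(length(bad) == 0, "config",
              sprintf("unknown filter kinds: %s", paste(bad, collapse = ", ")))
  assert_that(sigma_min >= 0.5, "config", "sigma_min must be >= 0.5")
  assert_that(sigma_max >= sigma_min, "config", "sigma_max must be >= sigma_min")
  assert_that(membrane_patch_size %% 2 == 1 &&
                membrane_patch_size >= membrane_thickness, "config",
              "membrane patch size must be odd and >= thickness")
  structure(list(enabled_filters = enabled_filters,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 membrane_thickness = membrane_thickness,
                 membrane_patch_size = membrane_patch_size,
                 hessian_t = hessian_t, hessian_det = hessian_det,
                 orientation_form = orientation_form,
                 extra = extra),
            class = "filter_config")
}

#' Scale ladder of a filter configuration
#' @param cfg a [filter_config()].
#' @return numeric vector `sigma_min * 2^k` up to `sigma_max`.
#' @export
config_scales <- function(cfg) {
  s <- cfg$sigma_min * 2^(0:floor(log2(cfg$sigma_max / cfg$sigma_min)))
  s[s <= cfg$sigma_max]
}

#' Build the per-pixel feature stack
#'
#' Evaluates every enabled filter at every scale of the ladder (membrane
#' projections once, since they have their own geometry) and prepends the
#' raw intensity plane.  Construction is pure and deterministic: the same
#' image and configuration always yield a bit-identical stack.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param cfg a [filter_config()].
#' @return an object of class `feature_stack`: list with `planes` (array
#'   height x width x n_features), `feature_names`, `dims`.
#' @export
build_stack <- function(img, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  x <- unclass(img)
  attr(x, "pixels_per_mm") <- NULL
  scales <- config_scales(cfg)
  planes <- list(raw = x)
  for (kind in cfg$enabled_filters) {
    ex <- cfg$extra[[kind]]
    if (kind == "membrane") {
      planes <- c(planes, membrane_projections(
        x, thickness = cfg$membrane_thickness,
        patch_size = cfg$membrane_patch_size))
    } else if (kind == "hessian") {
      for (s in scales) {
        planes <- c(planes, hessian_planes(
          x, s, t = cfg$hessian_t, det = cfg$hessian_det,
          orientation_form = cfg$orientation_form))
      }
    } else if (kind == "dog") {
      # all ladder pairs sigma_a < sigma_b
      if (length(scales) >= 2) {
        for (i in seq_len(length(scales) - 1)) {
          for (j in (i + 1):length(scales)) {
            planes <- c(planes, filt_dog(x, scales[i], scales[j]))
          }
        }
      }
    } else if (kind %in% c("aniso_diffusion", "lipschitz")) {
      # scale-free filters
      planes <- c(planes, do.call(apply_filter, c(list(x, kind), ex)))
    } else {
      for (s in scales) {
        planes <- c(planes, do.call(apply_filter,
                                    c(list(x, kind, sigma = s), ex)))
      }
    }
  }
  nms <- names(planes)
  assert_that(!anyDuplicated(nms), "config", "duplicate feature names")
  arr <- array(0, c(nrow(x), ncol(x), length(planes)),
               dimnames = list(NULL, NULL, nms))
  for (i in seq_along(planes)) arr[, , i] <- planes[[i]]
  assert_that(all(is.finite(arr)), "config",
              "feature stack contains non-finite values")
  structure(list(planes = arr, feature_names = nms, dims = dim(x)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d x %d px, %d features\n",
              x$dims[1], x$dims[2], length(x$feature_names)))
  cat("  ", paste(utils::head(x$feature_names, 8), collapse = ", "),
      if (length(x$feature_names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of features in a stack
#' @param stack a [feature_stack()].
#' @export
n_features <- function(stack) length(stack$feature_names)

#' Extract the feature matrix for a set of pixel coordinates
#'
#' @param stack a [feature_stack()].
#' @param coords integer matrix of 0-based (row, col) coordinates.
#' @return numeric matrix, one row per coordinate, one column per feature.
#' @export
stack_features_at <- function(stack, coords) {
  npx <- prod(stack$dims)
  assert_that(all(coords[, 1] >= 0 & coords[, 1] < stack$dims[1] &
                    coords[, 2] >= 0 & coords[, 2] < stack$dims[2]),
              "annotation", "coordinates outside the stack")
  lin <- (coords[, 1] + 1L) + coords[, 2] * stack$dims[1]
  flat <- matrix(stack$planes, npx, n_features(stack))
  m <- flat[lin, , drop = FALSE]
  colnames(m) <- stack$feature_names
  m
}

#' Write a feature stack as a multi-page float TIFF for inspection
#'
#' Planes are affinely rescaled to `[0, 1]` per page (TIFF float pages
#' store the rescaled values; the original ranges go in the sidecar JSON).
#'
#' @param stack a [feature_stack()].
#' @param path output TIFF path; a `<path>.json` sidecar lists names and
#'   ranges.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(n_features(stack)), function(i) {
    p <- stack$planes[, , i]
    rng <- range(p)
    if (diff(rng) == 0) p * 0 else (p - rng[1]) / diff(rng)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  ranges <- t(vapply(seq_len(n_features(stack)),
                     function(i) range(stack$planes[, , i]), numeric(2)))
  jsonlite::write_json(
    data.frame(name = stack$feature_names, min = ranges[, 1], max = ranges[, 2]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
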