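# Calibrated synthetic photomicrograph-like scenes with exact ground
# truth.  Background tissue is a stationary correlated Gaussian field;
# each defect class is a set of elliptical blobs whose texture (mean,
# sd, correlation length, optional orientation) differs from the
# background, standing in for architectural / cytological anomaly
# regions.  Masks are recorded exactly as rasterized, so coverage ground
# truth is known to the pixel.

#' Default scene parameters
#'
#' A 1 mm x 2 mm field at 1000 px/mm scaled down by `shrink` (e.g.
#' `shrink = 4` gives 250 x 500 px), light textured background, and two
#' darker defect classes with distinct texture statistics.
#'
#' @param height,width scene size in px.
#' @param pixels_per_mm calibration (default 1000).
#' @param background list(mean, sd, corr) of the background field.
#' @param classes named list; per class list(mean, sd, corr, theta,
#'   n_blobs, ax_range, ay_range) — blob semi-axes are drawn uniformly
#'   from the ranges, `theta` tilts the texture anisotropy.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(height = 250, width = 500, pixels_per_mm = 1000,
                         background = list(mean = 0.62, sd = 0.05, corr = 2),
                         classes = list(
                           C1 = list(mean = 0.30, sd = 0.05, corr = 2,
                                     theta = 0, n_blobs = 3,
                                     ax_range = c(12, 30), ay_range = c(12, 30)),
                           C2 = list(mean = 0.85, sd = 0.05, corr = 4,
                                     theta = pi / 4, n_blobs = 2,
                                     ax_range = c(10, 24), ay_range = c(10, 24))
                         )) {
  structure(list(height = height, width = width,
                 pixels_per_mm = pixels_per_mm,
                 background = background, classes = classes),
            class = "scene_params")
}

# Stationary Gaussian field: white noise smoothed at `corr` px, rescaled
# to the requested mean/sd.  `theta` stretches the smoothing kernel (3:1)
# along one direction for oriented texture.
gaussian_field <- function(nr, nc, mean, sd, corr, theta = 0) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr > 0) {
    if (theta == 0) {
      z <- gauss_blur(z, corr)
    } else {
      # oriented texture: smooth along the rotated axis with a 2-D kernel
      r <- max(2L, as.integer(ceiling(3 * corr)))
      g <- expand.grid(gy = -r:r, gx = -r:r)
      u <- g$gx * cos(theta) + g$gy * sin(theta)
      v <- -g$gx * sin(theta) + g$gy * cos(theta)
      k <- exp(-(u^2 / (2 * (3 * corr)^2) + v^2 / (2 * corr^2)))
      z <- correlate2(z, matrix(k / sum(k), 2 * r + 1))
    }
    z <- (z - mean(z)) / stats::sd(z)
  }
  mean + sd * z
}

# Rasterize an axis-tilted ellipse; returns a logical matrix.
ellipse_mask <- function(nr, nc, cy, cx, ay, ax, phi = 0) {
  ys <- matrix(seq_len(nr), nr, nc) - cy
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  u <- xs * cos(phi) + ys * sin(phi)
  v <- -xs * sin(phi) + ys * cos(phi)
  (u / ax)^2 + (v / ay)^2 <= 1
}

#' Generate a synthetic calibrated scene with ground-truth masks
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return object of class `synthetic_scene`: `image` (a [gray_image()]),
#'   `truth_masks` (named list of disjoint logical matrices), `params`,
#'   `seed`.
#' @details Blob centres and semi-axes are drawn uniformly; a blob that
#'   would overlap an earlier class keeps only its unclaimed pixels, so
#'   masks stay mutually disjoint.  Classes with identical texture
#'   parameters trigger a warning (the scene is still generated) because
#'   no classifier can separate them.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  assert_that(params$height > 0 && params$width > 0, "parameter",
              "scene dimensions must be positive")
  sigs <- vapply(params$classes, function(cl)
    paste(cl$mean, cl$sd, cl$corr), "")
  if (anyDuplicated(c(sigs, paste(params$background$mean,
                                  params$background$sd,
                                  params$background$corr)))) {
    warning("two classes share identical texture parameters; they will be inseparable",
            call. = FALSE)
  }
  nr <- params$height; nc <- params$width
  set.seed(seed)
  bg <- params$background
  img <- gaussian_field(nr, nc, bg$mean, bg$sd, bg$corr)
  claimed <- matrix(FALSE, nr, nc)
  truth <- list()
  for (nm in names(params$classes)) {
    cl <- params$classes[[nm]]
    mask <- matrix(FALSE, nr, nc)
    n_blobs <- cl$n_blobs
    if (n_blobs > 0) {
      for (b in seq_len(n_blobs)) {
        ax <- stats::runif(1, cl$ax_range[1], cl$ax_range[2])
        ay <- stats::runif(1, cl$ay_range[1], cl$ay_range[2])
        # blobs must fit the frame with a 2 px margin
        ax <- min(ax, (nc - 5) / 2)
        ay <- min(ay, (nr - 5) / 2)
        cy <- stats::runif(1, ay + 2, nr - ay - 2)
        cx <- stats::runif(1, ax + 2, nc - ax - 2)
        phi <- stats::runif(1, 0, pi)
        mask <- mask | ellipse_mask(nr, nc, cy, cx, ay, ax, phi)
      }
    }
    mask <- mask & !claimed
    claimed <- claimed | mask
    truth[[nm]] <- mask
    if (any(mask)) {
      tex <- gaussian_field(nr, nc, cl$mean, cl$sd, cl$corr,
                            theta = if (is.null(cl$theta)) 0 else cl$theta)
      img[mask] <- tex[mask]
    }
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = gray_image(img, params$pixels_per_mm),
                 truth_masks = truth, params = params, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cov <- vapply(x$truth_masks, function(m) 100 * mean(m), 0)
  cat(sprintf("<synthetic_scene> %d x %d px (seed %d); truth coverage: %s\n",
              nrow(x$image), ncol(x$image), x$seed,
              paste(sprintf("%s %.2f%%", names(cov), cov), collapse = ", ")))
  invisible(x)
}

#' Ground-truth coverage percentages of a scene
#' @param scene a [generate_scene()] scene.
#' @return named numeric vector (percent of field per class).
#' @export
truth_coverage <- function(scene) {
  vapply(scene$truth_masks, function(m) 100 * mean(m), 0)
}

#' Sample sparse annotations from ground truth
#'
#' Emulates a pathologist circling small clusters: uniform sampling
#' without replacement inside each truth mask, with the unclaimed pixels
#' forming a `background` class.
#'
#' @param scene a [generate_scene()] scene.
#' @param n_per_class labeled pixels per class (including background).
#' @param seed RNG seed.
#' @param include_background add a background class (default `TRUE`).
#' @return a [label_set()].
#' @export
sample_labels <- function(scene, n_per_class = 100L, seed = 1L,
                          include_background = TRUE) {
  masks <- scene$truth_masks
  if (include_background) {
    bg <- Reduce(`|`, masks, matrix(FALSE, nrow(scene$image), ncol(scene$image)))
    masks <- c(list(background = !bg), masks)
  }
  set.seed(seed)
  coords <- lapply(names(masks), function(nm) {
    w <- which(masks[[nm]])
    assert_that(length(w) >= n_per_class, "parameter",
                sprintf("class '%s' has only %d pixels (< %d requested)",
                        nm, length(w), n_per_class))
    pick <- sort(sample(w, n_per_class))
    cbind(row = (pick - 1L) %% nrow(scene$image),
          col = (pick - 1L) %/% nrow(scene$image))
  })
  names(coords) <- names(masks)
  label_set(coords, dims = dim(scene$image))
}

#' Write a scene to disk in the package's annotation dialect
#'
#' Writes the image as PNG, the ground-truth masks as an indexed PNG +
#' JSON class table (readable by [read_labels()]), and the parameters
#' (including seed and calibration) as JSON.
#'
#' @param scene a [generate_scene()] scene.
#' @param dir output directory (created if missing).
#' @param stem file stem (default `"scene"`).
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_truth.png"))
  table_path <- file.path(dir, paste0(stem, "_classes.json"))
  params_path <- file.path(dir, paste0(stem, "_params.json"))
  png::writePNG(unclass(scene$image), img_path)
  idx <- matrix(0L, nrow(scene$image), ncol(scene$image))
  for (i in seq_along(scene$truth_masks)) idx[scene$truth_masks[[i]]] <- i
  png::writePNG(idx / 255, mask_path)
  jsonlite::write_json(
    data.frame(index = seq_along(scene$truth_masks),
               name = names(scene$truth_masks),
               color = grDevices::hcl.colors(
                 max(length(scene$truth_masks), 2L), "Dark 3"
               )[seq_along(scene$truth_masks)]),
    table_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = scene$seed, pixels_per_mm = scene$params$pixels_per_mm,
         height = scene$params$height, width = scene$params$width,
         background = scene$params$background,
         classes = scene$params$classes),
    params_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, classes = table_path,
              params = params_path))
}
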