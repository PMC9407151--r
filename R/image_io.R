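# Reading and writing images, sparse annotations, probability maps.
#
# Conventions (fixed for the whole package):
#   * pixel grids are numeric matrices, row-major view with origin top-left;
#     coordinates are 0-based (row, col) in LabelSet coordinates,
#     1-based when indexing R matrices;
#   * intensities live in [0, 1];
#   * physical calibration is pixels per millimetre (default 1000 px/mm,
#     i.e. a 1000 x 2000 px field is 1 mm x 2 mm).

#' Construct a calibrated grayscale image
#'
#' @param pixels numeric matrix with finite values in `[0, 1]`.
#' @param pixels_per_mm positive scalar calibration (px/mm), or `NULL` when
#'   the physical scale is unknown.
#' @return an object of class `gray_image`: the pixel matrix with attributes
#'   `pixels_per_mm`.
#' @export
gray_image <- function(pixels, pixels_per_mm = 1000) {
  assert_that(is.matrix(pixels) && is.numeric(pixels), "format",
              "pixels must be a numeric matrix")
  assert_that(all(is.finite(pixels)), "format",
              "image intensities must all be finite")
  assert_that(min(pixels) >= 0 && max(pixels) <= 1, "format",
              "image intensities must lie in [0, 1]")
  if (!is.null(pixels_per_mm)) {
    assert_that(is.numeric(pixels_per_mm) && length(pixels_per_mm) == 1 &&
                  pixels_per_mm > 0, "parameter",
                "pixels_per_mm must be a positive number")
  }
  structure(pixels, pixels_per_mm = pixels_per_mm, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  ppm <- attr(x, "pixels_per_mm")
  cat(sprintf("<gray_image> %d x %d px", nrow(x), ncol(x)))
  if (!is.null(ppm)) {
    cat(sprintf(" (%.3g x %.3g mm at %g px/mm, %.4g mm^2)",
                nrow(x) / ppm, ncol(x) / ppm, ppm, physical_area(x)))
  }
  cat(sprintf("; intensity range [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

#' Physical area of a calibrated image
#'
#' @param img a `gray_image`.
#' @return area in mm^2, or `NA` when no calibration is attached.
#' @export
physical_area <- function(img) {
  ppm <- attr(img, "pixels_per_mm")
  if (is.null(ppm)) return(NA_real_)
  nrow(img) * ncol(img) / ppm^2
}

# BT.601 luma weights for RGB -> gray collapse.
.luma <- c(0.299, 0.587, 0.114)

#' Read a PNG or TIFF image as a calibrated grayscale image
#'
#' RGB images are collapsed to luma with BT.601 weights (0.299, 0.587,
#' 0.114); an alpha channel, if present, is dropped.  Intensities are
#' rescaled to `[0, 1]` (the png/tiff readers already deliver that range
#' for 8- and 16-bit data).
#'
#' @param path image file (.png, .tif/.tiff).
#' @param pixels_per_mm calibration passed through to [gray_image()].
#' @return a [gray_image()].
#' @export
read_image <- function(path, pixels_per_mm = 1000) {
  assert_that(is.character(path) && length(path) == 1, "parameter",
              "path must be a single file path")
  assert_that(file.exists(path), "io", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop_frfseg("format", sprintf("unsupported image extension: '%s'", ext))
    ),
    error = function(e) {
      if (inherits(e, "frfseg_error")) stop(e)
      stop_frfseg("io", sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
    }
  )
  gray_image(collapse_gray(arr), pixels_per_mm = pixels_per_mm)
}

# Collapse a decoded raster array (matrix, or H x W x C) to a gray matrix.
collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  assert_that(length(dim(arr)) == 3, "format", "expected a 2-D raster")
  nch <- dim(arr)[3]
  if (nch == 2) arr <- arr[, , 1, drop = FALSE]            # gray + alpha
  if (nch == 4) arr <- arr[, , 1:3, drop = FALSE]          # RGB + alpha
  nch <- dim(arr)[3]
  if (nch == 1) return(arr[, , 1])
  assert_that(nch == 3, "format",
              sprintf("unsupported channel count: %d", dim(arr)[3]))
  .luma[1] * arr[, , 1] + .luma[2] * arr[, , 2] + .luma[3] * arr[, , 3]
}

#' Construct a sparse annotation set
#'
#' A `label_set` holds, per class, the 0-based (row, col) coordinates of
#' annotated pixels — the serialized form of the clusters a pathologist
#' circles on the image.
#'
#' @param coords named list of integer matrices with columns `row`, `col`
#'   (0-based); names are the class names, in order.
#' @param colors optional character vector of display colors per class.
#' @param dims optional `c(height, width)` used to bound-check coordinates.
#' @return an object of class `label_set`.
#' @export
label_set <- function(coords, colors = NULL, dims = NULL) {
  assert_that(is.list(coords) && !is.null(names(coords)) &&
                all(nzchar(names(coords))), "annotation",
              "coords must be a named list of coordinate matrices")
  assert_that(!anyDuplicated(names(coords)), "annotation",
              "duplicate class names")
  coords <- lapply(coords, function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("row", "col")))
    m
  })
  if (!is.null(dims)) {
    for (nm in names(coords)) {
      m <- coords[[nm]]
      assert_that(all(m[, 1] >= 0 & m[, 1] < dims[1] &
                        m[, 2] >= 0 & m[, 2] < dims[2]), "annotation",
                  sprintf("class '%s' has coordinates outside the image", nm))
    }
  }
  all_keys <- unlist(lapply(coords, function(m) m[, 1] * 1e9 + m[, 2]))
  assert_that(!anyDuplicated(all_keys), "annotation",
              "a pixel is annotated with two classes")
  if (is.null(colors)) {
    colors <- grDevices::hcl.colors(max(length(coords), 2L), "Dark 3")[seq_along(coords)]
  }
  structure(list(classes = names(coords), coords = coords,
                 colors = stats::setNames(colors, names(coords)),
                 dims = dims),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d classes: %s\n", length(x$classes),
              paste(sprintf("%s (%d px)", x$classes,
                            vapply(x$coords, nrow, 0L)), collapse = ", ")))
  invisible(x)
}

#' Number of labeled pixels per class
#' @param labels a [label_set()].
#' @return named integer vector.
#' @export
label_counts <- function(labels) {
  vapply(labels$coords, nrow, 0L)
}

#' Read annotations from an indexed mask and a class table
#'
#' The mask is an 8-bit grayscale PNG whose pixel value is the class index
#' (0 = unlabeled); the class table is a JSON array of records
#' `{"index": i, "name": "...", "color": "#rrggbb"}`.
#'
#' @param mask_path indexed-mask PNG.
#' @param class_table_path JSON class table.
#' @param dims optional `c(height, width)` of the image the mask annotates;
#'   a mismatch raises an annotation error.
#' @return a [label_set()].
#' @export
read_labels <- function(mask_path, class_table_path, dims = NULL) {
  assert_that(file.exists(mask_path), "io",
              sprintf("mask file not found: %s", mask_path))
  assert_that(file.exists(class_table_path), "io",
              sprintf("class table not found: %s", class_table_path))
  mask <- png::readPNG(mask_path)
  if (!is.matrix(mask)) mask <- collapse_gray(mask)
  idx <- matrix(as.integer(round(mask * 255)), nrow(mask), ncol(mask))
  if (!is.null(dims)) {
    assert_that(all(dim(idx) == dims), "annotation",
                sprintf("mask is %d x %d but image is %d x %d",
                        nrow(idx), ncol(idx), dims[1], dims[2]))
  }
  tab <- jsonlite::fromJSON(class_table_path, simplifyDataFrame = TRUE)
  assert_that(is.data.frame(tab) && all(c("index", "name") %in% names(tab)),
              "annotation", "class table must have 'index' and 'name' fields")
  present <- sort(setdiff(unique(as.vector(idx)), 0L))
  missing <- setdiff(present, tab$index)
  assert_that(length(missing) == 0, "annotation",
              sprintf("mask indices absent from class table: %s",
                      paste(missing, collapse = ", ")))
  tab <- tab[tab$index %in% present, , drop = FALSE]
  tab <- tab[order(tab$index), , drop = FALSE]
  coords <- lapply(tab$index, function(i) {
    w <- which(idx == i, arr.ind = TRUE)
    cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
  })
  names(coords) <- tab$name
  if (length(coords) == 0) {
    return(structure(list(classes = character(), coords = list(),
                          colors = character(), dims = dim(idx)),
                     class = "label_set"))
  }
  label_set(coords,
            colors = if ("color" %in% names(tab)) tab$color else NULL,
            dims = dim(idx))
}

#' Write annotations as indexed mask + class table
#'
#' Inverse of [read_labels()].
#'
#' @param labels a [label_set()]; must carry `dims`.
#' @param mask_path,class_table_path output paths.
#' @return invisibly, the two paths.
#' @export
write_labels <- function(labels, mask_path, class_table_path) {
  assert_that(!is.null(labels$dims), "annotation",
              "label_set has no dims; cannot rasterize the mask")
  idx <- matrix(0L, labels$dims[1], labels$dims[2])
  for (i in seq_along(labels$classes)) {
    m <- labels$coords[[i]]
    idx[cbind(m[, 1] + 1L, m[, 2] + 1L)] <- i
  }
  png::writePNG(idx / 255, mask_path)
  tab <- data.frame(index = seq_along(labels$classes),
                    name = labels$classes,
                    color = unname(labels$colors))
  jsonlite::write_json(tab, class_table_path, auto_unbox = TRUE, digits = NA)
  invisible(c(mask_path, class_table_path))
}

#' Write a probability map as a multi-page float TIFF
#'
#' One 32-bit float page per class, in class order.  Optionally also writes
#' an 8-bit PNG preview per class with probability 1 rendered white.
#'
#' @param prob a [prob_map()].
#' @param path output TIFF path.
#' @param png_preview optional path *prefix*; previews are written as
#'   `<prefix>_<class>.png`.
#' @return invisibly, the TIFF path.
#' @export
write_probability_map <- function(prob, path, png_preview = NULL) {
  stopifnot(inherits(prob, "prob_map"))
  assert_that(all(is.finite(prob$planes)), "serialization",
              "probability map contains non-finite values")
  pages <- lapply(seq_along(prob$class_names), function(k) prob$planes[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!is.null(png_preview)) {
    for (k in seq_along(prob$class_names)) {
      png::writePNG(pages[[k]],
                    paste0(png_preview, "_", prob$class_names[k], ".png"))
    }
  }
  invisible(path)
}

#' Read a multi-page probability TIFF back into a `prob_map`
#'
#' @param path TIFF written by [write_probability_map()].
#' @param class_names class names for the pages, in page order.
#' @export
read_probability_map <- function(path, class_names) {
  assert_that(file.exists(path), "io", sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  assert_that(length(pages) == length(class_names), "format",
              "page count does not match class_names")
  planes <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) planes[, , k] <- pages[[k]]
  prob_map(planes, class_names, normalize = FALSE)
}
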