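# Defect quantification: threshold a probability plane into a binary
# defect mask, then convert pixel counts into coverage percent and
# physical extension via the px/mm calibration.

#' Threshold one class plane of a probability map
#'
#' @param prob a [prob_map()].
#' @param class class name.
#' @param thr threshold in `[0, 1]`; pixels with probability `>= thr`
#'   (inclusive, for bit-exact reproducibility) enter the mask.
#' @return logical matrix.
#' @export
threshold_probability <- function(prob, class, thr = 0.5) {
  stopifnot(inherits(prob, "prob_map"))
  assert_that(class %in% prob$class_names, "parameter",
              sprintf("unknown class '%s'", class))
  assert_that(is.numeric(thr) && length(thr) == 1 && thr >= 0 && thr <= 1,
              "parameter", "thr must be in [0, 1]")
  prob_plane(prob, class) >= thr
}

#' Coverage and physical extension of a defect mask
#'
#' @param mask logical matrix (a thresholded probability plane).
#' @param img the [gray_image()] the mask refers to (same dimensions);
#'   supplies the px/mm calibration.
#' @param class,threshold optional metadata recorded in the report row.
#' @return one-row data.frame: `class`, `threshold`, `covered_pixels`,
#'   `total_pixels`, `coverage_percent` (0-100), `extension_mm2` (`NA`
#'   with a warning when the image carries no calibration),
#'   `physical_area_mm2`.
#' @export
coverage_report <- function(mask, img, class = NA_character_,
                            threshold = NA_real_) {
  assert_that(is.logical(mask) && is.matrix(mask), "parameter",
              "mask must be a logical matrix")
  assert_that(all(dim(mask) == dim(img)), "parameter",
              "mask dimensions must equal image dimensions")
  covered <- sum(mask)
  total <- length(mask)
  pct <- 100 * covered / total
  area <- physical_area(img)
  ext <- if (is.na(area)) {
    warning("image has no px/mm calibration; extension_mm2 omitted",
            call. = FALSE)
    NA_real_
  } else {
    (pct / 100) * area
  }
  data.frame(class = class, threshold = threshold,
             covered_pixels = covered, total_pixels = total,
             coverage_percent = pct, extension_mm2 = ext,
             physical_area_mm2 = area)
}

#' Full defect report for a probability map
#'
#' Thresholds every class plane and assembles one row per class.
#'
#' @param prob a [prob_map()].
#' @param img the source [gray_image()].
#' @param thresholds single threshold or named per-class vector.
#' @param image_id optional identifier column.
#' @return object of class `defect_report` (a data.frame).
#' @export
defect_report <- function(prob, img, thresholds = 0.5, image_id = NA_character_) {
  stopifnot(inherits(prob, "prob_map"))
  if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length(prob$class_names)),
                                  prob$class_names)
  }
  assert_that(all(prob$class_names %in% names(thresholds)), "parameter",
              "thresholds must cover every class")
  rows <- lapply(prob$class_names, function(cl) {
    thr <- unname(thresholds[cl])
    coverage_report(threshold_probability(prob, cl, thr), img,
                    class = cl, threshold = thr)
  })
  out <- do.call(rbind, rows)
  out <- cbind(image_id = image_id, out)
  class(out) <- c("defect_report", "data.frame")
  out
}

#' @export
print.defect_report <- function(x, ...) {
  cat("Defect coverage report")
  if (!all(is.na(x$image_id))) cat(" for ", x$image_id[1], sep = "")
  cat("\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s thr %.2f: %5.1f%% of field", x$class[i],
                x$threshold[i], x$coverage_percent[i]))
    if (!is.na(x$extension_mm2[i])) {
      cat(sprintf(", %.3f mm^2", x$extension_mm2[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write a defect report as CSV and/or JSON
#'
#' CSV holds one row per class (percentages at full precision); JSON adds
#' provenance fields (`seed`, `config_hash`) when supplied.
#'
#' @param report a [defect_report()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @param provenance optional named list merged into the JSON payload.
#' @export
write_defect_report <- function(report, csv_path = NULL, json_path = NULL,
                                provenance = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- c(list(report = as.data.frame(report)), provenance)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}
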