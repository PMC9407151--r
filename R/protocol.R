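# End-to-end protocol: stack -> train -> predict -> threshold -> report,
# with artifacts and provenance on disk.  This is the function behind the
# command-line runner.

#' Assemble a run configuration
#'
#' @param image_path input image (PNG/TIFF).
#' @param mask_path,class_table_path annotation mask + class table (see
#'   [read_labels()]).
#' @param out_dir output directory for artifacts.
#' @param filter_cfg a [filter_config()].
#' @param n_trees,mtry forest hyperparameters.
#' @param thresholds single or named per-class threshold(s).
#' @param pixels_per_mm calibration (default 1000 px/mm).
#' @param seed RNG seed, recorded in every output.
#' @return list of class `run_config`.
#' @export
run_config <- function(image_path, mask_path, class_table_path,
                       out_dir = ".", filter_cfg = filter_config(),
                       n_trees = 200L, mtry = NULL, thresholds = 0.5,
                       pixels_per_mm = 1000, seed = 1L) {
  structure(list(image_path = image_path, mask_path = mask_path,
                 class_table_path = class_table_path, out_dir = out_dir,
                 filter_cfg = filter_cfg, n_trees = n_trees, mtry = mtry,
                 thresholds = thresholds, pixels_per_mm = pixels_per_mm,
                 seed = seed),
            class = "run_config")
}

# Canonical JSON of a config, and its md5 (the provenance hash embedded
# in every artifact).
config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                   force = TRUE)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(config_json(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the full classification protocol
#'
#' Reads the image and annotations, builds the feature stack, trains the
#' forest, predicts class and probability maps, thresholds each class,
#' and writes: the class map (indexed PNG), per-class probability maps
#' (float TIFF + PNG previews), the serialized model, a learning curve
#' CSV, and the defect report (CSV + JSON with seed and config hash).
#'
#' @param cfg a [run_config()].
#' @param verbose log stage progress to stderr (default `TRUE`).
#' @return the [defect_report()] (invisibly also written to disk).
#' @export
run_protocol <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(cfg)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  say("[io] reading image %s", cfg$image_path)
  img <- read_image(cfg$image_path, pixels_per_mm = cfg$pixels_per_mm)
  say("[io] reading annotations %s", cfg$mask_path)
  labels <- read_labels(cfg$mask_path, cfg$class_table_path, dims = dim(img))
  assert_that(length(labels$classes) >= 2, "annotation",
              "need at least two annotated classes")

  say("[stack] building feature stack (%s)",
      paste(cfg$filter_cfg$enabled_filters, collapse = "+"))
  stack <- build_stack(img, cfg$filter_cfg)
  say("[stack] %d features", n_features(stack))

  say("[train] %d trees, seed %d", cfg$n_trees, cfg$seed)
  model <- frf_train(stack, labels, n_trees = cfg$n_trees, mtry = cfg$mtry,
                     seed = cfg$seed)
  say("[train] training accuracy %.4f", model$training_accuracy)

  say("[predict] class + probability maps")
  pred <- predict(model, stack)

  say("[evaluate] learning curve")
  n_lab <- sum(label_counts(labels))
  sched <- unique(pmin(round(seq(10, n_lab, length.out = 6)), n_lab))
  curve <- learning_curve(stack, labels, sched, seed = cfg$seed,
                          n_trees = min(cfg$n_trees, 50L))

  say("[quantify] thresholding + coverage")
  report <- defect_report(pred$prob, img, thresholds = cfg$thresholds,
                          image_id = basename(cfg$image_path))

  # artifacts
  pm <- file.path(cfg$out_dir, "probability_maps.tif")
  write_probability_map(pred$prob, pm,
                        png_preview = file.path(cfg$out_dir, "prob"))
  png::writePNG(pred$class_map / 255,
                file.path(cfg$out_dir, "class_map.png"))
  write_frf(model, file.path(cfg$out_dir, "model.json"))
  write_curve(curve, file.path(cfg$out_dir, "learning_curve.csv"))
  prov <- list(seed = cfg$seed, config_hash = hash,
               package_version = as.character(utils::packageVersion("frfseg")))
  write_defect_report(report,
                      csv_path = file.path(cfg$out_dir, "report.csv"),
                      json_path = file.path(cfg$out_dir, "report.json"),
                      provenance = prov)
  jsonlite::write_json(c(list(config = unclass(cfg)), prov),
                       file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("[done] report in %s", cfg$out_dir)
  invisible(report)
}
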