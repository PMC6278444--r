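#' Pipeline run configuration
#'
#' One nested list drives the whole pipeline: study geometry, segmentation,
#' preprocessing, wavelength selection, classifiers, split and seeds. All
#' randomness flows from `master_seed`; the configuration round-trips
#' through YAML unchanged.
#'
#' @param preset `"desk"` (64x64 px, 6 scenes per class-grade group, 300
#'   k-means groups — runs in minutes) or `"paper"` (full study layout:
#'   200x200 px scenes, 30 scenes per group, 3000 k-means groups).
#' @param ... Named overrides of any top-level field.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    bands = 200L,
    wavelength_range = c(975, 1646),
    image_shape = if (preset == "desk") c(64L, 64L) else c(200L, 200L),
    n_objects = if (preset == "desk") 4L else 12L,
    scenes_per_group = if (preset == "desk") 6L else 30L,
    segmentation = list(band_nm = 1119, threshold = 0.122),
    preprocessing = list(wavelet = "db7", level = 3L),
    selection = list(method = "pca_loadings",
                     n_select_object = 20L, n_select_pixel = 17L),
    classifiers = c("svm", "knn", "rbfnn"),
    svm = list(log2_step = if (preset == "desk") 2 else 1, cv_folds = 5L),
    knn = list(k = 3L),
    rbfnn = list(tune = TRUE),
    n_groups = if (preset == "desk") 300L else 3000L,
    split_ratio = 2 / 3,
    master_seed = 1L
  )
  override <- list(...)
  base[names(override)] <- override
  structure(base, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_fields <- c("bands", "n_objects", "scenes_per_group", "n_groups",
                  "master_seed")
  for (f in int_fields) if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  if (!is.null(cfg$image_shape)) cfg$image_shape <- as.integer(cfg$image_shape)
  structure(cfg, class = "run_config")
}

classifier_specs_from_config <- function(config) {
  step <- config$svm$log2_step %||% 1
  specs <- list(
    svm = list(kind = "svm",
               config = svm_config(log2C = seq(-8, 8, by = step),
                                   log2gamma = seq(-8, 8, by = step),
                                   cv_folds = config$svm$cv_folds %||% 5L)),
    knn = list(kind = "knn", config = knn_config(k = config$knn$k %||% 3L)),
    rbfnn = list(kind = "rbfnn", tune = isTRUE(config$rbfnn$tune),
                 config = rbfnn_config(config$rbfnn$spread %||% 3))
  )
  specs[intersect(config$classifiers, names(specs))]
}

log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full pipeline
#'
#' simulate -> correct -> segment -> preprocess -> select wavelengths ->
#' train -> evaluate (four-way) -> prediction map, writing every artifact
#' (selection CSVs with provenance, report CSV/JSON, map PNG and label
#' raster, JSON-lines log, the config itself) into `out_dir`. Deterministic
#' given `config$master_seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `selection_object`,
#'   `selection_pixel`, `four_way`, `map`, `split`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("hsirun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log.jsonl"), "w")
  on.exit(close(logf))
  write_run_config(config, file.path(out_dir, "config.yml"))
  seed <- config$master_seed

  study <- generate_study(scenes_per_group = config$scenes_per_group,
                          master_seed = seed,
                          bands = config$bands,
                          wavelength_range = config$wavelength_range,
                          image_shape = config$image_shape,
                          n_objects = config$n_objects)
  log_line(logf, "simulate", n_scenes = length(study$scenes))

  pixels_raw <- extract_study_spectra(
    study, band_nm = config$segmentation$band_nm,
    threshold = config$segmentation$threshold)
  log_line(logf, "extract", n_pixels = nrow(pixels_raw$spectra))

  pixels <- preprocess_pixels(pixels_raw, level = config$preprocessing$level)
  objects <- average_by_object(pixels)
  log_line(logf, "preprocess", n_pixels = nrow(pixels$spectra),
           n_objects = nrow(objects$spectra), stage = pixels$stage)

  split <- split_scenes(study$meta, seed = derive_seed(seed, 1L),
                        ratio = config$split_ratio)
  log_line(logf, "split", n_calibration = length(split$calibration),
           n_prediction = length(split$prediction))

  obj_cal <- subset_table(objects,
                          objects$meta$scene_id %in% split$calibration)
  pix_cal <- subset_table(pixels,
                          pixels$meta$scene_id %in% split$calibration)
  wl <- pixels$wavelengths

  sel_fun <- function(tab, n_select, seed_i) {
    if (config$selection$method == "ica_weights") {
      m <- ica_fit(tab$spectra, n_components = 7L,
                   seed = derive_seed(seed, seed_i))
      select_by_ica_weights(m, wl, n_select)
    } else {
      m <- pca_fit(tab$spectra, stage = tab$stage)
      select_by_pca_loadings(m, wl, n_select)
    }
  }
  sel_obj <- sel_fun(obj_cal, config$selection$n_select_object, 2L)
  sel_pix <- sel_fun(pix_cal, config$selection$n_select_pixel, 3L)
  prov <- list(master_seed = seed, preset = config$preset,
               package_version = as.character(utils::packageVersion("hsichem")))
  write_selection(sel_obj, file.path(out_dir, "selection_object.csv"), prov)
  write_selection(sel_pix, file.path(out_dir, "selection_pixel.csv"), prov)
  log_line(logf, "select", n_object = nrow(sel_obj$selected),
           n_pixel = nrow(sel_pix$selected))

  features <- sel_obj$selected$band_index
  specs <- classifier_specs_from_config(config)
  fw <- run_four_way(pixels, objects, split, features, specs,
                     n_groups = config$n_groups,
                     seed = derive_seed(seed, 4L))
  utils::write.csv(fw$summary, file.path(out_dir, "four_way_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(fw$summary, file.path(out_dir, "four_way_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_line(logf, "evaluate", n_reports = nrow(fw$summary),
           n_representative = fw$n_representative)

  # prediction map for the first prediction scene, pixel-trained SVM
  first_pred <- which(study$meta$scene_id == split$prediction[1L])
  sc <- study$scenes[[first_pred]]
  corr <- correct_reflectance(sc$raw, sc$refs)
  om <- label_objects(segment_background(corr, config$segmentation$band_nm,
                                         config$segmentation$threshold))
  pix_model_spec <- specs[[1L]]
  pix_cal_rows <- which(pixels$meta$scene_id %in% split$calibration)
  Xr <- feature_matrix(pix_cal, features)
  rep_idx <- select_representative_pixels(Xr, config$n_groups,
                                          seed = derive_seed(seed, 5L))
  clf <- train_classifier(Xr[rep_idx, , drop = FALSE],
                          pix_cal$meta$class[rep_idx], pix_model_spec,
                          seed = derive_seed(seed, 6L))
  clf$stage <- "wt+snv"
  pm <- prediction_map(clf, corr, om, features,
                       level = config$preprocessing$level)
  render_prediction_map(pm$map, file.path(out_dir, "prediction_map.png"))
  utils::write.table(ifelse(is.na(pm$map), 0L, pm$map),
                     file.path(out_dir, "prediction_map_labels.txt"),
                     row.names = FALSE, col.names = FALSE)
  log_line(logf, "map", scene = split$prediction[1L],
           n_pixels = sum(!is.na(pm$map)))

  invisible(list(selection_object = sel_obj, selection_pixel = sel_pix,
                 four_way = fw, map = pm, split = split, study = study))
}
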