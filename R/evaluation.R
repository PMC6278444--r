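#' Scene-level calibration/prediction split
#'
#' Splits scenes 2:1 within every class-grade group (floor(2n/3) scenes to
#' calibration), so no scene — and therefore no pixel — leaks across sets.
#'
#' @param scene_meta Data frame with columns `scene_id`, `class`, `grade`
#'   (e.g. the `meta` element of a `scene_study`).
#' @param seed Split seed.
#' @param ratio Calibration fraction (default 2/3).
#' @return List with `calibration` and `prediction` scene-id vectors.
#' @export
split_scenes <- function(scene_meta, seed = 1L, ratio = 2 / 3) {
  stopifnot(all(c("scene_id", "class", "grade") %in% names(scene_meta)))
  groups <- split(scene_meta$scene_id,
                  paste(scene_meta$class, scene_meta$grade))
  if (any(vapply(groups, length, integer(1)) < 3L))
    stop("every class-grade group needs at least 3 scenes to split 2:1",
         call. = FALSE)
  with_seed(seed, {
    cal <- unlist(lapply(groups, function(ids) {
      n_cal <- floor(length(ids) * ratio)
      sample(ids, n_cal)
    }), use.names = FALSE)
  })
  list(calibration = cal,
       prediction = setdiff(scene_meta$scene_id, cal))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity from per-class correct/total
#' counts in the two-class convention: sensitivity is the classification
#' accuracy of the positive (first-variety) class, specificity that of the
#' other class.
#'
#' @param correct_pos,total_pos Correct and total counts, positive class.
#' @param correct_neg,total_neg Correct and total counts, other class.
#' @return List: `accuracy` (percent), `sensitivity`, `specificity`,
#'   `counts` (data frame in numerator/denominator form).
#' @export
metrics_from_counts <- function(correct_pos, total_pos, correct_neg,
                                total_neg) {
  list(accuracy = 100 * (correct_pos + correct_neg) /
         (total_pos + total_neg),
       sensitivity = correct_pos / total_pos,
       specificity = correct_neg / total_neg,
       counts = data.frame(
         class = c("positive", "negative"),
         correct = c(correct_pos, correct_neg),
         total = c(total_pos, total_neg),
         shown = c(sprintf("%d/%d", correct_pos, total_pos),
                   sprintf("%d/%d", correct_neg, total_neg))))
}

#' Evaluate a classifier on labeled spectra
#'
#' @param model An `hsi_classifier`.
#' @param X Feature matrix.
#' @param y True class labels.
#' @param positive_class Class whose per-class accuracy is reported as
#'   sensitivity (default: the model's first class).
#' @param mode Optional descriptor (e.g. `"object->object"`).
#' @return An `evaluation_report`: metrics, counts, mode, model params.
#' @export
evaluate <- function(model, X, y, positive_class = NULL, mode = NULL) {
  stopifnot(inherits(model, "hsi_classifier"))
  y <- as.character(y)
  if (!all(y %in% model$classes))
    stop("labels contain classes unseen by the model: ",
         paste(setdiff(unique(y), model$classes), collapse = ", "),
         call. = FALSE)
  positive_class <- positive_class %||% model$classes[1L]
  if (!positive_class %in% model$classes)
    stop("positive_class not among model classes", call. = FALSE)
  pred <- as.character(predict(model, X))
  pos <- y == positive_class
  m <- metrics_from_counts(sum(pred[pos] == y[pos]), sum(pos),
                           sum(pred[!pos] == y[!pos]), sum(!pos))
  m$counts$class <- c(positive_class,
                      paste(setdiff(model$classes, positive_class),
                            collapse = "/"))
  structure(list(mode = mode, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 counts = m$counts, n = length(y),
                 positive_class = positive_class,
                 params = model$params),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s acc %.2f%%, sens %.3f, spec %.3f (n=%d)\n",
              if (is.null(x$mode)) "" else paste0(" [", x$mode, "]"),
              x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

subset_table <- function(table, rows) {
  out <- table
  out$spectra <- table$spectra[rows, , drop = FALSE]
  out$meta <- table$meta[rows, , drop = FALSE]
  out
}

feature_matrix <- function(table, features) {
  table$spectra[, features, drop = FALSE]
}

#' Grade-transfer experiment
#'
#' Trains one classifier per grade on all spectra of that grade (both
#' classes) and predicts every grade, yielding a 3x3 grid of reports whose
#' diagonal is resubstitution on the calibration grade.
#'
#' @param table A `pixel_spectra` or `object_spectra` table with grade
#'   labels covering the three grades.
#' @param features Band indices to use as features.
#' @param spec Classifier spec for [train_classifier()].
#' @param positive_class Sensitivity class (default: first class level).
#' @param seed Seed for any CV inside training.
#' @return List with `reports` (3x3 list indexed `[[train]][[predict]]`)
#'   and `summary` (data frame: train_grade, predict_grade, accuracy,
#'   sensitivity, specificity).
#' @export
run_grade_transfer <- function(table, features, spec,
                               positive_class = NULL, seed = 1L) {
  grades <- c("Grade1", "Grade2", "Grade3")
  if (!all(grades %in% table$meta$grade))
    stop("grade-transfer needs all three grades present; missing: ",
         paste(setdiff(grades, unique(table$meta$grade)), collapse = ", "),
         call. = FALSE)
  X <- feature_matrix(table, features)
  reports <- stats::setNames(vector("list", 3L), grades)
  rows <- list()
  for (g in grades) {
    tr <- table$meta$grade == g
    clf <- train_classifier(X[tr, , drop = FALSE], table$meta$class[tr],
                            spec, seed = seed)
    reports[[g]] <- stats::setNames(vector("list", 3L), grades)
    for (h in grades) {
      te <- table$meta$grade == h
      rep_gh <- evaluate(clf, X[te, , drop = FALSE],
                         table$meta$class[te],
                         positive_class = positive_class,
                         mode = paste0(g, "->", h))
      reports[[g]][[h]] <- rep_gh
      rows[[length(rows) + 1L]] <- data.frame(
        train_grade = g, predict_grade = h,
        accuracy = rep_gh$accuracy, sensitivity = rep_gh$sensitivity,
        specificity = rep_gh$specificity, n = rep_gh$n)
    }
  }
  list(reports = reports, summary = do.call(rbind, rows))
}

#' Four-way pixel/object evaluation
#'
#' Crosses calibration level and prediction level: classifiers trained on
#' representative pixel spectra or on object-wise mean spectra, each
#' predicting pixel rows and object rows of the held-out scenes. A
#' pixel-trained model predicts an object by scoring the object's average
#' preprocessed spectrum; an object-trained model predicts pixel rows
#' directly. Calibration metrics are resubstitution on the training rows,
#' so they repeat between the two prediction levels of the same model.
#'
#' @param pixels Preprocessed `pixel_spectra` table (all scenes).
#' @param objects Matching `object_spectra` table.
#' @param split Output of [split_scenes()].
#' @param features Band indices to use as features.
#' @param specs Named list of classifier specs (e.g. svm/knn/rbfnn) for
#'   [train_classifier()].
#' @param n_groups Representative-pixel clusters per class
#'   (see [select_representative_pixels()]).
#' @param positive_class Sensitivity class.
#' @param seed Seed (folds, k-means).
#' @return List with `reports` (per classifier, per mode: calibration and
#'   prediction `evaluation_report`s) and `summary` data frame.
#' @export
run_four_way <- function(pixels, objects, split, features, specs,
                         n_groups = 300L, positive_class = NULL,
                         seed = 1L) {
  stopifnot(inherits(pixels, "pixel_spectra"),
            inherits(objects, "object_spectra"))
  pix_cal <- subset_table(pixels, pixels$meta$scene_id %in%
                            split$calibration)
  pix_pre <- subset_table(pixels, pixels$meta$scene_id %in%
                            split$prediction)
  obj_cal <- subset_table(objects, objects$meta$scene_id %in%
                            split$calibration)
  obj_pre <- subset_table(objects, objects$meta$scene_id %in%
                            split$prediction)
  # representative pixels, selected per class over all grades
  rep_rows <- function(tab, off) {
    unlist(lapply(sort(unique(tab$meta$class)), function(cl) {
      rows <- which(tab$meta$class == cl)
      Xcl <- feature_matrix(subset_table(tab, rows), features)
      rows[select_representative_pixels(Xcl, n_groups,
                                        seed = derive_seed(seed, off +
                                                             match(cl, sort(unique(tab$meta$class)))))]
    }), use.names = FALSE)
  }
  pix_cal_rep <- subset_table(pix_cal, rep_rows(pix_cal, 0L))
  pix_pre_rep <- subset_table(pix_pre, rep_rows(pix_pre, 10L))

  sets <- list(
    pixel = list(cal = list(X = feature_matrix(pix_cal_rep, features),
                            y = pix_cal_rep$meta$class),
                 pre = list(X = feature_matrix(pix_pre_rep, features),
                            y = pix_pre_rep$meta$class)),
    object = list(cal = list(X = feature_matrix(obj_cal, features),
                             y = obj_cal$meta$class),
                  pre = list(X = feature_matrix(obj_pre, features),
                             y = obj_pre$meta$class)))

  reports <- list()
  rows <- list()
  for (nm in names(specs)) {
    for (train_level in c("pixel", "object")) {
      tr <- sets[[train_level]]$cal
      clf <- train_classifier(tr$X, tr$y, specs[[nm]],
                              seed = derive_seed(seed, 100L))
      cal_rep <- evaluate(clf, tr$X, tr$y, positive_class,
                          mode = paste0(train_level, " calibration"))
      for (pred_level in c("pixel", "object")) {
        te <- sets[[pred_level]]$pre
        mode <- paste0(train_level, "->", pred_level)
        pre_rep <- evaluate(clf, te$X, te$y, positive_class, mode = mode)
        reports[[nm]][[mode]] <- list(calibration = cal_rep,
                                      prediction = pre_rep)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, mode = mode,
          cal_accuracy = cal_rep$accuracy,
          cal_sensitivity = cal_rep$sensitivity,
          cal_specificity = cal_rep$specificity,
          pre_accuracy = pre_rep$accuracy,
          pre_sensitivity = pre_rep$sensitivity,
          pre_specificity = pre_rep$specificity,
          n_pre = pre_rep$n)
      }
    }
  }
  list(reports = reports, summary = do.call(rbind, rows),
       n_representative = nrow(pix_cal_rep$spectra))
}

#' Per-pixel prediction map
#'
#' Predicts the class of every labeled pixel of a scene with a
#' pixel-trained model and paints the predictions back into the raster.
#' Background pixels are `NA`. The raster agrees row-for-row with the
#' tabular predictions by construction.
#'
#' @param model A pixel-trained `hsi_classifier`.
#' @param cube Corrected [hsi_cube] of the scene.
#' @param objmask The scene's `object_mask`.
#' @param features Band indices the model was trained on.
#' @param level Wavelet depth used for preprocessing.
#' @return List: `map` (integer matrix of class codes, `NA` background),
#'   `classes` (code-to-label mapping), `predictions` (factor),
#'   `meta` (pixel coordinates).
#' @export
prediction_map <- function(model, cube, objmask, features, level = 3L) {
  tab <- extract_pixel_spectra(cube, objmask)
  if (identical(model$stage, "wt+snv") || is.null(model$stage))
    tab <- preprocess_pixels(tab, level = level)
  X <- feature_matrix(tab, features)
  check_features(model, X, stage = tab$stage)
  pred <- predict(model, X)
  map <- matrix(NA_integer_, nrow(objmask$labels), ncol(objmask$labels))
  map[cbind(tab$meta$row, tab$meta$col)] <- as.integer(pred)
  list(map = map, classes = model$classes, predictions = pred,
       meta = tab$meta)
}

#' Render a prediction map (or scores image) to PNG
#'
#' Two-class maps use a fixed red/blue colormap on a dark background;
#' continuous rasters (scores images) are min-max scaled to a gray ramp —
#' display-only scaling.
#'
#' @param map Integer class raster or numeric score raster.
#' @param file PNG path.
#' @return `file`, invisibly.
#' @export
render_prediction_map <- function(map, file) {
  nr <- nrow(map); nc <- ncol(map)
  img <- array(0, dim = c(nr, nc, 3L))
  if (is.integer(map) || all(map[!is.na(map)] %in% c(1, 2))) {
    cols <- rbind(c(0.85, 0.20, 0.15), c(0.15, 0.35, 0.85))
    for (cl in 1:2) {
      sel <- !is.na(map) & map == cl
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[sel] <- cols[cl, ch]
        img[, , ch] <- plane
      }
    }
  } else {
    v <- map
    rng <- range(v, na.rm = TRUE)
    v <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0 + 0.5
    v[is.na(v)] <- 0
    for (ch in 1:3) img[, , ch] <- v
  }
  png::writePNG(img, file)
  invisible(file)
}
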