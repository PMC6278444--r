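fake_meta <- function(n_per_group) {
  g <- expand.grid(rep = seq_len(n_per_group),
                   grade = c("Grade1", "Grade2", "Grade3"),
                   class = c("A", "B"), stringsAsFactors = FALSE)
  data.frame(scene_id = sprintf("%s_%s_%02d", g$class, g$grade, g$rep),
             class = g$class, grade = g$grade, stringsAsFactors = FALSE)
}

test_that("scene split: 2:1 counts, determinism, no leakage", {
  meta30 <- fake_meta(30L)
  sp <- split_scenes(meta30, seed = 4L)
  expect_length(sp$calibration, 6L * 20L)
  expect_length(sp$prediction, 6L * 10L)
  # per-group counts
  for (g in unique(paste(meta30$class, meta30$grade))) {
    ids <- meta30$scene_id[paste(meta30$class, meta30$grade) == g]
    expect_length(intersect(ids, sp$calibration), 20L)
  }
  expect_length(intersect(sp$calibration, sp$prediction), 0L)
  sp2 <- split_scenes(meta30, seed = 4L)
  expect_identical(sp, sp2)

  meta3 <- fake_meta(3L)
  sp3 <- split_scenes(meta3, seed = 1L)
  expect_length(sp3$calibration, 6L * 2L)
  expect_length(sp3$prediction, 6L * 1L)
  expect_error(split_scenes(fake_meta(2L)), "at least 3")
})

test_that("metric arithmetic matches hand-computed confusion counts", {
  # counts in the printed numerator/denominator style: 665/665 and 245/246
  m <- metrics_from_counts(665L, 665L, 245L, 246L)
  expect_equal(m$sensitivity, 1.000, tolerance = 5e-4)
  expect_equal(m$specificity, 0.9959, tolerance = 5e-5)
  expect_equal(m$accuracy, 99.89, tolerance = 5e-3)
  expect_identical(m$counts$shown, c("665/665", "245/246"))
})

test_that("evaluate: perfect case, class swap symmetry, unseen labels", {
  d <- separable_blobs(n_per_class = 10L, seed = 2L)
  clf <- train_knn(d$X, d$y, knn_config(1L))
  r <- evaluate(clf, d$X, d$y, positive_class = "A")
  expect_equal(r$accuracy, 100)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(sum(r$counts$total), r$n)

  # make one B-row misclassified by relabeling it
  y2 <- d$y; y2[20] <- "A"
  ra <- evaluate(clf, d$X, y2, positive_class = "A")
  rb <- evaluate(clf, d$X, y2, positive_class = "B")
  expect_equal(ra$sensitivity, rb$specificity)
  expect_equal(ra$specificity, rb$sensitivity)
  expect_equal(ra$accuracy, rb$accuracy)

  expect_error(evaluate(clf, d$X, rep("C", 20)), "unseen")
})

test_that("metric identities hold on evaluated reports", {
  d <- separable_blobs(n_per_class = 12L, gap = 1.2, seed = 6L)
  clf <- train_knn(d$X, d$y, knn_config(3L))
  r <- evaluate(clf, d$X, d$y, positive_class = "A")
  cts <- r$counts
  again <- metrics_from_counts(cts$correct[1], cts$total[1],
                               cts$correct[2], cts$total[2])
  expect_equal(r$accuracy, again$accuracy)
  expect_equal(r$sensitivity, again$sensitivity)
  expect_equal(r$specificity, again$specificity)
})

make_toy_tables <- function(noise = 0, seed = 1L) {
  # degenerate study stand-in: 3 grades x 2 classes x 4 scenes, 2 objects
  # of 3 pixels each, class signatures orthogonal; optional noise
  wl <- tiny_axis(8L)
  base <- list(A = c(rep(1, 4), rep(-1, 4)), B = c(rep(-1, 4), rep(1, 4)))
  rows <- list(); meta <- list()
  hsichem:::with_seed(seed, {
    for (cl in c("A", "B")) for (g in c("Grade1", "Grade2", "Grade3"))
      for (s in 1:4) {
        sid <- sprintf("%s_%s_%02d", cl, g, s)
        for (ob in 1:2) for (px in 1:3) {
          rows[[length(rows) + 1L]] <- base[[cl]] + rnorm(8, 0, noise)
          meta[[length(meta) + 1L]] <- data.frame(
            scene_id = sid, object_id = ob, class = cl, grade = g,
            row = px, col = ob, stringsAsFactors = FALSE)
        }
      }
  })
  pix <- pixel_spectra(do.call(rbind, rows), do.call(rbind, meta), wl,
                       stage = "wt+snv")
  list(pix = pix, obj = average_by_object(pix))
}

test_that("grade transfer produces a full 3x3 grid with sane diagonals", {
  tt <- make_toy_tables(noise = 0.3)
  gt <- run_grade_transfer(tt$obj, features = 1:8,
                           spec = list(kind = "knn",
                                       config = knn_config(1L)))
  expect_equal(nrow(gt$summary), 9L)
  expect_setequal(unique(gt$summary$train_grade),
                  c("Grade1", "Grade2", "Grade3"))
  diag_acc <- gt$summary$accuracy[gt$summary$train_grade ==
                                    gt$summary$predict_grade]
  expect_true(all(diag_acc == 100))   # resubstitution with 1-NN

  bad <- tt$obj
  keep <- bad$meta$grade != "Grade3"
  bad <- hsichem:::subset_table(bad, which(keep))
  expect_error(run_grade_transfer(bad, 1:8,
                                  list(kind = "knn",
                                       config = knn_config(1L))),
               "Grade3")
})

test_that("four-way design: 12 reports, repeated calibration metrics, counts", {
  tt <- make_toy_tables(noise = 0)   # zero within-class variability
  sp <- split_scenes(unique(tt$pix$meta[, c("scene_id", "class", "grade")]),
                     seed = 2L)
  specs <- list(svm = list(kind = "svm", config = list(C = 1, gamma = 0.5)),
                knn = list(kind = "knn", config = knn_config(1L)),
                rbfnn = list(kind = "rbfnn",
                             config = rbfnn_config(1, 1e-8)))
  fw <- run_four_way(tt$pix, tt$obj, sp, features = 1:8, specs,
                     n_groups = 10L, seed = 3L)
  expect_equal(nrow(fw$summary), 12L)
  expect_true(all(fw$summary$pre_accuracy == 100))
  expect_true(all(fw$summary$cal_accuracy == 100))
  # pixel-trained calibration metrics repeat across prediction levels
  for (mdl in c("svm", "knn", "rbfnn")) {
    s <- fw$summary[fw$summary$model == mdl, ]
    expect_equal(s$cal_accuracy[s$mode == "pixel->pixel"],
                 s$cal_accuracy[s$mode == "pixel->object"])
    expect_equal(s$cal_accuracy[s$mode == "object->pixel"],
                 s$cal_accuracy[s$mode == "object->object"])
  }
  # every report's counts sum to the evaluated rows
  for (mdl in names(fw$reports)) for (md in names(fw$reports[[mdl]])) {
    rep_ <- fw$reports[[mdl]][[md]]$prediction
    expect_equal(sum(rep_$counts$total), rep_$n)
  }
})

test_that("prediction maps agree exactly with tabular predictions", {
  sc <- generate_scene(tiny_scene_config(seed = 61L, n_objects = 2L))
  corr <- correct_reflectance(sc$raw, sc$refs)
  om <- label_objects(segment_background(corr))
  tab <- preprocess_pixels(extract_pixel_spectra(corr, om))
  cls <- sc$truth$class_map[cbind(tab$meta$row, tab$meta$col)]
  keep <- which(!is.na(cls))   # segmentation can add a few noise pixels
  clf <- train_knn(tab$spectra[keep, 1:8], cls[keep], knn_config(1L))
  clf$stage <- "wt+snv"
  pm <- prediction_map(clf, corr, om, features = 1:8)
  expect_identical(pm$map[cbind(pm$meta$row, pm$meta$col)],
                   as.integer(pm$predictions))
  expect_true(all(is.na(pm$map[om$labels == 0L])))
  # 1-NN on its own training pixels is perfect -> uniform correct labels
  truth_codes <- match(cls, pm$classes)
  expect_equal(pm$map[cbind(pm$meta$row, pm$meta$col)][keep],
               truth_codes[keep])

  f <- tempfile(fileext = ".png")
  render_prediction_map(pm$map, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
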