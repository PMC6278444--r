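# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays fast.

tiny_axis <- function(bands = 32L) seq(975, 1646, length.out = bands)

tiny_scene_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(bands = 32L, image_shape = c(40L, 40L), n_objects = 3L,
         radius = 5, seed = seed),
    list(...))
  do.call(scene_config, args)
}

# Two well-separated 2-D Gaussian blobs, linearly separable.
separable_blobs <- function(n_per_class = 15L, gap = 8, seed = 1L) {
  hsichem:::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per_class, 0, 0.5), ncol = 2),
               matrix(rnorm(2 * n_per_class, gap, 0.5), ncol = 2))
    list(X = X, y = factor(rep(c("A", "B"), each = n_per_class)))
  })
}

# Brute-force re-implementation of the loadings-based selection rule,
# kept deliberately naive and independent of the package's code path;
# used as an oracle by several test files.
oracle_pca_select <- function(loadings, wavelengths, n_select, n_pcs) {
  bands <- nrow(loadings)
  score <- numeric(bands)
  for (b in seq_len(bands)) score[b] <- max(abs(loadings[b, seq_len(n_pcs)]))
  is_peak <- logical(bands)
  for (b in seq_len(bands)) {
    l <- b - 1L
    while (l >= 1L && score[l] == score[b]) l <- l - 1L   # walk past plateau
    r <- b + 1L
    while (r <= bands && score[r] == score[b]) r <- r + 1L
    left_ok <- l < 1L || score[l] < score[b]
    right_ok <- r > bands || score[r] < score[b]
    first_of_plateau <- b == 1L || score[b - 1L] != score[b]
    is_peak[b] <- left_ok && right_ok && first_of_plateau
  }
  ord <- order(-score, wavelengths)
  chosen <- c(ord[is_peak[ord]], ord[!is_peak[ord]])[seq_len(n_select)]
  sort(chosen)
}

# Lazily computed, memoized desk-scale study results shared by the
# acceptance blocks that exercise the full pipeline.
.desk_cache <- new.env(parent = emptyenv())

desk_study_results <- function() {
  if (!is.null(.desk_cache$res)) return(.desk_cache$res)
  study <- generate_study(scenes_per_group = 6L, master_seed = 20260901L)
  pixels <- preprocess_pixels(extract_study_spectra(study))
  objects <- average_by_object(pixels)
  split <- split_scenes(study$meta, seed = 77L)
  obj_cal <- hsichem:::subset_table(
    objects, objects$meta$scene_id %in% split$calibration)
  pca <- pca_fit(obj_cal$spectra, stage = "wt+snv")
  sel <- select_by_pca_loadings(pca, objects$wavelengths, n_select = 20L)
  features <- sel$selected$band_index
  specs <- list(
    svm = list(kind = "svm",
               config = svm_config(log2C = seq(-8, 8, by = 2),
                                   log2gamma = seq(-8, 8, by = 2))),
    rbfnn = list(kind = "rbfnn", tune = TRUE))
  fw <- run_four_way(pixels, objects, split, features, specs,
                     n_groups = 300L, seed = 99L)
  # a pixel-trained SVM for the prediction-map block
  pix_cal <- hsichem:::subset_table(
    pixels, pixels$meta$scene_id %in% split$calibration)
  Xr <- pix_cal$spectra[, features, drop = FALSE]
  rep_idx <- select_representative_pixels(Xr, 300L, seed = 5L)
  pix_svm <- grid_search_svm(Xr[rep_idx, , drop = FALSE],
                             pix_cal$meta$class[rep_idx],
                             svm_config(log2C = seq(-8, 8, by = 2),
                                        log2gamma = seq(-8, 8, by = 2)),
                             seed = 6L)$classifier
  pix_svm$stage <- "wt+snv"
  .desk_cache$res <- list(study = study, pixels = pixels, objects = objects,
                          split = split, features = features, fw = fw,
                          pix_svm = pix_svm)
  .desk_cache$res
}
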