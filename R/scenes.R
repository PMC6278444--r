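#' Spectral signature specification
#'
#' A clean class signature is a reflectance baseline minus Gaussian
#' absorbance dips, plus an optional deterministic per-band offset. Defaults
#' emulate NIR spectra of dried fruit: C-H overtone bands near 1123, 1210
#' and 1308 nm and the water band near 1473 nm.
#'
#' @param class_id Class label, e.g. `"A"` or `"B"`.
#' @param baseline Reflectance level in (0,1).
#' @param peaks Data frame with columns `center` (nm), `depth` (reflectance
#'   units) and `width` (FWHM, nm), one row per absorbance dip.
#' @param class_offset Scalar or per-band numeric offset added to the
#'   signature.
#' @return A `signature_spec` object.
#' @export
signature_spec <- function(class_id, baseline, peaks, class_offset = 0) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "depth", "width") %in% names(peaks)))
  if (baseline <= 0 || baseline >= 1)
    stop("baseline must lie in (0,1)", call. = FALSE)
  structure(list(class_id = class_id, baseline = baseline, peaks = peaks,
                 class_offset = class_offset), class = "signature_spec")
}

#' Default two-class signature pair
#'
#' Both classes share dips at 1123, 1210, 1308 and 1473 nm (the 1473 nm
#' water band is the deepest); they differ in baseline and dip depths so the
#' clean signatures carry a mean absolute contrast of a few percent
#' reflectance, comparable bands-wise but separable multivariately.
#'
#' @return Named list of two `signature_spec` objects (`A`, `B`).
#' @export
default_signatures <- function() {
  list(
    A = signature_spec("A", baseline = 0.62, peaks = data.frame(
      center = c(1123, 1210, 1308, 1473),
      depth  = c(0.10, 0.12, 0.09, 0.22),
      width  = c(30, 35, 30, 45))),
    B = signature_spec("B", baseline = 0.58, peaks = data.frame(
      center = c(1123, 1210, 1308, 1473),
      depth  = c(0.14, 0.07, 0.13, 0.18),
      width  = c(30, 35, 30, 45)))
  )
}

#' Evaluate a clean signature on a wavelength axis
#'
#' @param spec A [signature_spec].
#' @param wavelengths Ascending numeric axis (nm).
#' @return Numeric reflectance spectrum in (0,1), one value per band.
#' @export
make_signature <- function(spec, wavelengths) {
  stopifnot(inherits(spec, "signature_spec"))
  wavelengths <- as.numeric(wavelengths)
  pk <- spec$peaks
  if (nrow(pk) > 0 &&
      (any(pk$center < min(wavelengths)) || any(pk$center > max(wavelengths))))
    stop("peak center outside the wavelength axis", call. = FALSE)
  s <- rep(spec$baseline, length(wavelengths))
  for (i in seq_len(nrow(pk))) {
    sd <- pk$width[i] / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian SD
    s <- s - pk$depth[i] * exp(-0.5 * ((wavelengths - pk$center[i]) / sd)^2)
  }
  s <- s + spec$class_offset
  if (any(s <= 0) || any(s >= 1))
    stop("signature leaves (0,1); adjust baseline/depths", call. = FALSE)
  s
}

#' Scene configuration
#'
#' Geometry, optics and noise parameters of one synthetic scene. Grade
#' controls the object radius distribution: Grade1 large, Grade2 medium,
#' Grade3 small.
#'
#' @param bands Number of spectral bands (>= 8; default 200).
#' @param wavelength_range Axis limits in nm (default 975-1646).
#' @param image_shape `c(rows, cols)`.
#' @param n_objects Objects per scene.
#' @param grade `"Grade1"`, `"Grade2"` or `"Grade3"`.
#' @param background_level Clean background reflectance (default 0.05, below
#'   the 0.122 segmentation threshold).
#' @param scatter_gain_sd SD of the per-pixel multiplicative scatter gain.
#' @param scatter_offset_sd SD of the per-pixel additive scatter offset.
#' @param noise_sd SD of per-pixel-per-band sensor noise.
#' @param radius Mean object radius in pixels; default derived from grade and
#'   image size.
#' @param seed Scene seed.
#' @return A `scene_config` object.
#' @export
scene_config <- function(bands = 200L, wavelength_range = c(975, 1646),
                         image_shape = c(64L, 64L), n_objects = 4L,
                         grade = c("Grade2", "Grade1", "Grade3"),
                         background_level = 0.05,
                         scatter_gain_sd = 0.08, scatter_offset_sd = 0.01,
                         noise_sd = 0.035, radius = NULL, seed = 1L) {
  grade <- match.arg(grade)
  if (bands < 8L) stop("bands must be >= 8", call. = FALSE)
  if (is.null(radius)) {
    base <- min(image_shape) / 64
    radius <- switch(grade, Grade1 = 9, Grade2 = 7, Grade3 = 5) * base
  }
  structure(list(bands = as.integer(bands),
                 wavelength_range = wavelength_range,
                 image_shape = as.integer(image_shape),
                 n_objects = as.integer(n_objects), grade = grade,
                 background_level = background_level,
                 scatter_gain_sd = scatter_gain_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd, radius = radius,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Non-overlapping random ellipses; greedy placement with whole-layout
# restarts, erroring after bounded retries.
place_objects <- function(config) {
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  for (attempt in seq_len(30L)) {
    placed <- list()
    failed <- FALSE
    for (i in seq_len(config$n_objects)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- config$radius * stats::runif(1, 0.85, 1.15)   # semi-major
        b <- a * stats::runif(1, 0.6, 1.0)                 # semi-minor
        theta <- stats::runif(1, 0, pi)
        margin <- a + 1.5
        if (2 * margin >= min(nr, nc))
          stop("objects too large for the image: radius ", config$radius,
               " does not fit in ", nr, "x", nc, call. = FALSE)
        cr <- stats::runif(1, margin + 1, nr - margin)
        cc <- stats::runif(1, margin + 1, nc - margin)
        clear <- TRUE
        for (p in placed)
          if (sqrt((cr - p$cr)^2 + (cc - p$cc)^2) < a + p$a + 1.5) {
            clear <- FALSE; break
          }
        if (clear) {
          placed[[i]] <- list(cr = cr, cc = cc, a = a, b = b, theta = theta)
          ok <- TRUE
          break
        }
      }
      if (!ok) { failed <- TRUE; break }
    }
    if (!failed) return(placed)
  }
  stop("could not place ", config$n_objects, " non-overlapping objects ",
       "of radius ~", signif(config$radius, 3), " in a ", nr, "x", nc,
       " image after bounded retries", call. = FALSE)
}

rasterize_ellipse <- function(shape, e) {
  nr <- shape[1L]; nc <- shape[2L]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- rows - e$cr; dc <- cols - e$cc
  u <- (dr * cos(e$theta) + dc * sin(e$theta)) / e$a
  v <- (-dr * sin(e$theta) + dc * cos(e$theta)) / e$b
  u^2 + v^2 <= 1
}

#' Generate one synthetic raw scene
#'
#' Objects are random non-overlapping ellipses of a class-specific clean
#' signature on a dark background. The sensor model is
#' `raw = dark + (white - dark) * (reflectance * gain + offset + noise)`,
#' clipped to the sensor range `[0, 1]`, with one multiplicative gain and
#' one additive offset per pixel (shared across bands: the scatter structure
#' SNV removes) and independent per-pixel-per-band noise. White is about
#' 0.9 and dark about 0.02 with small deterministic spatial ripple, so
#' white/dark correction is a nontrivial normalization.
#'
#' @param config A [scene_config].
#' @param signatures Named list of [signature_spec]s; objects cycle through
#'   the classes unless `classes` is given.
#' @param classes Optional character vector of per-object class ids.
#' @return List with `raw` ([hsi_cube]), `refs` ([reference_frames]),
#'   `truth` (list: `label_map`, `class_map`, `object_table`) and
#'   `wavelengths`.
#' @export
generate_scene <- function(config, signatures = default_signatures(),
                           classes = NULL) {
  stopifnot(inherits(config, "scene_config"))
  wl <- seq(config$wavelength_range[1L], config$wavelength_range[2L],
            length.out = config$bands)
  sigs <- lapply(signatures, make_signature, wavelengths = wl)
  if (is.null(classes))
    classes <- rep(names(signatures), length.out = config$n_objects)
  stopifnot(all(classes %in% names(signatures)))
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]

  with_seed(config$seed, {
    placed <- place_objects(config)
    label_map <- matrix(0L, nr, nc)
    class_map <- matrix(NA_character_, nr, nc)
    for (i in seq_along(placed)) {
      inside <- rasterize_ellipse(config$image_shape, placed[[i]])
      label_map[inside] <- i
      class_map[inside] <- classes[i]
    }
    # clean reflectance cube
    refl <- array(config$background_level, dim = c(nr, nc, config$bands))
    flat <- matrix(refl, nr * nc, config$bands)
    for (cl in unique(classes)) {
      idx <- which(class_map == cl)
      flat[idx, ] <- matrix(sigs[[cl]], length(idx), config$bands,
                            byrow = TRUE)
    }
    # reference frames: deterministic ripple so correction is nontrivial
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    rows <- matrix(seq_len(nr), nr, nc)
    white <- 0.9 + 0.02 * sin(2 * pi * cols / nc) +
      0.01 * cos(2 * pi * rows / nr)
    dark <- 0.02 + 0.003 * sin(2 * pi * rows / nr)
    # per-pixel scatter, per-pixel-per-band noise
    gain <- 1 + stats::rnorm(nr * nc, 0, config$scatter_gain_sd)
    offset <- stats::rnorm(nr * nc, 0, config$scatter_offset_sd)
    noisy <- flat * gain + offset
    if (config$noise_sd > 0)
      noisy <- noisy + matrix(stats::rnorm(nr * nc * config$bands, 0,
                                           config$noise_sd),
                              nr * nc, config$bands)
    raw <- as.vector(dark) + as.vector(white - dark) * noisy
    raw[raw < 0] <- 0; raw[raw > 1] <- 1
    raw <- array(raw, dim = c(nr, nc, config$bands))

    counts <- tabulate(label_map[label_map > 0L],
                       nbins = config$n_objects)
    object_table <- data.frame(
      id = seq_along(placed),
      class = classes,
      grade = config$grade,
      centroid_row = vapply(placed, `[[`, numeric(1), "cr"),
      centroid_col = vapply(placed, `[[`, numeric(1), "cc"),
      n_pixels = counts,
      stringsAsFactors = FALSE
    )
    list(raw = hsi_cube(raw, wl, "raw"),
         refs = reference_frames(white, dark),
         truth = list(label_map = label_map, class_map = class_map,
                      object_table = object_table),
         wavelengths = wl,
         config = config)
  })
}

# Grade-dependent signature drift that changes spectral *shape* (a common
# scale factor on all dips would be an affine change that SNV removes): the
# water band (highest peak center) deepens with grade while the C-H bands
# weaken, emulating size-dependent drying.
apply_grade_drift <- function(spec, grade_index, drift) {
  if (drift == 0) return(spec)
  f <- drift * (grade_index - 2)
  water <- which.max(spec$peaks$center)
  spec$peaks$depth[water] <- spec$peaks$depth[water] * (1 + f)
  spec$peaks$depth[-water] <- spec$peaks$depth[-water] * (1 - f / 2)
  spec
}

#' Generate a full synthetic study
#'
#' `n_classes x 3 grades x scenes_per_group` scenes with per-scene seeds
#' derived deterministically from a master seed. With the defaults this is
#' the full study layout (2 classes x 3 grades x 30 scenes = 180); the desk
#' preset scales `scenes_per_group` down.
#'
#' @param signatures Named list of class [signature_spec]s.
#' @param scenes_per_group Scenes per class-grade group (default 30).
#' @param master_seed Master seed; per-scene seeds derive from it.
#' @param grade_drift If nonzero, the second class's dip depths drift
#'   linearly with grade (factor `1 + drift * (grade - 2)`), emulating
#'   grade-dependent composition differences.
#' @param ... Further arguments passed to [scene_config()] (image_shape,
#'   n_objects, noise levels, ...).
#' @return A `scene_study`: list with `scenes` (list of [generate_scene()]
#'   outputs) and `meta` (data.frame: scene_id, class, grade, seed).
#' @export
generate_study <- function(signatures = default_signatures(),
                           scenes_per_group = 30L, master_seed = 1L,
                           grade_drift = 0, ...) {
  grades <- c("Grade1", "Grade2", "Grade3")
  cls <- names(signatures)
  meta <- expand.grid(rep = seq_len(scenes_per_group), grade = grades,
                      class = cls, stringsAsFactors = FALSE)
  meta$scene_id <- sprintf("%s_%s_s%02d", meta$class, meta$grade, meta$rep)
  meta$seed <- derive_seed(master_seed, seq_len(nrow(meta)))
  scenes <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    g_idx <- match(meta$grade[i], grades)
    sigs_i <- signatures[meta$class[i]]
    if (grade_drift != 0)
      sigs_i[[1L]] <- apply_grade_drift(sigs_i[[1L]], g_idx, grade_drift)
    cfg <- scene_config(grade = meta$grade[i], seed = meta$seed[i], ...)
    scenes[[i]] <- generate_scene(cfg, sigs_i,
                                  classes = rep(meta$class[i],
                                                cfg$n_objects))
    scenes[[i]]$scene_id <- meta$scene_id[i]
  }
  structure(list(scenes = scenes,
                 meta = meta[, c("scene_id", "class", "grade", "seed")]),
            class = "scene_study")
}

#' Correct, segment and extract pixel spectra for a whole study
#'
#' Runs reflectance correction, background segmentation and object labeling
#' on every scene and stacks the extracted pixel spectra into one table,
#' discarding cubes as it goes.
#'
#' @param study A `scene_study` from [generate_study()].
#' @param band_nm,threshold Segmentation parameters (see
#'   [segment_background()]).
#' @param min_size Minimum object size in pixels.
#' @return A `pixel_spectra` table covering all scenes (stage `"raw"`).
#' @export
extract_study_spectra <- function(study, band_nm = 1119, threshold = 0.122,
                                  min_size = 5L) {
  stopifnot(inherits(study, "scene_study"))
  parts <- vector("list", length(study$scenes))
  for (i in seq_along(study$scenes)) {
    sc <- study$scenes[[i]]
    corr <- correct_reflectance(sc$raw, sc$refs)
    om <- label_objects(segment_background(corr, band_nm, threshold),
                        min_size = min_size)
    cls <- study$meta$class[i]
    grd <- study$meta$grade[i]
    parts[[i]] <- extract_pixel_spectra(corr, om,
                                        scene_id = study$meta$scene_id[i],
                                        class = cls, grade = grd)
  }
  spectra <- do.call(rbind, lapply(parts, `[[`, "spectra"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  pixel_spectra(spectra, meta, study$scenes[[1L]]$wavelengths, stage = "raw")
}

#' Write a scene to disk (ENVI cube + ground truth)
#'
#' Writes the raw cube (`<stem>.hdr`/`.raw`), white and dark frames as
#' plain-text rasters, the label map as a text raster and the object table
#' as CSV.
#'
#' @param scene Output of [generate_scene()].
#' @param stem Path stem.
#' @return `stem`, invisibly.
#' @export
write_scene <- function(scene, stem) {
  write_cube(scene$raw, stem, dialect = "envi")
  utils::write.table(scene$refs$white, paste0(stem, "_white.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$refs$dark, paste0(stem, "_dark.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$truth$label_map, paste0(stem, "_labels.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(scene$truth$object_table, paste0(stem, "_objects.csv"),
                   row.names = FALSE)
  invisible(stem)
}
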