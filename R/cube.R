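#' Hyperspectral cube container
#'
#' A cube is a `rows x cols x bands` numeric array together with an ascending
#' wavelength axis (nm) and a processing stage tag. Raw cubes hold sensor
#' counts; corrected cubes hold relative reflectance after white/dark
#' normalization.
#'
#' @param data 3-D numeric array, band axis last.
#' @param wavelengths Strictly increasing numeric vector, one value per band.
#' @param stage `"raw"` or `"corrected"`.
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelengths, stage = c("raw", "corrected")) {
  stage <- match.arg(stage)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) must equal the band dimension of `data`",
         call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, stage = stage),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), stage: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              x$stage))
  invisible(x)
}

#' Reference frames for reflectance correction
#'
#' White and dark reference images, either full-frame 2-D rasters or 3-D
#' rasters matching the cube. The white frame must exceed the dark frame
#' everywhere, otherwise the correction is undefined.
#'
#' @param white,dark Numeric matrices (rows x cols) or 3-D arrays.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  if (!identical(dim(white), dim(dark)))
    stop("white and dark frames must have identical dimensions", call. = FALSE)
  if (any(white <= dark))
    stop("white frame must exceed dark frame everywhere", call. = FALSE)
  structure(list(white = white, dark = dark), class = "reference_frames")
}

# ---- ENVI-style I/O ---------------------------------------------------------

#' Write a cube to disk
#'
#' `dialect = "envi"` writes an ASCII header (`<path>.hdr`) plus a raw binary
#' raster in BSQ or BIL interleave, 64-bit IEEE little-endian, with the
#' wavelength list embedded in the header. `dialect = "internal"` serializes
#' the container itself (RDS), preserving the stage tag.
#'
#' @param cube An [hsi_cube].
#' @param path Output path (without extension for ENVI; the header becomes
#'   `<path>.hdr` and the raster `<path>.raw`).
#' @param dialect `"envi"` or `"internal"`.
#' @param interleave `"bsq"` or `"bil"` (ENVI only).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "internal"),
                       interleave = c("bsq", "bil")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cube, "hsi_cube"))
  if (dialect == "internal") {
    saveRDS(cube, path)
    return(invisible(path))
  }
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("stage = %s", cube$stage),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: sample fastest, then line, then band; BIL: sample, band, line
  perm <- if (interleave == "bsq") c(2L, 1L, 3L) else c(2L, 3L, 1L)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, perm)), con, size = 8L,
           endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1L]]
    if (length(m) < 2L) NULL else trimws(m[2L])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1L]]
    if (length(m) < 2L) return(NULL)
    as.numeric(strsplit(m[2L], "[,\\s]+")[[1L]][nzchar(strsplit(
      m[2L], "[,\\s]+")[[1L]])])
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type") %||% "5"),
       interleave = tolower(get_scalar("interleave") %||% "bsq"),
       stage = get_scalar("stage") %||% "raw",
       wavelength = get_list("wavelength"))
}

#' Read a cube from disk
#'
#' @param path Path as given to [write_cube()].
#' @param dialect `"envi"` or `"internal"`.
#' @return An [hsi_cube].
#' @export
read_cube <- function(path, dialect = c("envi", "internal")) {
  dialect <- match.arg(dialect)
  if (dialect == "internal") {
    cube <- readRDS(path)
    stopifnot(inherits(cube, "hsi_cube"))
    return(cube)
  }
  hdr_path <- paste0(path, ".hdr")
  raw_path <- paste0(path, ".raw")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path,
                                   call. = FALSE)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength))
    stop("ENVI header lacks wavelength metadata", call. = FALSE)
  if (length(h$wavelength) != h$bands)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 h$bands, length(h$wavelength)), call. = FALSE)
  n <- h$samples * h$lines * h$bands
  size <- if (h$data_type == 4L) 4L else 8L
  vals <- readBin(raw_path, what = "double", n = n + 1L, size = size,
                  endian = "little")
  if (length(vals) != n)
    stop(sprintf("raster holds %d values but header implies %d",
                 length(vals), n), call. = FALSE)
  arr <- switch(h$interleave,
    bsq = aperm(array(vals, dim = c(h$samples, h$lines, h$bands)),
                c(2L, 1L, 3L)),
    bil = aperm(array(vals, dim = c(h$samples, h$bands, h$lines)),
                c(3L, 1L, 2L)),
    stop("unsupported interleave: ", h$interleave, call. = FALSE))
  hsi_cube(arr, h$wavelength, stage = h$stage)
}

# ---- Reflectance correction -------------------------------------------------

#' White/dark reflectance correction
#'
#' Converts raw counts to relative reflectance,
#' `(I_r - I_d) / (I_w - I_d)`, applied elementwise with 2-D reference
#' frames broadcast across bands.
#'
#' @param raw A raw-stage [hsi_cube].
#' @param refs A [reference_frames] object.
#' @return A corrected-stage [hsi_cube].
#' @export
correct_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hsi_cube"), inherits(refs, "reference_frames"))
  if (raw$stage != "raw")
    stop("cube is already corrected", call. = FALSE)
  d <- dim(raw$data)
  w <- refs$white; dk <- refs$dark
  if (is.matrix(w)) {
    if (!identical(dim(w), d[1:2]))
      stop("reference frame dimensions do not match cube", call. = FALSE)
    denom <- w - dk
    corr <- (raw$data - as.vector(dk)) / as.vector(denom)
  } else {
    if (!identical(dim(w), d))
      stop("reference frame dimensions do not match cube", call. = FALSE)
    corr <- (raw$data - dk) / (w - dk)
  }
  hsi_cube(corr, raw$wavelengths, stage = "corrected")
}

# ---- Segmentation and labeling ---------------------------------------------

#' Threshold-based background segmentation
#'
#' Binarizes the reflectance image at the band nearest `band_nm`. A pixel is
#' foreground when its reflectance is strictly greater than `threshold`;
#' a pixel exactly at the threshold is background.
#'
#' @param cube A corrected [hsi_cube].
#' @param band_nm Segmentation wavelength (nm); default 1119.
#' @param threshold Reflectance threshold; default 0.122.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
segment_background <- function(cube, band_nm = 1119, threshold = 0.122) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (band_nm < min(cube$wavelengths) || band_nm > max(cube$wavelengths))
    stop("band_nm outside the wavelength range", call. = FALSE)
  b <- nearest_band(cube$wavelengths, band_nm)
  cube$data[, , b] > threshold
}

#' Label connected foreground objects
#'
#' Connected components under 8-connectivity; components smaller than
#' `min_size` pixels are discarded as noise. Surviving components are
#' relabeled `1..n_objects` in raster (column-major) order of their first
#' pixel.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum component size in pixels (default 5).
#' @return An `object_mask`: list with `mask` (logical), `labels` (integer
#'   matrix, 0 = background) and `n_objects`.
#' @export
label_objects <- function(mask, min_size = 5L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  comp <- 0L
  # BFS flood fill with an explicit frontier; 8-neighborhood
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    frontier <- start
    labels[start] <- comp
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr[mask[nbr] & labels[nbr] == 0L])
      labels[nbr] <- comp
      frontier <- nbr
    }
  }
  if (comp > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = comp)
    keep <- which(sizes >= min_size)
    remap <- integer(comp)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    comp <- length(keep)
  }
  structure(list(mask = labels > 0L, labels = labels, n_objects = comp),
            class = "object_mask")
}

#' Extract per-pixel spectra for all labeled objects
#'
#' One row per foreground pixel, ordered by object id then raster order,
#' with scene/object/class/grade labels and pixel coordinates so prediction
#' maps can be reconstructed exactly.
#'
#' @param cube A corrected [hsi_cube].
#' @param objmask An `object_mask` from [label_objects()].
#' @param scene_id Scene identifier (scalar).
#' @param class Class label for every object (scalar), or a vector of length
#'   `n_objects` giving per-object classes.
#' @param grade Grade label, scalar or per-object vector.
#' @return A `pixel_spectra` table: list with `spectra` (rows x bands),
#'   `meta` (data.frame: scene_id, object_id, class, grade, row, col),
#'   `wavelengths`, and `stage = "raw"` (meaning unpreprocessed reflectance).
#' @export
extract_pixel_spectra <- function(cube, objmask, scene_id = "scene1",
                                  class = NA_character_, grade = NA_character_) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(objmask, "object_mask"))
  d <- dim(cube$data)
  if (!identical(dim(objmask$labels), d[1:2]))
    stop("object mask does not align with cube", call. = FALSE)
  idx <- which(objmask$labels > 0L)
  ids <- objmask$labels[idx]
  ord <- order(ids, idx)
  idx <- idx[ord]; ids <- ids[ord]
  n <- length(idx)
  flat <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  spectra <- flat[idx, , drop = FALSE]
  per_obj <- function(x) {
    if (length(x) == 1L) rep(x, n)
    else {
      if (length(x) != objmask$n_objects)
        stop("per-object label vector has wrong length", call. = FALSE)
      x[ids]
    }
  }
  meta <- data.frame(
    scene_id = rep(scene_id, n),
    object_id = ids,
    class = per_obj(class),
    grade = per_obj(grade),
    row = ((idx - 1L) %% d[1L]) + 1L,
    col = ((idx - 1L) %/% d[1L]) + 1L,
    stringsAsFactors = FALSE
  )
  pixel_spectra(spectra, meta, cube$wavelengths, stage = "raw")
}

#' Pixel-spectra table constructor
#'
#' @param spectra Numeric matrix, one spectrum per row.
#' @param meta Data frame with one row per spectrum (scene_id, object_id,
#'   class, grade, and optionally row/col coordinates).
#' @param wavelengths Band centers (nm).
#' @param stage Preprocessing stage: `"raw"`, `"wt"` or `"wt+snv"`.
#' @return A `pixel_spectra` object.
#' @export
pixel_spectra <- function(spectra, meta, wavelengths,
                          stage = c("raw", "wt", "wt+snv")) {
  stage <- match.arg(stage)
  spectra <- as.matrix(spectra)
  if (nrow(meta) != nrow(spectra))
    stop("meta and spectra row counts differ", call. = FALSE)
  if (length(wavelengths) != ncol(spectra))
    stop("wavelength axis does not match spectra", call. = FALSE)
  if (anyNA(spectra)) stop("spectra contain missing values", call. = FALSE)
  structure(list(spectra = spectra, meta = meta,
                 wavelengths = as.numeric(wavelengths), stage = stage),
            class = "pixel_spectra")
}

#' @export
print.pixel_spectra <- function(x, ...) {
  cat(sprintf("<pixel_spectra> %d spectra x %d bands, stage: %s\n",
              nrow(x$spectra), ncol(x$spectra), x$stage))
  invisible(x)
}

#' Write / read a pixel-spectra table as CSV
#'
#' Columns: scene_id, object_id, class, grade, row, col, band_0..band_{B-1};
#' the wavelength axis and stage travel in a YAML sidecar `<path>.meta.yml`.
#'
#' @param table A `pixel_spectra` or `object_spectra` table.
#' @param path CSV path.
#' @return `path` invisibly; `read_spectra_csv` returns the table.
#' @export
write_spectra_csv <- function(table, path) {
  sp <- table$spectra
  colnames(sp) <- paste0("band_", seq_len(ncol(sp)) - 1L)
  utils::write.csv(cbind(table$meta, as.data.frame(sp)), path,
                   row.names = FALSE)
  yaml::write_yaml(list(stage = table$stage,
                        wavelengths = as.numeric(table$wavelengths),
                        kind = class(table)[1L]),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- yaml::read_yaml(paste0(path, ".meta.yml"))
  bandcols <- grep("^band_", names(df))
  tab <- pixel_spectra(as.matrix(df[, bandcols, drop = FALSE]),
                       df[, -bandcols, drop = FALSE],
                       side$wavelengths, stage = side$stage)
  if (identical(side$kind, "object_spectra")) class(tab) <- "object_spectra"
  tab
}
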