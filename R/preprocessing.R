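# Daubechies-7 filter bank (14 taps), standard orthonormal coefficients.
.db7 <- local({
  dec_lo <- c(0.00035371379997452024, -0.0018016407040474908,
              0.0004295779729213665, 0.01255099855609984,
              -0.01657454163066688, -0.03802993693501441,
              0.08061260915108308, 0.07130921926683026,
              -0.22403618499387498, -0.14390600392856498,
              0.4697822874051931, 0.7291320908462351,
              0.3965393194819173, 0.07785205408500918)
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L))
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), L = L)
})

# One analysis step, symmetric (half-sample) signal extension. Returns the
# approximation and detail coefficient vectors, each of length
# floor((n + L - 1) / 2).
dwt_step <- function(x, filters = .db7) {
  n <- length(x); L <- filters$L; p <- L - 1L
  if (n < L)
    stop("signal of length ", n, " too short for a ", L, "-tap filter",
         call. = FALSE)
  ext <- c(x[p:1], x, x[n:(n - p + 1L)])
  out_len <- (n + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = out_len)
  full_lo <- stats::convolve(ext, rev(filters$dec_lo), type = "open")
  full_hi <- stats::convolve(ext, rev(filters$dec_hi), type = "open")
  list(a = full_lo[idx], d = full_hi[idx])
}

# One synthesis step to a target length.
idwt_step <- function(a, d, out_len, filters = .db7) {
  L <- filters$L
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq(1L, by = 2L, length.out = length(c))] <- c
    u
  }
  rec <- stats::convolve(up(a), rev(filters$rec_lo), type = "open") +
    stats::convolve(up(d), rev(filters$rec_hi), type = "open")
  rec[seq(L - 1L, length.out = out_len)]
}

#' Wavelet smoothing of a spectrum
#'
#' Multi-level Daubechies-7 decomposition with symmetric boundary extension.
#' The default denoising rule reconstructs from the deepest-level
#' approximation with every detail coefficient zeroed (deterministic and
#' parameter-free); `threshold = "soft"` instead soft-thresholds the detail
#' coefficients with the universal threshold estimated from the
#' finest-level median absolute deviation.
#'
#' @param x Numeric spectrum.
#' @param level Decomposition depth (default 3).
#' @param threshold `"none"` (zero all details) or `"soft"`.
#' @return Smoothed spectrum, same length as `x`.
#' @export
wt_smooth <- function(x, level = 3L, threshold = c("none", "soft")) {
  threshold <- match.arg(threshold)
  n0 <- length(x)
  lens <- integer(level)
  a <- x
  details <- vector("list", level)
  for (l in seq_len(level)) {
    lens[l] <- length(a)
    s <- dwt_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  if (threshold == "soft") {
    sigma <- stats::median(abs(details[[1L]])) / 0.6745
    thr <- sigma * sqrt(2 * log(n0))
    details <- lapply(details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  } else {
    details <- lapply(details, function(d) numeric(length(d)))
  }
  for (l in rev(seq_len(level)))
    a <- idwt_step(a, details[[l]], lens[l])
  a
}

# The zero-detail rule is linear, so smoothing a whole matrix of spectra is
# one multiplication by a precomputed bands x bands operator. Cached per
# (length, level).
.wt_cache <- new.env(parent = emptyenv())
wt_smooth_operator <- function(n, level = 3L) {
  key <- paste(n, level, sep = "_")
  if (!is.null(.wt_cache[[key]])) return(.wt_cache[[key]])
  S <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    wt_smooth(e, level = level)
  }, numeric(n))
  .wt_cache[[key]] <- S   # column j = smoothed unit impulse at j
  S
}

# Rows of X smoothed: (S %*% x) per column vector x => X %*% t(S).
wt_smooth_rows <- function(X, level = 3L) {
  X %*% t(wt_smooth_operator(ncol(X), level))
}

#' Standard normal variate transform
#'
#' Centers each spectrum to zero mean and scales it to unit sample standard
#' deviation (n-1 denominator), removing per-spectrum multiplicative and
#' additive scatter.
#'
#' @param x Numeric spectrum.
#' @return Transformed spectrum with mean 0, sample SD 1.
#' @export
snv <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("SNV undefined for a zero-variance spectrum", call. = FALSE)
  (x - mean(x)) / s
}

snv_rows <- function(X) {
  s <- row_sds(X)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad))
    stop("SNV undefined for zero-variance spectra at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  (X - row_means(X)) / s
}

#' Preprocess a pixel-spectra table (wavelet smoothing then SNV)
#'
#' Applies Daubechies-7 smoothing followed by the standard normal variate
#' to every row, in that order. Labels are untouched; the stage tag
#' advances from `"raw"` to `"wt+snv"`.
#'
#' @param table A raw-stage `pixel_spectra` table.
#' @param level Wavelet decomposition depth (default 3).
#' @return The preprocessed table (stage `"wt+snv"`).
#' @export
preprocess_pixels <- function(table, level = 3L) {
  stopifnot(inherits(table, "pixel_spectra"))
  if (table$stage != "raw")
    stop("table is already at stage ", table$stage,
         "; stages only advance forward", call. = FALSE)
  sm <- wt_smooth_rows(table$spectra, level = level)
  out <- pixel_spectra(snv_rows(sm), table$meta, table$wavelengths,
                       stage = "wt+snv")
  out
}

#' Object-wise average spectra
#'
#' One row per (scene, object): the arithmetic mean of that object's
#' preprocessed pixel spectra. Averaging happens after preprocessing, so an
#' object spectrum is the mean of SNV-normalized pixel spectra (not itself
#' re-normalized).
#'
#' @param table A `pixel_spectra` table at stage `"wt+snv"`.
#' @return An `object_spectra` table: `spectra`, `meta` (scene_id,
#'   object_id, class, grade, n_pixels), `wavelengths`, `stage`.
#' @export
average_by_object <- function(table) {
  stopifnot(inherits(table, "pixel_spectra"))
  if (table$stage != "wt+snv")
    stop("object averages are computed from preprocessed (wt+snv) pixel ",
         "spectra; got stage ", table$stage, call. = FALSE)
  key <- paste(table$meta$scene_id, table$meta$object_id, sep = "\r")
  ukey <- unique(key)
  grp <- match(key, ukey)
  sums <- rowsum(table$spectra, grp, reorder = TRUE)
  counts <- tabulate(grp, nbins = length(ukey))
  first <- match(ukey, key)
  meta <- data.frame(
    scene_id = table$meta$scene_id[first],
    object_id = table$meta$object_id[first],
    class = table$meta$class[first],
    grade = table$meta$grade[first],
    n_pixels = counts,
    stringsAsFactors = FALSE
  )
  out <- pixel_spectra(sums / counts, meta, table$wavelengths,
                       stage = "wt+snv")
  class(out) <- c("object_spectra", class(out))
  out
}

#' @export
print.object_spectra <- function(x, ...) {
  cat(sprintf("<object_spectra> %d objects x %d bands, stage: %s\n",
              nrow(x$spectra), ncol(x$spectra), x$stage))
  invisible(x)
}
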