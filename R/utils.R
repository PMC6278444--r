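#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded package
#' operations never disturb the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Index of the band nearest a target wavelength
#'
#' Ties by absolute difference resolve to the lower wavelength (the first
#' match on an ascending axis).
#'
#' @param wavelengths Ascending numeric vector of band centers (nm).
#' @param nm Target wavelength (nm).
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, nm) {
  stopifnot(is.numeric(wavelengths), length(wavelengths) >= 1L)
  which.min(abs(wavelengths - nm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise means/sds without apply()
row_means <- function(m) .rowMeans(m, nrow(m), ncol(m))
row_sds <- function(m) {
  mu <- row_means(m)
  sqrt(.rowSums((m - mu)^2, nrow(m), ncol(m)) / (ncol(m) - 1L))
}
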