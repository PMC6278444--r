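#' Principal component analysis of a spectra matrix
#'
#' Column-centered PCA (no scaling) via [stats::prcomp]. Loadings columns
#' are orthonormal; explained-variance ratios are non-increasing fractions
#' of total variance.
#'
#' @param X Spectra matrix, one spectrum per row.
#' @param n_components Number of components to retain (default: all
#'   available, `min(nrow - 1, ncol)`).
#' @param stage Preprocessing stage the spectra are at (recorded so scores
#'   images can match it).
#' @return A `pca_model`: loadings (bands x k), scores (rows x k),
#'   `explained_variance_ratio`, `center`, `wavelengths` attribute optional.
#' @export
pca_fit <- function(X, n_components = NULL, stage = NULL) {
  X <- as.matrix(X)
  max_k <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_k
  if (nrow(X) <= n_components)
    stop("need more rows than components", call. = FALSE)
  if (n_components > max_k)
    stop("n_components exceeds the rank bound ", max_k, call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  structure(list(loadings = p$rotation[, k, drop = FALSE],
                 scores = p$x[, k, drop = FALSE],
                 explained_variance_ratio = evr[k],
                 all_variance_ratio = evr,
                 center = p$center,
                 n_components = n_components,
                 stage = stage),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#' @param model A `pca_model`.
#' @param X Spectra matrix.
#' @return Scores matrix (rows x n_components).
#' @export
pca_scores <- function(model, X) {
  sweep(as.matrix(X), 2L, model$center) %*% model$loadings
}

#' Per-pixel PCA scores image
#'
#' Assigns each foreground pixel its score on one principal component,
#' after preprocessing the pixel spectra to the stage the model was fit on.
#' Background pixels get `NA`.
#'
#' @param model A `pca_model` fit on preprocessed spectra.
#' @param cube A corrected [hsi_cube].
#' @param objmask An `object_mask`.
#' @param pc Component index (1-based).
#' @return Numeric matrix (rows x cols) of scores, `NA` in the background.
#' @export
scores_image <- function(model, cube, objmask, pc = 1L) {
  if (pc < 1L || pc > model$n_components)
    stop("pc out of range 1..", model$n_components, call. = FALSE)
  img <- matrix(NA_real_, nrow(objmask$labels), ncol(objmask$labels))
  if (objmask$n_objects == 0L || !any(objmask$labels > 0L)) return(img)
  tab <- extract_pixel_spectra(cube, objmask)
  if (identical(model$stage, "wt+snv")) tab <- preprocess_pixels(tab)
  sc <- pca_scores(model, tab$spectra)[, pc]
  img[cbind(tab$meta$row, tab$meta$col)] <- sc
  img
}

# Local maxima of a score vector with plateau handling: a run of equal
# values is a peak if it exceeds both adjacent values (boundary runs need
# only beat their single inner neighbor); the peak position is the run's
# first (lowest-wavelength) band.
local_peak_indices <- function(score) {
  r <- rle(score)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peaks <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    if (left_ok && right_ok) peaks <- c(peaks, starts[i])
  }
  peaks
}

new_selection <- function(method, band_index, wavelengths, score,
                          n_requested) {
  ord <- order(wavelengths[band_index])
  band_index <- band_index[ord]
  structure(list(method = method,
                 selected = data.frame(
                   wavelength_nm = wavelengths[band_index],
                   band_index = band_index,
                   score = score[band_index]),
                 n_requested = n_requested,
                 band_score = score),
            class = "wavelength_selection")
}

#' @export
print.wavelength_selection <- function(x, ...) {
  cat(sprintf("<wavelength_selection> %s: %d bands\n%s\n", x$method,
              nrow(x$selected),
              paste(round(x$selected$wavelength_nm), collapse = ", ")))
  invisible(x)
}

#' Effective wavelengths from PCA loadings
#'
#' Scores each band by the maximum absolute loading over the retained PCs,
#' restricts candidates to local maxima of that score (plateaus collapse to
#' their lowest-wavelength band), and picks the top `n_select` by score
#' (ties to the lower wavelength). If there are fewer peaks than requested,
#' the remainder is filled with the highest-scoring non-peak bands.
#'
#' @param model A `pca_model`.
#' @param wavelengths Band centers (nm).
#' @param n_select Number of wavelengths to select.
#' @param n_pcs PCs whose loadings are pooled. Default: the smallest number
#'   of leading PCs whose cumulative explained variance reaches 99%, capped
#'   at 7 (the usual retention rule for NIR spectra, where a handful of PCs
#'   carry over 99% of the variance).
#' @return A `wavelength_selection` (method `"pca_loadings"`).
#' @export
select_by_pca_loadings <- function(model, wavelengths, n_select = 20L,
                                   n_pcs = NULL) {
  stopifnot(inherits(model, "pca_model"))
  bands <- nrow(model$loadings)
  if (n_select > bands) stop("n_select exceeds the number of bands",
                             call. = FALSE)
  if (is.null(n_pcs)) {
    cum <- cumsum(model$explained_variance_ratio)
    n_pcs <- min(which(cum >= 0.99), 7L, model$n_components)
    if (!is.finite(n_pcs) || length(n_pcs) == 0L) n_pcs <- model$n_components
  }
  if (n_pcs > model$n_components)
    stop("n_pcs exceeds the fitted components", call. = FALSE)
  A <- abs(model$loadings[, seq_len(n_pcs), drop = FALSE])
  score <- apply(A, 1L, max)
  peaks <- local_peak_indices(score)
  rank_order <- function(idx) idx[order(-score[idx], wavelengths[idx])]
  chosen <- rank_order(peaks)
  if (length(chosen) >= n_select) {
    chosen <- chosen[seq_len(n_select)]
  } else {
    rest <- rank_order(setdiff(seq_len(bands), peaks))
    chosen <- c(chosen, rest[seq_len(n_select - length(chosen))])
  }
  sel <- new_selection("pca_loadings", chosen, wavelengths, score, n_select)
  sel$n_pcs <- n_pcs
  sel
}

# ---- FastICA ---------------------------------------------------------------

#' FastICA decomposition of a spectra matrix
#'
#' Fixed-point FastICA with symmetric decorrelation and the logcosh
#' contrast. The data matrix (rows = samples, columns = bands) is centered
#' and whitened by SVD; the returned unmixing matrix `W` acts on centered
#' data: `S = Xc %*% t(W)` recovers the estimated sources. Sources are
#' defined up to permutation and sign.
#'
#' @param X Spectra matrix (samples x bands).
#' @param n_components Number of independent components.
#' @param seed Seed for the random orthogonal start.
#' @param max_iter Maximum fixed-point iterations (default 500).
#' @param tol Convergence tolerance on the rotation update (default 1e-6).
#' @return An `ica_model`: `W` (unmixing, k x bands), `A` (mixing, bands x
#'   k), `S` (sources, samples x k), `center`, `n_iter`, `seed`.
#' @export
ica_fit <- function(X, n_components, seed = 1L, max_iter = 500L,
                    tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= n_components)
    stop("need more rows than components", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = min(n, p))
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds the data rank (", rank,
         ")", call. = FALSE)
  k <- seq_len(n_components)
  # whitening: Z = Xc %*% t(K) has identity covariance (k x bands K)
  K <- t(sv$v[, k, drop = FALSE] / rep(sv$d[k] / sqrt(n - 1), each = p))
  Z <- Xc %*% t(K)                       # n x k, unit covariance
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), n_components) %*%
      t(e$vectors) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(n_components^2), n_components))
  W <- sym_decorrelate(W)
  it <- 0L
  repeat {
    it <- it + 1L
    U <- Z %*% t(W)                      # n x k projections
    G <- tanh(U)
    Gp <- 1 - G^2
    W_new <- (t(G) %*% Z) / n - diag(colMeans(Gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
    if (it >= max_iter)
      stop("FastICA did not converge after ", it, " iterations (delta = ",
           signif(delta, 3), ")", call. = FALSE)
  }
  W_full <- W %*% K                      # k x bands, acts on centered data
  S <- Xc %*% t(W_full)
  # mixing matrix: least-squares pseudoinverse of the unmixing map
  A <- t(W_full) %*% solve(W_full %*% t(W_full))
  structure(list(W = W_full, A = A, S = S, center = ctr,
                 n_components = n_components, n_iter = it, seed = seed),
            class = "ica_model")
}

#' Effective wavelengths from ICA unmixing weights
#'
#' Scores each band by the mean absolute unmixing weight across independent
#' components and selects the top `n_select` (ties to the lower
#' wavelength).
#'
#' @param model An `ica_model`.
#' @param wavelengths Band centers (nm).
#' @param n_select Number of wavelengths to select.
#' @return A `wavelength_selection` (method `"ica_weights"`).
#' @export
select_by_ica_weights <- function(model, wavelengths, n_select = 20L) {
  stopifnot(inherits(model, "ica_model"))
  bands <- ncol(model$W)
  if (n_select > bands) stop("n_select exceeds the number of bands",
                             call. = FALSE)
  score <- colMeans(abs(model$W))
  chosen <- order(-score, wavelengths)[seq_len(n_select)]
  new_selection("ica_weights", chosen, wavelengths, score, n_select)
}

#' Serialize a wavelength selection
#'
#' CSV columns `wavelength_nm, band_index, score, method` plus a YAML
#' provenance sidecar.
#'
#' @param sel A `wavelength_selection`.
#' @param path CSV path.
#' @param provenance Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, provenance = list()) {
  df <- sel$selected
  df$method <- sel$method
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(c(list(method = sel$method,
                          n_requested = sel$n_requested), provenance),
                   paste0(path, ".meta.yml"))
  invisible(path)
}
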