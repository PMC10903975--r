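#' Gray-matter analysis mask
#'
#' Thresholds a gray-matter probability map at `prob > threshold` (strict
#' inequality).
#'
#' @param prob_map 3D array of probabilities in `[0, 1]`.
#' @param threshold Probability threshold (default 0.3).
#' @return Logical 3D array with attributes `threshold` and `n_voxels`.
#' @export
#' @examples
#' p <- array(c(0.2, 0.3, 0.31, 0.9), c(4, 1, 1))
#' sum(gm_mask(p))  # 2: the value exactly at threshold is excluded
gm_mask <- function(prob_map, threshold = 0.3) {
  if (any(prob_map < 0 | prob_map > 1, na.rm = TRUE)) {
    stopf("probabilities must lie in [0, 1]")
  }
  mask <- prob_map > threshold
  if (sum(mask) < 2) stopf("gray-matter mask has fewer than 2 voxels at threshold %g", threshold)
  structure(mask, threshold = threshold, n_voxels = sum(mask))
}

# T x V matrix of in-mask voxel series from a bold_run / clean_run / array
mask_series <- function(run, mask) {
  data <- if (inherits(run, "clean_run")) run$run$data else if (inherits(run, "bold_run")) run$data else run
  d <- dim(data)
  if (length(d) != 4) stopf("expected a 4D array of volumes")
  if (!all(d[1:3] == dim(mask))) stopf("mask grid does not match the image grid")
  t(matrix(data, prod(d[1:3]), d[4])[c(mask), , drop = FALSE])
}

# column-standardize a T x V series matrix; constant columns become zeros
# (they contribute r = 0 edges) and are reported via the "constant" attribute
standardize_series <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  const <- s == 0
  s[const] <- 1
  structure(sweep(xc, 2, s, "/"), constant = const)
}

new_centrality_map <- function(values, mask, metric, params, standardized = FALSE,
                               smoothed_fwhm = NULL, provenance = list()) {
  structure(
    list(values = values, mask = mask, metric = metric, params = params,
         standardized = standardized, smoothed_fwhm = smoothed_fwhm,
         provenance = provenance),
    class = "centrality_map"
  )
}

#' @export
print.centrality_map <- function(x, ...) {
  cat("<centrality_map> ", x$metric, ", ", sum(x$mask), " voxels",
      if (x$standardized) ", standardized",
      if (!is.null(x$smoothed_fwhm)) paste0(", smoothed ", x$smoothed_fwhm, " mm"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.centrality_map <- function(x, ...) {
  co <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                 value = x$values[x$mask], metric = x$metric)
}

#' Voxel-wise degree centrality
#'
#' For every in-mask voxel, counts the other in-mask voxels whose time-series
#' Pearson correlation is at or above `r_threshold` (binarized positive tail;
#' negative correlations never contribute; the self-connection is excluded).
#' Correlations are computed blockwise from standardized series so the full
#' V x V matrix is never materialized. Constant voxel series get degree 0
#' with a warning.
#'
#' @param run A `clean_run`, `bold_run`, or 4D array.
#' @param mask Logical 3D mask (e.g. from [gm_mask()]).
#' @param r_threshold Correlation threshold (default 0.25, inclusive).
#' @param block_size Voxels per block in the blockwise pass (default 512).
#' @return A `centrality_map` with integer counts in `[0, V - 1]`.
#' @export
degree_centrality <- function(run, mask, r_threshold = 0.25, block_size = 512) {
  x <- mask_series(run, mask)
  nt <- nrow(x)
  if (nt < 3) stopf("need at least 3 volumes")
  z <- standardize_series(x)
  if (any(attr(z, "constant"))) {
    warnf("%d constant voxel series inside the mask; assigned degree 0",
          sum(attr(z, "constant")))
  }
  v <- ncol(z)
  dc <- integer(v)
  for (start in seq(1, v, by = block_size)) {
    idx <- start:min(start + block_size - 1, v)
    r <- crossprod(z[, idx, drop = FALSE], z) / (nt - 1)
    dc[idx] <- rowSums(r >= r_threshold) - 1L  # remove the self-connection
  }
  dc[attr(z, "constant")] <- 0L  # r(const, const) fell below threshold anyway
  vals <- array(NA_real_, dim(mask))
  vals[mask] <- dc
  new_centrality_map(vals, mask, "DC", list(r_threshold = r_threshold),
                     provenance = list(n_volumes = nt, block_size = block_size))
}

#' Fast eigenvector centrality mapping
#'
#' Computes the voxel-wise eigenvector centrality map: the principal
#' eigenvector (unit Euclidean norm, nonnegative) of the rescaled
#' correlation matrix A = (1 + R) / 2, where R is the in-mask voxel-wise
#' Pearson correlation matrix. The matrix is never formed: each power-
#' iteration step uses the identity
#' \deqn{A x = (\mathbf{1} (\mathbf{1}^T x) + Z^T (Z x) / (T - 1)) / 2}
#' with Z the column-standardized T x V series matrix, giving O(V T) cost
#' per iteration.
#'
#' @inheritParams degree_centrality
#' @param tol Convergence tolerance on the successive-iterate max-abs
#'   difference (default 1e-10).
#' @param max_iter Maximum power iterations (default 1000).
#' @return A `centrality_map` with nonnegative weights of unit norm;
#'   `provenance` records iterations and the final residual.
#' @export
fast_ecm <- function(run, mask, tol = 1e-10, max_iter = 1000) {
  x <- mask_series(run, mask)
  nt <- nrow(x)
  if (nt < 3) stopf("need at least 3 volumes")
  z <- standardize_series(x)
  v <- ncol(z)
  ec <- rep(1 / sqrt(v), v)
  resid <- Inf
  iters <- 0L
  for (i in seq_len(max_iter)) {
    ax <- (sum(ec) + crossprod(z, z %*% ec) / (nt - 1)) / 2
    ax <- as.numeric(ax)
    ax <- ax / sqrt(sum(ax^2))
    resid <- max(abs(ax - ec))
    ec <- ax
    iters <- i
    if (resid < tol) break
  }
  if (resid >= tol) {
    stopf("fast ECM did not converge in %d iterations (last residual %.3e)",
          max_iter, resid)
  }
  vals <- array(NA_real_, dim(mask))
  vals[mask] <- ec
  new_centrality_map(vals, mask, "EC", list(tol = tol, max_iter = max_iter),
                     provenance = list(n_volumes = nt, iterations = iters,
                                       residual = resid))
}

#' Standardize a centrality map
#'
#' Per-subject within-mask standardization of a raw centrality map before
#' group analysis. The default (`method = "zscore"`) subtracts the within-
#' mask mean and divides by the within-mask SD; `method = "fisher"` applies
#' atanh, appropriate only for correlation-valued maps.
#'
#' @param map A `centrality_map`.
#' @param method `"zscore"` (default) or `"fisher"`.
#' @return The standardized `centrality_map`.
#' @export
standardize_map <- function(map, method = c("zscore", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "centrality_map"))
  vals <- map$values[map$mask]
  if (method == "zscore") {
    s <- sd(vals)
    if (s == 0) stopf("within-mask SD is zero; cannot standardize a constant map")
    map$values[map$mask] <- (vals - mean(vals)) / s
  } else {
    if (any(abs(vals) >= 1)) stopf("Fisher transform requires values in (-1, 1)")
    map$values[map$mask] <- atanh(vals)
  }
  map$standardized <- TRUE
  map$params$standardize_method <- method
  map
}

# 1D Gaussian kernel sampled at integer offsets, truncated at 4 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable 3D convolution of `arr` with per-axis kernel `k` (zero padding)
convolve_separable <- function(arr, k) {
  d <- dim(arr)
  half <- (length(k) - 1) / 2
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, da[1], da[2] * da[3])
    padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- matrix(0, da[1], ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + da[1] - 1), , drop = FALSE]
    }
    arr <- aperm(array(out, da), order(perm))
  }
  arr
}

#' Smooth a centrality map
#'
#' Masked 3D Gaussian smoothing: the map (zeros outside the mask) and the
#' mask itself are convolved with a separable Gaussian kernel of the given
#' full width at half maximum, and their ratio is re-masked, so out-of-mask
#' voxels neither contribute signal nor dilute edge voxels. FWHM below half
#' a voxel leaves the map unchanged.
#'
#' @param map A `centrality_map` (standardize first; the published order is
#'   standardization then smoothing).
#' @param fwhm_mm Kernel full width at half maximum in mm (default 6).
#' @param voxel_size_mm Isotropic voxel size in mm (default 3.31).
#' @return The smoothed `centrality_map`.
#' @export
smooth_map <- function(map, fwhm_mm = 6, voxel_size_mm = 3.31) {
  stopifnot(inherits(map, "centrality_map"))
  if (fwhm_mm <= 0) stopf("`fwhm_mm` must be positive")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  if (fwhm_mm < voxel_size_mm / 2) {
    map$smoothed_fwhm <- fwhm_mm
    return(map)
  }
  k <- gaussian_kernel_1d(sigma_vox)
  vals <- map$values
  vals[!map$mask] <- 0
  num <- convolve_separable(vals, k)
  den <- convolve_separable(array(as.numeric(map$mask), dim(map$mask)), k)
  sm <- array(NA_real_, dim(map$mask))
  sm[map$mask] <- num[map$mask] / den[map$mask]
  map$values <- sm
  map$smoothed_fwhm <- fwhm_mm
  map
}

#' Write / read a centrality map as NIfTI
#'
#' @param map A `centrality_map` (out-of-mask voxels are written as 0).
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size recorded in the header (default 3.31).
#' @return `write_centrality_map()` returns `path` invisibly.
#' @export
write_centrality_map <- function(map, path, voxel_size_mm = 3.31) {
  vals <- map$values
  vals[!map$mask] <- 0
  RNifti::writeNifti(RNifti::asNifti(vals, pixdim = rep(voxel_size_mm, 3)), path)
  invisible(path)
}
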