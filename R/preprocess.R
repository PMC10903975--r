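#' Discard initial volumes
#'
#' Drops the first `n` volumes of a BOLD run (signal-equilibration scans) and
#' truncates the motion trace identically.
#'
#' @param run A `bold_run` object.
#' @param n Number of leading volumes to discard (default 10).
#' @return The truncated `bold_run`.
#' @export
discard_initial <- function(run, n = 10) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (nt <= n) stopf("run has %d volumes; cannot discard %d", nt, n)
  if (n > 0) {
    run$data <- run$data[, , , -(seq_len(n)), drop = FALSE]
    run$motion <- run$motion[-(seq_len(n)), , drop = FALSE]
  }
  run$steps <- c(run$steps, sprintf("discard_initial(n = %d)", n))
  run
}

#' Frame-wise displacement (Power's method)
#'
#' Per-volume head-motion summary: the sum of absolute backward differences
#' of the three translations (mm) plus the three rotations (rad) converted to
#' arc length on a 50 mm sphere. The first frame's FD is 0 by convention.
#'
#' @param motion T x 6 matrix: columns 1-3 translations in mm, 4-6 rotations
#'   in radians.
#' @param radius_mm Sphere radius for the rotation-to-displacement conversion
#'   (default 50).
#' @return Tibble with columns `frame` and `fd` (mm); attribute-free, use
#'   `mean(fd)` for the mean FD covariate.
#' @export
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 1
#' compute_fd_power(m)$fd  # 0 0 1 1 0
compute_fd_power <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion trace must have 6 columns, got %d", ncol(motion))
  if (nrow(motion) < 2) stopf("need at least 2 volumes to compute FD")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  tibble::tibble(frame = seq_len(nrow(motion)), fd = fd)
}

#' Motion-based exclusion decision
#'
#' Excludes a run when the maximum absolute translation exceeds 3 mm on any
#' axis or the maximum absolute rotation exceeds 3 degrees on any axis
#' (strictly "more than": values at exactly the limit are kept).
#'
#' @param motion T x 6 matrix (translations mm, rotations rad).
#' @param trans_limit_mm,rot_limit_deg Exclusion limits (defaults 3 mm, 3
#'   degrees).
#' @return One-row tibble: `max_translation_mm`, `max_rotation_deg`,
#'   `exclude`.
#' @export
screen_motion <- function(motion, trans_limit_mm = 3, rot_limit_deg = 3) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion trace must have 6 columns")
  max_trans <- max(abs(motion[, 1:3]))
  max_rot_deg <- max(abs(motion[, 4:6])) * 180 / pi
  tibble::tibble(
    max_translation_mm = max_trans,
    max_rotation_deg = max_rot_deg,
    exclude = max_trans > trans_limit_mm | max_rot_deg > rot_limit_deg
  )
}

#' Friston 24-parameter motion expansion
#'
#' Expands a 6-parameter rigid motion trace into the 24-regressor set: the
#' parameters, their squares, their one-volume lags, and the squared lags.
#' The first row of the lagged blocks is zero-padded.
#'
#' @param motion T x 6 matrix.
#' @return T x 24 matrix with columns `p1..p6, p1_sq.., p1_lag.., p1_lag_sq..`.
#' @export
friston24_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion trace must have 6 columns")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("p", 1:6, "_lag"), paste0("p", 1:6, "_lag_sq"))
  out
}

# mean tissue signal within an eroded high-probability mask; falls back to
# the uneroded mask when erosion empties it
tissue_mean_series <- function(data4d, prob_map, threshold = 0.9, erode = TRUE) {
  mask <- prob_map > threshold
  if (erode) {
    # erosion guards against partial-volume contamination; thin compartments
    # (small phantoms) erode to nothing, in which case the full mask is used
    er <- erode_mask(mask)
    if (any(er)) mask <- er
  }
  if (!any(mask)) stopf("tissue mask empty at probability threshold %g", threshold)
  apply(matrix(data4d, prod(dim(data4d)[1:3]), dim(data4d)[4])[c(mask), , drop = FALSE], 2, mean)
}

# 6-neighbourhood binary erosion of a 3D logical array
erode_mask <- function(mask) {
  d <- dim(mask)
  shift1 <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- mask
  for (ax in 1:3) for (by in c(1, -1)) out <- out & shift1(mask, ax, by)
  out
}

#' Assemble the nuisance regressor set
#'
#' Builds the joint nuisance design for a run: Friston-24 motion regressors,
#' mean white-matter and CSF signals from eroded high-probability tissue
#' masks, a linear trend, and an intercept.
#'
#' @param run A `bold_run` (after [discard_initial()]).
#' @param tissue_threshold Probability threshold for the WM/CSF masks
#'   (default 0.9, eroded by one voxel).
#' @return T x 28 numeric matrix (intercept, trend, 24 motion columns, WM,
#'   CSF).
#' @export
build_nuisance <- function(run, tissue_threshold = 0.9) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  fr24 <- friston24_expand(run$motion)
  wm <- tissue_mean_series(run$data, run$wm_prob, tissue_threshold)
  csf <- tissue_mean_series(run$data, run$csf_prob, tissue_threshold)
  x <- cbind(intercept = 1, trend = seq_len(nt) - (nt + 1) / 2, fr24, wm = wm, csf = csf)
  rownames(x) <- NULL
  x
}

#' Nuisance regression of voxel time series
#'
#' Removes the nuisance set from every voxel series by a single joint OLS
#' (detrending via the trend column), returning residuals. Collinear
#' regressors are dropped with a warning.
#'
#' @param run A `bold_run`.
#' @param nuisance T x k regressor matrix, e.g. from [build_nuisance()].
#' @return The `bold_run` with `data` replaced by residuals.
#' @export
clean_timeseries <- function(run, nuisance) {
  stopifnot(inherits(run, "bold_run"))
  nuisance <- as.matrix(nuisance)
  nt <- dim(run$data)[4]
  if (nrow(nuisance) != nt) {
    stopf("nuisance rows (%d) must match volumes (%d)", nrow(nuisance), nt)
  }
  qrx <- qr(nuisance)
  if (qrx$rank < ncol(nuisance)) {
    dropped <- colnames(nuisance)[qrx$pivot[(qrx$rank + 1):ncol(nuisance)]]
    warnf("dropping collinear nuisance regressors: %s", paste(dropped, collapse = ", "))
    nuisance <- nuisance[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(nuisance)
  }
  y <- matrix(run$data, prod(dim(run$data)[1:3]), nt)
  resid <- t(qr.resid(qrx, t(y)))
  run$data <- array(resid, dim = dim(run$data))
  run$steps <- c(run$steps, sprintf("clean_timeseries(k = %d)", ncol(nuisance)))
  run
}

#' Ideal band-pass filter
#'
#' Retains frequency content in `[low, high]` Hz with an ideal rectangular
#' transfer function in the discrete Fourier domain after demeaning (the DC
#' component is always removed). A Butterworth alternative (order 4,
#' forward-backward) is available via `method = "butterworth"`.
#'
#' @param x Numeric vector, T x V matrix of time series (columns = voxels),
#'   or a `bold_run`.
#' @param low,high Pass-band edges in Hz (defaults 0.01 and 0.1).
#' @param tr Repetition time in seconds (default 3; taken from the run when
#'   `x` is a `bold_run`).
#' @param method `"ideal"` (default) or `"butterworth"` (requires the
#'   `signal` package).
#' @return Object of the same shape as `x`, filtered.
#' @export
#' @examples
#' t <- seq_len(130)
#' s <- sin(2 * pi * 0.05 * t * 3)   # 0.05 Hz at TR 3 s: inside the band
#' f <- bandpass_filter(s, tr = 3)
#' max(abs(f - (s - mean(s)))) < 1e-6
bandpass_filter <- function(x, low = 0.01, high = 0.1, tr = 3,
                            method = c("ideal", "butterworth")) {
  method <- match.arg(method)
  if (low >= high) stopf("`low` must be below `high`")
  if (inherits(x, "bold_run")) {
    nt <- dim(x$data)[4]
    y <- matrix(x$data, prod(dim(x$data)[1:3]), nt)
    filt <- bandpass_filter(t(y), low, high, tr = x$tr %||% tr, method = method)
    x$data <- array(t(filt), dim = dim(x$data))
    x$steps <- c(x$steps, sprintf("bandpass_filter(%g-%g Hz, %s)", low, high, method))
    return(x)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  nt <- nrow(xm)
  if (nt < 16) stopf("need at least 16 volumes to band-pass filter")
  if (method == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stopf("the `signal` package is required for method = \"butterworth\"")
    }
    nyq <- 1 / (2 * tr)
    bf <- signal::butter(4, c(low, min(high, nyq * 0.999)) / nyq, type = "pass")
    xm <- sweep(xm, 2, colMeans(xm))
    out <- apply(xm, 2, function(col) signal::filtfilt(bf, col))
  } else {
    xm <- sweep(xm, 2, colMeans(xm))
    freqs <- seq(0, nt - 1) / (nt * tr)
    freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
    keep <- freqs >= low & freqs <= high
    keep[1] <- FALSE  # DC always removed
    ft <- stats::mvfft(xm)
    ft[!keep, ] <- 0
    out <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  }
  if (vec) drop(out) else out
}

#' Run the full cleaning chain on a BOLD run
#'
#' Applies the fixed preprocessing order: discard initial volumes, motion
#' screening, joint detrend + nuisance regression (Friston-24, WM, CSF), and
#' band-pass filtering. Mean FD is computed on the retained volumes.
#'
#' @param run A raw `bold_run`.
#' @param discard Leading volumes to drop (default 10).
#' @param low,high Band-pass edges in Hz.
#' @param trans_limit_mm,rot_limit_deg Motion-exclusion limits.
#' @param bandpass_method Passed to [bandpass_filter()].
#' @return A list of class `clean_run`: the cleaned `bold_run` (`run`), the
#'   QC row (`qc`: mean FD, max motion, exclusion flag) and the provenance of
#'   applied steps.
#' @export
preprocess_run <- function(run, discard = 10, low = 0.01, high = 0.1,
                           trans_limit_mm = 3, rot_limit_deg = 3,
                           bandpass_method = "ideal") {
  stopifnot(inherits(run, "bold_run"))
  run <- discard_initial(run, n = discard)
  qc <- screen_motion(run$motion, trans_limit_mm, rot_limit_deg)
  fd <- compute_fd_power(run$motion)
  qc$mean_fd <- mean(fd$fd)
  qc$participant_id <- run$participant_id %||% NA_character_
  qc$timepoint <- run$timepoint %||% NA_character_
  if (!qc$exclude) {
    run <- clean_timeseries(run, build_nuisance(run))
    run <- bandpass_filter(run, low = low, high = high, method = bandpass_method)
  }
  structure(list(run = run, qc = qc, fd = fd, steps = run$steps),
            class = "clean_run")
}

#' @export
print.clean_run <- function(x, ...) {
  cat("<clean_run> ", paste(dim(x$run$data), collapse = " x "),
      if (x$qc$exclude) "  [EXCLUDED: motion]" else "", "\n", sep = "")
  cat("  mean FD:", signif(x$qc$mean_fd, 4), "mm; steps:",
      paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}
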