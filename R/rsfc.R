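# Resting-state functional connectivity: framewise displacement, motion
# scrubbing, band-pass filtering, nuisance regression, seed correlation.
#
# Cleaning order (fixed, mirroring the reported recipe): linear+quadratic
# detrend -> motion regression -> FD scrubbing (mask) -> band-pass on the
# scrub-interpolated series -> nuisance regression -> drop masked volumes
# -> correlate -> Fisher z.

#' Framewise displacement from a six-parameter motion table
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) and the three rotations converted to arc length on a
#' sphere of `head_radius` mm. The first volume has FD 0.
#'
#' @param motion volumes x 6 table: 3 translations (mm) then 3 rotations.
#' @param head_radius sphere radius for the rotation conversion (mm,
#'   default 50).
#' @param rotation_unit `"degrees"` (default) or `"radians"`.
#' @return FD per volume (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 50,
                                   rotation_unit = c("degrees", "radians")) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have exactly 6 columns")
  rotation_unit <- match.arg(rotation_unit)
  rot <- motion[, 4:6, drop = FALSE]
  if (rotation_unit == "degrees") rot <- rot * pi / 180
  m <- cbind(motion[, 1:3, drop = FALSE], rot * head_radius)
  d <- abs(diff(m))
  c(0, rowSums(d))
}

#' Scrub high-motion volumes
#'
#' Flags volumes whose framewise displacement exceeds `threshold` (mm); the
#' flagged volumes are excluded from the connectivity computation. More than
#' 10% flagged raises a warning; more than 50% is an error (series unusable).
#'
#' @param series volumes x ROIs matrix.
#' @param fd framewise displacement per volume.
#' @param threshold FD threshold in mm (default 0.5).
#' @return the series with attributes `keep` (logical mask of retained
#'   volumes) and `n_scrubbed`.
#' @export
scrub <- function(series, fd, threshold = 0.5) {
  series <- as.matrix(series)
  if (length(fd) != nrow(series)) stop("FD length must match volume count")
  bad <- fd > threshold
  if (mean(bad) > 0.5)
    stop("more than 50% of volumes exceed the FD threshold; series unusable")
  if (mean(bad) > 0.1)
    warning(sprintf("%d of %d volumes scrubbed (>10%%)", sum(bad), length(bad)))
  attr(series, "keep") <- !bad
  attr(series, "n_scrubbed") <- sum(bad)
  series
}

#' Band-pass filter ROI time series
#'
#' Ideal zero-phase Fourier-domain band-pass: frequency components outside
#' \[low, high\] Hz (including DC) are removed from each column.
#'
#' @param series volumes x ROIs matrix (or a vector).
#' @param low,high band edges in Hz (defaults 0.01 and 0.08).
#' @param TR repetition time in seconds.
#' @return the filtered series, same shape.
#' @export
bandpass <- function(series, low = 0.01, high = 0.08, TR = 2) {
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  n <- nrow(x)
  nyq <- 1 / (2 * TR)
  if (low <= 0 || high <= low || high > nyq)
    stop("band edges must satisfy 0 < low < high <= Nyquist")
  f <- seq(0, n - 1) / (n * TR)
  f <- pmin(f, 1 / TR - f)                 # folded (absolute) frequency
  keep <- f >= low & f <= high
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares residualization of each ROI column on the supplied
#' regressors (e.g. the six motion parameters, or white-matter and CSF
#' average signals), with an intercept.
#'
#' @param series volumes x ROIs matrix (or vector).
#' @param regressors volumes x k matrix of nuisance signals.
#' @param add_intercept include an intercept column (default TRUE).
#' @return residual series, orthogonal to the regressors.
#' @export
nuisance_regress <- function(series, regressors, add_intercept = TRUE) {
  vec <- is.null(dim(series))
  y <- as.matrix(series)
  X <- as.matrix(regressors)
  if (nrow(X) != nrow(y)) stop("regressors must have one row per volume")
  if (add_intercept) X <- cbind(intercept = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("nuisance regressor set is rank deficient")
  out <- y - X %*% qr.coef(qx, y)
  if (vec) drop(out) else out
}

# remove per-column linear and quadratic trends (plus mean)
detrend_quadratic <- function(series) {
  y <- as.matrix(series)
  t1 <- seq_len(nrow(y))
  nuisance_regress(y, cbind(t1, t1^2))
}

#' Seed-to-seed connectivity of two ROIs
#'
#' Pearson correlation of two ROI columns over the retained volumes, with
#' Fisher z transform.
#'
#' @param series volumes x ROIs matrix (cleaned).
#' @param roi_a,roi_b column names or indices of the two ROIs (must differ).
#' @param keep optional logical mask of volumes to use (e.g. the scrub
#'   mask); default all.
#' @return An object of class `connectivity_result`: `roi_a`, `roi_b`, `r`,
#'   `z` (= atanh(r)), `n_volumes`.
#' @export
seed_connectivity <- function(series, roi_a, roi_b, keep = NULL) {
  series <- as.matrix(series)
  ia <- if (is.character(roi_a)) match(roi_a, colnames(series)) else roi_a
  ib <- if (is.character(roi_b)) match(roi_b, colnames(series)) else roi_b
  if (is.na(ia) || is.na(ib)) stop("unknown ROI")
  if (ia == ib) stop("self-connectivity is not meaningful: choose two distinct ROIs")
  if (is.null(keep)) keep <- rep(TRUE, nrow(series))
  if (sum(keep) < 30L) stop("fewer than 30 usable volumes")
  r <- stats::cor(series[keep, ia], series[keep, ib])
  structure(list(roi_a = roi_a, roi_b = roi_b, r = r, z = atanh(r),
                 n_volumes = sum(keep)),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("rsFC %s - %s: r = %.3f, Fisher z = %.3f (%d volumes)\n",
              x$roi_a, x$roi_b, x$r, x$z, x$n_volumes))
  invisible(x)
}

# linear interpolation across masked volumes, per column (so the Fourier
# filter does not see the scrubbed spikes)
.interpolate_masked <- function(series, keep) {
  y <- as.matrix(series)
  if (all(keep)) return(y)
  t1 <- seq_len(nrow(y))
  apply(y, 2L, function(cl)
    stats::approx(t1[keep], cl[keep], xout = t1, rule = 2)$y)
}

#' Full resting-state connectivity pipeline
#'
#' Applies the cleaning chain (detrend, motion regression, FD scrubbing,
#' band-pass on the scrub-interpolated series, optional nuisance regression)
#' and returns the Fisher-z connectivity of every ROI pair over the
#' retained volumes.
#'
#' @param series volumes x ROIs matrix with ROI column names.
#' @param motion volumes x 6 motion table (translations mm, rotations
#'   degrees).
#' @param TR repetition time (s).
#' @param fd_threshold scrubbing threshold in mm (default 0.5).
#' @param band band-pass edges in Hz (default c(0.01, 0.08)).
#' @param nuisance optional volumes x k matrix of additional nuisance
#'   signals (e.g. white-matter and CSF averages), regressed out after
#'   filtering.
#' @param interpolate interpolate across scrubbed volumes before filtering
#'   (default TRUE).
#' @return A list with `pairs` (data.frame: roi_a, roi_b, r, z, n_volumes),
#'   `n_scrubbed` and the cleaned `series`.
#' @export
rsfc_pipeline <- function(series, motion, TR = 2, fd_threshold = 0.5,
                          band = c(0.01, 0.08), nuisance = NULL,
                          interpolate = TRUE) {
  y <- detrend_quadratic(series)
  colnames(y) <- colnames(as.matrix(series))
  mo <- as.matrix(motion)
  mo <- mo[, apply(mo, 2L, function(cl) stats::sd(cl) > 0), drop = FALSE]
  if (ncol(mo) > 0) y <- nuisance_regress(y, mo)
  fd <- framewise_displacement(motion)
  y <- scrub(y, fd, fd_threshold)
  keep <- attr(y, "keep")
  n_scrubbed <- attr(y, "n_scrubbed")
  yf <- if (interpolate) .interpolate_masked(y, keep) else y
  yf <- bandpass(yf, band[1], band[2], TR)
  if (!is.null(nuisance)) yf <- nuisance_regress(yf, nuisance)
  colnames(yf) <- colnames(as.matrix(series))
  rois <- colnames(yf)
  if (is.null(rois)) rois <- paste0("roi", seq_len(ncol(yf)))
  cmb <- utils::combn(rois, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    cr <- seed_connectivity(yf, cmb[1, j], cmb[2, j], keep)
    data.frame(roi_a = cr$roi_a, roi_b = cr$roi_b, r = cr$r, z = cr$z,
               n_volumes = cr$n_volumes, stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, n_scrubbed = n_scrubbed, series = yf, keep = keep)
}
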