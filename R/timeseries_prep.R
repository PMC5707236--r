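# ROI time-series cleanup: nuisance regression with temporal derivatives,
# FFT band-pass filtering, and framewise-displacement scrubbing with the
# subject-exclusion rule.

#' Nuisance regression with temporal derivatives
#'
#' Replaces every ROI series by its least-squares residual against a design
#' made of an intercept, the nuisance regressors, and (optionally) their
#' backward-difference first temporal derivatives (the derivative at the
#' first volume is defined as 0). Exactly duplicated design columns are
#' dropped; a design that is still rank-deficient is an error naming the
#' offending columns.
#'
#' @param ts numeric matrix, volumes x ROIs.
#' @param nuisance numeric matrix, volumes x k (e.g. 6 motion parameters,
#'   global, WM and CSF signals).
#' @param include_derivatives add backward-difference derivatives of every
#'   nuisance column (default TRUE).
#' @return residual matrix, volumes x ROIs (same dimnames as `ts`).
#' @export
nuisance_regress <- function(ts, nuisance, include_derivatives = TRUE) {
  ts <- as.matrix(ts); nuisance <- as.matrix(nuisance)
  if (nrow(ts) != nrow(nuisance))
    stop("time series and nuisance matrices differ in volume count",
         call. = FALSE)
  if (any(!is.finite(ts)) || any(!is.finite(nuisance)))
    stop("non-finite values in input", call. = FALSE)
  X <- nuisance
  colnames(X) <- if (is.null(colnames(nuisance)))
    paste0("nuis", seq_len(ncol(nuisance))) else colnames(nuisance)
  if (include_derivatives) {
    D <- rbind(0, diff(X))
    colnames(D) <- paste0("d_", colnames(X))
    X <- cbind(X, D)
  }
  X <- cbind(intercept = 1, X)
  # drop exact duplicate columns
  dup <- duplicated(t(X))
  if (any(dup)) X <- X[, !dup, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("nuisance design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- ts - X %*% qr.coef(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Band-pass filter ROI time series
#'
#' Removes a per-series linear trend, then keeps only Fourier components with
#' frequency inside `[low_hz, high_hz]` by masking the FFT. Because
#' detrending and masking do not commute (a band-limited series still has a
#' small fitted trend), the in-band image of the trend line is projected out
#' afterwards; with the default hard mask the whole operator is then an
#' exact orthogonal projection, hence exactly idempotent. A cosine roll-off
#' of width `taper_hz` on each band edge is available when a gentler
#' transition is wanted (idempotency then holds only approximately on the
#' taper bins).
#'
#' @param ts numeric matrix, volumes x ROIs.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param low_hz,high_hz pass band in Hz; defaults 0.008-0.08, the standard
#'   resting-state band.
#' @param taper_hz cosine roll-off half-width in Hz (default 0 = hard mask).
#' @return filtered matrix, same shape and dimnames as `ts`.
#' @export
bandpass <- function(ts, tr_seconds = 2, low_hz = 0.008, high_hz = 0.08,
                     taper_hz = 0) {
  ts <- as.matrix(ts)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist))
    stop(sprintf("band must satisfy 0 < low < high < Nyquist (%.3f Hz)",
                 nyquist), call. = FALSE)
  n <- nrow(ts)
  t0 <- seq_len(n)
  X <- cbind(1, t0 - mean(t0))
  qrX <- qr(X)
  k <- seq_len(n) - 1
  # mirrored integer bins keep the mask exactly conjugate-symmetric
  freqs <- pmin(k, n - k) / (n * tr_seconds)
  mask <- if (taper_hz <= 0) {
    as.numeric(freqs >= low_hz & freqs <= high_hz)
  } else {
    ramp_up <- 0.5 * (1 - cos(pi * pmin(pmax((freqs - (low_hz - taper_hz)) /
                                               taper_hz, 0), 1)))
    ramp_dn <- 0.5 * (1 + cos(pi * pmin(pmax((freqs - high_hz) /
                                               taper_hz, 0), 1)))
    ramp_up * ramp_dn
  }
  apply_mask <- function(m)
    Re(stats::mvfft(stats::mvfft(m) * mask, inverse = TRUE)) / n
  out <- apply_mask(ts - X %*% qr.coef(qrX, ts))
  # the trend line leaks slightly into the pass band; remove its in-band
  # image so the operator is an exact projection (mask o detrend alone is
  # not: the masked series regains a small fitted trend)
  MX <- apply_mask(X)
  MX <- MX[, sqrt(colSums(MX^2)) > 1e-10 * sqrt(n), drop = FALSE]
  if (ncol(MX) > 0)
    out <- out - MX %*% qr.coef(qr(MX), out)
  dimnames(out) <- dimnames(ts)
  out
}

#' Framewise displacement from motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six rigid
#' body parameters, with the three rotation columns (radians) converted to
#' arc length on a `head_radius_mm` sphere. FD of the first volume is 0.
#'
#' @param motion numeric matrix, volumes x 6: three translations (mm) then
#'   three rotations (radians).
#' @param head_radius_mm sphere radius for rotation-to-mm conversion
#'   (default 50).
#' @return numeric vector of FD values (mm), one per volume.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion matrix must have 6 columns (x, y, z, pitch, roll, yaw)",
         call. = FALSE)
  if (nrow(motion) < 2)
    stop("need at least 2 volumes", call. = FALSE)
  scaled <- motion
  scaled[, 4:6] <- scaled[, 4:6] * head_radius_mm
  c(0, rowSums(abs(diff(scaled))))
}

#' Motion scrubbing mask and subject-exclusion flag
#'
#' Volumes whose framewise displacement exceeds `fd_threshold_mm` are marked
#' bad, together with `n_back` preceding and `n_forward` following volumes
#' (to catch spin-history effects). The subject is flagged for exclusion when
#' strictly more than `exclude_fraction` of the volumes are scrubbed.
#'
#' @param motion volumes x 6 motion-parameter matrix (mm, radians).
#' @param fd_threshold_mm FD threshold in mm (default 0.5).
#' @param n_back,n_forward augmentation width (defaults 1 and 2).
#' @param exclude_fraction exclusion rule fraction (default 1/3).
#' @param head_radius_mm passed to [framewise_displacement()].
#' @return list with `volume_mask` (TRUE = retained), `fd`, `n_scrubbed`,
#'   `exclude` flag.
#' @export
scrub <- function(motion, fd_threshold_mm = 0.5, n_back = 1, n_forward = 2,
                  exclude_fraction = 1 / 3, head_radius_mm = 50) {
  fd <- framewise_displacement(motion, head_radius_mm)
  n <- length(fd)
  bad <- which(fd > fd_threshold_mm)
  if (length(bad)) {
    aug <- unique(unlist(lapply(bad, function(i)
      seq(i - n_back, i + n_forward))))
    bad <- sort(aug[aug >= 1 & aug <= n])
  }
  mask <- rep(TRUE, n)
  mask[bad] <- FALSE
  n_scrubbed <- sum(!mask)
  list(volume_mask = mask, fd = fd, n_scrubbed = n_scrubbed,
       exclude = n_scrubbed > exclude_fraction * n)
}

#' Clean one subject's ROI time series
#'
#' Convenience chain in the pipeline's canonical order: nuisance regression
#' (with derivatives) on the full series, band-pass filtering, then
#' scrubbing-by-deletion of high-motion volumes.
#'
#' @param ts volumes x ROIs matrix.
#' @param motion volumes x 6 motion parameters.
#' @param nuisance volumes x k nuisance regressors (typically the 6 motion
#'   parameters plus global/WM/CSF signals).
#' @param tr_seconds repetition time (s).
#' @param fd_threshold_mm,low_hz,high_hz tuning, see the stage functions.
#' @return list with `data` (retained volumes x ROIs), `volume_mask`,
#'   `exclude` flag, `fd`.
#' @export
prep_subject <- function(ts, motion, nuisance, tr_seconds = 2,
                         fd_threshold_mm = 0.5,
                         low_hz = 0.008, high_hz = 0.08) {
  clean <- nuisance_regress(ts, nuisance)
  clean <- bandpass(clean, tr_seconds, low_hz, high_hz)
  sc <- scrub(motion, fd_threshold_mm)
  list(data = clean[sc$volume_mask, , drop = FALSE],
       volume_mask = sc$volume_mask, exclude = sc$exclude, fd = sc$fd)
}
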