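#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of an acquisition (and the matching
#' motion rows) so that only steady-state magnetisation volumes enter the
#' analysis; the conventional choice, and the default throughout the
#' pipeline, is 5.
#'
#' @param vs a [volume_series()].
#' @param motion `T x 6` motion-parameter matrix (or `NULL`).
#' @param n_discard number of leading volumes to drop (< T).
#' @return List with the trimmed `vs` and `motion`.
#' @export
discard_initial <- function(vs, motion = NULL, n_discard = 5L) {
  stopifnot(inherits(vs, "volume_series"))
  nt <- ncol(vs$mat)
  if (n_discard < 0 || n_discard >= nt) {
    stop("`n_discard` (", n_discard, ") must be in [0, T) with T = ", nt)
  }
  if (!is.null(motion) && nrow(motion) != nt) {
    stop("motion table has ", nrow(motion), " rows but T = ", nt)
  }
  if (n_discard == 0) return(list(vs = vs, motion = motion))
  keep <- (n_discard + 1L):nt
  vs$mat <- vs$mat[, keep, drop = FALSE]
  list(vs = vs,
       motion = if (is.null(motion)) NULL else motion[keep, , drop = FALSE])
}

# 1D Gaussian convolution matrix with edge renormalisation (rows sum to 1),
# used separably along each axis.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma_vox))
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  M
}

#' Spatial Gaussian smoothing at a given FWHM
#'
#' Per-volume separable Gaussian smoothing restricted to the mask, at the
#' stated full-width-half-maximum in mm (`sigma = FWHM / (2 sqrt(2 ln 2))`
#' per axis, in voxel units). Voxels outside the mask contribute nothing:
#' the data are smoothed as `G*(x * m) / G*(m)` (normalised convolution), so
#' signal mass is neither drawn from nor leaked into the background.
#' `fwhm_mm = 0` is the identity.
#'
#' @param vs a [volume_series()].
#' @param fwhm_mm smoothing kernel FWHM in mm (>= 0).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return The smoothed [volume_series()].
#' @export
smooth_spatial <- function(vs, fwhm_mm = 1.2, voxel_size_mm = c(0.4, 0.4, 0.6)) {
  stopifnot(inherits(vs, "volume_series"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (fwhm_mm == 0) return(vs)
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- vs$dims
  Mx <- gauss_conv_matrix(d[1], sig_vox[1])
  My <- gauss_conv_matrix(d[2], sig_vox[2])
  Mz <- gauss_conv_matrix(d[3], sig_vox[3])

  smooth_vol <- function(v3) {
    # separable convolution as matrix products along each axis
    a <- matrix(v3, d[1], d[2] * d[3])
    a <- Mx %*% a
    a <- array(a, d)
    a <- aperm(a, c(2, 1, 3))
    a <- My %*% matrix(a, d[2], d[1] * d[3])
    a <- aperm(array(a, c(d[2], d[1], d[3])), c(2, 1, 3))
    a <- aperm(a, c(3, 1, 2))
    a <- Mz %*% matrix(a, d[3], d[1] * d[2])
    aperm(array(a, c(d[3], d[1], d[2])), c(2, 3, 1))
  }

  mask_num <- array(0, d)
  mask_num[vs$mask] <- 1
  sm_mask <- smooth_vol(mask_num)
  sm_mask_v <- sm_mask[vs$mask]
  sm_mask_v[sm_mask_v <= 0] <- 1

  idx <- which(vs$mask)
  out <- vs$mat
  vol <- array(0, d)
  for (t in seq_len(ncol(vs$mat))) {
    vol[] <- 0
    vol[idx] <- vs$mat[, t]
    sm <- smooth_vol(vol)
    out[, t] <- sm[idx] / sm_mask_v
  }
  vs$mat <- out
  vs
}

#' Regress polynomial trend and motion parameters out of voxel time-series
#'
#' Ordinary least-squares projection of each voxel series onto an intercept,
#' a polynomial time trend of order `detrend_order`, and the 6 motion
#' columns; the residuals are returned. Collinear columns (rank-deficient
#' design) are dropped with a warning.
#'
#' @param ts_matrix `V x T` matrix of voxel time-series.
#' @param motion `T x 6` motion matrix, or `NULL` for detrending only.
#' @param detrend_order polynomial trend order (0 = mean removal only; the
#'   pipeline default is 1, linear detrending).
#' @return `V x T` residual matrix with attribute `design` (the regressors
#'   used).
#' @export
regress_nuisance <- function(ts_matrix, motion = NULL, detrend_order = 1L) {
  stopifnot(is.matrix(ts_matrix))
  nt <- ncol(ts_matrix)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt) {
      stop("motion table rows (", nrow(motion), ") != T (", nt, ")")
    }
  }
  tt <- seq_len(nt) / nt
  X <- cbind(intercept = rep(1, nt))
  if (detrend_order >= 1) {
    P <- stats::poly(tt, degree = detrend_order, raw = FALSE)
    colnames(P) <- paste0("trend", seq_len(detrend_order))
    X <- cbind(X, P)
  }
  if (!is.null(motion)) {
    mm <- scale(motion, center = TRUE, scale = FALSE)
    colnames(mm) <- colnames(motion) %||% paste0("motion", 1:ncol(mm))
    X <- cbind(X, mm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping ", length(drop), " collinear nuisance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  # residual = ts - fitted, computed for all voxels at once
  coefs <- qr.coef(qrX, t(ts_matrix))
  resid <- ts_matrix - t(X %*% coefs)
  attr(resid, "design") <- X
  resid
}

#' Voxelwise z-score normalisation
#'
#' Standardises each voxel's time-series to zero mean and unit sample SD.
#' Constant (zero-variance) voxels cannot be standardised; they are set to
#' all-zero and reported in the `constant_rows` attribute so later stages can
#' exclude them instead of propagating NaN.
#'
#' @param ts_matrix `V x T` matrix, `T >= 2`.
#' @return `V x T` matrix with attribute `constant_rows`.
#' @export
zscore_voxelwise <- function(ts_matrix) {
  stopifnot(is.matrix(ts_matrix), ncol(ts_matrix) >= 2)
  zscore_rows(ts_matrix)
}

# Hamming-window band-pass FIR coefficients. Length = 4 / (normalised
# transition width) capped at T/3 taps, forced odd (linear phase type I);
# the taps are re-centred so the DC gain is exactly zero.
design_bandpass_fir <- function(tr, low_hz, high_hz, n_time) {
  nyq <- 1 / (2 * tr)
  if (low_hz < 0 || low_hz >= high_hz || high_hz > nyq) {
    stop("band must satisfy 0 <= low < high <= Nyquist (", nyq, " Hz)")
  }
  trans <- max(low_hz, 1e-3) / nyq
  ntap <- min(ceiling(4 / trans), floor(n_time / 3))
  if (ntap %% 2 == 0) ntap <- ntap - 1L
  ntap <- max(ntap, 9L)
  h <- signal::fir1(ntap - 1L, c(max(low_hz, 1e-6), high_hz) / nyq,
                    type = "pass", window = signal::hamming(ntap))
  h <- as.numeric(h)
  h - mean(h)  # exact DC rejection
}

#' Band-pass filter voxel time-series
#'
#' Zero-phase band-pass with a linear-phase FIR filter built from a Hamming
#' window. The symmetric impulse response is applied centred
#' (delay-compensated single pass) with reflection padding at the edges; the
#' taps are re-centred so a constant series maps exactly to zero. Filter
#' length is `4/(transition width)` capped at `T/3` taps (odd), with the
#' transition width taken as the lower band edge.
#'
#' @param ts_matrix `V x T` matrix.
#' @param tr repetition time, seconds.
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.1, the
#'   conventional resting-state band).
#' @return Filtered `V x T` matrix with attribute `fir` (the taps used).
#' @export
bandpass <- function(ts_matrix, tr, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(is.matrix(ts_matrix))
  nt <- ncol(ts_matrix)
  h <- design_bandpass_fir(tr, low_hz, high_hz, nt)
  half <- (length(h) - 1L) / 2L
  # reflect-pad each series, convolve centred, trim
  pad_l <- ts_matrix[, rev(seq_len(min(half, nt - 1)) + 1L), drop = FALSE]
  pad_r <- ts_matrix[, rev(nt - seq_len(min(half, nt - 1))), drop = FALSE]
  padded <- cbind(pad_l, ts_matrix, pad_r)
  filt <- t(stats::filter(t(padded), h, method = "convolution", sides = 2))
  off <- ncol(pad_l)
  out <- filt[, off + seq_len(nt), drop = FALSE]
  dimnames(out) <- dimnames(ts_matrix)
  attr(out, "fir") <- h
  out
}

#' Full temporal/spatial preprocessing of one acquisition
#'
#' Applies the fixed stage order: discard initial volumes, spatial smoothing,
#' polynomial detrending + motion regression, voxelwise z-scoring, and
#' Hamming-window band-pass (the series is not re-standardised after
#' filtering). Only mask voxels are ever touched.
#'
#' @param vs a [volume_series()].
#' @param motion `T x 6` motion matrix or `NULL`.
#' @param n_discard leading volumes to drop.
#' @param fwhm_mm smoothing FWHM in mm (0 disables).
#' @param voxel_size_mm voxel size in mm.
#' @param detrend_order polynomial trend order.
#' @param band length-2 passband in Hz.
#' @return A [volume_series()] whose `mat` holds the preprocessed `V x T'`
#'   series (attribute `constant_rows` lists zero-variance voxels).
#' @export
preprocess_series <- function(vs, motion = NULL, n_discard = 5L,
                              fwhm_mm = 1.2, voxel_size_mm = c(0.4, 0.4, 0.6),
                              detrend_order = 1L, band = c(0.01, 0.1)) {
  d <- discard_initial(vs, motion, n_discard)
  vs <- d$vs
  motion <- d$motion
  if (fwhm_mm > 0) vs <- smooth_spatial(vs, fwhm_mm, voxel_size_mm)
  m <- regress_nuisance(vs$mat, motion, detrend_order)
  m <- zscore_voxelwise(m)
  const <- attr(m, "constant_rows")
  m <- bandpass(m, vs$tr, band[1], band[2])
  vs$mat <- m
  attr(vs$mat, "constant_rows") <- const
  vs
}
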