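#' Dual regression, stage 1: subject network time-series
#'
#' For each volume, the K group-map values at the mask voxels (plus an
#' intercept) are regressed onto that volume's voxel vector by multiple OLS;
#' the K coefficients over volumes form the subject's network time-series.
#' Equivalently the whole stage is `pinv(design) %*% data`.
#'
#' @param ts_matrix preprocessed `V x T` matrix.
#' @param maps_z `K x V` group spatial maps (z-scored over mask voxels).
#' @return `T x K` time-series matrix.
#' @export
dual_regression_stage1 <- function(ts_matrix, maps_z) {
  stopifnot(is.matrix(ts_matrix), is.matrix(maps_z),
            ncol(maps_z) == nrow(ts_matrix))
  X <- cbind(1, t(maps_z))                 # V x (K+1)
  XtX <- crossprod(X)
  cond <- kappa(XtX, exact = FALSE)
  if (cond > 1e8) {
    warning("spatial design nearly collinear (condition number ",
            signif(cond, 3), ")")
  }
  coefs <- solve(XtX, crossprod(X, ts_matrix))   # (K+1) x T
  ts <- t(coefs[-1, , drop = FALSE])             # T x K
  colnames(ts) <- rownames(maps_z)
  ts
}

#' Dual regression, stage 2: subject spatial maps
#'
#' Each voxel's time-series is regressed by multiple OLS on the stage-1
#' network time-series (plus an intercept); the coefficients form the
#' subject-specific beta maps, and each network's beta map is standardised
#' over mask voxels into a z-map. With `variance_normalize = TRUE` the
#' time-series are scaled to unit SD before the fit (the "design
#' normalisation" convention), which rescales the beta maps but leaves the
#' z-maps unchanged. Zero-variance time-series columns produce zeroed maps
#' and are reported in the `flagged` attribute.
#'
#' @param ts_matrix preprocessed `V x T` matrix.
#' @param timeseries `T x K` stage-1 output for the same acquisition.
#' @param variance_normalize scale each network time-series to unit SD first.
#' @return List with `beta_maps` (`K x V`) and `z_maps` (`K x V`, rows
#'   zero-mean unit-SD).
#' @export
dual_regression_stage2 <- function(ts_matrix, timeseries,
                                   variance_normalize = FALSE) {
  stopifnot(is.matrix(ts_matrix), is.matrix(timeseries),
            nrow(timeseries) == ncol(ts_matrix))
  K <- ncol(timeseries)
  sds <- apply(timeseries, 2, sd)
  flagged <- which(sds < 1e-12)
  D <- timeseries
  if (variance_normalize) {
    sc <- ifelse(sds < 1e-12, 1, sds)
    D <- sweep(D, 2, sc, "/")
  }
  if (length(flagged)) D[, flagged] <- 0
  X <- cbind(1, D)                         # T x (K+1)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, t(ts_matrix))      # (K+1) x V
  coefs[is.na(coefs)] <- 0
  beta <- coefs[-1, , drop = FALSE]
  if (length(flagged)) beta[flagged, ] <- 0
  z <- zscore_rows(beta)
  attr(z, "constant_rows") <- NULL
  rownames(beta) <- rownames(z) <- colnames(timeseries)
  out <- list(beta_maps = beta, z_maps = z)
  attr(out, "flagged") <- flagged
  out
}

#' Full dual regression for one acquisition
#'
#' Runs both stages and packages the result.
#'
#' @param vs preprocessed [volume_series()] (or a `V x T` matrix).
#' @param maps_z `K x V` group maps.
#' @param variance_normalize stage-2 design normalisation flag.
#' @param subject_id,timepoint identifiers (taken from `vs` if available).
#' @return A `subject_network_set`: `timeseries` (`T x K`), `beta_maps`,
#'   `z_maps` (`K x V`), identifiers.
#' @export
dual_regression <- function(vs, maps_z, variance_normalize = FALSE,
                            subject_id = NULL, timepoint = NULL) {
  if (inherits(vs, "volume_series")) {
    subject_id <- subject_id %||% vs$subject_id
    timepoint <- timepoint %||% vs$timepoint
    m <- vs$mat
  } else {
    m <- vs
  }
  ts <- dual_regression_stage1(m, maps_z)
  s2 <- dual_regression_stage2(m, ts, variance_normalize)
  structure(
    list(timeseries = ts, beta_maps = s2$beta_maps, z_maps = s2$z_maps,
         subject_id = subject_id %||% NA_character_,
         timepoint = timepoint %||% NA_character_),
    class = "subject_network_set"
  )
}

#' @export
print.subject_network_set <- function(x, ...) {
  cat("<subject_network_set> ", ncol(x$timeseries), " networks, T=",
      nrow(x$timeseries), "  [", x$subject_id, "/", x$timepoint, "]\n",
      sep = "")
  invisible(x)
}
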