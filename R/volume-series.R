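#' Volume time-series container
#'
#' A `volume_series` holds one acquisition's 4D data in masked form: a
#' `V x T` matrix of voxel time-series (rows are mask voxels in array order),
#' together with the boolean brain mask, the grid dimensions and the
#' repetition time. Storing only mask voxels keeps desk-scale cohorts small
#' while [as_volume_array()] reconstructs the full `X x Y x Z x T` grid on
#' demand (e.g. for NIfTI export or spatial smoothing).
#'
#' @param mat numeric `V x T` matrix, `V = sum(mask)`.
#' @param mask logical 3D array (the brain mask).
#' @param tr repetition time in seconds.
#' @param subject_id,timepoint identifiers carried along the pipeline.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(mat, mask, tr, subject_id = NA_character_,
                          timepoint = NA_character_) {
  stopifnot(is.matrix(mat), is.array(mask), length(dim(mask)) == 3)
  if (nrow(mat) != sum(mask)) {
    stop("`mat` must have one row per mask voxel (", sum(mask), "), got ",
         nrow(mat))
  }
  if (ncol(mat) < 1) stop("volume series needs at least one volume")
  if (!any(mask)) stop("mask is empty")
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be positive")
  if (any(!is.finite(mat))) stop("non-finite values inside mask")
  structure(
    list(mat = mat, mask = mask, dims = dim(mask), tr = tr,
         subject_id = subject_id, timepoint = timepoint),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  cat("<volume_series> ", paste(x$dims, collapse = "x"), " grid, ",
      nrow(x$mat), " mask voxels, T=", ncol(x$mat),
      ", TR=", x$tr, "s", sep = "")
  if (!is.na(x$subject_id)) cat("  [", x$subject_id, "/", x$timepoint, "]",
                                sep = "")
  cat("\n")
  invisible(x)
}

#' Reconstruct the full 4D array of a volume series
#'
#' @param vs a [volume_series()].
#' @param fill value outside the mask (default 0).
#' @return numeric `X x Y x Z x T` array.
#' @export
as_volume_array <- function(vs, fill = 0) {
  stopifnot(inherits(vs, "volume_series"))
  arr <- array(fill, dim = c(vs$dims, ncol(vs$mat)))
  idx <- which(vs$mask)
  nv <- prod(vs$dims)
  for (t in seq_len(ncol(vs$mat))) {
    arr[idx + (t - 1) * nv] <- vs$mat[, t]
  }
  arr
}

#' Build a volume series from a 4D array
#'
#' @param arr numeric `X x Y x Z x T` array.
#' @inheritParams volume_series
#' @return A [volume_series()].
#' @export
as_volume_series <- function(arr, mask, tr, subject_id = NA_character_,
                             timepoint = NA_character_) {
  stopifnot(length(dim(arr)) == 4, all(dim(arr)[1:3] == dim(mask)))
  nt <- dim(arr)[4]
  m <- matrix(arr, nrow = prod(dim(mask)), ncol = nt)[which(mask), , drop = FALSE]
  volume_series(m, mask, tr, subject_id, timepoint)
}

#' Ellipsoidal brain mask for a voxel grid
#'
#' Default mask used by the synthetic generator: an axis-aligned ellipsoid
#' with semi-axes at `radius_frac` of each half-dimension, mimicking a
#' brain-shaped region inside the field of view.
#'
#' @param grid_dims integer length-3 vector of voxel counts.
#' @param radius_frac semi-axis as a fraction of each half-dimension.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(grid_dims, radius_frac = 0.9) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 3))
  ctr <- (grid_dims + 1) / 2
  semi <- pmax((grid_dims - 1) / 2 * radius_frac, 1)
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  d <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(d <= 1, dim = grid_dims)
}
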