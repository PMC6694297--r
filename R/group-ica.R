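#' Temporally concatenate a cohort of preprocessed acquisitions
#'
#' Stacks the `V x T` matrices of all acquisitions along time (columns
#' ordered by subject then timepoint), the standard multisession
#' "temporal-concatenation" arrangement for group spatial ICA. Each block can
#' be variance-normalised per voxel beforehand (on by default) so no single
#' acquisition dominates the decomposition. All acquisitions must share the
#' same mask.
#'
#' @param series list of [volume_series()] (preprocessed).
#' @param variance_normalize logical; per-voxel, per-block scaling to unit SD.
#' @return A `concat_series` list: `mat` (`V x sum(T)`), `ranges` (tibble with
#'   `subject_id`, `timepoint`, `start`, `end`, 1-based inclusive), `mask`,
#'   `tr`.
#' @export
concatenate_cohort <- function(series, variance_normalize = TRUE) {
  stopifnot(length(series) >= 1)
  ref <- series[[1]]
  for (i in seq_along(series)) {
    s <- series[[i]]
    stopifnot(inherits(s, "volume_series"))
    if (!identical(dim(s$mask), dim(ref$mask)) ||
        !identical(which(s$mask), which(ref$mask))) {
      stop("mask mismatch at acquisition ", i, " (",
           s$subject_id, "/", s$timepoint, ")")
    }
  }
  mats <- lapply(series, function(s) {
    m <- s$mat
    if (variance_normalize) {
      sds <- sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1))
      sds[sds < 1e-12] <- 1
      m <- m / sds
    }
    m
  })
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  ranges <- tibble::tibble(
    subject_id = vapply(series, function(s) s$subject_id, character(1)),
    timepoint = vapply(series, function(s) s$timepoint, character(1)),
    start = c(1L, head(ends, -1L) + 1L),
    end = ends
  )
  structure(
    list(mat = do.call(cbind, mats), ranges = ranges,
         mask = ref$mask, tr = ref$tr),
    class = "concat_series"
  )
}

#' Extract one acquisition's block from a concatenation
#'
#' @param cc a `concat_series` from [concatenate_cohort()].
#' @param i block index (row of `cc$ranges`).
#' @return The `V x T_i` matrix of block `i`.
#' @export
concat_block <- function(cc, i) {
  r <- cc$ranges[i, ]
  cc$mat[, r$start:r$end, drop = FALSE]
}

# Fixed-point ICA with the logcosh contrast and symmetric decorrelation.
# Z: n x K whitened data (rows = samples, columns uncorrelated, unit var).
# Returns the K x K orthogonal unmixing matrix W such that S = Z %*% t(W).
fastica_symm <- function(Z, seed, max_iter = 1000L, tol = 1e-6, alpha = 1) {
  K <- ncol(Z)
  n <- nrow(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)), K) %*%
      t(e$vectors) %*% W
  }
  # When K exceeds the number of non-Gaussian sources the update has no
  # stable fixed point in the Gaussian directions, so the strict tolerance
  # may never be met; the best iterate is then accepted at `tol_relaxed`
  # (the usual practice for fixed-order decompositions of noisy data).
  tol_relaxed <- 1e-3
  attempt <- function(init_seed) {
    W <- with_seed(init_seed, matrix(rnorm(K * K), K, K))
    W <- sym_decorrelate(W)
    best <- list(W = W, delta = Inf, it = 0L)
    for (it in seq_len(max_iter)) {
      WX <- Z %*% t(W)                  # n x K source estimates
      G <- tanh(alpha * WX)
      g_prime <- alpha * colMeans(1 - G^2)
      W_new <- t(G) %*% Z / n - diag(g_prime, K) %*% W
      W_new <- sym_decorrelate(W_new)
      conv <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (conv < best$delta) best <- list(W = W, delta = conv, it = it)
      if (conv < tol) break
    }
    best
  }
  n_restarts <- 4L
  overall <- NULL
  for (a in seq_len(n_restarts)) {
    res <- attempt(derive_seed(seed, a - 1L))
    if (res$delta < tol) {
      attr(res$W, "iterations") <- res$it
      attr(res$W, "delta") <- res$delta
      return(res$W)
    }
    if (is.null(overall) || res$delta < overall$delta) overall <- res
  }
  if (overall$delta < tol_relaxed) {
    warning("fixed-point ICA accepted at relaxed tolerance ",
            signif(overall$delta, 3), " (strict tol = ", tol,
            ", iteration ", overall$it, ")")
    attr(overall$W, "iterations") <- overall$it
    attr(overall$W, "delta") <- overall$delta
    return(overall$W)
  }
  stop("fixed-point ICA did not converge after ", max_iter,
       " iterations in any of ", n_restarts,
       " restarts (best delta = ", signif(overall$delta, 3),
       ", tol = ", tol, ")")
}

#' PCA reduction followed by spatial ICA
#'
#' Reduces the concatenated data to `order` principal components (via an
#' eigendecomposition of the smaller Gram matrix) and runs fixed-point ICA
#' with the logcosh contrast and symmetric decorrelation on the whitened
#' spatial representation, so the estimated sources are spatial maps over
#' mask voxels. Maps are z-scored over voxels, their sign fixed so each map's
#' skewness is non-negative, and components are ordered by explained
#' variance. The associated mixing matrix (concatenated time-courses) is the
#' least-squares regression of the data on the maps.
#'
#' @param cc a `concat_series` from [concatenate_cohort()], or a plain
#'   `V x T` matrix.
#' @param order number of components `K` (<= rank of the data).
#' @param seed integer seed for the ICA initialisation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return A `component_set`: `maps_z` (`K x V`, rows zero-mean unit-SD over
#'   mask voxels), `mixing` (`sum(T) x K`), `order`, `seed`, `var_explained`
#'   (fraction of total variance captured by the retained subspace), `mask`,
#'   `ranges`.
#' @export
reduce_and_ica <- function(cc, order, seed = 1L, max_iter = 1000L, tol = 1e-6) {
  if (inherits(cc, "concat_series")) {
    X <- cc$mat
    mask <- cc$mask
    ranges <- cc$ranges
  } else {
    X <- cc
    mask <- NULL
    ranges <- NULL
  }
  V <- nrow(X)
  Tn <- ncol(X)
  X <- X - rowMeans(X)
  total_var <- sum(X^2)

  # PCA via the smaller Gram matrix
  if (V <= Tn) {
    G <- tcrossprod(X)              # V x V
    e <- eigen(G, symmetric = TRUE)
    rank_eff <- sum(e$values > max(e$values) * 1e-10)
    if (order > rank_eff) {
      stop("requested order ", order, " exceeds effective rank ", rank_eff)
    }
    U <- e$vectors[, seq_len(order), drop = FALSE]   # spatial eigenvectors
    ev <- e$values[seq_len(order)]
    Y <- U %*% diag(sqrt(ev), order)                 # V x K spatial scores
  } else {
    G <- crossprod(X)               # T x T
    e <- eigen(G, symmetric = TRUE)
    rank_eff <- sum(e$values > max(e$values) * 1e-10)
    if (order > rank_eff) {
      stop("requested order ", order, " exceeds effective rank ", rank_eff)
    }
    Vt <- e$vectors[, seq_len(order), drop = FALSE]
    ev <- e$values[seq_len(order)]
    Y <- X %*% Vt                                    # V x K spatial scores
  }
  var_explained <- sum(ev) / total_var

  # whiten over voxels: columns zero-mean, identity covariance
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Cw <- crossprod(Yc) / (V - 1)
  ew <- eigen(Cw, symmetric = TRUE)
  Wh <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-15)), order) %*%
    t(ew$vectors)
  Z <- Yc %*% Wh

  W <- fastica_symm(Z, seed = seed, max_iter = max_iter, tol = tol)
  S <- Z %*% t(W)                                    # V x K spatial sources

  maps_z <- t(apply(S, 2, function(v) (v - mean(v)) / sd(v)))
  # sign convention: non-negative skewness (activation-positive maps)
  for (k in seq_len(order)) {
    if (skewness(maps_z[k, ]) < 0) maps_z[k, ] <- -maps_z[k, ]
  }
  # mixing = least-squares time-courses of the maps in the data
  M <- maps_z
  mixing <- t(solve(tcrossprod(M), M %*% X))          # sum(T) x K
  # order components by explained variance (maps are unit-SD, so column
  # energy of the mixing matrix ranks them)
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  maps_z <- maps_z[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  rownames(maps_z) <- paste0("IC", seq_len(order))
  colnames(mixing) <- rownames(maps_z)

  structure(
    list(maps_z = maps_z, mixing = mixing, order = order, seed = seed,
         var_explained = var_explained, eigenvalues = ev,
         iterations = attr(W, "iterations"), mask = mask, ranges = ranges),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> K=", x$order, ", ", ncol(x$maps_z), " voxels, ",
      nrow(x$mixing), " concatenated volumes, ",
      round(100 * x$var_explained, 1), "% variance in subspace\n", sep = "")
  invisible(x)
}

#' Label components by template matching
#'
#' Automated surrogate for visual component selection: each component map is
#' thresholded at `|z| > z_thresh` and compared to each labelled template
#' mask by the Dice coefficient; labels are assigned greedily by descending
#' Dice (ties broken toward the lower component index). A label may take up
#' to `max_per_label` components (the somatosensorial system is classically
#' represented by two components, so pass 2 for such labels). Components
#' whose thresholded map is empty are skipped with a warning; components
#' below `min_dice` stay unlabeled.
#'
#' @param cs a `component_set`.
#' @param templates named list of logical vectors over mask voxels (or 3D
#'   logical arrays matching the mask).
#' @param z_thresh map threshold (default 2.3).
#' @param max_per_label named integer vector, or a single integer applied to
#'   all labels (default 1).
#' @param min_dice minimum Dice to accept a match.
#' @return Tibble: `component`, `label`, `dice` (one row per component;
#'   unmatched components have label `"unlabeled"`).
#' @export
match_templates <- function(cs, templates, z_thresh = 2.3,
                            max_per_label = 1L, min_dice = 0.1) {
  stopifnot(inherits(cs, "component_set"), length(templates) >= 1,
            !is.null(names(templates)))
  V <- ncol(cs$maps_z)
  tmpl <- lapply(templates, function(tm) {
    if (is.array(tm) && !is.null(cs$mask)) tm <- tm[cs$mask]
    stopifnot(length(tm) == V)
    as.logical(tm)
  })
  if (length(max_per_label) == 1L && is.null(names(max_per_label))) {
    max_per_label <- setNames(rep(max_per_label, length(tmpl)), names(tmpl))
  }
  quota <- setNames(rep(1L, length(tmpl)), names(tmpl))
  quota[names(max_per_label)] <- max_per_label

  K <- nrow(cs$maps_z)
  thr <- lapply(seq_len(K), function(k) abs(cs$maps_z[k, ]) > z_thresh)
  empty <- vapply(thr, function(x) !any(x), logical(1))
  if (any(empty)) {
    warning("component(s) with empty thresholded map skipped: ",
            paste(which(empty), collapse = ", "))
  }
  dice <- matrix(0, K, length(tmpl),
                 dimnames = list(rownames(cs$maps_z), names(tmpl)))
  for (k in which(!empty)) {
    for (j in seq_along(tmpl)) {
      inter <- sum(thr[[k]] & tmpl[[j]])
      dice[k, j] <- 2 * inter / (sum(thr[[k]]) + sum(tmpl[[j]]))
    }
  }
  label <- rep("unlabeled", K)
  score <- rep(NA_real_, K)
  cand <- which(dice >= min_dice, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(dice[cand], -cand[, 1], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      k <- cand[i, 1]; j <- cand[i, 2]
      lbl <- names(tmpl)[j]
      if (label[k] != "unlabeled" || quota[lbl] == 0L) next
      label[k] <- lbl
      score[k] <- dice[k, j]
      quota[lbl] <- quota[lbl] - 1L
    }
  }
  tibble::tibble(component = rownames(cs$maps_z) %||% paste0("IC", 1:K),
                 label = label, dice = score)
}
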