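#' Network amplitude
#'
#' Amplitude of a network is the sample standard deviation (denominator
#' `T - 1`) of its stage-1 dual-regression time-series — the magnitude of the
#' network's spontaneous fluctuation in signal units.
#'
#' @param ts numeric vector (length >= 2).
#' @return Non-negative scalar.
#' @export
network_amplitude <- function(ts) {
  if (length(ts) < 2) stop("amplitude needs at least 2 samples")
  sd(ts)
}

#' Network shape
#'
#' Shape is the mean of the z-values strictly above `z_thresh` in the
#' subject's stage-2 spatial z-map — a summary of how strongly the network's
#' spatial pattern is expressed. When no voxel exceeds the threshold the
#' value is missing (`NA`), never zero.
#'
#' @param z_map numeric vector of z-values over mask voxels.
#' @param z_thresh threshold (default 2.3).
#' @return Scalar, or `NA_real_` if no voxel is suprathreshold.
#' @export
network_shape <- function(z_map, z_thresh = 2.3) {
  v <- z_map[z_map > z_thresh]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Pearson correlation between two network time-series
#'
#' @param ts_a,ts_b numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA_real_` if either series has zero variance.
#' @export
between_network_corr <- function(ts_a, ts_b) {
  stopifnot(length(ts_a) == length(ts_b), length(ts_a) >= 3)
  if (sd(ts_a) < 1e-12 || sd(ts_b) < 1e-12) return(NA_real_)
  cor(ts_a, ts_b)
}

#' Long-format metric table for a cohort
#'
#' Computes amplitude and shape for every subject x timepoint x network from
#' the dual-regression outputs and joins the cohort covariates, producing the
#' long table that feeds all longitudinal statistics.
#'
#' @param subject_sets list of `subject_network_set` (one per acquisition).
#' @param cohort tibble with `subject_id`, `timepoint`, `group_code`,
#'   `age_months` (as produced by [simulate_cohort()]).
#' @param networks optional character vector selecting/ordering networks
#'   (default: all columns of the first set).
#' @param z_thresh shape threshold.
#' @return Tibble: `subject_id`, `group`, `age_months`, `timepoint`,
#'   `network`, `amplitude`, `shape`.
#' @export
metric_table <- function(subject_sets, cohort, networks = NULL,
                         z_thresh = 2.3) {
  stopifnot(length(subject_sets) >= 1)
  networks <- networks %||% colnames(subject_sets[[1]]$timeseries)
  rows <- purrr::map_dfr(subject_sets, function(s) {
    tibble::tibble(
      subject_id = s$subject_id,
      timepoint = s$timepoint,
      network = networks,
      amplitude = unname(vapply(networks, function(k)
        network_amplitude(s$timeseries[, k]), numeric(1))),
      shape = unname(vapply(networks, function(k)
        network_shape(s$z_maps[k, ], z_thresh), numeric(1)))
    )
  })
  dplyr::inner_join(
    dplyr::select(cohort, "subject_id", "timepoint", group = "group_code",
                  "age_months"),
    rows, by = c("subject_id", "timepoint")
  )
}

#' Between-network connectivity table for a cohort
#'
#' Pearson correlations between the stage-1 time-series of every network
#' pair, per acquisition.
#'
#' @inheritParams metric_table
#' @return Tibble: `subject_id`, `group`, `age_months`, `timepoint`,
#'   `network_a`, `network_b`, `pearson_r` (unordered pairs, `a < b`).
#' @export
connectivity_table <- function(subject_sets, cohort, networks = NULL) {
  networks <- networks %||% colnames(subject_sets[[1]]$timeseries)
  if (length(networks) < 2) {
    return(tibble::tibble(subject_id = character(0), timepoint = character(0),
                          group = integer(0), age_months = numeric(0),
                          network_a = character(0), network_b = character(0),
                          pearson_r = numeric(0)))
  }
  pairs <- utils::combn(networks, 2)
  rows <- purrr::map_dfr(subject_sets, function(s) {
    tibble::tibble(
      subject_id = s$subject_id,
      timepoint = s$timepoint,
      network_a = pairs[1, ],
      network_b = pairs[2, ],
      pearson_r = apply(pairs, 2, function(p)
        between_network_corr(s$timeseries[, p[1]], s$timeseries[, p[2]]))
    )
  })
  dplyr::inner_join(
    dplyr::select(cohort, "subject_id", "timepoint", group = "group_code",
                  "age_months"),
    rows, by = c("subject_id", "timepoint")
  )
}

#' Assign high-order components to a parent network
#'
#' Spatio-temporal matching of subnetworks: a high-order component belongs to
#' the parent network iff its concatenated group time-course correlates with
#' the parent's above `r_thresh` AND the two thresholded maps (`z > z_thresh`
#' in both) share more than `overlap_thresh` voxels. Both criteria must hold
#' jointly. Matching is done once at cohort level (group time-courses), not
#' per subject. Defaults: `r_thresh = 0.4`, `overlap_thresh = 250`,
#' `z_thresh = 2.3`.
#'
#' @param parent_label label of the parent network in `labels`.
#' @param cs_low low-order `component_set` (the parent's decomposition).
#' @param labels component labels for `cs_low` (tibble from
#'   [match_templates()] or a character vector along components).
#' @param cs_high high-order `component_set` to search for subnetworks.
#' @param r_thresh temporal-correlation threshold (signed by default).
#' @param overlap_thresh minimum shared suprathreshold voxels.
#' @param z_thresh map threshold for overlap counting.
#' @param use_abs match on `|r|` instead of signed r.
#' @return A `subnetwork_assignment` tibble: `component`, `temporal_r`,
#'   `overlap_voxels`, `assigned`; attribute `parent` holds the parent
#'   component index.
#' @export
match_subnetworks <- function(parent_label, cs_low, labels, cs_high,
                              r_thresh = 0.4, overlap_thresh = 250L,
                              z_thresh = 2.3, use_abs = FALSE) {
  stopifnot(inherits(cs_low, "component_set"),
            inherits(cs_high, "component_set"),
            ncol(cs_low$maps_z) == ncol(cs_high$maps_z))
  if (is.data.frame(labels)) labels <- labels$label
  pk <- which(labels == parent_label)
  if (length(pk) == 0) stop("parent label '", parent_label,
                            "' not found among component labels")
  pk <- pk[1]
  if (nrow(cs_low$mixing) != nrow(cs_high$mixing)) {
    stop("component sets come from different concatenations (",
         nrow(cs_low$mixing), " vs ", nrow(cs_high$mixing), " volumes)")
  }
  parent_ts <- cs_low$mixing[, pk]
  parent_sup <- cs_low$maps_z[pk, ] > z_thresh

  K <- nrow(cs_high$maps_z)
  r <- vapply(seq_len(K), function(k)
    cor(parent_ts, cs_high$mixing[, k]), numeric(1))
  r_eff <- if (use_abs) abs(r) else r
  overlap <- vapply(seq_len(K), function(k)
    sum(parent_sup & (cs_high$maps_z[k, ] > z_thresh)), integer(1))
  out <- tibble::tibble(
    component = rownames(cs_high$maps_z) %||% paste0("IC", seq_len(K)),
    temporal_r = r,
    overlap_voxels = overlap,
    assigned = (r_eff > r_thresh) & (overlap > overlap_thresh)
  )
  attr(out, "parent") <- pk
  class(out) <- c("subnetwork_assignment", class(out))
  out
}

#' Mean within-network connectivity of a set of subnetworks
#'
#' The overall cohesion of a decomposed network: the mean of all pairwise
#' Pearson correlations between the stage-1 time-series of its subnetworks,
#' for one subject-timepoint.
#'
#' @param ts `T x n` matrix of subnetwork time-series (n >= 2).
#' @return Scalar mean of the `choose(n, 2)` pairwise correlations, or
#'   `NA_real_` if fewer than 2 subnetworks.
#' @export
mean_within_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  n <- ncol(ts)
  if (n < 2) return(NA_real_)
  cm <- cor(ts)
  mean(cm[upper.tri(cm)])
}
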