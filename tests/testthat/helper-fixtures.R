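# Shared fixtures, all generated in code at test time.

# A small two-group, three-timepoint design for fast end-to-end runs.
small_design <- function(seed = 1L, grid = c(14, 14, 8), n_volumes = 80L,
                         n_per_group = 3L, n_tp = 3L) {
  cohort_design(
    group_sizes = matrix(n_per_group, 2, n_tp),
    age_mean = matrix(rep(seq(5, 17, length.out = n_tp), each = 2), 2, n_tp),
    age_sd = matrix(0.3, 2, n_tp),
    grid_dims = grid, n_volumes = n_volumes, tr = 2, seed = seed
  )
}

# Planted-source matrix fixture for ICA / dual-regression oracles:
# K sparse non-overlapping blocks over V voxels, optionally with noise.
planted_sources <- function(V = 400L, T = 150L, K = 3L, fill = 40L,
                            noise_sd = 0, seed = 1L) {
  set.seed(seed)
  maps <- matrix(0, K, V)
  for (k in seq_len(K)) {
    maps[k, ((k - 1) * 2 * fill + 1):((k - 1) * 2 * fill + fill)] <-
      runif(fill, 0.6, 1)
  }
  courses <- matrix(rnorm(K * T), K, T)
  X <- crossprod(maps, courses)
  if (noise_sd > 0) X <- X + matrix(rnorm(V * T, sd = noise_sd), V, T)
  list(X = X, maps = maps, courses = courses)
}

# Metric-level cohort: planted linear amplitude model feeding the LME layer
# without any imaging (fast Monte-Carlo).
metric_cohort <- function(seed, b0 = 1, b1 = 0, b2 = 0, b3 = 0,
                          design = cohort_design(seed = seed)) {
  tr <- ground_truth(
    design, networks = "net1",
    amp_intercept = matrix(c(b0, b0 + b1), 2, 1),
    amp_slope = matrix(c(b2, b2 + b3), 2, 1),
    blob_radius = 2.4
  )
  co <- simulate_cohort(design, tr, images = FALSE)
  dplyr::inner_join(
    dplyr::select(co$cohort, "subject_id", "timepoint",
                  group = "group_code", "age_months"),
    dplyr::mutate(co$truth_amplitudes, network = .data$source),
    by = c("subject_id", "timepoint")
  )
}
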