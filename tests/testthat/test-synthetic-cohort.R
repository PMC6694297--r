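test_that("cohort_design validates its invariants", {
  expect_error(cohort_design(group_sizes = matrix(0, 2, 5)), "sizes")
  expect_error(cohort_design(n_volumes = 10), "n_volumes")
  expect_error(cohort_design(tr = 0), "tr")
  bad_ages <- default_age_mean()
  bad_ages[1, 2] <- 5.0   # not increasing
  expect_error(cohort_design(age_mean = bad_ages), "increasing")
  d <- cohort_design()
  expect_equal(sum(d$group_sizes), 84)
  # FOV-derived voxel size: full-size grid reproduces native resolution
  full <- cohort_design(grid_dims = c(64, 64, 34), n_volumes = 600)
  expect_equal(full$voxel_size_mm, c(0.4, 0.4, 0.6))
})

test_that("planted network maps honour support, positivity and dissimilarity", {
  grid <- c(20, 20, 10)
  mask <- array(TRUE, grid)
  maps <- make_network_maps(grid, mask, 4, blob_radius = 4.5, seed = 2)
  expect_equal(nrow(maps), 4)
  expect_true(all(maps >= 0))
  expect_equal(unname(apply(maps, 1, max)), rep(1, 4))
  expect_true(all(rowSums(maps >= 0.5) >= 300))
  pc <- abs(cor(t(maps)))
  diag(pc) <- 0
  expect_lt(max(pc), 0.5)

  one <- make_network_maps(grid, mask, 1, blob_radius = 4.5, seed = 2)
  expect_equal(cor(one[1, ], one[1, ]), 1)

  again <- make_network_maps(grid, mask, 4, blob_radius = 4.5, seed = 2)
  expect_identical(maps, again)

  tiny <- ellipsoid_mask(c(6, 6, 4))
  expect_error(
    make_network_maps(c(6, 6, 4), tiny, 3, blob_radius = 4.5,
                      max_attempts = 50),
    "mask"
  )
})

test_that("source time courses are unit-SD and band-limited", {
  tc <- make_timecourses(3, 200, tr = 2, band = c(0.01, 0.08), seed = 5)
  expect_equal(dim(tc), c(3, 200))
  expect_equal(rowMeans(tc), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(tc, 1, sd), rep(1, 3), tolerance = 1e-12)
  # periodogram oracle: fraction of power inside the band
  for (k in 1:3) {
    sp <- Mod(stats::fft(tc[k, ]))^2
    freqs <- (seq_along(sp) - 1) / (200 * 2)
    half <- freqs <= 0.25
    inband <- freqs >= 0.01 & freqs <= 0.08 & half
    expect_gte(sum(sp[inband]) / sum(sp[half & freqs > 0]), 0.9)
  }
  expect_identical(tc, make_timecourses(3, 200, 2, c(0.01, 0.08), seed = 5))
  expect_error(make_timecourses(1, 100, 2, c(0.2, 0.3)), "Nyquist")
})

test_that("synthesized subjects follow the planted linear amplitude model", {
  des <- small_design(seed = 11)
  tr0 <- ground_truth(des, networks = "net1",
                      amp_intercept = matrix(0.4, 2, 1),
                      amp_slope = matrix(c(0.05, -0.05), 2, 1),
                      noise_sd = 0, motion_coupling = 0)
  acq <- synthesize_subject(tr0, des, group = 0, age = 10, seed = 3)
  # noiseless single network: every voxel series is a multiple of the course
  v_top <- which.max(tr0$source_maps[1, ])
  active <- which(tr0$source_maps[1, ] > 0.2)
  cc <- abs(cor(t(acq$vs$mat[active, , drop = FALSE]), acq$vs$mat[v_top, ]))
  expect_true(all(cc > 1 - 1e-10))
  # planted amplitude follows intercept + slope * age
  expect_equal(unname(acq$amplitudes), 0.4 + 0.05 * 10)

  # monotone construction: rising group-0 slope
  a5 <- synthesize_subject(tr0, des, 0, age = 5, seed = 3)$amplitudes
  a18 <- synthesize_subject(tr0, des, 0, age = 18, seed = 3)$amplitudes
  expect_gt(a18, a5)
  # group 1 has the opposite trend
  b5 <- synthesize_subject(tr0, des, 1, age = 5, seed = 3)$amplitudes
  b18 <- synthesize_subject(tr0, des, 1, age = 18, seed = 3)$amplitudes
  expect_lt(b18, b5)
})

test_that("noiseless signal is exactly linear in the amplitude parameters", {
  des <- small_design(seed = 12)
  tr1 <- ground_truth(des, networks = c("a", "b"),
                      amp_intercept = matrix(0.5, 2, 2),
                      amp_slope = matrix(0.02, 2, 2),
                      noise_sd = 0, motion_coupling = 0)
  tr2 <- tr1
  tr2$amp_intercept <- 2 * tr1$amp_intercept
  tr2$amp_slope <- 2 * tr1$amp_slope
  x1 <- synthesize_subject(tr1, des, 0, age = 9, seed = 21)$vs$mat
  x2 <- synthesize_subject(tr2, des, 0, age = 9, seed = 21)$vs$mat
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
})

test_that("simulate_cohort reproduces the reference cohort layout deterministically", {
  des <- cohort_design(grid_dims = c(10, 10, 6), n_volumes = 24, seed = 8)
  tr <- ground_truth(des, blob_radius = 2.2)
  co <- simulate_cohort(des, tr, images = FALSE)
  expect_equal(nrow(co$cohort), 84)   # sum of the reference group sizes
  expect_equal(sum(co$cohort$group_code == 0), 43)
  expect_equal(sum(co$cohort$group_code == 1), 41)
  # per-subject ages strictly increasing
  inc <- co$cohort |>
    dplyr::arrange(.data$subject_id, .data$age_months) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = all(diff(.data$age_months) > 0), .groups = "drop")
  expect_true(all(inc$ok))

  co2 <- simulate_cohort(des, tr, images = FALSE)
  expect_identical(co$cohort, co2$cohort)
  expect_identical(co$truth_amplitudes, co2$truth_amplitudes)
  expect_identical(co$behavior, co2$behavior)
})

test_that("minimal cohorts write one file per acquisition plus tables", {
  des <- cohort_design(
    group_sizes = matrix(1, 2, 1), age_mean = matrix(c(5, 6), 2, 1),
    age_sd = matrix(0.1, 2, 1), grid_dims = c(10, 10, 6),
    n_volumes = 24, timepoints = "t1", seed = 3
  )
  tr <- ground_truth(des, networks = c("a", "b"), blob_radius = 2.2)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(des, tr, dir = dir)
  expect_equal(nrow(co$cohort), 2)
  vols <- list.files(file.path(dir, "raw"), pattern = "t1\\.nii\\.gz$")
  expect_length(vols, 2)
  expect_true(file.exists(file.path(dir, "raw", "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "raw", "behavior.tsv")))
  expect_true(file.exists(file.path(dir, "raw", "manifest.json")))

  # same seed -> identical checksums
  dir2 <- withr::local_tempdir()
  co2 <- simulate_cohort(des, tr, dir = dir2)
  f1 <- sort(names(co$manifest$files))
  expect_identical(unname(unlist(co$manifest$files[f1])),
                   unname(unlist(co2$manifest$files[sort(names(co2$manifest$files))])))
})

test_that("behaviour couples to amplitude as configured", {
  des <- small_design(seed = 14, n_per_group = 5)
  # null coupling: behaviour independent of amplitude
  tr0 <- ground_truth(des, networks = c("n1", "n2"),
                      cognition_coupling = c(n1 = 0, n2 = 0))
  co0 <- simulate_cohort(des, tr0, images = FALSE)
  j0 <- dplyr::inner_join(
    dplyr::filter(co0$truth_amplitudes, .data$source == "n1"),
    co0$behavior, by = c("subject_id", "timepoint")
  )
  expect_lt(abs(cor(j0$amplitude, j0$n_trials, method = "spearman")), 0.3)

  # strong coupling, vanishing noise: monotone map, rho = 1 within ties
  tr1 <- ground_truth(des, networks = c("n1", "n2"),
                      cognition_coupling = c(n1 = 1, n2 = 0),
                      cognition_noise_sd = 1e-9)
  co1 <- simulate_cohort(des, tr1, images = FALSE)
  j1 <- dplyr::inner_join(
    dplyr::filter(co1$truth_amplitudes, .data$source == "n1"),
    co1$behavior, by = c("subject_id", "timepoint")
  )
  expect_gt(cor(j1$amplitude, j1$n_trials, method = "spearman"), 0.99)
})

test_that("spearman screening flags the coupled network, not the uncoupled ones", {
  # moderate coupling power check over seeded replicates
  hits <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    des <- cohort_design(
      group_sizes = matrix(c(12, 12), 2, 1),
      age_mean = matrix(c(5, 6), 2, 1), age_sd = matrix(0.1, 2, 1),
      grid_dims = c(10, 10, 6), n_volumes = 24, timepoints = "t1",
      seed = 100 + r
    )
    tr <- ground_truth(des, networks = c("n1", "n2", "n3"),
                       cognition_coupling = c(n1 = 1, n2 = 0, n3 = 0),
                       cognition_noise_sd = 0.03)
    co <- simulate_cohort(des, tr, images = FALSE)
    mt <- dplyr::inner_join(
      dplyr::select(co$cohort, "subject_id", "timepoint",
                    group = "group_code", "age_months"),
      dplyr::mutate(co$truth_amplitudes, network = .data$source,
                    amplitude = .data$amplitude),
      by = c("subject_id", "timepoint")
    )
    res <- suppressWarnings(
      spearman_behavior(mt, co$behavior, metrics_cols = "amplitude")
    )
    res <- dplyr::filter(res, .data$measure == "n_trials")
    flagged <- res$network[res$significant]
    if (("n1" %in% flagged) && !any(c("n2", "n3") %in% flagged)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.8)
})
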