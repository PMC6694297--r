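#' Longitudinal cohort design
#'
#' Describes the sampling frame of a two-group, multi-timepoint resting-state
#' cohort: per-group per-timepoint subject counts, age means and jitter SDs
#' (months), the acquisition grid and the repetition time. The default mirrors
#' the study design this package emulates: wild-type and transgenic rats
#' followed at five timepoints from roughly 5 to 18 months of age, with the
#' reference per-timepoint group sizes, at a desk-scale 20 x 20 x 10 grid and
#' 200 volumes (the full-size 64 x 64 x 34 x 600 protocol is available by
#' passing those dimensions explicitly).
#'
#' @param group_sizes integer matrix `groups x timepoints` of subject counts.
#' @param age_mean,age_sd numeric matrices `groups x timepoints`: mean age in
#'   months at each timepoint and its between-subject jitter SD.
#' @param grid_dims integer length-3 voxel grid.
#' @param n_volumes volumes per acquisition (>= 20).
#' @param tr repetition time, seconds.
#' @param voxel_size_mm length-3 voxel size in mm (used by spatial
#'   smoothing). `NULL` (default) derives it from the acquisition field of
#'   view of 25.6 x 25.6 x 20.4 mm, so a desk-scale grid means coarser
#'   voxels over the same brain, and the full 64 x 64 x 34 grid reproduces
#'   the native 0.4 x 0.4 x 0.6 mm resolution.
#' @param timepoints,groups labels; groups are coded 0 (first row, control)
#'   and 1 (second row, transgenic) in all downstream models.
#' @param seed integer RNG seed for everything derived from this design.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(group_sizes = default_group_sizes(),
                          age_mean = default_age_mean(),
                          age_sd = default_age_sd(),
                          grid_dims = c(20L, 20L, 10L),
                          n_volumes = 200L,
                          tr = 2,
                          voxel_size_mm = NULL,
                          timepoints = paste0("t", seq_len(ncol(group_sizes))),
                          groups = c("WT", "Tg"),
                          seed = 1L) {
  group_sizes <- as.matrix(group_sizes)
  age_mean <- as.matrix(age_mean)
  age_sd <- as.matrix(age_sd)
  stopifnot(nrow(group_sizes) == 2, all(dim(age_mean) == dim(group_sizes)),
            all(dim(age_sd) == dim(group_sizes)))
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1")
  if (n_volumes < 20) stop("`n_volumes` must be >= 20")
  if (tr <= 0) stop("`tr` must be positive")
  if (any(apply(age_mean, 1, diff) <= 0)) {
    stop("timepoint mean ages must be strictly increasing")
  }
  if (any(age_sd < 0)) stop("age jitter SDs must be non-negative")
  if (is.null(voxel_size_mm)) {
    voxel_size_mm <- c(25.6, 25.6, 20.4) / grid_dims
  }
  dimnames(group_sizes) <- dimnames(age_mean) <- dimnames(age_sd) <-
    list(groups, timepoints)
  structure(
    list(group_sizes = group_sizes, age_mean = age_mean, age_sd = age_sd,
         grid_dims = as.integer(grid_dims), n_volumes = as.integer(n_volumes),
         tr = tr, voxel_size_mm = voxel_size_mm, timepoints = timepoints,
         groups = groups, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @rdname cohort_design
#' @export
default_group_sizes <- function() {
  matrix(c(6L, 10L, 9L, 9L, 9L,
           8L, 9L, 9L, 9L, 6L),
         nrow = 2, byrow = TRUE)
}

#' @rdname cohort_design
#' @export
default_age_mean <- function() {
  matrix(c(5.3, 8.1, 11.3, 14.8, 17.8,
           6.3, 8.5, 11.3, 14.9, 18.1),
         nrow = 2, byrow = TRUE)
}

#' @rdname cohort_design
#' @export
default_age_sd <- function() {
  matrix(c(0.3, 0.3, 0.1, 0.3, 0.3,
           1.0, 0.3, 0.1, 0.2, 0.5),
         nrow = 2, byrow = TRUE)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", paste(x$grid_dims, collapse = "x"),
      " grid, T=", x$n_volumes, ", TR=", x$tr, "s, ",
      sum(x$group_sizes), " acquisitions\n", sep = "")
  print(x$group_sizes)
  invisible(x)
}

#' Plant compact spatial network maps inside a mask
#'
#' Networks are modelled as compact "plateau" blobs: a logistic radial profile
#' that is ~1 inside `blob_radius` voxels of the centre and rolls off over
#' `edge_sigma` voxels. A plateau (rather than a Gaussian peak) guarantees
#' that, after the z-scoring applied to every spatial map in the pipeline, the
#' whole blob core survives a z-threshold, which is what makes voxel-count
#' overlap criteria meaningful. Centres are rejection-sampled inside the mask
#' until each map has at least `min_support` half-maximum voxels and all
#' pairwise spatial correlations stay below `max_pair_r`.
#'
#' @param grid_dims integer length-3 voxel grid.
#' @param mask logical 3D array.
#' @param n_networks number of maps to place (>= 1).
#' @param blob_radius plateau radius in voxels.
#' @param edge_sigma roll-off scale in voxels.
#' @param min_support minimum half-maximum voxels per map.
#' @param max_pair_r maximum allowed pairwise spatial correlation.
#' @param seed integer seed.
#' @param centers optional `n_networks x 3` matrix of fixed centres (skips
#'   sampling; still validated against `min_support`/`max_pair_r`).
#' @param max_attempts rejection-sampling budget.
#' @return `n_networks x V` matrix of non-negative weights (peak 1) over mask
#'   voxels, with attributes `centers` and `support`.
#' @export
make_network_maps <- function(grid_dims, mask, n_networks,
                              blob_radius = 4.2, edge_sigma = 0.7,
                              min_support = 300L, max_pair_r = 0.5,
                              seed = 1L, centers = NULL,
                              max_attempts = 2000L) {
  stopifnot(n_networks >= 1, length(dim(mask)) == 3)
  if (!any(mask)) stop("mask is empty")
  vox <- which(mask, arr.ind = TRUE)
  V <- nrow(vox)
  # compactly supported plateau: logistic roll-off truncated where the
  # profile falls to 5% so distant voxels are exactly zero (tails would
  # otherwise be inflated to full variance by voxelwise z-scoring)
  p_cut <- 0.05
  blob_at <- function(ctr) {
    d <- sqrt((vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 +
                (vox[, 3] - ctr[3])^2)
    w <- 1 / (1 + exp((d - blob_radius) / edge_sigma))
    w <- pmax(w - p_cut, 0) / (1 - p_cut)
    w / max(w)
  }
  maps <- matrix(0, nrow = n_networks, ncol = V)
  ctrs <- matrix(NA_real_, nrow = n_networks, ncol = 3)
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n_networks, ncol(centers) == 3)
    for (k in seq_len(n_networks)) {
      maps[k, ] <- blob_at(centers[k, ])
      ctrs[k, ] <- centers[k, ]
    }
  } else {
    with_seed(seed, {
      placed <- 0L
      attempts <- 0L
      while (placed < n_networks) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("could not place ", n_networks, " networks with >= ",
               min_support, " support voxels and pairwise r < ", max_pair_r,
               " in a mask of ", V, " voxels (placed ", placed,
               "); enlarge the mask or shrink the blobs")
        }
        ctr <- vox[sample.int(V, 1L), ]
        cand <- blob_at(ctr)
        if (sum(cand >= 0.5) < min_support) next
        if (placed > 0L) {
          rs <- apply(maps[seq_len(placed), , drop = FALSE], 1,
                      function(m) abs(cor(m, cand)))
          if (any(rs >= max_pair_r)) next
        }
        placed <- placed + 1L
        maps[placed, ] <- cand
        ctrs[placed, ] <- ctr
      }
    })
  }
  support <- rowSums(maps >= 0.5)
  if (any(support < min_support)) {
    stop("map support below ", min_support, " voxels (got ",
         paste(support, collapse = ", "), "); mask too small for blob radius ",
         blob_radius)
  }
  if (n_networks > 1) {
    pc <- abs(cor(t(maps)))
    diag(pc) <- 0
    if (max(pc) >= max_pair_r) {
      stop("planted maps too similar (max pairwise r = ",
           round(max(pc), 3), ")")
    }
  }
  attr(maps, "centers") <- ctrs
  attr(maps, "support") <- support
  maps
}

#' Band-limited source time courses
#'
#' Source courses are built directly in the frequency domain: unit complex
#' Gaussian coefficients on the DFT bins falling inside `band`, zero
#' elsewhere, inverse-transformed and standardised to zero mean and unit
#' sample SD. By construction essentially all spectral power lies inside the
#' band, so planted sources survive the pipeline's band-pass filter.
#'
#' @param n_courses number of courses (rows).
#' @param n_volumes samples per course.
#' @param tr sampling interval, seconds.
#' @param band length-2 passband in Hz, inside `(0, 1/(2*tr))`.
#' @param seed integer seed.
#' @return `n_courses x n_volumes` matrix, each row zero-mean unit-SD.
#' @export
make_timecourses <- function(n_courses, n_volumes, tr, band = c(0.01, 0.08),
                             seed = 1L) {
  nyq <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] > nyq) {
    stop("`band` must satisfy 0 < low < high <= Nyquist (", nyq, " Hz)")
  }
  freqs <- seq_len(floor(n_volumes / 2)) / (n_volumes * tr)
  keep <- which(freqs >= band[1] & freqs <= band[2])
  if (length(keep) == 0) {
    stop("no DFT bin falls inside the band; increase `n_volumes` or widen it")
  }
  with_seed(seed, {
    out <- matrix(0, n_courses, n_volumes)
    for (k in seq_len(n_courses)) {
      spec <- complex(real = rep(0, n_volumes), imaginary = rep(0, n_volumes))
      co <- complex(real = rnorm(length(keep)), imaginary = rnorm(length(keep)))
      spec[keep + 1L] <- co
      # Hermitian symmetry -> real inverse transform
      spec[n_volumes + 1L - keep] <- Conj(co)
      x <- Re(stats::fft(spec, inverse = TRUE)) / n_volumes
      out[k, ] <- (x - mean(x)) / sd(x)
    }
    out
  })
}

#' Ground truth for a synthetic cohort
#'
#' Collects everything the generator plants and the pipeline must recover:
#' spatial network maps, per-group linear amplitude-vs-age trajectories, the
#' subject random-offset SD, voxel noise SD, motion-leakage scale, the source
#' passband, and the coupling between network amplitude and behaviour. When
#' `dmn_subnets > 0`, the last analysis network ("DMN") is generated as that
#' many spatially compact subnetworks whose time courses share a common
#' parent signal (weight `subnet_shared`), so a low-order decomposition sees
#' one merged network while a high-order one resolves the subnetworks.
#'
#' The default trajectories emulate the qualitative study finding: the two
#' somatosensorial networks rise with age in controls (slope +0.03 amplitude
#' units/month) and fall in transgenics (-0.03), while the sensorimotor and
#' DMN networks carry no group-by-age interaction.
#'
#' @param design a [cohort_design()].
#' @param networks analysis-network labels; the last one is the subnetwork
#'   parent when `dmn_subnets > 0`.
#' @param dmn_subnets number of planted subnetworks inside the last network
#'   (0 = plain blob).
#' @param amp_slope,amp_intercept `groups x networks` matrices (amplitude
#'   units/month and units); defaults as described above.
#' @param subject_sd SD of the subject random amplitude offset.
#' @param amp_resid_sd SD of the per-acquisition, per-network amplitude
#'   fluctuation (session-to-session network state); this is the generative
#'   counterpart of the mixed model's residual term.
#' @param noise_sd voxelwise Gaussian noise SD.
#' @param motion_coupling scale of rank-6 motion leakage into voxel signals.
#' @param cognition_coupling named per-network weights linking amplitude to
#'   the behavioural score (default: first network only).
#' @param cognition_noise_sd SD of the behavioural score noise.
#' @param band source-course passband (Hz).
#' @param subnet_shared weight of the shared parent course in each
#'   subnetwork's time course (pairwise subnetwork r = `subnet_shared^2`).
#' @param blob_radius,edge_sigma,min_support blob geometry passed to
#'   [make_network_maps()]; defaults scale with the grid.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(design,
                         networks = c("somatosensorial_I", "somatosensorial_II",
                                      "sensorimotor", "DMN"),
                         dmn_subnets = 0L,
                         amp_slope = NULL, amp_intercept = NULL,
                         subject_sd = 0.1, amp_resid_sd = 0.08,
                         noise_sd = 0.5,
                         motion_coupling = 0.1,
                         cognition_coupling = NULL,
                         cognition_noise_sd = 0.05,
                         band = c(0.01, 0.08),
                         subnet_shared = 0.8,
                         blob_radius = NULL, edge_sigma = 0.7,
                         min_support = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  nyq <- 1 / (2 * design$tr)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] > nyq) {
    stop("`band` must lie inside (0, Nyquist)")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  K <- length(networks)
  mask <- ellipsoid_mask(design$grid_dims)
  # blob geometry scaled to the grid: ~4 disjoint networks fit and each
  # blob fills well under 10% of the mask, so its plateau survives the
  # z > 2.3 cut applied to every spatial map downstream
  if (is.null(blob_radius)) {
    blob_radius <- max(2.2, 0.24 * min(design$grid_dims))
  }
  if (is.null(min_support)) {
    # 0.55 x continuous ball volume is a safe bound for the discrete lattice
    min_support <- max(15L, floor(0.55 * (4 / 3) * pi * blob_radius^3))
  }

  n_sub <- as.integer(dmn_subnets)
  n_place <- if (n_sub > 0) K - 1L + n_sub else K
  placed <- make_network_maps(design$grid_dims, mask, n_place,
                              blob_radius = blob_radius,
                              edge_sigma = edge_sigma,
                              min_support = min_support,
                              seed = derive_seed(design$seed, 11L))

  if (n_sub > 0) {
    src_names <- c(networks[-K],
                   paste0(networks[K], "_sub", seq_len(n_sub)))
    source_maps <- placed
    rownames(source_maps) <- src_names
    parent_map <- apply(placed[K:(K - 1L + n_sub), , drop = FALSE], 2, max)
    network_maps <- rbind(placed[seq_len(K - 1L), , drop = FALSE],
                          parent_map)
    subnet_of <- setNames(rep(networks[K], n_sub), src_names[K:(K - 1L + n_sub)])
  } else {
    src_names <- networks
    source_maps <- placed
    rownames(source_maps) <- src_names
    network_maps <- placed
    subnet_of <- setNames(character(0), character(0))
  }
  rownames(network_maps) <- networks

  if (is.null(amp_slope)) {
    amp_slope <- matrix(0, 2, K, dimnames = list(design$groups, networks))
    ss <- grep("^somatosensorial", networks)
    amp_slope[1, ss] <- 0.03
    amp_slope[2, ss] <- -0.03
  }
  if (is.null(amp_intercept)) {
    # amplitude = 1 at mid-cohort age for every group/network
    mid_age <- mean(range(design$age_mean))
    amp_intercept <- 1 - amp_slope * mid_age
    dimnames(amp_intercept) <- list(design$groups, networks)
  }
  stopifnot(all(dim(amp_slope) == c(2, K)),
            all(dim(amp_intercept) == c(2, K)))
  dimnames(amp_slope) <- dimnames(amp_intercept) <-
    list(design$groups, networks)

  if (is.null(cognition_coupling)) {
    cognition_coupling <- setNames(c(1, rep(0, K - 1)), networks)
  }

  structure(
    list(networks = networks, source_networks = src_names,
         network_maps = network_maps, source_maps = source_maps,
         subnet_of = subnet_of, subnet_shared = subnet_shared,
         mask = mask, amp_slope = amp_slope, amp_intercept = amp_intercept,
         subject_sd = subject_sd, amp_resid_sd = amp_resid_sd,
         noise_sd = noise_sd,
         motion_coupling = motion_coupling,
         cognition_coupling = cognition_coupling,
         cognition_noise_sd = cognition_noise_sd,
         band = band, blob_radius = blob_radius,
         min_support = min_support),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$source_networks), " planted sources over ",
      sum(x$mask), " mask voxels\n", sep = "")
  cat("  networks:", paste(x$networks, collapse = ", "), "\n")
  if (length(x$subnet_of)) {
    cat("  subnetworks:", paste(names(x$subnet_of), collapse = ", "), "\n")
  }
  invisible(x)
}

# Planted amplitude of source k for one subject-acquisition.
planted_amplitude <- function(truth, group_idx, age, subject_offset) {
  net_of_src <- ifelse(truth$source_networks %in% names(truth$subnet_of),
                       truth$subnet_of[truth$source_networks],
                       truth$source_networks)
  a <- truth$amp_intercept[group_idx, net_of_src] +
    truth$amp_slope[group_idx, net_of_src] * age + subject_offset
  setNames(pmax(a, 0), truth$source_networks)
}

# Smooth rigid-body motion traces: integrated white noise, slightly smoothed,
# 3 translations (mm) and 3 rotations (rad).
make_motion <- function(n_volumes, seed) {
  with_seed(seed, {
    steps <- c(rep(0.01, 3), rep(0.001, 3))
    m <- vapply(steps, function(s) {
      x <- cumsum(rnorm(n_volumes, sd = s))
      stats::filter(c(x[1], x, x[n_volumes]), rep(1 / 3, 3))[2:(n_volumes + 1)]
    }, numeric(n_volumes))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Synthesize one subject acquisition
#'
#' Builds the 4D signal as a sum of planted spatial maps times band-limited
#' time courses, each scaled by a linear-in-age amplitude with a subject
#' random offset (mirroring the mixed-model structure fitted downstream),
#' plus a rank-6 motion-correlated nuisance term and voxelwise Gaussian
#' noise. Subnetwork sources share a common parent course with weight
#' `truth$subnet_shared`.
#'
#' @param truth a [ground_truth()].
#' @param design a [cohort_design()].
#' @param group 0 (control) or 1 (transgenic).
#' @param age age in months (> 0).
#' @param subject_offset amplitude offset: a scalar (subject random
#'   intercept), or a vector along `truth$source_networks` that additionally
#'   carries per-network session fluctuation.
#' @param seed integer seed for this acquisition.
#' @param subject_id,timepoint identifiers.
#' @return A list with elements `vs` (a [volume_series()]), `motion`
#'   (`T x 6` matrix) and `amplitudes` (named planted source amplitudes).
#' @export
synthesize_subject <- function(truth, design, group, age, subject_offset = 0,
                               seed = 1L, subject_id = NA_character_,
                               timepoint = NA_character_) {
  stopifnot(group %in% c(0, 1), age > 0)
  gi <- group + 1L
  Ks <- length(truth$source_networks)
  n_shared <- as.integer(length(truth$subnet_of) > 0)
  courses <- make_timecourses(Ks + n_shared, design$n_volumes, design$tr,
                              truth$band, seed = derive_seed(seed, 1L))
  if (n_shared) {
    shared <- courses[Ks + 1L, ]
    w <- truth$subnet_shared
    for (k in which(truth$source_networks %in% names(truth$subnet_of))) {
      mixed <- w * shared + sqrt(1 - w^2) * courses[k, ]
      courses[k, ] <- (mixed - mean(mixed)) / sd(mixed)
    }
    courses <- courses[seq_len(Ks), , drop = FALSE]
  }
  a <- planted_amplitude(truth, gi, age, subject_offset)
  sig <- crossprod(truth$source_maps, a * courses)  # V x T

  motion <- make_motion(design$n_volumes, derive_seed(seed, 2L))
  if (truth$motion_coupling > 0) {
    with_seed(derive_seed(seed, 3L), {
      patt <- matrix(rnorm(6 * nrow(sig)), nrow = 6)
    })
    ms <- scale(motion)
    sig <- sig + truth$motion_coupling * crossprod(patt, t(ms))
  }
  if (truth$noise_sd > 0) {
    with_seed(derive_seed(seed, 4L), {
      sig <- sig + matrix(rnorm(length(sig), sd = truth$noise_sd),
                          nrow = nrow(sig))
    })
  }
  list(
    vs = volume_series(sig, truth$mask, design$tr, subject_id, timepoint),
    motion = motion,
    amplitudes = a
  )
}

#' Simulate a full longitudinal cohort
#'
#' Generates every subject-by-timepoint acquisition of the design, with
#' subject random offsets drawn once per subject and ages jittered around the
#' per-group timepoint means (a single per-subject jitter scalar, clipped to
#' +/- 3 SD, keeps each subject's ages strictly increasing). When subjects
#' enter or leave the study (unequal per-timepoint counts) the first
#' `group_sizes[g, t]` subjects of the group's roster are present at
#' timepoint `t`. Optionally writes the dataset to disk: one 4D NIfTI per
#' acquisition, TSV motion/cohort/behaviour tables and a JSON ground-truth
#' manifest.
#'
#' @param design a [cohort_design()].
#' @param truth a [ground_truth()]; defaults to `ground_truth(design)`.
#' @param dir output directory (created). `NULL` keeps the cohort in memory.
#' @param images generate the 4D data (`TRUE`); `FALSE` returns only the
#'   cohort frame, planted amplitudes and behaviour (cheap, deterministic,
#'   identical covariates to the full run).
#' @return An `rsn_cohort` list: `design`, `truth`, `cohort` (tibble with one
#'   row per acquisition), `acquisitions` (named list of
#'   [synthesize_subject()] results), `truth_amplitudes` (planted source
#'   amplitudes, long format), `behavior` (see [simulate_behavior()]) and,
#'   when written, `paths`/`manifest`.
#' @export
simulate_cohort <- function(design, truth = ground_truth(design), dir = NULL,
                            images = TRUE) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "ground_truth"))
  gs <- design$group_sizes
  K_net <- length(truth$networks)
  rows <- list()
  # per-subject, per-network random intercepts (each network's mixed model
  # carries its own subject term), plus per-subject age jitter
  off_mat <- list()
  for (g in 1:2) {
    n_max <- max(gs[g, ])
    ids <- sprintf("%s%02d", design$groups[g], seq_len(n_max))
    off_mat[[g]] <- with_seed(
      derive_seed(design$seed, 100L + g),
      matrix(rnorm(n_max * K_net, sd = truth$subject_sd), n_max, K_net,
             dimnames = list(ids, truth$networks))
    )
    jit <- with_seed(derive_seed(design$seed, 200L + g),
                     pmin(pmax(rnorm(n_max), -3), 3))
    for (t in seq_along(design$timepoints)) {
      present <- seq_len(gs[g, t])
      for (s in present) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = ids[s], group = design$groups[g],
          group_code = g - 1L, timepoint = design$timepoints[t],
          age_months = design$age_mean[g, t] + jit[s] * design$age_sd[g, t],
          roster_idx = s
        )
      }
    }
  }
  cohort <- dplyr::bind_rows(rows)
  cohort <- dplyr::arrange(cohort, .data$group_code, .data$subject_id,
                           .data$timepoint)

  # total amplitude offset per acquisition = subject-by-network random
  # intercept + per-network session fluctuation (the generative residual);
  # one RNG stream for the whole cohort so draws are mutually independent
  net_of_src <- ifelse(truth$source_networks %in% names(truth$subnet_of),
                       truth$subnet_of[truth$source_networks],
                       truth$source_networks)
  n_src <- length(truth$source_networks)
  eta_mat <- with_seed(derive_seed(design$seed, 4000L),
                       matrix(rnorm(nrow(cohort) * n_src,
                                    sd = truth$amp_resid_sd),
                              nrow = nrow(cohort)))
  offsets <- lapply(seq_len(nrow(cohort)), function(i) {
    g <- cohort$group_code[i] + 1L
    off_mat[[g]][cohort$roster_idx[i], net_of_src] + eta_mat[i, ]
  })
  cohort$roster_idx <- NULL

  amp_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    a <- planted_amplitude(truth, r$group_code + 1L, r$age_months,
                           offsets[[i]])
    amp_rows[[i]] <- tibble::tibble(
      subject_id = r$subject_id, timepoint = r$timepoint,
      source = names(a), amplitude = unname(a)
    )
  }
  truth_amps <- dplyr::bind_rows(amp_rows)

  acqs <- list()
  if (images) {
    acqs <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      r <- cohort[i, ]
      acqs[[i]] <- synthesize_subject(truth, design, r$group_code,
                                      r$age_months, offsets[[i]],
                                      seed = derive_seed(design$seed,
                                                         1000L + i),
                                      subject_id = r$subject_id,
                                      timepoint = r$timepoint)
    }
    names(acqs) <- paste(cohort$subject_id, cohort$timepoint, sep = "_")
  }

  behavior <- simulate_behavior(
    truth,
    analysis_amplitudes(truth, truth_amps),
    noise_sd = truth$cognition_noise_sd,
    seed = derive_seed(design$seed, 300L)
  )

  out <- structure(
    list(design = design, truth = truth, cohort = cohort,
         acquisitions = acqs, truth_amplitudes = truth_amps,
         behavior = behavior),
    class = "rsn_cohort"
  )
  if (!is.null(dir)) {
    if (!images) stop("cannot write a cohort simulated with images = FALSE")
    out <- write_cohort(out, dir)
  }
  out
}

#' @export
print.rsn_cohort <- function(x, ...) {
  cat("<rsn_cohort> ", nrow(x$cohort), " acquisitions, ",
      length(unique(x$cohort$subject_id)), " subjects, ",
      length(x$design$timepoints), " timepoints\n", sep = "")
  invisible(x)
}

# Collapse planted source amplitudes to analysis-network level (subnetworks
# report their shared parent amplitude).
analysis_amplitudes <- function(truth, truth_amps) {
  net <- ifelse(truth_amps$source %in% names(truth$subnet_of),
                truth$subnet_of[truth_amps$source], truth_amps$source)
  df <- dplyr::mutate(truth_amps, network = net)
  dplyr::summarise(dplyr::group_by(df, .data$subject_id, .data$timepoint,
                                   .data$network),
                   amplitude = mean(.data$amplitude), .groups = "drop")
}

#' Simulate behavioural outcomes coupled to network amplitude
#'
#' The behavioural score of each subject-timepoint is a weighted sum of its
#' planted network amplitudes (weights `truth$cognition_coupling`) plus
#' Gaussian noise, mapped affinely to a positive trial count and a correct
#' -response ratio clipped to `[0, 1]` — the two outcomes of an operant
#' working-memory task.
#'
#' @param truth a [ground_truth()].
#' @param amplitudes tibble with columns `subject_id`, `timepoint`,
#'   `network`, `amplitude` (one row per subject x timepoint x network).
#' @param noise_sd SD of the score noise (score is in amplitude units).
#' @param seed integer seed.
#' @param base_trials,trial_gain affine map from score to trial count.
#' @param ratio_base,ratio_gain affine map from score to correct ratio.
#' @return Tibble: `subject_id`, `timepoint`, `n_trials`, `correct_ratio`.
#' @export
simulate_behavior <- function(truth, amplitudes, noise_sd = 0.05, seed = 1L,
                              base_trials = 60, trial_gain = 30,
                              ratio_base = 0.7, ratio_gain = 0.2) {
  w <- truth$cognition_coupling
  amp <- dplyr::filter(amplitudes, .data$network %in% names(w))
  amp <- dplyr::mutate(amp, wamp = .data$amplitude * w[.data$network])
  score <- dplyr::summarise(
    dplyr::group_by(amp, .data$subject_id, .data$timepoint),
    score = sum(.data$wamp), .groups = "drop"
  )
  # centre so zero coupling maps to the baseline behaviour
  score$score <- score$score - if (all(w == 0)) 0 else mean(score$score)
  n <- nrow(score)
  with_seed(seed, {
    e1 <- rnorm(n, sd = noise_sd)
    e2 <- rnorm(n, sd = noise_sd)
  })
  tibble::tibble(
    subject_id = score$subject_id,
    timepoint = score$timepoint,
    n_trials = pmax(1L, as.integer(round(base_trials +
                                           trial_gain * (score$score + e1)))),
    correct_ratio = pmin(1, pmax(0, ratio_base +
                                   ratio_gain * (score$score + e2)))
  )
}
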