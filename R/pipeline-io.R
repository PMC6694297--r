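# File formats and end-to-end orchestration.

md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}

# Content hash of an R object (serialised canonically to JSON).
hash_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read / write 4D volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping double precision so that a
#' write-then-read round trip is bit-identical.
#'
#' @param arr numeric 3D or 4D array (or a [volume_series()]).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes (mm) for the spatial dimensions.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   plain numeric array.
#' @export
write_nifti <- function(arr, path, pixdim = c(0.4, 0.4, 0.6)) {
  if (inherits(arr, "volume_series")) arr <- as_volume_array(arr)
  attr(arr, "pixdim") <- c(pixdim, rep(1, length(dim(arr)) - 3))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write a simulated cohort to disk
#'
#' One 4D NIfTI per acquisition, 6-column TSV motion tables, TSV cohort and
#' behaviour tables, the mask and labelled template volumes, the planted
#' amplitude table, and a JSON ground-truth manifest listing every file with
#' its checksum and generating parameters. A partial write is cleaned up
#' before the error is rethrown.
#'
#' @param cohort an `rsn_cohort` from [simulate_cohort()].
#' @param dir output directory (created; must be empty or absent).
#' @return The cohort, with `paths` (named file list) and `manifest` added.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rsn_cohort"))
  created <- !dir.exists(dir)
  dir.create(file.path(dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  tryCatch({
    vox <- cohort$design$voxel_size_mm
    paths <- list()
    for (nm in names(cohort$acquisitions)) {
      acq <- cohort$acquisitions[[nm]]
      f <- file.path(dir, "raw", paste0(nm, ".nii.gz"))
      write_nifti(acq$vs, f, vox)
      fm <- file.path(dir, "raw", paste0(nm, "_motion.tsv"))
      readr::write_tsv(tibble::as_tibble(acq$motion), fm)
      paths[[nm]] <- c(volume = f, motion = fm)
    }
    mask_arr <- array(0, cohort$design$grid_dims)
    mask_arr[cohort$truth$mask] <- 1
    f_mask <- file.path(dir, "raw", "mask.nii.gz")
    write_nifti(mask_arr, f_mask, vox)

    K <- nrow(cohort$truth$network_maps)
    tmpl <- array(0, c(cohort$design$grid_dims, K))
    for (k in seq_len(K)) {
      v <- array(0, cohort$design$grid_dims)
      v[cohort$truth$mask] <- as.numeric(cohort$truth$network_maps[k, ] >= 0.5)
      tmpl[, , , k] <- v
    }
    f_tmpl <- file.path(dir, "raw", "templates.nii.gz")
    write_nifti(tmpl, f_tmpl, vox)

    f_cohort <- file.path(dir, "raw", "cohort.tsv")
    readr::write_tsv(cohort$cohort, f_cohort)
    f_behav <- file.path(dir, "raw", "behavior.tsv")
    readr::write_tsv(cohort$behavior, f_behav)
    f_amps <- file.path(dir, "raw", "truth_amplitudes.tsv")
    readr::write_tsv(cohort$truth_amplitudes, f_amps)

    files <- c(unlist(paths), f_mask, f_tmpl, f_cohort, f_behav, f_amps)
    manifest <- list(
      n_acquisitions = length(cohort$acquisitions),
      grid_dims = cohort$design$grid_dims,
      n_volumes = cohort$design$n_volumes,
      tr = cohort$design$tr,
      seed = cohort$design$seed,
      networks = cohort$truth$networks,
      source_networks = cohort$truth$source_networks,
      subnet_of = as.list(cohort$truth$subnet_of),
      amp_slope = cohort$truth$amp_slope,
      amp_intercept = cohort$truth$amp_intercept,
      subject_sd = cohort$truth$subject_sd,
      noise_sd = cohort$truth$noise_sd,
      motion_coupling = cohort$truth$motion_coupling,
      files = as.list(setNames(md5_of(files), files))
    )
    f_manifest <- file.path(dir, "raw", "manifest.json")
    jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                         digits = 12, pretty = TRUE)
    cohort$paths <- paths
    cohort$manifest <- manifest
    cohort$dir <- dir
    cohort
  }, error = function(e) {
    if (created) unlink(dir, recursive = TRUE) else
      unlink(file.path(dir, "raw"), recursive = TRUE)
    stop("cohort write failed (partial output removed): ",
         conditionMessage(e))
  })
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end experiment with the conventional
#' defaults: 5 discarded volumes, 1.2 mm FWHM smoothing, linear detrend,
#' 0.01-0.1 Hz band, ICA orders 30/150 (capped at the data rank when the
#' desk-scale grid cannot support them), z-threshold 2.3, subnetwork matching
#' at r > 0.4 with > 250 shared voxels, significance 0.05 with a 0.1 tendency
#' tier.
#'
#' @param n_discard,fwhm_mm,voxel_size_mm,detrend_order,band preprocessing.
#' @param order_low,order_high,ica_seed,z_thresh ICA / thresholding.
#' @param r_thresh,overlap_thresh,use_abs subnetwork matching.
#' @param alpha,tendency,fdr_family,df,fisher_z statistics layer.
#' @param parent_label network decomposed into subnetworks.
#' @param variance_normalize block variance normalisation at concatenation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_discard = 5L, fwhm_mm = 1.2,
                            voxel_size_mm = NULL,
                            detrend_order = 1L, band = c(0.01, 0.1),
                            order_low = 30L, order_high = 150L,
                            ica_seed = 1L, z_thresh = 2.3,
                            r_thresh = 0.4, overlap_thresh = 250L,
                            use_abs = FALSE,
                            alpha = 0.05, tendency = 0.1,
                            fdr_family = "network_metric",
                            df = "satterthwaite", fisher_z = TRUE,
                            parent_label = "DMN",
                            variance_normalize = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Internal: does the stored manifest still describe this stage's outputs?
stage_current <- function(manifest, stage, hash) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec) || !identical(rec$hash, hash)) return(FALSE)
  files <- names(rec$outputs)
  if (!all(file.exists(files))) return(FALSE)
  all(md5_of(files) == unlist(rec$outputs, use.names = FALSE))
}

record_stage <- function(manifest, stage, hash, files) {
  manifest$stages[[stage]] <- list(
    hash = hash, outputs = as.list(setNames(md5_of(files), files))
  )
  manifest
}

read_run_manifest <- function(dir) {
  f <- file.path(dir, "run_manifest.json")
  if (file.exists(f)) jsonlite::read_json(f) else list(stages = list())
}

write_run_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full longitudinal RSN experiment
#'
#' Orchestrates simulate -> preprocess -> group ICA (low and high order) ->
#' dual regression -> metrics -> subnetworks -> statistics over a synthetic
#' cohort, writing each stage's outputs under `out_dir` and gating stages on
#' checksums: a rerun with unchanged configuration and intact files is a
#' no-op, while a corrupted or outdated stage re-runs together with
#' everything downstream of it. Any stage failure halts with the stage name.
#'
#' @param design a [cohort_design()].
#' @param truth a [ground_truth()]; default derives from the design.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return An `rsn_pipeline_result` list: result tables (`metrics`,
#'   `connectivity`, `lme`, `lme_connectivity`, `group_tests`, `spearman`,
#'   `subnets`, `within_connectivity`, `labels`), the component sets, the
#'   cohort, `stages_run` (stages executed this invocation) and the manifest.
#' @export
run_pipeline <- function(design, truth = ground_truth(design),
                         config = pipeline_config(), out_dir) {
  stopifnot(inherits(design, "cohort_design"), inherits(config,
                                                        "pipeline_config"))
  if (is.null(config$voxel_size_mm)) {
    config$voxel_size_mm <- design$voxel_size_mm
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_run_manifest(out_dir)
  stages_run <- character(0)
  state <- new.env(parent = emptyenv())

  # A stage is skipped only if its parameter hash and output checksums are
  # intact AND no upstream stage re-ran this invocation (so a corrupted
  # intermediate re-runs exactly itself plus everything downstream).
  run_stage <- function(stage, hash, runner) {
    if (stage_current(manifest, stage, hash) && length(stages_run) == 0) {
      return(invisible(NULL))
    }
    files <- tryCatch(runner(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest <<- record_stage(manifest, stage, hash, files)
    stages_run <<- c(stages_run, stage)
    write_run_manifest(manifest, out_dir)
    invisible(NULL)
  }

  ## -- simulate ------------------------------------------------------------
  sim_hash <- hash_obj(list(design = unclass(design),
                            noise = truth$noise_sd,
                            motion = truth$motion_coupling,
                            subject_sd = truth$subject_sd,
                            networks = truth$source_networks))
  run_stage("simulate", sim_hash, function() {
    cohort <- simulate_cohort(design, truth, dir = out_dir)
    state$cohort <- cohort
    f <- file.path(out_dir, "raw")
    list.files(f, full.names = TRUE)
  })
  if (is.null(state$cohort)) {
    # stage skipped: cheap deterministic rebuild of the cohort frame;
    # raw images are reloaded from disk only if a later stage needs them
    state$cohort <- simulate_cohort(design, truth, images = FALSE)
    state$cohort$dir <- out_dir
  }
  cohort <- state$cohort
  get_acq <- function(nm) {
    if (!is.null(cohort$acquisitions[[nm]])) return(cohort$acquisitions[[nm]])
    arr <- read_nifti(file.path(out_dir, "raw", paste0(nm, ".nii.gz")))
    motion <- as.matrix(readr::read_tsv(
      file.path(out_dir, "raw", paste0(nm, "_motion.tsv")),
      show_col_types = FALSE))
    parts <- strsplit(nm, "_")[[1]]
    list(vs = as_volume_series(arr, truth$mask, design$tr,
                               parts[1], parts[2]),
         motion = motion)
  }
  acq_names <- paste(cohort$cohort$subject_id, cohort$cohort$timepoint,
                     sep = "_")

  ## -- preprocess ----------------------------------------------------------
  pp_dir <- file.path(out_dir, "preproc")
  pp_hash <- hash_obj(list(sim_hash, config$n_discard, config$fwhm_mm,
                           config$detrend_order, config$band))
  run_stage("preprocess", pp_hash, function() {
    dir.create(pp_dir, showWarnings = FALSE)
    files <- character(0)
    state$preproc <- lapply(acq_names, function(nm) {
      acq <- get_acq(nm)
      pv <- preprocess_series(acq$vs, acq$motion,
                              n_discard = config$n_discard,
                              fwhm_mm = config$fwhm_mm,
                              voxel_size_mm = config$voxel_size_mm,
                              detrend_order = config$detrend_order,
                              band = config$band)
      f <- file.path(pp_dir, paste0(nm, ".nii.gz"))
      write_nifti(pv, f, config$voxel_size_mm)
      files <<- c(files, f)
      pv
    })
    names(state$preproc) <- acq_names
    files
  })
  if (is.null(state$preproc)) {
    state$preproc <- lapply(acq_names, function(nm) {
      arr <- read_nifti(file.path(pp_dir, paste0(nm, ".nii.gz")))
      parts <- strsplit(nm, "_")[[1]]
      as_volume_series(arr, truth$mask, design$tr, parts[1], parts[2])
    })
    names(state$preproc) <- acq_names
  }

  ## -- group ICA -----------------------------------------------------------
  ica_dir <- file.path(out_dir, "ica")
  ica_hash <- hash_obj(list(pp_hash, config$order_low, config$order_high,
                            config$ica_seed, config$z_thresh,
                            config$variance_normalize))
  run_stage("ica", ica_hash, function() {
    dir.create(ica_dir, showWarnings = FALSE)
    cc <- concatenate_cohort(state$preproc, config$variance_normalize)
    rank_cap <- min(nrow(cc$mat), ncol(cc$mat)) - 1L
    k_low <- min(config$order_low, rank_cap)
    k_high <- min(config$order_high, rank_cap)
    if (k_low < config$order_low || k_high < config$order_high) {
      message("ICA order capped at data rank: low ", k_low, ", high ", k_high)
    }
    cs_low <- reduce_and_ica(cc, k_low, seed = config$ica_seed)
    cs_high <- reduce_and_ica(cc, k_high,
                              seed = derive_seed(config$ica_seed, 2L))
    templates <- lapply(seq_len(nrow(truth$network_maps)), function(k)
      truth$network_maps[k, ] >= 0.5)
    names(templates) <- truth$networks
    quota <- setNames(rep(1L, length(templates)), names(templates))
    labels <- match_templates(cs_low, templates, z_thresh = config$z_thresh,
                              max_per_label = quota)
    state$cc <- cc
    state$cs_low <- cs_low
    state$cs_high <- cs_high
    state$labels <- labels
    f1 <- file.path(ica_dir, "mixing_low.tsv")
    readr::write_tsv(tibble::as_tibble(cs_low$mixing), f1)
    f2 <- file.path(ica_dir, "maps_low.tsv")
    readr::write_tsv(tibble::as_tibble(t(cs_low$maps_z)), f2)
    f3 <- file.path(ica_dir, "labels.json")
    jsonlite::write_json(labels, f3, auto_unbox = TRUE, pretty = TRUE)
    f4 <- file.path(ica_dir, "mixing_high.tsv")
    readr::write_tsv(tibble::as_tibble(cs_high$mixing), f4)
    f5 <- file.path(ica_dir, "maps_high.tsv")
    readr::write_tsv(tibble::as_tibble(t(cs_high$maps_z)), f5)
    c(f1, f2, f3, f4, f5)
  })
  if (is.null(state$cs_low)) {
    state$cc <- concatenate_cohort(state$preproc, config$variance_normalize)
    ml <- t(as.matrix(readr::read_tsv(file.path(ica_dir, "maps_low.tsv"),
                                      show_col_types = FALSE)))
    mh <- t(as.matrix(readr::read_tsv(file.path(ica_dir, "maps_high.tsv"),
                                      show_col_types = FALSE)))
    state$cs_low <- structure(list(
      maps_z = ml,
      mixing = as.matrix(readr::read_tsv(file.path(ica_dir, "mixing_low.tsv"),
                                         show_col_types = FALSE)),
      order = nrow(ml), mask = truth$mask, ranges = state$cc$ranges),
      class = "component_set")
    state$cs_high <- structure(list(
      maps_z = mh,
      mixing = as.matrix(readr::read_tsv(file.path(ica_dir,
                                                   "mixing_high.tsv"),
                                         show_col_types = FALSE)),
      order = nrow(mh), mask = truth$mask, ranges = state$cc$ranges),
      class = "component_set")
    lj <- jsonlite::read_json(file.path(ica_dir, "labels.json"),
                              simplifyVector = TRUE)
    state$labels <- tibble::as_tibble(lj)
  }

  ## -- dual regression -----------------------------------------------------
  dr_dir <- file.path(out_dir, "dualreg")
  dr_hash <- hash_obj(list(ica_hash, "stage12"))
  run_stage("dualreg", dr_hash, function() {
    dir.create(dr_dir, showWarnings = FALSE)
    files <- character(0)
    state$dr <- lapply(names(state$preproc), function(nm) {
      d <- dual_regression(state$preproc[[nm]], state$cs_low$maps_z)
      f <- file.path(dr_dir, paste0(nm, "_timeseries.tsv"))
      readr::write_tsv(tibble::as_tibble(d$timeseries), f)
      files <<- c(files, f)
      d
    })
    names(state$dr) <- names(state$preproc)
    files
  })
  if (is.null(state$dr)) {
    state$dr <- lapply(names(state$preproc), function(nm)
      dual_regression(state$preproc[[nm]], state$cs_low$maps_z))
    names(state$dr) <- names(state$preproc)
  }

  ## -- metrics -------------------------------------------------------------
  met_dir <- file.path(out_dir, "metrics")
  # rename components to their network labels where matched
  lab <- state$labels
  keep <- which(lab$label != "unlabeled")
  relabel <- function(sns) {
    ts <- sns$timeseries[, keep, drop = FALSE]
    colnames(ts) <- lab$label[keep]
    zm <- sns$z_maps[keep, , drop = FALSE]
    rownames(zm) <- lab$label[keep]
    sns$timeseries <- ts
    sns$z_maps <- zm
    sns
  }
  met_hash <- hash_obj(list(dr_hash, config$z_thresh))
  run_stage("metrics", met_hash, function() {
    dir.create(met_dir, showWarnings = FALSE)
    sets <- lapply(state$dr, relabel)
    state$metrics <- metric_table(sets, cohort$cohort,
                                  z_thresh = config$z_thresh)
    state$connectivity <- connectivity_table(sets, cohort$cohort)
    f1 <- file.path(met_dir, "metrics.tsv")
    readr::write_tsv(state$metrics, f1)
    f2 <- file.path(met_dir, "connectivity.tsv")
    readr::write_tsv(state$connectivity, f2)
    c(f1, f2)
  })
  if (is.null(state$metrics)) {
    state$metrics <- readr::read_tsv(file.path(met_dir, "metrics.tsv"),
                                     show_col_types = FALSE)
    state$connectivity <- readr::read_tsv(
      file.path(met_dir, "connectivity.tsv"), show_col_types = FALSE)
  }

  ## -- subnetworks ---------------------------------------------------------
  sub_dir <- file.path(out_dir, "subnets")
  sub_hash <- hash_obj(list(met_hash, config$r_thresh, config$overlap_thresh,
                            config$use_abs, config$parent_label))
  has_parent <- config$parent_label %in% state$labels$label
  run_stage("subnets", sub_hash, function() {
    dir.create(sub_dir, showWarnings = FALSE)
    if (!has_parent) {
      state$subnets <- NULL
      state$within <- NULL
      f <- file.path(sub_dir, "assignment.json")
      jsonlite::write_json(list(parent = config$parent_label,
                                assigned = character(0)), f,
                           auto_unbox = TRUE)
      return(f)
    }
    asg <- match_subnetworks(config$parent_label, state$cs_low,
                             state$labels, state$cs_high,
                             r_thresh = config$r_thresh,
                             overlap_thresh = config$overlap_thresh,
                             z_thresh = config$z_thresh,
                             use_abs = config$use_abs)
    state$subnets <- asg
    sub_idx <- which(asg$assigned)
    within <- NULL
    if (length(sub_idx) >= 2) {
      sub_maps <- state$cs_high$maps_z[sub_idx, , drop = FALSE]
      within <- purrr::map_dfr(names(state$preproc), function(nm) {
        d <- dual_regression(state$preproc[[nm]], sub_maps)
        tibble::tibble(subject_id = state$preproc[[nm]]$subject_id,
                       timepoint = state$preproc[[nm]]$timepoint,
                       mean_connectivity =
                         mean_within_connectivity(d$timeseries))
      })
      within <- dplyr::inner_join(
        dplyr::select(cohort$cohort, "subject_id", "timepoint",
                      group = "group_code", "age_months"),
        within, by = c("subject_id", "timepoint"))
    }
    state$within <- within
    f1 <- file.path(sub_dir, "assignment.json")
    jsonlite::write_json(asg, f1, auto_unbox = TRUE, pretty = TRUE)
    fs <- f1
    if (!is.null(within)) {
      f2 <- file.path(sub_dir, "within_connectivity.tsv")
      readr::write_tsv(within, f2)
      fs <- c(f1, f2)
    }
    fs
  })
  if (is.null(state$subnets) && has_parent &&
      file.exists(file.path(sub_dir, "assignment.json"))) {
    state$subnets <- tibble::as_tibble(
      jsonlite::read_json(file.path(sub_dir, "assignment.json"),
                          simplifyVector = TRUE))
    f2 <- file.path(sub_dir, "within_connectivity.tsv")
    if (file.exists(f2)) {
      state$within <- readr::read_tsv(f2, show_col_types = FALSE)
    }
  }

  ## -- statistics ----------------------------------------------------------
  st_dir <- file.path(out_dir, "stats")
  st_hash <- hash_obj(list(sub_hash, config$alpha, config$tendency,
                           config$fdr_family, config$df, config$fisher_z))
  run_stage("stats", st_hash, function() {
    dir.create(st_dir, showWarnings = FALSE)
    state$lme <- lme_table(state$metrics, df = config$df,
                           alpha = config$alpha)
    conn <- dplyr::mutate(state$connectivity,
                          network = paste(.data$network_a, .data$network_b,
                                          sep = "~"))
    state$lme_conn <- lme_table(conn, metrics_cols = "pearson_r",
                                df = config$df, alpha = config$alpha)
    state$group_tests <- timepoint_group_tests(
      state$metrics, family = config$fdr_family,
      alpha = config$alpha, tendency = config$tendency)
    state$spearman <- spearman_behavior(state$metrics, cohort$behavior,
                                        alpha = config$alpha)
    f1 <- file.path(st_dir, "lme.tsv")
    readr::write_tsv(state$lme, f1)
    f2 <- file.path(st_dir, "lme_connectivity.tsv")
    readr::write_tsv(state$lme_conn, f2)
    f3 <- file.path(st_dir, "group_tests.tsv")
    readr::write_tsv(state$group_tests, f3)
    f4 <- file.path(st_dir, "spearman.tsv")
    readr::write_tsv(state$spearman, f4)
    c(f1, f2, f3, f4)
  })
  if (is.null(state$lme)) {
    state$lme <- readr::read_tsv(file.path(st_dir, "lme.tsv"),
                                 show_col_types = FALSE)
    state$lme_conn <- readr::read_tsv(
      file.path(st_dir, "lme_connectivity.tsv"), show_col_types = FALSE)
    state$group_tests <- readr::read_tsv(file.path(st_dir, "group_tests.tsv"),
                                         show_col_types = FALSE)
    state$spearman <- readr::read_tsv(file.path(st_dir, "spearman.tsv"),
                                      show_col_types = FALSE)
  }

  structure(
    list(cohort = cohort, labels = state$labels,
         cs_low = state$cs_low, cs_high = state$cs_high,
         metrics = state$metrics, connectivity = state$connectivity,
         lme = state$lme, lme_connectivity = state$lme_conn,
         group_tests = state$group_tests, spearman = state$spearman,
         subnets = state$subnets, within_connectivity = state$within,
         stages_run = stages_run, manifest = manifest, out_dir = out_dir),
    class = "rsn_pipeline_result"
  )
}

#' @export
print.rsn_pipeline_result <- function(x, ...) {
  cat("<rsn_pipeline_result> ", nrow(x$cohort$cohort), " acquisitions; ",
      "stages run this invocation: ",
      if (length(x$stages_run)) paste(x$stages_run, collapse = ", ")
      else "(none - all current)", "\n", sep = "")
  invisible(x)
}
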