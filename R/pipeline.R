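#' Run the full dALFF analysis pipeline
#'
#' Chains simulation (or loading) of a cohort, preprocessing, windowed
#' ALFF coefficient-of-variation mapping, voxelwise group inference with
#' cluster correction, and clinical association statistics, writing every
#' product plus a run manifest into the output directory. All stage and
#' subject seeds derive from the single configured seed, so deterministic
#' stages reproduce bit-identically.
#'
#' @param config A `pipeline_config` from [load_config()], a path to a
#'   YAML config, or a plain list of overrides.
#' @param cohort Optional pre-built `cohort_bundle`, bypassing the
#'   simulate/load stage.
#' @return A list with `cv_maps`, `statmap`, `clusters`, `roi_means`,
#'   `correlations`, `roc`, `demographics`, `smoothness`, `out_dir`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("stage setup: cannot create output directory ", out_dir)
  log_lines <- c(sprintf("dalff pipeline %s", as.character(utils::packageVersion("dalff"))),
                 sprintf("seed: %d", as.integer(config$seed)),
                 sprintf("band: %g-%g Hz; window %d TRs step %d; normalize_by %s",
                         config$alff$f_lo, config$alff$f_hi,
                         config$alff$window_length_tr, config$alff$window_step_tr,
                         config$alff$normalize_by),
                 sprintf("inference: %s, voxel_p %g, cluster_p %g, connectivity %d, two_sided %s",
                         config$inference$method, config$inference$voxel_p,
                         config$inference$cluster_p, config$inference$connectivity,
                         config$inference$two_sided),
                 sprintf("smoothing: %g mm FWHM at stage '%s'",
                         config$preprocess$fwhm_mm[1], config$preprocess$smooth_stage))

  # --- stage 1: cohort -----------------------------------------------------
  if (is.null(cohort)) {
    if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      ccfg <- cohort_config(n_patients = sim$n_patients,
                            n_controls = sim$n_controls,
                            grid_shape = sim$grid_shape,
                            voxel_size_mm = sim$voxel_size_mm,
                            n_timepoints = sim$n_timepoints, tr_s = sim$tr_s,
                            modulation_depth_patient = sim$modulation_depth_patient,
                            modulation_depth_control = sim$modulation_depth_control,
                            seed = config$seed)
      cohort <- generate_cohort(ccfg)
      log_lines <- c(log_lines, sprintf("simulated cohort: %d + %d subjects",
                                        sim$n_patients, sim$n_controls))
    } else {
      cohort <- read_cohort(config$paths$input_dir, tr_s = config$simulate$tr_s)
      log_lines <- c(log_lines, paste("loaded cohort from", config$paths$input_dir))
    }
  }

  # --- stage 2 + 3: preprocess and CV maps ---------------------------------
  pp <- config$preprocess
  smooth_bold <- if (pp$smooth_stage == "bold") pp$fwhm_mm else 0
  band <- frequency_band(config$alff$f_lo, config$alff$f_hi)
  mask <- cohort$brain_mask$values
  cv_maps <- vector("list", length(cohort$runs))
  names(cv_maps) <- names(cohort$runs)
  win <- NULL
  for (id in names(cohort$runs)) {
    pre <- preprocess_run(cohort$runs[[id]], cohort$regressors[[id]],
                          drop_k = pp$drop_k, fwhm_mm = smooth_bold)
    if (is.null(win))
      win <- sliding_windows(dim(pre$data)[4], config$alff$window_length_tr,
                             config$alff$window_step_tr)
    cv <- dalff_cv_map(pre, win, band, mask = mask,
                       normalize_by = config$alff$normalize_by)
    if (pp$smooth_stage == "cv") cv <- smooth_gaussian(cv, pp$fwhm_mm)
    cv_maps[[id]] <- cv
    write_volume(cv, file.path(out_dir, paste0(id, "_dalff_cv.nii.gz")))
  }
  log_lines <- c(log_lines, sprintf("retained %d TRs; %d windows",
                                    win$n_timepoints, win$n_windows))

  # --- stage 4: group inference --------------------------------------------
  covars <- intersect(config$inference$covariates, names(cohort$participants))
  design <- group_design(cohort$participants, covars)
  statmap <- fit_voxelwise_glm(cv_maps[design$subject_ids], design, mask)
  write_volume(statmap$tmap, file.path(out_dir, "group_tstat.nii.gz"))
  write_volume(statmap$zmap, file.path(out_dir, "group_zstat.nii.gz"))
  smoothness <- estimate_smoothness(statmap$residuals, mask,
                                    affine_voxel_sizes(statmap$affine))
  if (config$inference$method == "grf") {
    clusters <- grf_cluster_inference(statmap, smoothness,
                                      voxel_p = config$inference$voxel_p,
                                      cluster_p = config$inference$cluster_p,
                                      two_sided = config$inference$two_sided,
                                      connectivity = config$inference$connectivity)
  } else {
    clusters <- permutation_cluster_inference(
      cv_maps[design$subject_ids], design,
      voxel_p = config$inference$voxel_p,
      cluster_p = config$inference$cluster_p,
      n_perm = config$inference$n_perm, seed = config$seed,
      connectivity = config$inference$connectivity, mask = mask)
  }
  clusters <- report_cluster_table(clusters, cohort$roi_masks, statmap,
                                   connectivity = config$inference$connectivity,
                                   path = file.path(out_dir, "cluster_table.tsv"))
  log_lines <- c(log_lines,
                 sprintf("smoothness FWHM (mm): %s; %.1f resels",
                         paste(signif(smoothness$fwhm_mm, 4), collapse = ", "),
                         smoothness$resels),
                 sprintf("cluster threshold u = %.4f (%s); %d significant cluster(s)",
                         attr(clusters, "u"), attr(clusters, "method"),
                         nrow(clusters)))

  # --- stage 5: clinical associations --------------------------------------
  roi_means <- lapply(cohort$roi_masks, function(m)
    extract_roi_means(cv_maps, m))
  pat_ids <- cohort$participants$id[cohort$participants$group == "patient"]
  correlations <- roc <- NULL
  if (!is.null(cohort$clinical) && nrow(cohort$clinical) >= 4) {
    clin <- cohort$clinical[match(pat_ids, cohort$clinical$id), , drop = FALSE]
    scales <- intersect(config$clinical$scales, names(clin))
    correlations <- clinical_correlation_table(
      lapply(roi_means, function(v) v[pat_ids]), clin, scales)
    write_tsv_table(correlations, file.path(out_dir, "clinical_correlations.tsv"),
                    comments = "Spearman rho; two-sided t-approximation p; patients only")
    roc <- lapply(roi_means, function(v)
      roc_auc(v, cohort$participants$group == "patient"))
    for (rg in names(roc))
      write_tsv_table(roc[[rg]]$curve,
                      file.path(out_dir, paste0("roc_", rg, ".tsv")),
                      comments = sprintf("ROC for %s; AUC = %.4f", rg,
                                         roc[[rg]]$auc))
    log_lines <- c(log_lines, sprintf("AUC (%s): %s", names(roc),
                                      sapply(roc, function(r) sprintf("%.3f", r$auc))))
  }
  demographics <- demographics_report(cohort$participants, cohort$clinical)
  write_tsv_table(demographics, file.path(out_dir, "demographics.tsv"),
                  comments = "mean ± SD with pooled t; sex by Pearson chi-square; scales as median (Q1, Q3)")

  # --- manifest ------------------------------------------------------------
  writeLines(log_lines, file.path(out_dir, "run.log"))
  write_manifest(config, out_dir)

  list(cohort = cohort, cv_maps = cv_maps, window = win, statmap = statmap,
       smoothness = smoothness, clusters = clusters, roi_means = roi_means,
       correlations = correlations, roc = roc, demographics = demographics,
       out_dir = out_dir)
}

# Manifest: config snapshot, version, seed, product checksums, timestamp.
write_manifest <- function(config, out_dir) {
  files <- setdiff(list.files(out_dir), c("manifest.txt"))
  sums <- tools::md5sum(file.path(out_dir, files))
  lines <- c("# dalff run manifest",
             paste("version:", as.character(utils::packageVersion("dalff"))),
             paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             paste("seed:", config$seed),
             "",
             "## config",
             strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]],
             "",
             "## checksums (md5)",
             sprintf("%s  %s", unname(sums), files))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(NULL)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `sub-*_bold.nii.gz`, masks and tables.
#' @param tr_s Fallback TR passed to [read_volume()].
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(dir, tr_s = NULL) {
  if (is.null(dir) || !dir.exists(dir)) stop("no such cohort directory: ", dir)
  participants <- read_tsv_table(file.path(dir, "participants.tsv"))
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path)) read_tsv_table(clin_path) else NULL
  bm <- read_volume(file.path(dir, "brain_mask.nii.gz"), "map")
  bm <- scalar_map(bm$values, bm$values, bm$affine)
  roi_files <- list.files(dir, "^roi_.*\\.nii(\\.gz)?$")
  roi_masks <- lapply(roi_files, function(f)
    (read_volume(file.path(dir, f), "map")$values != 0) * 1)
  names(roi_masks) <- sub("^roi_", "", sub("\\.nii(\\.gz)?$", "", roi_files))
  runs <- regs <- list()
  for (id in participants$id) {
    runs[[id]] <- read_volume(file.path(dir, paste0(id, "_bold.nii.gz")),
                              "run", tr_s = tr_s, mask = bm$values)
    reg_path <- file.path(dir, paste0(id, "_regressors.tsv"))
    regs[[id]] <- if (file.exists(reg_path))
      as.matrix(read_tsv_table(reg_path)) else NULL
  }
  structure(list(runs = runs, regressors = regs, brain_mask = bm,
                 roi_masks = roi_masks, participants = participants,
                 clinical = clinical, roi_depths = NULL, config = NULL),
            class = "cohort_bundle")
}
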