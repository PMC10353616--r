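#' Default pipeline configuration
#'
#' One flat, human-readable configuration for the full analysis:
#' simulation (or input paths), preprocessing, windowed-ALFF, inference
#' and clinical blocks plus a single master seed from which every stage
#' and subject seed is derived.
#'
#' @return A named list of blocks with documented defaults.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(input_dir = NULL, out_dir = "dalff_out"),
    simulate = list(enabled = TRUE, n_patients = 15, n_controls = 15,
                    grid_shape = c(20, 24, 18), voxel_size_mm = c(3, 3, 3),
                    n_timepoints = 186, tr_s = 2,
                    modulation_depth_patient = 0.6,
                    modulation_depth_control = 0.2),
    preprocess = list(drop_k = 10, fwhm_mm = 6, smooth_stage = "bold"),
    alff = list(window_length_tr = 50, window_step_tr = 1,
                f_lo = 0.01, f_hi = 0.08, normalize_by = "window"),
    inference = list(method = "grf", voxel_p = 0.05, cluster_p = 0.05,
                     n_perm = 1000, connectivity = 26, two_sided = TRUE,
                     covariates = c("age", "sex", "education")),
    clinical = list(scales = c("NIHSS", "WE_FMA", "UE_FMA", "LE_FMA", "BI")),
    seed = 1)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills documented defaults, rejects unknown keys
#' (typo safety) and validates numeric ranges; all schema violations are
#' reported at once.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop("`path` must be a file path or a list")
  if (is.null(user)) user <- list()
  defaults <- default_pipeline_config()
  errors <- character(0)
  for (blk in names(user)) {
    if (!blk %in% names(defaults)) {
      errors <- c(errors, paste0("unknown block: ", blk))
      next
    }
    if (blk == "seed") next
    for (key in names(user[[blk]]))
      if (!key %in% names(defaults[[blk]]))
        errors <- c(errors, paste0("unknown key: ", blk, ".", key))
  }
  cfg <- utils::modifyList(defaults, user)
  # modifyList drops NULL-valued keys; keep the documented slot present
  if (!"input_dir" %in% names(cfg$paths)) {
    cfg$paths["input_dir"] <- list(NULL)
    cfg$paths <- cfg$paths[names(defaults$paths)]
  }
  with(cfg, {
    if (alff$f_lo >= alff$f_hi)
      errors <<- c(errors, "alff.f_lo must be < alff.f_hi")
    if (alff$f_lo <= 0)
      errors <<- c(errors, "alff.f_lo must be positive")
    if (alff$window_length_tr < 1 || alff$window_step_tr < 1)
      errors <<- c(errors, "alff window length and step must be >= 1")
    if (preprocess$drop_k < 0)
      errors <<- c(errors, "preprocess.drop_k must be >= 0")
    if (any(preprocess$fwhm_mm < 0))
      errors <<- c(errors, "preprocess.fwhm_mm must be >= 0")
    if (!preprocess$smooth_stage %in% c("bold", "cv"))
      errors <<- c(errors, "preprocess.smooth_stage must be 'bold' or 'cv'")
    if (inference$voxel_p <= 0 || inference$voxel_p >= 1 ||
        inference$cluster_p <= 0 || inference$cluster_p >= 1)
      errors <<- c(errors, "inference voxel_p and cluster_p must be in (0, 1)")
    if (!inference$method %in% c("grf", "perm"))
      errors <<- c(errors, "inference.method must be 'grf' or 'perm'")
    if (!inference$connectivity %in% c(6, 18, 26))
      errors <<- c(errors, "inference.connectivity must be 6, 18 or 26")
    if (!is.null(paths$input_dir) && !dir.exists(paths$input_dir))
      errors <<- c(errors, paste0("paths.input_dir does not exist: ",
                                  paths$input_dir))
  })
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Save a pipeline configuration to YAML
#'
#' @param config A configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
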