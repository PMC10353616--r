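# Small cohorts reused across test files. Grids are kept desk-scale so the
# whole suite stays fast; the generator itself is exercised at its default
# scale in the planted-effect recovery test.

small_cohort_config <- function(seed = 1L, depth_p = 0.6, depth_c = 0.2,
                                n_pat = 6L, n_ctl = 6L,
                                grid = c(12L, 12L, 10L), n_t = 60L) {
  cohort_config(n_patients = n_pat, n_controls = n_ctl, grid_shape = grid,
                n_timepoints = n_t,
                modulation_depth_patient = depth_p,
                modulation_depth_control = depth_c,
                modulation_period_s = 60,
                effect_rois = list(roi_sphere(round(grid * c(0.65, 0.4, 0.4)),
                                              radius_mm = 7,
                                              label = "rectus_R")),
                seed = seed)
}

# Preprocess every run of a bundle and return dALFF-CV maps.
cohort_cv_maps <- function(bundle, drop_k = 10L, fwhm_mm = 6,
                           length_tr = 20L, step_tr = 2L,
                           band = frequency_band()) {
  mask <- bundle$brain_mask$values
  n_t <- bundle$config$n_timepoints - drop_k
  win <- sliding_windows(n_t, length_tr, step_tr)
  lapply(names(bundle$runs), function(id) {
    pre <- preprocess_run(bundle$runs[[id]], bundle$regressors[[id]],
                          drop_k = drop_k, fwhm_mm = fwhm_mm)
    dalff_cv_map(pre, win, band, mask = mask)
  })
}

# A deterministic small run: independent noise series at every voxel.
noise_run <- function(seed = 1L, grid = c(6L, 6L, 6L), n_t = 60L, tr_s = 2) {
  set.seed(seed)
  bold_run(array(rnorm(prod(grid) * n_t), dim = c(grid, n_t)), tr_s = tr_s,
           mask = array(1, dim = grid))
}
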