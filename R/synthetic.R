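#' Configuration for a synthetic two-group cohort
#'
#' Describes a seeded cohort of patient and control BOLD runs whose voxel
#' time series are band-limited oscillations carrying a slow multiplicative
#' amplitude envelope, plus AR(1) noise, a linear drift and nuisance
#' components (motion-like regressors, white-matter and CSF signals).
#' The group contrast is planted as a higher envelope depth inside the
#' effect ROIs for the patient group, which raises the temporal coefficient
#' of variation of windowed ALFF exactly where the analysis should find it.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param grid_shape 3 voxel counts (default 20 x 24 x 18).
#' @param voxel_size_mm Voxel edges in mm (default 3 mm isotropic).
#' @param n_timepoints Number of acquired volumes before any dropping
#'   (default 186).
#' @param tr_s Repetition time in seconds (default 2).
#' @param carrier_band_hz Frequency interval (Hz) from which each subject's
#'   carrier frequency is drawn uniformly; must lie inside (0, Nyquist).
#' @param carrier_freq_step_hz Quantisation step for the carrier frequency
#'   (Hz). The default 0.01 Hz restricts carriers to frequencies
#'   commensurate with a 100 s analysis window, so a constant-amplitude
#'   oscillation has a window-invariant amplitude estimate and the planted
#'   slow modulation is the only systematic source of windowed-amplitude
#'   variability. Set to 0 for a continuous uniform draw.
#' @param carrier_amplitude Carrier amplitude A in BOLD units.
#' @param carrier_phase_fwhm_mm Correlation length (FWHM, mm) of the
#'   spatially smooth per-voxel carrier phase field. Spontaneous
#'   low-frequency fluctuations are regionally coherent, so neighbouring
#'   voxels oscillate nearly in phase; this also means spatial smoothing
#'   preserves the oscillation while attenuating independent voxel noise.
#' @param carrier_phase_sd Standard deviation (radians) of the phase field.
#' @param modulation_depth_patient,modulation_depth_control Envelope depths
#'   d in \[0, 1\]: the instantaneous amplitude is `(1 + d * m(t)) * A` with
#'   `m(t) = sin(2 pi t / P + psi)`. Patients receive the patient depth
#'   inside effect ROIs and the control depth elsewhere; controls receive
#'   the control depth everywhere. The control depth defaults to 0: a
#'   globally coherent nonzero background envelope survives global-mean
#'   normalisation as a rank-one between-subject mode shared by both
#'   groups, so it adds no group contrast but degrades cluster inference;
#'   set it above 0 to study exactly that regime.
#' @param modulation_period_s Envelope period P in seconds. The default
#'   252 s equals the span of window centres at the default run length
#'   (176 retained volumes, 50-volume windows, TR 2 s), so the sliding
#'   windows sample exactly one envelope cycle and the across-window
#'   amplitude variance does not depend on the random envelope phase.
#' @param depth_jitter Relative per-subject jitter of the ROI envelope
#'   depth (uniform in `depth * (1 +/- depth_jitter)`); gives patients a
#'   heterogeneous severity axis that clinical scores can couple to.
#' @param noise_sd Marginal SD of the AR(1) noise (BOLD units).
#' @param ar1_coef AR(1) coefficient in (-1, 1).
#' @param drift_per_tr Linear drift slope per volume (BOLD units).
#' @param effect_rois List of [roi_sphere()] regions carrying the planted
#'   effect; defaults to one 9 mm sphere labelled `"rectus_R"`.
#' @param nuisance_amplitudes Named numeric vector of loadings for the
#'   generated nuisance regressors: `motion` (applied to each of the 24
#'   Friston-style columns), `wm` and `csf`.
#' @param clinical_coupling Data frame with one row per clinical scale
#'   (columns `scale`, `sign`, `strength`, `noise_sd`, `center`, `lo`,
#'   `hi`); see [default_clinical_coupling()].
#' @param prop_male Length-2 proportions of male subjects
#'   (patients, controls).
#' @param seed Integer master seed; all subject-level seeds derive from it.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 34, n_controls = 44,
                          grid_shape = c(20, 24, 18),
                          voxel_size_mm = c(3, 3, 3),
                          n_timepoints = 186, tr_s = 2,
                          carrier_band_hz = c(0.01, 0.08),
                          carrier_freq_step_hz = 0.01,
                          carrier_amplitude = 1,
                          carrier_phase_fwhm_mm = 12,
                          carrier_phase_sd = 0.3,
                          modulation_depth_patient = 0.6,
                          modulation_depth_control = 0,
                          modulation_period_s = 252,
                          depth_jitter = 0.3,
                          noise_sd = 0.5, ar1_coef = 0.3,
                          drift_per_tr = 0.01,
                          effect_rois = NULL,
                          nuisance_amplitudes = c(motion = 0.05, wm = 0.2,
                                                  csf = 0.2),
                          clinical_coupling = default_clinical_coupling(),
                          prop_male = c(0.74, 0.43),
                          seed = 1L) {
  if (n_patients < 2 || n_controls < 2)
    stop("both groups need at least 2 subjects")
  if (any(grid_shape < 8))
    stop("`grid_shape` dimensions must all be >= 8")
  if (modulation_depth_patient < 0 || modulation_depth_patient > 1 ||
      modulation_depth_control < 0 || modulation_depth_control > 1)
    stop("modulation depths must lie in [0, 1]")
  nyq <- 1 / (2 * tr_s)
  if (carrier_band_hz[1] <= 0 || carrier_band_hz[2] >= nyq ||
      carrier_band_hz[1] > carrier_band_hz[2])
    stop(sprintf("`carrier_band_hz` must lie within (0, %g) Hz (Nyquist)", nyq))
  if (abs(ar1_coef) >= 1) stop("`ar1_coef` must lie in (-1, 1)")
  if (is.null(effect_rois))
    effect_rois <- list(roi_sphere(round(grid_shape * c(0.7, 0.38, 0.33)),
                                   radius_mm = 9, label = "rectus_R"))
  if (inherits(effect_rois, "roi_sphere")) effect_rois <- list(effect_rois)
  cfg <- structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
    carrier_band_hz = carrier_band_hz,
    carrier_freq_step_hz = carrier_freq_step_hz,
    carrier_amplitude = carrier_amplitude,
    carrier_phase_fwhm_mm = carrier_phase_fwhm_mm,
    carrier_phase_sd = carrier_phase_sd,
    modulation_depth_patient = modulation_depth_patient,
    modulation_depth_control = modulation_depth_control,
    modulation_period_s = modulation_period_s, depth_jitter = depth_jitter,
    noise_sd = noise_sd, ar1_coef = ar1_coef, drift_per_tr = drift_per_tr,
    effect_rois = effect_rois, nuisance_amplitudes = nuisance_amplitudes,
    clinical_coupling = clinical_coupling, prop_male = prop_male,
    seed = as.integer(seed)), class = "cohort_config")
  # effect ROIs must intersect the brain mask (checked at rasterisation)
  bm <- generate_brain_mask(cfg$grid_shape, cfg$voxel_size_mm)
  for (roi in cfg$effect_rois)
    roi_mask(roi, cfg$grid_shape, cfg$voxel_size_mm, bm$values)
  cfg
}

#' Default clinical-scale coupling table
#'
#' One row per scale: severity scales (NIHSS) couple negatively to the
#' planted ROI temporal variability, function scales (BI and the Fugl-Meyer
#' subscores) positively. `strength` is the score change per SD of the
#' variability axis, `noise_sd` the additive Gaussian noise, and
#' `[lo, hi]` the admissible range scores are clipped to (NIHSS 0-42,
#' BI 0-100, Fugl-Meyer whole/upper/lower maxima 100/66/34).
#'
#' @return A data frame with columns `scale`, `sign`, `strength`,
#'   `noise_sd`, `center`, `lo`, `hi`.
#' @export
default_clinical_coupling <- function() {
  data.frame(
    scale = c("NIHSS", "WE_FMA", "UE_FMA", "LE_FMA", "BI"),
    sign = c(-1, 1, 1, 1, 1),
    strength = c(1.8, 10, 7, 3.5, 12),
    noise_sd = c(0.9, 5, 3.5, 1.8, 6),
    center = c(4, 76, 50, 27, 76),
    lo = c(0, 0, 0, 0, 0),
    hi = c(42, 100, 66, 34, 100),
    stringsAsFactors = FALSE)
}

# Deterministic 31-bit seed for subject `index` under master seed `seed`.
derive_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 10007 +
                as.numeric(stream) * 97003) %% 2147483647)
}

# 6 smooth random-walk motion series expanded to 24 Friston-style columns
# (values, one-volume lag, squares, squared lag), plus WM and CSF series.
generate_nuisance_regressors <- function(n_t, seed) {
  set.seed(seed)
  mot <- apply(matrix(stats::rnorm(n_t * 6, sd = 0.02), n_t, 6), 2, cumsum)
  lag1 <- rbind(0, mot[-n_t, , drop = FALSE])
  reg <- cbind(mot, lag1, mot^2, lag1^2)
  colnames(reg) <- c(paste0("mot", 1:6), paste0("mot_lag", 1:6),
                     paste0("mot_sq", 1:6), paste0("mot_lagsq", 1:6))
  wm <- as.numeric(stats::filter(stats::rnorm(n_t), 0.8, method = "recursive"))
  csf <- as.numeric(stats::filter(stats::rnorm(n_t), 0.8, method = "recursive"))
  cbind(reg, wm = wm / stats::sd(wm), csf = csf / stats::sd(csf))
}

#' Generate one subject's synthetic BOLD run
#'
#' Voxel series follow
#' `y(t) = (1 + d_v m(t)) A sin(2 pi f t + phi_v) + drift t + sum_j w_j g_j(t) + e(t)`
#' where `f` is drawn uniformly from the carrier band (one per subject),
#' `phi_v` is a per-voxel phase, `m(t)` a unit sinusoidal envelope with the
#' configured period and a per-subject phase, `d_v` the envelope depth
#' (the group's depth, with per-subject jitter, inside effect ROIs; the
#' control depth elsewhere), `g_j` the generated nuisance regressors and
#' `e` AR(1) noise.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index (used to derive the seed).
#' @param group_label `"patient"` or `"control"`.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A list with elements `run` ([bold_run()]), `regressors`
#'   (time x regressor matrix), and `roi_depth` (the subject's realised
#'   envelope depth inside the effect ROIs).
#' @export
generate_subject_bold <- function(config, subject_index,
                                  group_label = c("patient", "control"),
                                  seed = config$seed) {
  group_label <- match.arg(group_label)
  nyq <- 1 / (2 * config$tr_s)
  if (config$carrier_band_hz[2] >= nyq)
    stop("carrier frequency band reaches the Nyquist frequency")
  gs <- config$grid_shape
  n_t <- config$n_timepoints
  n_vox <- prod(gs)
  set.seed(derive_seed(seed, subject_index))

  group_depth <- if (group_label == "patient")
    config$modulation_depth_patient else config$modulation_depth_control
  roi_depth <- group_depth *
    (1 + config$depth_jitter * stats::runif(1, -1, 1))
  roi_depth <- min(max(roi_depth, 0), 1)

  bm <- generate_brain_mask(gs, config$voxel_size_mm)
  d_map <- array(config$modulation_depth_control, dim = gs)
  for (roi in config$effect_rois) {
    m <- roi_mask(roi, gs, config$voxel_size_mm, bm$values)
    d_map[m > 0] <- roi_depth
  }

  tt <- (seq_len(n_t) - 1) * config$tr_s
  f <- draw_carrier_freq(config)
  psi <- stats::runif(1, 0, 2 * pi)
  m_t <- sin(2 * pi * tt / config$modulation_period_s + psi)
  phi_v <- smooth_phase_field(gs, config$voxel_size_mm,
                              config$carrier_phase_fwhm_mm,
                              config$carrier_phase_sd)

  # T x V carrier with per-voxel phase, modulated by the envelope
  carrier <- sin(outer(2 * pi * f * tt, phi_v, `+`)) * config$carrier_amplitude
  envelope <- 1 + outer(m_t, as.vector(d_map))
  sig <- carrier * envelope

  reg <- generate_nuisance_regressors(n_t, derive_seed(seed, subject_index, 1L))
  w <- c(rep(config$nuisance_amplitudes[["motion"]], 24),
         config$nuisance_amplitudes[["wm"]], config$nuisance_amplitudes[["csf"]])
  nuis <- as.vector(reg %*% w)

  eps <- matrix(stats::rnorm(n_t * n_vox,
                             sd = config$noise_sd * sqrt(1 - config$ar1_coef^2)),
                n_t, n_vox)
  if (config$ar1_coef != 0)
    for (t in 2:n_t)
      eps[t, ] <- config$ar1_coef * eps[t - 1, ] + eps[t, ]

  y <- sig + config$drift_per_tr * (seq_len(n_t) - 1) + nuis + eps
  data4d <- array(t(y), dim = c(gs, n_t))
  run <- bold_run(data4d, tr_s = config$tr_s,
                  voxel_size_mm = config$voxel_size_mm, mask = bm$values)
  list(run = run, regressors = reg, roi_depth = roi_depth)
}

#' Generate clinical scores coupled to ROI temporal variability
#'
#' Each scale is a monotone affine function of the subject's ROI
#' variability (standardised across patients) plus Gaussian noise, then
#' clipped to the scale's admissible range. Severity-type scales use a
#' negative sign, function-type scales a positive one.
#'
#' @param patient_ids Character vector of patient identifiers.
#' @param roi_cv Numeric vector, one ROI variability value per patient
#'   (a measured dALFF-CV mean, or the planted per-subject depth).
#' @param coupling Coupling table as in [default_clinical_coupling()].
#' @param seed Integer seed.
#' @return Data frame with `id` plus one column per scale.
#' @export
generate_clinical_scores <- function(patient_ids, roi_cv,
                                     coupling = default_clinical_coupling(),
                                     seed = 1L) {
  n <- length(patient_ids)
  if (n == 0) stop("empty patient set")
  if (length(roi_cv) != n)
    stop("`roi_cv` must have one value per patient")
  s <- stats::sd(roi_cv)
  z <- if (is.na(s) || s == 0) rep(0, n) else (roi_cv - mean(roi_cv)) / s
  set.seed(derive_seed(seed, 0L, 2L))
  out <- data.frame(id = patient_ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(coupling))) {
    cp <- coupling[i, ]
    score <- cp$center + cp$sign * cp$strength * z +
      stats::rnorm(n, sd = cp$noise_sd)
    out[[cp$scale]] <- pmin(pmax(score, cp$lo), cp$hi)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Produces all patient and control runs, the shared brain mask, labelled
#' effect-ROI masks, a participants table (age truncated-normal 56 +/- 11
#' in \[30, 75\], education truncated-normal 12 +/- 3 in \[6, 20\], sex by
#' the configured proportions) and patient clinical scores coupled to the
#' subjects' planted ROI envelope depths.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, NIfTI volumes, masks and
#'   TSV tables are written there.
#' @return An object of class `cohort_bundle`: list with `runs`,
#'   `regressors`, `brain_mask`, `roi_masks`, `participants`, `clinical`,
#'   `roi_depths`, `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  n <- config$n_patients + config$n_controls
  group <- rep(c("patient", "control"),
               c(config$n_patients, config$n_controls))
  ids <- sprintf("sub-%03d", seq_len(n))

  runs <- vector("list", n)
  regs <- vector("list", n)
  roi_depths <- numeric(n)
  for (i in seq_len(n)) {
    s <- generate_subject_bold(config, i, group[i], seed = config$seed)
    runs[[i]] <- s$run
    regs[[i]] <- s$regressors
    roi_depths[i] <- s$roi_depth
  }
  names(runs) <- names(regs) <- ids

  bm <- generate_brain_mask(config$grid_shape, config$voxel_size_mm)
  roi_masks <- lapply(config$effect_rois, roi_mask,
                      grid_shape = config$grid_shape,
                      voxel_size_mm = config$voxel_size_mm,
                      brain_mask = bm$values)
  names(roi_masks) <- vapply(config$effect_rois, `[[`, "", "label")

  set.seed(derive_seed(config$seed, 0L, 3L))
  age <- rtrunc_norm(n, 56, 11, 30, 75)
  education <- rtrunc_norm(n, 12, 3, 6, 20)
  pm <- ifelse(group == "patient", config$prop_male[1], config$prop_male[2])
  sex <- ifelse(stats::runif(n) < pm, "M", "F")
  participants <- data.frame(id = ids, group = group, age = age, sex = sex,
                             education = education, stringsAsFactors = FALSE)

  pat <- group == "patient"
  clinical <- generate_clinical_scores(ids[pat], roi_depths[pat],
                                       config$clinical_coupling,
                                       seed = config$seed)

  bundle <- structure(list(runs = runs, regressors = regs, brain_mask = bm,
                           roi_masks = roi_masks, participants = participants,
                           clinical = clinical, roi_depths = roi_depths,
                           config = config),
                      class = "cohort_bundle")
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d patients + %d controls, grid %s, T = %d\n",
              x$config$n_patients, x$config$n_controls,
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_timepoints))
  invisible(x)
}

# Truncated normal draws by inverse-CDF (deterministic given the RNG state).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Write a cohort bundle to disk
#'
#' Writes one gzipped NIfTI per run (`<id>_bold.nii.gz`), the brain and
#' ROI masks, per-subject nuisance regressors
#' (`<id>_regressors.tsv`), `participants.tsv` and `clinical.tsv`.
#'
#' @param bundle A `cohort_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  for (id in names(bundle$runs)) {
    write_volume(bundle$runs[[id]], file.path(out_dir, paste0(id, "_bold.nii.gz")))
    utils::write.table(bundle$regressors[[id]],
                       file.path(out_dir, paste0(id, "_regressors.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_volume(bundle$brain_mask, file.path(out_dir, "brain_mask.nii.gz"))
  for (lab in names(bundle$roi_masks))
    write_volume(scalar_map(bundle$roi_masks[[lab]], bundle$roi_masks[[lab]],
                            bundle$brain_mask$affine),
                 file.path(out_dir, paste0("roi_", lab, ".nii.gz")))
  utils::write.table(bundle$participants, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$clinical, file.path(out_dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

# One carrier frequency from the configured band, quantised to the
# configured step when requested.
draw_carrier_freq <- function(config) {
  band <- config$carrier_band_hz
  step <- config$carrier_freq_step_hz
  if (is.null(step) || step <= 0)
    return(stats::runif(1, band[1], band[2]))
  k <- seq(ceiling(band[1] / step - 1e-9), floor(band[2] / step + 1e-9))
  if (length(k) == 0)
    stop("no quantised carrier frequency inside the band")
  k[sample.int(length(k), 1)] * step
}

# Spatially smooth zero-mean phase field (radians): white noise smoothed to
# the requested correlation length, restandardised to the requested SD.
smooth_phase_field <- function(grid_shape, voxel_size_mm, fwhm_mm, sd_rad) {
  raw <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (fwhm_mm > 0) {
    for (ax in 1:3) {
      k <- gaussian_kernel_1d(fwhm_mm / voxel_size_mm[ax])
      raw <- convolve_axis(raw, k, ax)
    }
  }
  as.vector((raw - mean(raw)) / stats::sd(raw)) * sd_rad
}
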