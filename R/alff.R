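#' Sliding-window scheme
#'
#' Enumerates windows of `length_tr` volumes advanced by `step_tr`,
#' covering `n_timepoints`; the count obeys
#' `floor((T - L) / s) + 1`.
#'
#' @param n_timepoints Series length T (volumes).
#' @param length_tr Window length L in volumes.
#' @param step_tr Step s in volumes (default 1).
#' @return An object of class `window_spec`: list with `length_tr`,
#'   `step_tr`, `n_timepoints`, `n_windows`, and `windows`, an
#'   `n_windows` x 2 matrix of 1-based inclusive `[start, end]` indices.
#' @export
sliding_windows <- function(n_timepoints, length_tr, step_tr = 1L) {
  n_timepoints <- as.integer(n_timepoints)
  length_tr <- as.integer(length_tr)
  step_tr <- as.integer(step_tr)
  if (length_tr < 1L || length_tr > n_timepoints)
    stop(sprintf("window length %d invalid for series of %d time points",
                 length_tr, n_timepoints))
  if (step_tr < 1L) stop("`step_tr` must be >= 1")
  n_win <- (n_timepoints - length_tr) %/% step_tr + 1L
  starts <- (seq_len(n_win) - 1L) * step_tr + 1L
  structure(list(length_tr = length_tr, step_tr = step_tr,
                 n_timepoints = n_timepoints, n_windows = n_win,
                 windows = cbind(start = starts,
                                 end = starts + length_tr - 1L)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d TRs, step %d, over %d TRs\n",
              x$n_windows, x$length_tr, x$step_tr, x$n_timepoints))
  invisible(x)
}

#' Frequency band
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(f_lo = 0.01, f_hi = 0.08) {
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi)
    stop("need 0 < f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "frequency_band")
}

# DFT bin indices k (1..floor(N/2)) whose frequency k/(N tr) falls in the
# band, inclusive, with a small relative tolerance for edge bins.
band_bins <- function(n, tr_s, band) {
  k <- seq_len(n %/% 2)
  f <- k / (n * tr_s)
  tol <- 1e-9
  bins <- k[f >= band$f_lo * (1 - tol) & f <= band$f_hi * (1 + tol)]
  if (length(bins) == 0)
    stop(sprintf(
      "no DFT bin in band [%g, %g] Hz at resolution %g Hz (N = %d, TR = %g s)",
      band$f_lo, band$f_hi, 1 / (n * tr_s), n, tr_s))
  bins
}

#' Amplitude of low-frequency fluctuation of one series
#'
#' One-sided discrete-Fourier amplitude spectrum `a_k = 2 |X_k| / N` at
#' frequencies `k / (N tr)` for `k = 1 .. floor(N/2)`; ALFF is the mean of
#' `a_k` over bins inside the band (inclusive). A unit-amplitude sinusoid
#' sitting exactly on a bin contributes amplitude 1 at that bin.
#'
#' @param series Numeric time series.
#' @param tr_s Sampling interval (s).
#' @param band A [frequency_band()].
#' @return ALFF in the series' amplitude units.
#' @export
compute_alff <- function(series, tr_s, band = frequency_band()) {
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  bins <- band_bins(n, tr_s, band)
  amp <- 2 * Mod(stats::fft(series)[bins + 1L]) / n
  mean(amp)
}

# ALFF for every column of a T x V matrix (single FFT call).
alff_matrix <- function(y, tr_s, band) {
  n <- nrow(y)
  bins <- band_bins(n, tr_s, band)
  amp <- 2 * Mod(stats::mvfft(y)[bins + 1L, , drop = FALSE]) / n
  colMeans(amp)
}

#' Voxelwise ALFF map
#'
#' @param run A preprocessed [bold_run()].
#' @param band A [frequency_band()].
#' @param mask Binary 3D array; defaults to the run's mask. Out-of-mask
#'   voxels are set to 0.
#' @return A [scalar_map()] of kind `"alff"`.
#' @export
alff_map <- function(run, band = frequency_band(), mask = run$mask) {
  if (is.null(mask)) stop("an analysis mask is required")
  idx <- which(mask != 0)
  y <- run_as_matrix(run)[, idx, drop = FALSE]
  vals <- array(0, dim = dim(run$data)[1:3])
  vals[idx] <- alff_matrix(y, run$tr_s, band)
  scalar_map(vals, mask, run$affine, kind = "alff")
}

#' Divide a map by its in-mask global mean
#'
#' @param map A [scalar_map()].
#' @param mask Binary 3D array; defaults to the map's mask.
#' @return A [scalar_map()] of kind `"malff"` whose in-mask mean is 1.
#' @export
normalize_global_mean <- function(map, mask = map$mask) {
  idx <- which(mask != 0)
  g <- mean(map$values[idx])
  if (!is.finite(g) || g <= 0)
    stop(sprintf("global mean over mask is %g; must be positive", g))
  vals <- array(0, dim = dim(map$values))
  vals[idx] <- map$values[idx] / g
  scalar_map(vals, mask, map$affine, kind = "malff")
}

#' Dynamic ALFF coefficient-of-variation map
#'
#' Computes windowed ALFF over a sliding-window scheme, normalises each
#' window's map by its own in-mask global mean (or by the static
#' whole-run mean), and summarises each voxel's across-window variability
#' as the coefficient of variation CV = SD / mean (SD with the n-1
#' denominator). Voxels with nonpositive window-mean ALFF are set to 0.
#'
#' @param run A preprocessed [bold_run()].
#' @param window A [sliding_windows()] spec matching the run's length.
#' @param band A [frequency_band()].
#' @param mask Binary 3D array; defaults to the run's mask.
#' @param normalize_by `"window"` (each window's own global mean, default)
#'   or `"run"` (static whole-run mean ALFF) or `"none"`.
#' @return A [scalar_map()] of kind `"dalff_cv"`, with attribute
#'   `n_nonpositive` counting zeroed voxels.
#' @export
dalff_cv_map <- function(run, window, band = frequency_band(),
                         mask = run$mask,
                         normalize_by = c("window", "run", "none")) {
  normalize_by <- match.arg(normalize_by)
  if (is.null(mask)) stop("an analysis mask is required")
  n_t <- dim(run$data)[4]
  if (window$n_timepoints != n_t)
    stop(sprintf("window spec is for %d time points but run has %d",
                 window$n_timepoints, n_t))
  if (window$n_windows < 2)
    stop("CV needs at least 2 windows")
  idx <- which(mask != 0)
  y <- run_as_matrix(run)[, idx, drop = FALSE]
  wa <- matrix(0, window$n_windows, length(idx))
  for (w in seq_len(window$n_windows)) {
    rows <- window$windows[w, 1]:window$windows[w, 2]
    wa[w, ] <- alff_matrix(y[rows, , drop = FALSE], run$tr_s, band)
    if (normalize_by == "window") {
      g <- mean(wa[w, ])
      if (!is.finite(g) || g <= 0)
        stop(sprintf("window %d has nonpositive global mean ALFF", w))
      wa[w, ] <- wa[w, ] / g
    }
  }
  if (normalize_by == "run") {
    g <- mean(alff_matrix(y, run$tr_s, band))
    if (!is.finite(g) || g <= 0) stop("whole-run global mean ALFF nonpositive")
    wa <- wa / g
  }
  mu <- colMeans(wa)
  nw <- window$n_windows
  # two-pass SD: centring first avoids cancellation for near-constant columns
  sdv <- sqrt(colSums((wa - rep(mu, each = nw))^2) / (nw - 1))
  cv <- ifelse(mu > 0, sdv / mu, 0)
  vals <- array(0, dim = dim(run$data)[1:3])
  vals[idx] <- cv
  out <- scalar_map(vals, mask, run$affine, kind = "dalff_cv")
  attr(out, "n_nonpositive") <- sum(mu <= 0)
  out
}
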