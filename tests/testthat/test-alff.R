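test_that("sliding windows enumerate half-open ranges with the count identity", {
  w <- sliding_windows(176, 50, 1)
  expect_equal(w$n_windows, 127)
  expect_equal(w$windows[1, ], c(start = 1, end = 50))
  expect_equal(w$windows[127, ], c(start = 127, end = 176))
  w1 <- sliding_windows(50, 50, 1)
  expect_equal(w1$n_windows, 1)
  expect_equal(unname(w1$windows[1, ]), c(1, 50))
  w2 <- sliding_windows(10, 4, 2)
  expect_equal(w2$n_windows, 4)
  expect_equal(unname(w2$windows),
               cbind(c(1, 3, 5, 7), c(4, 6, 8, 10)))
  expect_error(sliding_windows(40, 50, 1), "invalid")
  expect_error(sliding_windows(40, 10, 0), ">= 1")
})

test_that("the window-count identity holds over a parameter grid", {
  for (T in c(20, 67, 176)) for (L in c(5, 20)) for (s in c(1, 3, 7)) {
    w <- sliding_windows(T, L, s)
    expect_equal(w$n_windows, floor((T - L) / s) + 1)
    expect_true(all(w$windows[, 2] <= T))
    expect_true(all(w$windows[, 2] - w$windows[, 1] + 1 == L))
  }
})

test_that("ALFF of an exact-bin unit sinusoid averages to 1/nbins", {
  tt <- seq(0, by = 2, length.out = 50)
  s4 <- sin(2 * pi * 0.04 * tt)          # bin k = 4 of 8 in 0.01-0.08 Hz
  expect_equal(compute_alff(s4, 2, frequency_band(0.01, 0.08)), 1 / 8,
               tolerance = 1e-10)
  expect_equal(compute_alff(rep(0, 50), 2, frequency_band(0.01, 0.08)), 0)
  # out-of-band exact-bin component contributes nothing
  s_out <- 3 * sin(2 * pi * 0.15 * tt)   # bin k = 15, outside the band
  expect_equal(compute_alff(s4 + s_out, 2, frequency_band(0.01, 0.08)),
               compute_alff(s4, 2, frequency_band(0.01, 0.08)),
               tolerance = 1e-10)
  expect_error(compute_alff(rnorm(20), 2, frequency_band(0.001, 0.002)),
               "no DFT bin")
})

test_that("compute_alff matches a direct DFT oracle on random series", {
  set.seed(8)
  band <- frequency_band(0.01, 0.08)
  for (rep in 1:5) {
    y <- rnorm(60)
    n <- length(y); tr <- 2
    k <- 1:(n %/% 2)
    f <- k / (n * tr)
    keep <- f >= 0.01 - 1e-12 & f <= 0.08 + 1e-12
    # explicit trigonometric sums, independent of fft()
    amp <- sapply(k[keep], function(kk) {
      re <- sum(y * cos(-2 * pi * kk * (0:(n - 1)) / n))
      im <- sum(y * sin(-2 * pi * kk * (0:(n - 1)) / n))
      2 * sqrt(re^2 + im^2) / n
    })
    expect_equal(compute_alff(y, tr, band), mean(amp), tolerance = 1e-10)
  }
})

test_that("alff_map is local and equals the per-voxel loop", {
  run <- noise_run(3, grid = c(5L, 4L, 3L), n_t = 40L)
  m <- alff_map(run)
  for (v in list(c(1, 1, 1), c(3, 2, 2), c(5, 4, 3)))
    expect_equal(m$values[v[1], v[2], v[3]],
                 compute_alff(run$data[v[1], v[2], v[3], ], run$tr_s),
                 tolerance = 1e-12)
  zero <- bold_run(array(0, dim = c(4, 4, 3, 40)), 2,
                   mask = array(1, c(4, 4, 3)))
  expect_true(all(alff_map(zero)$values == 0))
  one <- zero
  one$data[2, 3, 1, ] <- sin(2 * pi * 0.05 * seq(0, 78, 2))
  mo <- alff_map(one)
  expect_gt(mo$values[2, 3, 1], 0)
  expect_equal(sum(mo$values != 0), 1)
})

test_that("global-mean normalisation scales the mask mean to one", {
  grid <- c(4, 4, 3)
  mask <- array(0, grid); mask[1:2, 1, 1] <- 1
  vals <- array(0, grid); vals[1, 1, 1] <- 2; vals[2, 1, 1] <- 4
  m <- scalar_map(vals, mask, diag(4))
  nm <- normalize_global_mean(m)
  expect_equal(nm$values[1:2, 1, 1], c(2 / 3, 4 / 3))
  expect_equal(mean(nm$values[mask != 0]), 1, tolerance = 1e-12)
  const <- scalar_map(array(5, grid), array(1, grid), diag(4))
  expect_true(all(normalize_global_mean(const)$values == 1))
  neg <- scalar_map(array(-1, grid), array(1, grid), diag(4))
  expect_error(normalize_global_mean(neg), "positive")
})

test_that("constant-amplitude exact-bin oscillations have zero dALFF-CV", {
  grid <- c(4L, 4L, 3L)
  n_t <- 60L
  tt <- seq(0, by = 2, length.out = n_t)
  set.seed(11)
  arr <- array(0, dim = c(grid, n_t))
  for (i in 1:4) for (j in 1:4) for (k in 1:3) {
    a <- runif(1, 0.5, 2)          # amplitude varies by voxel, not by time
    arr[i, j, k, ] <- a * sin(2 * pi * 0.05 * tt + runif(1, 0, 2 * pi))
  }
  run <- bold_run(arr, 2, mask = array(1, grid))
  # window length 50 keeps 0.05 Hz on an exact bin in every window
  cv <- dalff_cv_map(run, sliding_windows(n_t, 50L, 2L))
  expect_lte(max(cv$values), 1e-8)
  expect_error(dalff_cv_map(run, sliding_windows(n_t, 60L, 1L)),
               "at least 2 windows")
})

test_that("amplitude modulation raises CV at the modulated voxel", {
  n_t <- 150L
  tt <- seq(0, by = 2, length.out = n_t)
  carrier <- sin(2 * pi * 0.05 * tt)
  env <- 1 + 0.5 * sin(2 * pi * tt / 150)
  grid <- c(3L, 3L, 3L)
  base <- array(rep(carrier, each = prod(grid)), dim = c(grid, n_t))
  mod <- base
  mod[2, 2, 2, ] <- carrier * env
  win <- sliding_windows(n_t, 50L, 5L)
  cv_b <- dalff_cv_map(bold_run(base, 2, mask = array(1, grid)), win,
                       normalize_by = "none")
  cv_m <- dalff_cv_map(bold_run(mod, 2, mask = array(1, grid)), win,
                       normalize_by = "none")
  expect_gt(cv_m$values[2, 2, 2], cv_b$values[2, 2, 2] + 0.01)
})

test_that("dALFF-CV is nonnegative and invariant to global rescaling", {
  run <- noise_run(21, grid = c(5L, 5L, 4L), n_t = 60L)
  win <- sliding_windows(60, 30, 3)
  cv1 <- dalff_cv_map(run, win)
  expect_true(all(cv1$values >= 0))
  run2 <- bold_run(run$data * 3.7, run$tr_s, run$affine, mask = run$mask)
  cv2 <- dalff_cv_map(run2, win)
  expect_lt(max(abs(cv2$values - cv1$values)), 1e-10)
})

test_that("static-mean normalisation mode is exposed and differs from per-window", {
  run <- noise_run(22, grid = c(4L, 4L, 3L), n_t = 60L)
  win <- sliding_windows(60, 30, 3)
  a <- dalff_cv_map(run, win, normalize_by = "window")
  b <- dalff_cv_map(run, win, normalize_by = "run")
  expect_false(isTRUE(all.equal(a$values, b$values)))
})
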