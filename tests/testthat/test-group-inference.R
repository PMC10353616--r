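random_maps <- function(n, grid = c(6L, 6L, 5L), seed = 1L, mask = NULL) {
  set.seed(seed)
  if (is.null(mask)) mask <- array(1, grid)
  lapply(seq_len(n), function(i)
    scalar_map(array(rnorm(prod(grid)), grid), mask, diag(c(3, 3, 3, 1))))
}

test_that("covariate-free GLM t equals the pooled two-sample t", {
  n1 <- 7; n2 <- 9
  maps <- random_maps(n1 + n2, seed = 3)
  part <- data.frame(id = sprintf("s%02d", 1:(n1 + n2)),
                     group = rep(c("patient", "control"), c(n1, n2)))
  fit <- fit_voxelwise_glm(maps, group_design(part, character(0)))
  y <- sapply(maps, function(m) m$values[3, 3, 3])
  a <- y[1:n1]; b <- y[-(1:n1)]
  # closed-form pooled t, written out independently of the implementation
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(fit$tmap$values[3, 3, 3], t_ref, tolerance = 1e-10)
  expect_equal(fit$df, n1 + n2 - 2)
})

test_that("hand example: groups {1,2,3} vs {4,5,6} give t = -3.674, df = 4", {
  grid <- c(2L, 2L, 2L)
  maps <- lapply(c(1, 2, 3, 4, 5, 6), function(v)
    scalar_map(array(v, grid), array(1, grid), diag(4)))
  part <- data.frame(id = letters[1:6],
                     group = rep(c("patient", "control"), each = 3))
  fit <- fit_voxelwise_glm(maps, group_design(part, character(0)))
  expect_equal(fit$tmap$values[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(fit$tmap$values[1, 1, 1], 3), -3.674)
  expect_equal(fit$df, 4)
})

test_that("identical values across subjects give t = 0 everywhere", {
  grid <- c(3L, 3L, 2L)
  maps <- lapply(1:8, function(i)
    scalar_map(array(7, grid), array(1, grid), diag(4)))
  part <- data.frame(id = letters[1:8],
                     group = rep(c("patient", "control"), each = 4))
  fit <- fit_voxelwise_glm(maps, group_design(part, character(0)))
  expect_true(all(fit$tmap$values == 0))
})

test_that("flipping the group coding negates every t exactly", {
  maps <- random_maps(12, seed = 9)
  part <- data.frame(id = sprintf("s%02d", 1:12),
                     group = rep(c("patient", "control"), each = 6),
                     age = rnorm(12, 55, 10))
  f1 <- fit_voxelwise_glm(maps, group_design(part, "age"))
  part2 <- part
  part2$group <- rev(part$group)  # same assignment pattern, labels swapped
  f2 <- fit_voxelwise_glm(maps, group_design(part2, "age"))
  expect_equal(f2$tmap$values, -f1$tmap$values, tolerance = 1e-12)
})

test_that("t-to-z transform matches a numerical-integration oracle", {
  expect_equal(t_to_z(0, 5), 0)
  expect_lt(max(abs(t_to_z(c(-3, -1, 0.5, 3), 1e6) - c(-3, -1, 0.5, 3))),
            1e-3)
  # oracle: tail probability of t(10) by quadrature of the density
  for (tv in c(2.0, -1.3, 4.5)) {
    p_tail <- integrate(function(x) dt(x, 10), abs(tv), Inf,
                        rel.tol = 1e-12)$value
    z_ref <- sign(tv) * qnorm(p_tail, lower.tail = FALSE)
    expect_equal(t_to_z(tv, 10), z_ref, tolerance = 1e-6)
  }
  expect_warning(t_to_z(c(1, NaN), 10), "non-finite")
})

test_that("cluster labelling follows the declared connectivity", {
  g <- c(6L, 6L, 4L)
  empty <- array(0, g)
  expect_length(label_clusters(empty)$sizes, 0)
  one <- empty; one[3, 3, 2] <- 1
  expect_equal(label_clusters(one)$sizes, 1L)
  # two voxels sharing only an edge: separate at 6, joined at 18
  pair <- empty; pair[2, 2, 2] <- 1; pair[3, 3, 2] <- 1
  expect_equal(sort(label_clusters(pair, 6)$sizes), c(1L, 1L))
  expect_equal(label_clusters(pair, 18)$sizes, 2L)
  # corner contact joins only at 26
  corner <- empty; corner[2, 2, 2] <- 1; corner[3, 3, 3] <- 1
  expect_equal(sort(label_clusters(corner, 18)$sizes), c(1L, 1L))
  expect_equal(label_clusters(corner, 26)$sizes, 2L)
  # face contact joins at 6
  face <- empty; face[2, 2, 2] <- 1; face[2, 2, 3] <- 1
  expect_equal(label_clusters(face, 6)$sizes, 2L)
})

test_that("smoothness estimation recovers a known applied FWHM", {
  grid <- c(16L, 16L, 12L)
  mask <- array(1, grid)
  est_for <- function(fwhm, seed) {
    set.seed(seed)
    res <- t(sapply(1:12, function(s) {
      f <- array(rnorm(prod(grid)), grid)
      if (fwhm > 0)
        f <- smooth_gaussian(scalar_map(f, mask, diag(c(3, 3, 3, 1))),
                             fwhm)$values
      as.vector(f)[mask != 0]
    }))
    estimate_smoothness(res, mask, c(3, 3, 3))
  }
  est6 <- sapply(1:12, function(s) mean(est_for(6, s)$fwhm_mm))
  expect_lt(abs(mean(est6) - 6) / 6, 0.15)
  # doubling the applied smoothing roughly doubles the estimate
  est12 <- sapply(1:6, function(s) mean(est_for(12, s)$fwhm_mm))
  ratio <- mean(est12) / mean(est6)
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)
  # unsmoothed white noise estimates below 2 voxel widths
  est0 <- est_for(0, 1)
  expect_lt(max(est0$fwhm_mm), 2 * 3)
})

test_that("GRF cluster p-values are monotone nonincreasing in cluster size", {
  p <- sapply(c(5, 10, 20, 40, 80), function(k)
    dalff:::grf_cluster_p(k, u = 2.24, resels = 150, n_mask_voxels = 3000))
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("peak world coordinates round-trip through the affine", {
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-30, -36, -27)
  ijk <- c(5, 7, 3)
  expect_equal(round(world_to_voxel(voxel_to_world(ijk, aff), aff)), ijk)
  m <- matrix(c(1, 1, 1, 10, 12, 9), 2, 3, byrow = TRUE)
  expect_equal(world_to_voxel(voxel_to_world(m, aff), aff), m)
})

test_that("permutation inference is seed-reproducible and GRF rejects weak thresholds", {
  co <- generate_cohort(small_cohort_config(seed = 14L, n_pat = 5L,
                                            n_ctl = 5L, n_t = 50L))
  cvs <- cohort_cv_maps(co, length_tr = 16L, step_tr = 4L)
  des <- group_design(co$participants, character(0))
  t1 <- permutation_cluster_inference(cvs, des, n_perm = 100, seed = 5,
                                      mask = co$brain_mask$values)
  t2 <- permutation_cluster_inference(cvs, des, n_perm = 100, seed = 5,
                                      mask = co$brain_mask$values)
  expect_identical(t1, t2)
  fit <- fit_voxelwise_glm(cvs, des, co$brain_mask$values)
  expect_error(grf_cluster_inference(fit, voxel_p = 0.4), "u > 1")
  expect_error(permutation_cluster_inference(cvs, des, n_perm = 10),
               ">= 100")
})

test_that("a strong planted effect is recovered by permutation inference", {
  # a strict cluster-forming threshold keeps null clusters small, so the
  # extent-saturated planted cluster dominates the permutation null
  cfg <- small_cohort_config(seed = 23L, depth_p = 0.9, depth_c = 0,
                             n_pat = 12L, n_ctl = 12L, n_t = 70L)
  co <- generate_cohort(cfg)
  cvs <- cohort_cv_maps(co)
  des <- group_design(co$participants)
  tab <- permutation_cluster_inference(cvs, des, voxel_p = 0.01,
                                       n_perm = 199, seed = 3,
                                       mask = co$brain_mask$values)
  expect_gt(nrow(tab), 0)
  expect_lt(min(tab$cluster_p), 0.05)
  # the top cluster peak lies inside the planted ROI
  roi <- co$roi_masks[[1]]
  pk <- round(world_to_voxel(as.numeric(tab[1, c("peak_x", "peak_y", "peak_z")]),
                             co$brain_mask$affine))
  expect_equal(roi[pk[1], pk[2], pk[3]], 1)
  # ROI labelling picks the planted region
  fit <- fit_voxelwise_glm(cvs, des, co$brain_mask$values)
  lab <- report_cluster_table(tab, co$roi_masks, fit)
  expect_equal(lab$label[1], "rectus_R")
})
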