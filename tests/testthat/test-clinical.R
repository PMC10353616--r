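test_that("ROI means match a per-voxel loop oracle", {
  grid <- c(5L, 5L, 4L)
  roi <- array(0, grid); roi[2:3, 2, 2] <- 1
  maps <- lapply(1:4, function(i) {
    set.seed(i)
    scalar_map(array(rnorm(prod(grid)), grid), array(1, grid), diag(4))
  })
  means <- extract_roi_means(maps, roi)
  loop <- sapply(maps, function(m) {
    acc <- 0; n <- 0
    for (i in 1:5) for (j in 1:5) for (k in 1:4)
      if (roi[i, j, k] != 0) { acc <- acc + m$values[i, j, k]; n <- n + 1 }
    acc / n
  })
  expect_equal(unname(means), loop, tolerance = 1e-12)
  const <- scalar_map(array(0.3, grid), array(1, grid), diag(4))
  expect_equal(unname(extract_roi_means(list(const), roi)), 0.3)
  two <- const; two$values[2, 2, 2] <- 0.2; two$values[3, 2, 2] <- 0.4
  expect_equal(unname(extract_roi_means(list(two), roi)), 0.3)
  expect_error(extract_roi_means(maps, array(0, grid)), "empty")
})

test_that("spearman matches the classic rank-difference formula", {
  r <- spearman_assoc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))   # 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(r$rho, 0.8)
  x <- c(0.3, 1.1, 2.0, 2.5, 4.2)
  expect_equal(spearman_assoc(x, exp(x))$rho, 1)      # monotone increasing
  expect_equal(spearman_assoc(x, -x^3)$rho, -1)       # monotone decreasing
  expect_error(spearman_assoc(rep(1, 5), x), "zero variance")
  expect_error(spearman_assoc(1:3, 1:3), ">= 4")
})

test_that("spearman is symmetric, monotone-invariant, and matches cor.test", {
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  a <- spearman_assoc(x, y); b <- spearman_assoc(y, x)
  expect_equal(a$rho, b$rho)
  expect_equal(a$rho, spearman_assoc(exp(x), y)$rho)   # strictly monotone map
  expect_equal(a$rho, unname(cor.test(x, y, method = "spearman")$estimate))
  # exact permutation p agrees in direction with the approximation
  xs <- x[1:8]; ys <- y[1:8]
  pe <- spearman_assoc(xs, ys, exact = TRUE)$p
  pa <- spearman_assoc(xs, ys)$p
  expect_true(abs(pe - pa) < 0.2)
})

test_that("roc_auc follows the Mann-Whitney tie convention", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 8 / 9)                  # 8 of 9 concordant pairs
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # curve starts at (0,0) and ends at (1,1)
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("roc_auc complement and U-statistic properties hold", {
  set.seed(7)
  for (i in 1:5) {
    sc <- rnorm(15)
    lb <- rbinom(15, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == 15) next
    expect_equal(roc_auc(sc, lb)$auc + roc_auc(sc, 1 - lb)$auc, 1)
    u <- wilcox.test(sc[lb == 1], sc[lb == 0])$statistic
    expect_equal(roc_auc(sc, lb)$auc,
                 unname(u) / (sum(lb) * sum(1 - lb)))
  }
  skip_if_not_installed("pROC")
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(suppressMessages(pROC::auc(lb, sc))))
})

test_that("pooled t reproduces printed group statistics from moments", {
  a <- moment_matched_sample(34, 56.500, 10.999, seed = 1)
  b <- moment_matched_sample(44, 55.340, 11.485, seed = 2)
  expect_equal(mean(a), 56.5); expect_equal(sd(a), 10.999)
  tt <- two_sample_t_pooled(a, b)
  expect_lt(abs(tt$t - 0.450), 0.001)
  expect_equal(tt$df, 76)
  expect_equal(two_sample_t_pooled(c(1, 2, 3), c(4, 5, 6))$t, -3 / sqrt(2 / 3),
               tolerance = 1e-10)
  expect_equal(two_sample_t_pooled(c(1, 2), c(1, 2))$t, 0)
  # antisymmetry
  expect_equal(two_sample_t_pooled(a, b)$t, -two_sample_t_pooled(b, a)$t)
  expect_equal(two_sample_t_pooled(c(2, 2), c(2, 2))$t, 0)
  expect_error(two_sample_t_pooled(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("chi-square without continuity correction matches printed value", {
  cs <- chi_square_2x2(matrix(c(25, 19, 9, 25), 2))
  expect_equal(cs$chi2, 7.184, tolerance = 0.01)
  expect_equal(cs$df, 1)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(suppressWarnings(chi_square_2x2(matrix(c(5, 0, 0, 5), 2)))$chi2,
               10)
  m <- matrix(c(12, 5, 7, 20), 2)
  expect_equal(chi_square_2x2(m)$chi2, chi_square_2x2(t(m))$chi2)
  expect_equal(chi_square_2x2(m)$chi2,
               chi_square_2x2(m[2:1, 2:1])$chi2)   # row+column swap
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginals")
})

test_that("demographics report is re-derivable from the raw columns", {
  set.seed(12)
  part <- data.frame(id = sprintf("s%02d", 1:20),
                     group = rep(c("patient", "control"), each = 10),
                     age = rnorm(20, 55, 8),
                     sex = sample(c("M", "F"), 20, replace = TRUE),
                     education = rnorm(20, 12, 3))
  clin <- data.frame(id = part$id[1:10], NIHSS = rpois(10, 4))
  rep_ <- suppressWarnings(demographics_report(part, clin))
  age_row <- rep_[rep_$variable == "age", ]
  tt <- two_sample_t_pooled(part$age[1:10], part$age[11:20])
  expect_equal(age_row$statistic, sprintf("t = %.3f", tt$t))
  expect_equal(age_row$p, tt$p)
  # median (Q1, Q3) against a sort-based computation
  ni <- rep_[rep_$variable == "NIHSS", ]
  s <- sort(clin$NIHSS)
  q <- quantile(s, c(0.5, 0.25, 0.75), type = 7)
  expect_equal(ni$patients, sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3]))
  expect_error(demographics_report(data.frame(x = 1)), "missing required")
  single <- part[part$group == "patient", ]
  expect_message(demographics_report(single), "one group")
})

test_that("correlation tables carry one row per region-scale pair", {
  set.seed(3)
  clin <- data.frame(id = sprintf("p%02d", 1:12), NIHSS = rpois(12, 4),
                     BI = pmin(100, rnorm(12, 80, 10)))
  means <- list(roiA = rnorm(12), roiB = rnorm(12))
  tab <- clinical_correlation_table(means, clin)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$scale[tab$region == "roiA"], c("NIHSS", "BI"))
  tab2 <- clinical_correlation_table(means, clin, p_adjust = "BH")
  expect_true(all(tab2$p_adj >= tab2$p - 1e-12))
})
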