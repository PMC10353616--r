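#' Per-subject mean of a map within an ROI
#'
#' @param cv_maps List of per-subject [scalar_map()]s (or 3D arrays).
#' @param roi Binary 3D array, nonempty, inside the analysis mask.
#' @return Numeric vector, one arithmetic mean per subject, named by the
#'   list names.
#' @export
extract_roi_means <- function(cv_maps, roi) {
  idx <- which(roi != 0)
  if (length(idx) == 0) stop("ROI mask is empty")
  out <- vapply(cv_maps, function(m) {
    v <- if (inherits(m, "scalar_map")) m$values else m
    mean(v[idx])
  }, numeric(1))
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average-ranked data (ties get average
#' ranks); the two-sided p-value uses
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' For n <= 10 an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact Use exact permutation p (only for n <= 10).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need x, y of equal length >= 4")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    perms <- permute_all(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

# All permutations of 1..n (n small).
permute_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permute_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random positive scores above
#' a random negative, ties credited 0.5 (computed from average ranks).
#' The curve enumerates (FPR, TPR) at every distinct score threshold.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels (1/TRUE = positive class); both classes
#'   must be present.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels != 0 & !is.na(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    fpr = vapply(th, function(u) mean(scores[labels == 0] >= u), numeric(1)),
    tpr = vapply(th, function(u) mean(scores[labels == 1] >= u), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Pooled-variance two-sample t-test
#'
#' Classic equal-variance t with `df = n_a + n_b - 2` and two-sided p.
#' Degenerate input with zero pooled variance returns t = 0 when the
#' means agree and is rejected otherwise.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `p`, group means.
#' @export
two_sample_t_pooled <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = df, p = 1, mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means; t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction; expected counts from the marginals.
#'
#' @param table 2x2 matrix of counts with all marginals positive.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("`table` must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Draw a sample with exactly the given mean and SD
#'
#' Rescales standard-normal draws affinely so the sample moments match the
#' printed summary statistics exactly; used to reproduce group-comparison
#' statistics from published mean +/- SD rows.
#'
#' @param n Sample size.
#' @param mean,sd Target sample mean and SD (n - 1 denominator).
#' @param seed Optional seed.
#' @return Numeric vector of length n.
#' @export
moment_matched_sample <- function(n, mean, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}

#' Demographic and clinical summary table
#'
#' Group-wise mean +/- SD with pooled t for continuous demographics,
#' male/female counts with Pearson chi-square (no continuity correction)
#' for sex, and median (Q1, Q3) (type-7 quantiles) for clinical scales,
#' which are reported for the patient group.
#'
#' @param participants Data frame with `id`, `group`, `age`, `sex`,
#'   `education`.
#' @param clinical Optional data frame with `id` and scale columns.
#' @return Data frame with columns `variable`, `patients`, `controls`,
#'   `statistic`, `p`.
#' @export
demographics_report <- function(participants, clinical = NULL) {
  need <- c("id", "group")
  missing_cols <- setdiff(need, names(participants))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  pat <- participants$group == "patient"
  ctl <- participants$group == "control"
  single_group <- !any(pat) || !any(ctl)
  if (single_group)
    message("only one group present; group-comparison columns omitted")
  rows <- list()
  fmt <- function(x) sprintf("%.3f ± %.3f", mean(x), stats::sd(x))
  for (v in intersect(c("age", "education"), names(participants))) {
    x <- participants[[v]]
    if (single_group) {
      g <- if (any(pat)) pat else ctl
      rows[[v]] <- data.frame(variable = v,
                              patients = if (any(pat)) fmt(x[pat]) else "",
                              controls = if (any(ctl)) fmt(x[ctl]) else "",
                              statistic = NA_character_, p = NA_real_)
    } else {
      tt <- two_sample_t_pooled(x[pat], x[ctl])
      rows[[v]] <- data.frame(variable = v, patients = fmt(x[pat]),
                              controls = fmt(x[ctl]),
                              statistic = sprintf("t = %.3f", tt$t),
                              p = tt$p)
    }
  }
  if ("sex" %in% names(participants) && !single_group) {
    tab <- table(factor(participants$group, c("patient", "control")),
                 factor(participants$sex, c("M", "F")))
    cs <- chi_square_2x2(tab)
    rows$sex <- data.frame(
      variable = "sex (M/F)",
      patients = sprintf("%d/%d", tab[1, 1], tab[1, 2]),
      controls = sprintf("%d/%d", tab[2, 1], tab[2, 2]),
      statistic = sprintf("chi2 = %.3f", cs$chi2), p = cs$p)
  }
  if (!is.null(clinical)) {
    for (v in setdiff(names(clinical), "id")) {
      q <- stats::quantile(clinical[[v]], c(0.5, 0.25, 0.75), type = 7)
      rows[[v]] <- data.frame(
        variable = v,
        patients = sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3]),
        controls = "-", statistic = NA_character_, p = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROI-by-scale Spearman correlation table
#'
#' Correlates each ROI's per-patient mean dALFF-CV with each clinical
#' scale; layout mirrors a regions-by-scales report. No multiplicity
#' correction is applied by default; Benjamini-Hochberg adjustment across
#' the whole table is available as an extension.
#'
#' @param roi_means Named list (or single vector) of per-patient ROI mean
#'   CVs, aligned with `clinical` rows.
#' @param clinical Data frame with `id` plus scale columns.
#' @param scales Scale columns to use (default all but `id`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `region`, `scale`, `rho`, `p`
#'   (and `p_adj` when adjusted).
#' @export
clinical_correlation_table <- function(roi_means, clinical,
                                       scales = setdiff(names(clinical), "id"),
                                       p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(roi_means)) roi_means <- list(roi = roi_means)
  rows <- list()
  for (rg in names(roi_means)) {
    for (sc in scales) {
      sp <- spearman_assoc(roi_means[[rg]], clinical[[sc]])
      rows[[paste(rg, sc)]] <- data.frame(region = rg, scale = sc,
                                          rho = sp$rho, p = sp$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
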