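#' Build a group design for voxelwise inference
#'
#' Design matrix `[intercept | group | covariates]` with covariates
#' mean-centred so the group coefficient is the adjusted group difference
#' at covariate means. Sex is encoded 0/1 (`M` = 1 when given as
#' characters).
#'
#' @param participants Data frame with columns `id`, `group`
#'   (`"patient"`/`"control"` or 0/1) and optionally `age`, `sex`,
#'   `education`.
#' @param covariates Character vector of covariate columns to adjust for
#'   (default the available ones among age, sex, education); use
#'   `character(0)` for an unadjusted two-sample comparison.
#' @return An object of class `group_design`: list with `x` (design
#'   matrix), `contrast` (selects the group effect), `subject_ids`,
#'   `group` (0/1 vector).
#' @export
group_design <- function(participants,
                         covariates = intersect(c("age", "sex", "education"),
                                                names(participants))) {
  g <- participants$group
  if (is.character(g) || is.factor(g))
    g <- as.numeric(as.character(g) == "patient")
  g <- as.numeric(g)
  if (!all(g %in% c(0, 1)) || length(unique(g)) < 2)
    stop("`group` must contain both patients (1) and controls (0)")
  x <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    v <- participants[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(as.character(v) == "M")
    x <- cbind(x, scale(as.numeric(v), scale = FALSE))
    colnames(x)[ncol(x)] <- cv
  }
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  contrast <- as.numeric(colnames(x) == "group")
  structure(list(x = x, contrast = contrast,
                 subject_ids = as.character(participants$id), group = g),
            class = "group_design")
}

# Stack per-subject scalar maps into an n x V matrix over the mask.
stack_maps <- function(maps, mask) {
  idx <- which(mask != 0)
  t(vapply(maps, function(m) {
    v <- if (inherits(m, "scalar_map")) m$values else m
    v[idx]
  }, numeric(length(idx))))
}

# Contrast t-statistics for Y (n x V) under fixed design x; returns list
# with t, fitted, residuals, df. Core of both observed and permuted fits.
glm_contrast_t <- function(x, y, contrast) {
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)
  fitted <- x %*% beta
  res <- y - fitted
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  se <- sqrt(sigma2 * cvar)
  tv <- drop(crossprod(contrast, beta))
  tv <- ifelse(se > 0, tv / se, 0)
  list(t = tv, fitted = fitted, residuals = res, df = df)
}

#' Voxelwise covariate-adjusted GLM
#'
#' Fits, at every in-mask voxel, an OLS regression of the per-subject map
#' values on the design and tests the group contrast; with no covariates
#' this reduces exactly to the pooled-variance two-sample t-test. Residual
#' maps are retained for smoothness estimation.
#'
#' @param maps List of per-subject [scalar_map()]s (or 3D arrays) sharing
#'   geometry, in the order of the design rows.
#' @param design A [group_design()].
#' @param mask Binary 3D array; defaults to the first map's mask.
#' @return An object of class `stat_map`: list with `tmap`, `zmap`
#'   ([scalar_map()]s), `df`, `residuals` (n x V matrix), `mask_idx`,
#'   `mask`, `affine`, `design`.
#' @export
fit_voxelwise_glm <- function(maps, design, mask = NULL) {
  if (is.null(mask)) mask <- maps[[1]]$mask
  n <- length(maps)
  if (n != nrow(design$x))
    stop(sprintf("%d maps but %d design rows", n, nrow(design$x)))
  if (n <= ncol(design$x))
    stop("need more subjects than design columns")
  y <- stack_maps(maps, mask)
  fit <- glm_contrast_t(design$x, y, design$contrast)
  affine <- if (inherits(maps[[1]], "scalar_map")) maps[[1]]$affine
            else diag(4)
  idx <- which(mask != 0)
  tvals <- array(0, dim = dim(mask))
  tvals[idx] <- fit$t
  zvals <- array(0, dim = dim(mask))
  zvals[idx] <- t_to_z(fit$t, fit$df)
  structure(list(
    tmap = scalar_map(tvals, mask, affine, "tstat"),
    zmap = scalar_map(zvals, mask, affine, "zstat"),
    df = fit$df, residuals = fit$residuals, mask_idx = idx, mask = mask,
    affine = affine, design = design), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> df = %d, %d in-mask voxels, t range [%.3f, %.3f]\n",
              x$df, length(x$mask_idx), min(x$tmap$values[x$mask_idx]),
              max(x$tmap$values[x$mask_idx])))
  invisible(x)
}

#' Convert t statistics to z scores
#'
#' Probit transform of the t cumulative probability,
#' `z = qnorm(pt(t, df))`, evaluated on the log scale in the matching tail
#' so large |t| keep full precision; the sign of z equals the sign of t.
#'
#' @param t Numeric t values.
#' @param df Residual degrees of freedom (>= 1).
#' @return z values of the same length; non-finite t propagate with a
#'   warning.
#' @export
t_to_z <- function(t, df) {
  if (df < 1) stop("`df` must be >= 1")
  if (any(!is.finite(t))) warning("non-finite t values propagated")
  z <- numeric(length(t))
  neg <- !is.na(t) & t <= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE), log.p = TRUE)
  z[!is.finite(t)] <- t[!is.finite(t)]
  z
}

#' Estimate spatial smoothness from GLM residuals
#'
#' Standardises each voxel's residual vector to unit norm across subjects
#' and, per axis, averages squared first differences between in-mask
#' neighbour pairs over subjects; this estimates the derivative variance
#' `lambda` of the unit-variance error field, giving
#' `FWHM = voxel_size * sqrt(4 log 2 / lambda)` and
#' `resels = |mask| * prod(voxel) / prod(FWHM)`.
#'
#' @param residuals n x V matrix of residuals over the in-mask voxels
#'   (column order = `which(mask != 0)`), e.g. from [fit_voxelwise_glm()].
#' @param mask Binary 3D array.
#' @param voxel_size_mm Length-3 voxel edges in mm.
#' @return An object of class `smoothness_estimate`: list with `fwhm_mm`,
#'   `fwhm_vox`, `resels`, `n_mask_voxels`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm) {
  if (nrow(residuals) < 3) stop("need >= 3 residual maps")
  norms <- sqrt(colSums(residuals^2))
  if (any(norms == 0)) stop("zero-variance residuals at some voxels")
  e <- sweep(residuals, 2, norms, `/`)
  d <- dim(mask)
  idx <- which(mask != 0)
  coords <- arrayInd(idx, d)
  pos <- array(NA_integer_, dim = d)
  pos[idx] <- seq_along(idx)    # column index in `e` for each mask voxel
  lambda <- numeric(3)
  for (ax in 1:3) {
    nb <- coords
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    j <- pos[nb[ok, , drop = FALSE]]
    keep <- !is.na(j)
    i <- which(ok)[keep]
    j <- j[keep]
    if (length(j) < 1) stop("mask has no interior voxel pairs along axis ", ax)
    diffs <- e[, j, drop = FALSE] - e[, i, drop = FALSE]
    lambda[ax] <- mean(colSums(diffs^2))
  }
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  fwhm_mm <- fwhm_vox * voxel_size_mm
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
                 resels = length(idx) * prod(voxel_size_mm) / prod(fwhm_mm),
                 n_mask_voxels = length(idx)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness> FWHM = %s mm, %.1f resels over %d voxels\n",
              paste(signif(x$fwhm_mm, 3), collapse = " x "), x$resels,
              x$n_mask_voxels))
  invisible(x)
}

# Neighbour offsets for 6/18/26 connectivity (positive half-space only).
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  deg <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6"  = off[deg == 1, , drop = FALSE],
                "18" = off[deg <= 2, , drop = FALSE],
                "26" = off,
                stop("connectivity must be 6, 18 or 26"))
  # keep one direction per pair (lexicographically positive)
  keep <- off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
           (off[, 2] == 0 & off[, 1] > 0)))
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D map
#'
#' Union-find over in-map voxels under 6, 18 or 26 connectivity; labels
#' are assigned in linear scan order (x fastest), so the labelling is
#' deterministic.
#'
#' @param bin Binary 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List with `labels` (3D integer array, 0 = background),
#'   `sizes` (voxel count per cluster, by label).
#' @export
label_clusters <- function(bin, connectivity = 26) {
  d <- dim(bin)
  idx <- which(bin != 0)
  labels <- array(0L, dim = d)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  pos <- array(NA_integer_, dim = d)
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(off <- connectivity_offsets(connectivity)))) {
    nb <- coords + rep(off[o, ], each = nrow(coords))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- pos[nb[ok, , drop = FALSE]]
    keep <- !is.na(j)
    ii <- which(ok)[keep]
    jj <- j[keep]
    for (k in seq_along(ii)) {
      ri <- find(ii[k]); rj <- find(jj[k])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab <- match(roots, unique(roots))   # scan-order labels
  labels[idx] <- lab
  list(labels = labels, sizes = as.integer(table(lab)))
}

# Expected number of clusters (EC heuristic) and expected suprathreshold
# voxel count for a unit Gaussian field thresholded at u.
grf_expected <- function(u, resels, n_mask_voxels) {
  em <- resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
  en <- n_mask_voxels * stats::pnorm(u, lower.tail = FALSE)
  list(em = em, en = en)
}

# RFT cluster-extent p-value: P(one cluster >= k) and FWE across E[m_tot].
grf_cluster_p <- function(k, u, resels, n_mask_voxels, n_tails = 2) {
  ex <- grf_expected(u, resels, n_mask_voxels)
  nbar <- ex$en / ex$em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  p_ge_k <- exp(-beta * k^(2 / 3))
  1 - exp(-n_tails * ex$em * p_ge_k)
}

# Extract clusters from a thresholded z map for one tail; returns rows of
# size / peak t / peak ijk.
extract_tail_clusters <- function(zvals, tvals, mask, u, tail, connectivity) {
  bin <- if (tail == "pos") (zvals >= u) & (mask != 0)
         else (zvals <= -u) & (mask != 0)
  cl <- label_clusters(bin, connectivity)
  if (length(cl$sizes) == 0) return(NULL)
  do.call(rbind, lapply(seq_along(cl$sizes), function(l) {
    vox <- which(cl$labels == l)
    pk <- vox[which.max(abs(tvals[vox]))]
    ijk <- arrayInd(pk, dim(mask))
    data.frame(size_voxels = cl$sizes[l], peak_stat = tvals[pk],
               i = ijk[1], j = ijk[2], k = ijk[3], tail = tail,
               stringsAsFactors = FALSE)
  }))
}

finalize_cluster_table <- function(rows, affine, method) {
  if (is.null(rows) || nrow(rows) == 0) {
    out <- data.frame(label = character(0), size_voxels = integer(0),
                      peak_stat = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      cluster_p = numeric(0), tail = character(0),
                      stringsAsFactors = FALSE)
  } else {
    xyz <- voxel_to_world(as.matrix(rows[, c("i", "j", "k")]), affine)
    xyz <- matrix(xyz, ncol = 3)
    out <- data.frame(label = "", size_voxels = rows$size_voxels,
                      peak_stat = rows$peak_stat, peak_x = xyz[, 1],
                      peak_y = xyz[, 2], peak_z = xyz[, 3],
                      cluster_p = rows$cluster_p, tail = rows$tail,
                      stringsAsFactors = FALSE)
    ord <- order(-out$size_voxels, -abs(out$peak_stat),
                 out$peak_x, out$peak_y, out$peak_z)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "method") <- method
  class(out) <- c("cluster_table", class(out))
  out
}

#' Gaussian-random-field cluster inference
#'
#' Thresholds the z field at `u = qnorm(1 - voxel_p)` (per tail, with
#' `voxel_p` halved per tail when two-sided), forms clusters, and assigns
#' each cluster the RFT family-wise p-value
#' `1 - exp(-E[m] P(n >= k))`, where the expected cluster count `E[m]`
#' uses the 3D Euler-characteristic density at `u` and the extent tail is
#' the exponential approximation `P(n >= k) = exp(-beta k^(2/3))` with
#' `beta` matched to the expected cluster size. Clusters with
#' `p < cluster_p` are retained.
#'
#' @param statmap A `stat_map` from [fit_voxelwise_glm()].
#' @param smoothness A [estimate_smoothness()] result; estimated from the
#'   fit's residuals when omitted.
#' @param voxel_p Cluster-forming voxel threshold (default 0.05).
#' @param cluster_p Cluster-level significance level (default 0.05).
#' @param two_sided Search both tails (default `TRUE`).
#' @param connectivity Cluster connectivity (default 26).
#' @return A `cluster_table` data frame: `label`, `size_voxels`,
#'   `peak_stat`, `peak_x/y/z` (world mm), `cluster_p`, `tail`; sorted by
#'   size. Attributes: `method`, `u`, `smoothness`.
#' @export
grf_cluster_inference <- function(statmap, smoothness = NULL,
                                  voxel_p = 0.05, cluster_p = 0.05,
                                  two_sided = TRUE, connectivity = 26) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  if (is.null(smoothness))
    smoothness <- estimate_smoothness(statmap$residuals, statmap$mask,
                                      affine_voxel_sizes(statmap$affine))
  n_tails <- if (two_sided) 2 else 1
  u <- stats::qnorm(1 - voxel_p / n_tails)
  if (u <= 1)
    stop(sprintf("voxel threshold u = %.3f too low for the cluster-count
approximation; use voxel_p giving u > 1", u))
  fwhm_vox <- smoothness$fwhm_vox
  resels <- smoothness$resels
  tails <- if (two_sided) c("pos", "neg") else "pos"
  rows <- do.call(rbind, lapply(tails, function(tl)
    extract_tail_clusters(statmap$zmap$values, statmap$tmap$values,
                          statmap$mask, u, tl, connectivity)))
  if (!is.null(rows) && nrow(rows) > 0) {
    rows$cluster_p <- grf_cluster_p(rows$size_voxels, u, resels,
                                    smoothness$n_mask_voxels, n_tails)
    rows <- rows[rows$cluster_p < cluster_p, , drop = FALSE]
  }
  out <- finalize_cluster_table(rows, statmap$affine, "grf")
  attr(out, "u") <- u
  attr(out, "smoothness") <- smoothness
  out
}

#' Permutation-based cluster inference
#'
#' Freedman-Lane style maximum-cluster-size test: the data are
#' residualised on the nuisance covariates, the reduced-model residuals
#' are permuted over subjects and added back to the reduced fit, the full
#' model is refitted and the largest suprathreshold cluster size recorded;
#' observed clusters get `p = (1 + #(perm max >= k)) / (1 + n_perm)`.
#'
#' @param maps List of per-subject [scalar_map()]s (or 3D arrays).
#' @param design A [group_design()].
#' @param voxel_p Cluster-forming voxel threshold (two-sided; halved per
#'   tail), default 0.05.
#' @param cluster_p Cluster-level significance level (default 0.05).
#' @param n_perm Number of permutations (>= 100; exact enumeration with a
#'   warning when fewer distinct relabelings exist).
#' @param seed Integer seed for the permutation stream.
#' @param connectivity Cluster connectivity (default 26).
#' @param mask Binary 3D array; defaults to the first map's mask.
#' @return A `cluster_table` (see [grf_cluster_inference()]) with
#'   attributes `method = "perm"`, `u`, `perm_max` (the null
#'   distribution).
#' @export
permutation_cluster_inference <- function(maps, design, voxel_p = 0.05,
                                          cluster_p = 0.05, n_perm = 1000L,
                                          seed = 1L, connectivity = 26,
                                          mask = NULL) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (is.null(mask)) mask <- maps[[1]]$mask
  affine <- if (inherits(maps[[1]], "scalar_map")) maps[[1]]$affine else diag(4)
  y <- stack_maps(maps, mask)
  x <- design$x
  contrast <- design$contrast
  idx <- which(mask != 0)
  d <- dim(mask)
  u <- stats::qnorm(1 - voxel_p / 2)

  # observed fit and clusters
  fit <- glm_contrast_t(x, y, contrast)
  df <- fit$df
  zv <- array(0, dim = d); zv[idx] <- t_to_z(fit$t, df)
  tv <- array(0, dim = d); tv[idx] <- fit$t
  rows <- rbind(extract_tail_clusters(zv, tv, mask, u, "pos", connectivity),
                extract_tail_clusters(zv, tv, mask, u, "neg", connectivity))

  # reduced model: everything but the group column
  keep <- contrast == 0
  xr <- x[, keep, drop = FALSE]
  fitted_r <- xr %*% solve(crossprod(xr), crossprod(xr, y))
  res_r <- y - fitted_r

  max_cluster_size <- function(tstat) {
    zz <- array(0, dim = d); zz[idx] <- t_to_z(tstat, df)
    mx <- 0L
    for (sgn in c(1, -1)) {
      bin <- array((sgn * zz >= u) & (mask != 0), dim = d)
      sz <- label_clusters(bin, connectivity)$sizes
      if (length(sz)) mx <- max(mx, max(sz))
    }
    mx
  }

  set.seed(derive_seed(seed, 0L, 4L))
  n <- nrow(y)
  n1 <- sum(design$group == 1)
  if (choose(n, n1) <= n_perm)
    warning(sprintf(
      "only %.0f distinct group relabelings exist (< n_perm = %d); p-values are coarse",
      choose(n, n1), n_perm))
  # permute rows of the reduced-model residuals (Freedman-Lane)
  perm_max <- vapply(seq_len(n_perm), function(i) {
    pr <- sample.int(n)
    ystar <- fitted_r + res_r[pr, , drop = FALSE]
    max_cluster_size(glm_contrast_t(x, ystar, contrast)$t)
  }, integer(1))

  n_eff <- length(perm_max)
  if (!is.null(rows) && nrow(rows) > 0) {
    rows$cluster_p <- vapply(rows$size_voxels, function(k)
      (1 + sum(perm_max >= k)) / (1 + n_eff), numeric(1))
    rows <- rows[rows$cluster_p < cluster_p, , drop = FALSE]
  }
  out <- finalize_cluster_table(rows, affine, "perm")
  attr(out, "u") <- u
  attr(out, "perm_max") <- perm_max
  out
}

#' Format and optionally label a cluster table
#'
#' Sorts clusters by size (ties broken by peak statistic then
#' coordinates), labels each cluster by the ROI mask with maximal overlap
#' (when given), and optionally writes a TSV.
#'
#' @param table A `cluster_table`.
#' @param roi_masks Optional named list of binary 3D arrays.
#' @param statmap Optional `stat_map` used to recover cluster voxel sets
#'   for ROI overlap (required when `roi_masks` is given).
#' @param connectivity Connectivity used to form the clusters.
#' @param path Optional TSV output path.
#' @return The labelled, sorted `cluster_table`.
#' @export
report_cluster_table <- function(table, roi_masks = NULL, statmap = NULL,
                                 connectivity = 26, path = NULL) {
  if (!is.null(roi_masks) && nrow(table) > 0) {
    if (is.null(statmap))
      stop("`statmap` is needed to compute ROI overlaps")
    u <- attr(table, "u")
    for (r in seq_len(nrow(table))) {
      tl <- table$tail[r]
      bin <- if (tl == "pos") statmap$zmap$values >= u
             else statmap$zmap$values <= -u
      bin <- bin & statmap$mask != 0
      cl <- label_clusters(bin, connectivity)
      # locate the cluster containing the reported peak
      ijk <- round(world_to_voxel(
        as.numeric(table[r, c("peak_x", "peak_y", "peak_z")]),
        statmap$affine))
      lab <- cl$labels[ijk[1], ijk[2], ijk[3]]
      if (lab == 0) next
      vox <- cl$labels == lab
      ov <- vapply(roi_masks, function(m) sum(vox & m != 0), numeric(1))
      if (max(ov) > 0) table$label[r] <- names(roi_masks)[which.max(ov)]
    }
  }
  if (!is.null(path)) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  table
}
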