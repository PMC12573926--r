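# Shared Wilson machinery. Convention used throughout the package:
#   <I>(d) proportional to exp(-B / (2 d^2))
# so ln<I> vs 1/d^2 is a line of slope -B/2. Bin abscissae are the mean
# 1/d^2 of the contributing reflections (not the bin midpoint), which
# removes the leading binning bias.
.wilson_fit <- function(inv_d2, lnI, weight, fit_range, source) {
  pts <- data.frame(inv_d2 = inv_d2, ln_mean_I = lnI, weight = weight)
  sel <- is.finite(pts$ln_mean_I) & is.finite(pts$inv_d2) &
    pts$inv_d2 >= fit_range[1] & pts$inv_d2 <= fit_range[2]
  sel[is.na(sel)] <- FALSE
  if (sum(sel) < 2) stop("fewer than 2 usable Wilson points in the fit range")
  fit <- stats::lm(ln_mean_I ~ inv_d2, data = pts[sel, ], weights = pts$weight[sel])
  co <- stats::coef(fit)
  structure(list(points = pts,
                 fit_range = range(pts$inv_d2[sel]),
                 B = -2 * unname(co[2]),
                 intercept = unname(co[1]),
                 source = source),
            class = "wilson_fit")
}

#' @export
print.wilson_fit <- function(x, ...) {
  cat(sprintf("Wilson fit (%s): B = %.2f A^2 over 1/d^2 in [%.3f, %.3f] (%d bins)\n",
              x$source, x$B, x$fit_range[1], x$fit_range[2], nrow(x$points)))
  invisible(x)
}

#' Wilson plot and B factor from merged (observed) intensities
#'
#' Bins merged intensities in 1/d^2, takes the log of each bin mean and
#' fits a weighted line over `fit_range`; `B = -2 * slope`. Bins with a
#' non-positive mean are excluded with a warning. The default fit range
#' excludes the low-resolution region (1/d^2 < 0.1) where observed Wilson
#' plots are routinely non-linear for reasons unrelated to Bragg
#' diffraction.
#'
#' @param merged a `merged_dataset`
#' @param n_bins number of 1/d^2 bins
#' @param fit_range numeric length-2, fit window in 1/d^2 (1/Angstrom^2)
#' @return object of class `wilson_fit`; report `fit_range` together with B
#' @export
wilson_observed <- function(merged, n_bins = 30, fit_range = c(0.1, Inf)) {
  ent <- as.data.frame(merged$entries)
  if (!nrow(ent)) stop("empty merged dataset")
  x <- 1 / ent$d^2
  edges <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = n_bins + 1)
  bin <- factor(cut(x, edges, labels = FALSE), levels = seq_len(n_bins))
  mid <- as.numeric(tapply(x, bin, mean))
  mI <- tapply(ent$mean_I, bin, mean)
  n <- tapply(rep(1, nrow(ent)), bin, sum)
  n[is.na(n)] <- 0
  bad <- which(!is.na(mI) & mI <= 0)
  if (length(bad))
    warning(length(bad), " bin(s) with non-positive mean intensity excluded")
  lnI <- ifelse(!is.na(mI) & mI > 0, log(pmax(mI, .Machine$double.xmin)), NA_real_)
  .wilson_fit(mid, as.numeric(lnI), as.numeric(n), fit_range, "observed")
}

#' Wilson plot from calculated intensities
#'
#' The same binning and fit applied to `|F_calc|^2` over the full HKL
#' sphere of the structure. Calculated-intensity Wilson plots are immune
#' to background and scaling artefacts and reflect only the falloff of
#' Bragg diffraction encoded in the model, which makes them the preferred
#' basis for cross-dataset falloff comparisons.
#'
#' @param structure a `toy_structure`
#' @param cell override cell (default: the structure's)
#' @param d_min high-resolution limit (Angstrom)
#' @param n_bins number of 1/d^2 bins
#' @param fit_range fit window in 1/d^2; default uses everything
#' @return object of class `wilson_fit`
#' @export
wilson_calculated <- function(structure, cell = NULL, d_min = 1.5,
                              n_bins = 30, fit_range = c(0, Inf)) {
  st <- structure
  if (!is.null(cell)) st$cell <- cell
  hkls <- hkl_sphere(st$cell, d_min)
  I <- Mod(calc_structure_factors(st, hkls))^2
  x <- 1 / hkls$d^2
  edges <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = n_bins + 1)
  bin <- factor(cut(x, edges, labels = FALSE), levels = seq_len(n_bins))
  mid <- as.numeric(tapply(x, bin, mean))
  mI <- tapply(I, bin, mean)
  n <- tapply(rep(1, length(I)), bin, sum)
  n[is.na(n)] <- 0
  lnI <- ifelse(!is.na(mI) & mI > 0, log(mI), NA_real_)
  .wilson_fit(mid, as.numeric(lnI), as.numeric(n), fit_range, "calculated")
}

#' Intensity falloff ratio between two Wilson fits
#'
#' Evaluates both fitted lines at `inv_d2` after matching their intercepts
#' at a low-resolution anchor (default: the extrapolated 1/d^2 = 0 point,
#' so only the slope difference matters):
#' `ratio = exp(-(B1 - B2)/2 * (inv_d2 - anchor))`. A ratio > 1 means
#' dataset 1 retains more intensity at that resolution; swapping the
#' arguments inverts the ratio.
#'
#' @param fit1,fit2 `wilson_fit` objects
#' @param inv_d2 evaluation point (1/Angstrom^2); must lie inside both fit
#'   ranges unless `force = TRUE`
#' @param anchor intercept-matching point in 1/d^2 (default 0)
#' @param force allow extrapolation beyond the fit ranges
#' @return intensity ratio (dataset 1 over dataset 2)
#' @export
falloff_ratio <- function(fit1, fit2, inv_d2, anchor = 0, force = FALSE) {
  if (!force) {
    if (inv_d2 < fit1$fit_range[1] || inv_d2 > fit1$fit_range[2] ||
        inv_d2 < fit2$fit_range[1] || inv_d2 > fit2$fit_range[2])
      stop("inv_d2 outside a fit range; use force = TRUE to extrapolate")
  }
  exp(-(fit1$B - fit2$B) / 2 * (inv_d2 - anchor))
}

#' Cluster unit cells into populations
#'
#' k-means clustering of per-image unit cells on standardized
#' (a, b, c, beta), with many restarts under a fixed seed. Clusters are
#' reported sorted by cell volume, so labels are deterministic. The
#' per-image `assignment_margin` (distance to the second-nearest centre
#' minus distance to the nearest, in standardized units) and the
#' `degenerate` flag expose splits of what is really a single population.
#'
#' @param cells list of `unit_cell` objects, or a data.frame with columns
#'   a, b, c, beta
#' @param k number of clusters (default 2: compact vs expanded population)
#' @param seed RNG seed
#' @param nstart k-means restarts
#' @return list of class `cell_cluster_result`: `labels`,
#'   `cluster_centers` (list of `unit_cell`), `fraction_per_cluster`,
#'   `assignment_margin`, `degenerate`
#' @export
cluster_cells <- function(cells, k = 2, seed = 1, nstart = 25) {
  df <- if (is.data.frame(cells)) cells
        else do.call(rbind, lapply(cells, function(cl)
          data.frame(a = cl$a, b = cl$b, c = cl$c, beta = cl$beta)))
  if (nrow(df) < k) stop("fewer cells than clusters requested")
  X <- as.matrix(df[, c("a", "b", "c", "beta")])
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  if (nrow(unique(Z)) < k) {
    # fewer distinct cells than clusters: a single (or repeated) population;
    # report one real cluster duplicated, flagged degenerate
    ctr <- unit_cell(mean(df$a), mean(df$b), mean(df$c), beta = mean(df$beta))
    return(structure(list(labels = rep(1L, nrow(df)),
                          cluster_centers = rep(list(ctr), k),
                          fraction_per_cluster = c(1, rep(0, k - 1)),
                          assignment_margin = rep(0, nrow(df)),
                          degenerate = TRUE),
                     class = "cell_cluster_result"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100)
  centers_raw <- sweep(sweep(km$centers, 2, sg, "*"), 2, mu, "+")
  vols <- apply(centers_raw, 1, function(r)
    cell_volume(unit_cell(r[1], r[2], r[3], beta = r[4])))
  ord <- order(vols)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  centers <- lapply(ord, function(i)
    unit_cell(centers_raw[i, 1], centers_raw[i, 2], centers_raw[i, 3],
              beta = centers_raw[i, 4]))
  dmat <- vapply(ord, function(i)
    sqrt(rowSums(sweep(Z, 2, km$centers[i, ])^2)), numeric(nrow(Z)))
  dmat <- matrix(dmat, nrow = nrow(Z))
  margin <- apply(dmat, 1, function(r) {
    s <- sort(r); s[2] - s[1]
  })
  within <- sqrt(mean(apply(dmat, 1, min)^2))
  sep <- if (k >= 2) min(stats::dist(km$centers)) else Inf
  structure(list(labels = labels,
                 cluster_centers = centers,
                 fraction_per_cluster = as.numeric(table(factor(labels, 1:k))) / nrow(Z),
                 assignment_margin = margin,
                 degenerate = is.finite(sep) && sep < 2 * within),
            class = "cell_cluster_result")
}

#' @export
print.cell_cluster_result <- function(x, ...) {
  k <- length(x$cluster_centers)
  cat(sprintf("cell clustering: %d clusters%s\n", k,
              if (x$degenerate) " [DEGENERATE: populations not separated]" else ""))
  for (i in seq_len(k)) {
    cl <- x$cluster_centers[[i]]
    cat(sprintf("  cluster %d (%.0f%%): a=%.2f b=%.2f c=%.2f beta=%.2f\n",
                i, 100 * x$fraction_per_cluster[i], cl$a, cl$b, cl$c, cl$beta))
  }
  invisible(x)
}
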