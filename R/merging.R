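#' @import data.table
NULL

# canonical representative of the symmetry orbit of (h,k,l)
# monoclinic_2: point group 2 (unique axis b) plus Friedel mates, i.e.
# {(h,k,l), (-h,k,-l), (-h,-k,-l), (h,-k,l)}; the lexicographically largest
# member is chosen. P1 keeps indices as observed.
canonical_hkl <- function(h, k, l, symmetry = c("P1", "monoclinic_2")) {
  symmetry <- match.arg(symmetry)
  if (symmetry == "P1") return(data.frame(h = h, k = k, l = l))
  eq <- list(cbind(h, k, l), cbind(-h, k, -l), cbind(-h, -k, -l), cbind(h, -k, l))
  best <- eq[[1]]
  for (m in eq[-1]) {
    better <- (m[, 1] > best[, 1]) |
      (m[, 1] == best[, 1] & m[, 2] > best[, 2]) |
      (m[, 1] == best[, 1] & m[, 2] == best[, 2] & m[, 3] > best[, 3])
    best[better, ] <- m[better, ]
  }
  data.frame(h = best[, 1], k = best[, 2], l = best[, 3])
}

#' Monte-Carlo merging of snapshot reflection lists
#'
#' Per-unique-reflection unweighted mean of all observations across images,
#' the convention used when merging still snapshots so that partiality
#' averages out. Symmetry-equivalent observations are folded together under
#' the chosen point group. The merged cell is the per-axis median of the
#' image cells; images whose cell deviates from that median by more than
#' `cell_tol` (fractional, per axis or beta) abort the merge, since mixing
#' cell populations produces a meaningless average - split them first with
#' [cluster_cells()].
#'
#' @param images list of image records (see [simulate_image_set()] /
#'   [read_reflection_tsv()])
#' @param symmetry `"P1"` (no folding) or `"monoclinic_2"` (point group 2,
#'   unique axis b, Friedel mates folded)
#' @param weighted if TRUE use `1/sigma^2`-weighted means instead of the
#'   unweighted Monte-Carlo convention
#' @param cell_tol per-axis fractional tolerance for cell consistency
#' @return list of class `merged_dataset` with `entries` (data.table:
#'   h, k, l, mean_I, sem_I, redundancy, d), `cell`, `n_images`, `symmetry`
#' @export
mc_merge <- function(images, symmetry = c("P1", "monoclinic_2"),
                     weighted = FALSE, cell_tol = 0.01) {
  symmetry <- match.arg(symmetry)
  if (length(images) < 1) stop("need at least one image")
  cells <- do.call(rbind, lapply(images, function(im)
    c(im$cell$a, im$cell$b, im$cell$c, im$cell$beta)))
  med <- apply(cells, 2, stats::median)
  rel <- abs(sweep(cells, 2, med, "/") - 1)
  if (any(rel > cell_tol))
    stop("inconsistent cells beyond ", cell_tol * 100,
         "% tolerance: the image set appears to contain more than one ",
         "cell population; split it with cluster_cells() before merging")
  cell <- unit_cell(med[1],
                    stats::median(cells[, 2]),
                    med[3],
                    alpha = stats::median(vapply(images, function(im) im$cell$alpha, 0)),
                    beta = med[4],
                    gamma = stats::median(vapply(images, function(im) im$cell$gamma, 0)))
  obs <- data.table::rbindlist(lapply(images, function(im) {
    o <- im$obs
    if (any(o$sigma <= 0)) stop("sigma must be > 0")
    data.table::data.table(h = o$h, k = o$k, l = o$l, I = o$I, sigma = o$sigma)
  }))
  can <- canonical_hkl(obs$h, obs$k, obs$l, symmetry)
  obs[, c("h", "k", "l") := can]
  I <- sigma <- mean_I <- sem_I <- redundancy <- NULL  # NSE bindings
  if (weighted) {
    ent <- obs[, {
      w <- 1 / sigma^2
      mu <- sum(w * I) / sum(w)
      list(mean_I = mu,
           sem_I = if (.N >= 2) sqrt(sum(w * (I - mu)^2) / ((.N - 1) * sum(w))) else NA_real_,
           redundancy = .N)
    }, by = c("h", "k", "l")]
  } else {
    ent <- obs[, list(mean_I = mean(I),
                      sem_I = if (.N >= 2) stats::sd(I) / sqrt(.N) else NA_real_,
                      redundancy = .N),
               by = c("h", "k", "l")]
  }
  ent$d <- d_spacing(as.matrix(ent[, c("h", "k", "l")]), cell)
  data.table::setorder(ent, -d)
  structure(list(entries = ent, cell = cell, n_images = length(images),
                 symmetry = symmetry),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("merged dataset: %d unique reflections from %d images (%s), d %.2f-%.2f A\n",
              nrow(x$entries), x$n_images, x$symmetry,
              max(x$entries$d), min(x$entries$d)))
  invisible(x)
}

#' Resolution-shell statistics
#'
#' Partitions merged reflections into `n_shells` shells of equal volume in
#' reciprocal space (equal width in 1/d^3) and reports per-shell means.
#' Completeness is measured against the full Friedel-unique HKL sphere of
#' the merged cell, folded under the dataset's symmetry.
#'
#' @param merged a `merged_dataset`
#' @param n_shells number of shells
#' @return data.frame of class `shell_table`: `d_max`, `d_min` (Angstrom,
#'   low to high resolution), `mean_I`, `mean_I_over_sigma`, `n_refl`,
#'   `completeness`
#' @export
shell_statistics <- function(merged, n_shells = 10) {
  ent <- as.data.frame(merged$entries)
  if (nrow(ent) == 0) stop("empty merged dataset")
  if (n_shells > nrow(ent)) stop("more shells than unique reflections")
  u <- 1 / ent$d^3
  edges <- seq(min(u), max(u), length.out = n_shells + 1)
  edges[1] <- edges[1] - 1e-9; edges[n_shells + 1] <- edges[n_shells + 1] + 1e-9
  bin <- cut(u, edges, labels = FALSE)
  full <- hkl_sphere(merged$cell, d_min = min(ent$d))
  canf <- canonical_hkl(full$h, full$k, full$l, merged$symmetry)
  canf <- unique(canf)
  df <- d_spacing(as.matrix(canf), merged$cell)
  ufull <- 1 / df^3
  binf <- cut(ufull, edges, labels = FALSE)
  shells <- lapply(seq_len(n_shells), function(i) {
    sel <- which(bin == i)
    ios <- ent$mean_I[sel] / ent$sem_I[sel]
    ios <- ios[is.finite(ios)]
    n_possible <- sum(binf == i, na.rm = TRUE)
    data.frame(
      d_max = 1 / edges[i]^(1/3) , d_min = 1 / edges[i + 1]^(1/3),
      mean_I = mean(ent$mean_I[sel]),
      mean_I_over_sigma = if (length(ios)) mean(ios) else NA_real_,
      n_refl = length(sel),
      completeness = if (n_possible > 0) min(1, length(sel) / n_possible) else NA_real_)
  })
  out <- do.call(rbind, shells)
  class(out) <- c("shell_table", "data.frame")
  out
}

#' Resolution cut-off from a signal-to-noise threshold
#'
#' Interpolates the per-shell mean I/sigma against 1/d^2 (shell centres)
#' and returns the resolution at which it crosses the threshold. If the
#' signal never drops below the threshold the dataset is geometry-limited
#' and the best shell edge is returned with a flag.
#'
#' @param shells a `shell_table`
#' @param threshold S/N threshold, > 0 (1.0 is a common choice)
#' @return list with `d` (Angstrom) and `geometry_limited` (logical)
#' @export
snr_resolution <- function(shells, threshold = 1.0) {
  stopifnot(threshold > 0)
  if (nrow(shells) == 0) stop("empty shell table")
  x <- (1 / shells$d_max^2 + 1 / shells$d_min^2) / 2
  yv <- shells$mean_I_over_sigma
  ok <- is.finite(yv)
  x <- x[ok]; yv <- yv[ok]
  if (!length(x)) stop("no shells with finite I/sigma")
  below <- which(yv < threshold)
  if (!length(below))
    return(list(d = min(shells$d_min), geometry_limited = TRUE))
  i <- below[1]
  if (i == 1) return(list(d = 1 / sqrt(x[1]), geometry_limited = FALSE))
  # linear interpolation in 1/d^2 between the bracketing shell centres
  x_cross <- x[i - 1] + (threshold - yv[i - 1]) * (x[i] - x[i - 1]) / (yv[i] - yv[i - 1])
  list(d = 1 / sqrt(x_cross), geometry_limited = FALSE)
}

#' Detector saturation (clipping) report
#'
#' Fraction of observations at or above a saturation cap, overall and per
#' resolution shell. Useful for diagnosing datasets in which strong
#' low-resolution intensities were clipped by the detector, which flattens
#' the low-resolution end of the observed Wilson plot.
#'
#' @param images list of image records
#' @param cap saturation level (intensity units), > 0
#' @param n_shells number of equal-volume resolution shells
#' @return list with `clipped_fraction` and `per_shell` (data.frame:
#'   d_max, d_min, n_obs, clipped_fraction)
#' @export
clipping_report <- function(images, cap, n_shells = 10) {
  stopifnot(cap > 0)
  obs <- data.table::rbindlist(lapply(images, function(im) {
    d <- d_spacing(as.matrix(im$obs[, c("h", "k", "l")]), im$cell)
    data.table::data.table(I = im$obs$I, d = d)
  }))
  clipped <- obs$I >= cap
  u <- 1 / obs$d^3
  edges <- seq(min(u), max(u), length.out = n_shells + 1)
  edges[1] <- edges[1] - 1e-9; edges[n_shells + 1] <- edges[n_shells + 1] + 1e-9
  bin <- cut(u, edges, labels = FALSE)
  per <- do.call(rbind, lapply(seq_len(n_shells), function(i) {
    sel <- bin == i
    data.frame(d_max = 1 / edges[i]^(1/3), d_min = 1 / edges[i + 1]^(1/3),
               n_obs = sum(sel),
               clipped_fraction = if (any(sel)) mean(clipped[sel]) else NA_real_)
  }))
  list(clipped_fraction = mean(clipped), per_shell = per)
}
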