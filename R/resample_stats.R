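#' Bootstrap draws of an image set
#'
#' "Drawing with replacement": each replica contains the same number of
#' images as the original set, sampled uniformly with replacement.
#'
#' @param images list of images (or an integer, interpreted as the set size,
#'   in which case index vectors are returned)
#' @param n_replicas number of replicas (100 is the customary choice)
#' @param seed RNG seed
#' @return list of `n_replicas` image-lists (or index vectors)
#' @export
draw_with_replacement <- function(images, n_replicas = 100, seed = 1) {
  n <- if (is.numeric(images) && length(images) == 1) as.integer(images)
       else length(images)
  if (n < 1) stop("need at least one image")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- lapply(seq_len(n_replicas), function(i) sample.int(n, n, replace = TRUE))
  if (is.numeric(images) && length(images) == 1) idx
  else lapply(idx, function(i) images[i])
}

#' Bootstrap a processing pipeline over image replicas
#'
#' Applies `pipeline` (typically merge -> scramble -> refine ->
#' geometry report) to each bootstrap replica of the image set and
#' summarises every returned parameter by its replica mean and SD - the
#' error-bar machinery for refined structural parameters. Failed replicas
#' (e.g. non-converged refinements) are dropped and counted; more than 50%
#' failures aborts.
#'
#' @param images list of image records
#' @param pipeline function(images, replica_seed) -> named numeric vector
#' @param n_replicas number of bootstrap replicas
#' @param seed master seed; each replica receives a derived seed so that
#'   scrambling differs between replicas
#' @return list of class `bootstrap_result`: `parameters` (data.frame
#'   parameter/mean/sd/n_replicas), `replica_values` (matrix), `n_failed`
#' @export
bootstrap_pipeline <- function(images, pipeline, n_replicas = 100, seed = 1) {
  reps <- draw_with_replacement(images, n_replicas, seed)
  vals <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    vals[i] <- list(tryCatch(pipeline(reps[[i]], split_seed(seed, paste0("replica", i))),
                             error = function(e) NULL))
  }
  ok <- !vapply(vals, is.null, TRUE)
  n_failed <- sum(!ok)
  if (n_failed > n_replicas / 2)
    stop("bootstrap aborted: ", n_failed, "/", n_replicas,
         " replicas failed; first error at replica ", which(!ok)[1])
  m <- do.call(rbind, vals[ok])
  params <- data.frame(parameter = colnames(m),
                       mean = colMeans(m),
                       sd = apply(m, 2, stats::sd),
                       n_replicas = nrow(m),
                       row.names = NULL)
  structure(list(parameters = params, replica_values = m, n_failed = n_failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap over %d replicas (%d failed):\n",
              x$parameters$n_replicas[1] + x$n_failed, x$n_failed))
  print(x$parameters)
  invisible(x)
}

#' Equal-weight Gaussian mixture summary
#'
#' Combines per-dataset parameter estimates (mean, SD) into one overall
#' distribution by summing equally weighted Gaussians, and reports the
#' mean and SD of that mixture. Closed form:
#' `overall_var = mean(sd_i^2 + mean_i^2) - overall_mean^2`, cross-checked
#' internally by numerical summation of the mixture density on a grid.
#'
#' @param means component means
#' @param sds component SDs, all > 0
#' @return list of class `mixture_summary`: `components`, `overall_mean`,
#'   `overall_sd`
#' @export
combine_gaussians <- function(means, sds) {
  if (!length(means)) stop("empty input")
  if (length(means) != length(sds)) stop("means and sds must match")
  if (any(sds <= 0)) stop("component sds must be > 0")
  overall_mean <- mean(means)
  overall_var <- mean(sds^2 + means^2) - overall_mean^2
  # numeric cross-check by summation over +-10 sd of every component; the
  # grid must resolve the narrowest component, so its size is capped and the
  # check skipped when components are too disparate to grid affordably
  lo <- min(means - 10 * sds); hi <- max(means + 10 * sds)
  n_grid <- min(2e6, max(20001, ceiling(8 * (hi - lo) / min(sds))))
  if (n_grid < 2e6) {
    x <- seq(lo, hi, length.out = n_grid)
    dens <- rowMeans(vapply(seq_along(means),
                            function(i) stats::dnorm(x, means[i], sds[i]),
                            numeric(length(x))))
    dx <- x[2] - x[1]
    gm <- sum(x * dens) * dx
    gv <- sum((x - gm)^2 * dens) * dx
    if (abs(gv - overall_var) > 1e-6 * max(overall_var, 1))
      warning("grid cross-check deviates from the closed form; result kept")
  }
  structure(list(components = data.frame(mean = means, sd = sds),
                 overall_mean = overall_mean,
                 overall_sd = sqrt(overall_var)),
            class = "mixture_summary")
}

#' Welch's t-test from summary statistics
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite (fractional)
#' degrees of freedom, computed from per-group mean, SD and n. Used to
#' compare a parameter's overall distribution between two beamtimes; the
#' appropriate `n` (number of datasets per beamtime, by default) is the
#' caller's choice and should be reported alongside the p-value.
#'
#' @param mean1,sd1,n1 first group summary (n >= 2)
#' @param mean2,sd2,n2 second group summary
#' @return list of class `welch_result`: `t_statistic`, `dof`, `p_value`
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(structure(list(t_statistic = 0, dof = n1 + n2 - 2, p_value = 1),
                       class = "welch_result"))
    stop("degenerate input: both sds zero with unequal means")
  }
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  dof <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), dof)
  structure(list(t_statistic = t, dof = dof, p_value = p),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4f, dof = %.2f, p = %.4g\n",
              x$t_statistic, x$dof, x$p_value))
  invisible(x)
}

#' Weighted trend of a parameter against scan step size
#'
#' Inverse-variance-weighted linear regression of a structural parameter on
#' step size, with the slope standard error taken from the (known) weights
#' - the formal test behind statements like "the parameter is independent
#' of the scanning step size". The two-sided p-value is computed from the
#' normal reference distribution of slope/SE.
#'
#' @param step step sizes (micrometre), >= 3 distinct values
#' @param value parameter values
#' @param sd per-value SDs (e.g. bootstrap SDs), > 0
#' @return list of class `step_trend`: `slope`, `slope_se`, `p`,
#'   `intercept`
#' @export
step_trend <- function(step, value, sd) {
  if (length(unique(step)) < 3) stop("need >= 3 distinct step sizes")
  if (any(sd <= 0)) stop("sds must be > 0")
  w <- 1 / sd^2
  xm <- sum(w * step) / sum(w)
  ym <- sum(w * value) / sum(w)
  sxx <- sum(w * (step - xm)^2)
  if (sxx <= 0) stop("degenerate design: all steps identical")
  slope <- sum(w * (step - xm) * (value - ym)) / sxx
  se <- sqrt(1 / sxx)
  p <- 2 * stats::pnorm(-abs(slope / se))
  structure(list(slope = slope, slope_se = se, p = p,
                 intercept = ym - slope * xm),
            class = "step_trend")
}

#' @export
print.step_trend <- function(x, ...) {
  cat(sprintf("step-size trend: slope %.4g +- %.4g per um (p = %.3g)\n",
              x$slope, x$slope_se, x$p))
  invisible(x)
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic seed splitting so that each pipeline stage (or bootstrap
#' replica) draws from an independent, reproducible stream; adding a stage
#' does not perturb the others. Result is a positive 32-bit integer.
#'
#' @param seed master seed (integer)
#' @param label stage label (character)
#' @return derived integer seed
#' @export
split_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 2147483629
  s <- (as.numeric(seed) * 48271 + h) %% 2147483647
  as.integer(s + (s == 0))
}
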