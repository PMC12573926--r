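#' Raster-scan grid description
#'
#' Geometry and timing of a serpentine (boustrophedon) raster scan over a
#' sheet-on-sheet fixed target. The "fast" axis is stepped within a line,
#' the "slow" axis between lines; which laboratory axis is fast differs
#' between facilities, so it is stored explicitly.
#'
#' @param step_fast intra-line step (micrometre), > 0
#' @param step_slow inter-line step (micrometre), > 0
#' @param n_per_line exposures per line, >= 1
#' @param n_lines number of lines, >= 1
#' @param rate exposure rate (exposures per second), > 0.
#'   Typical values: 231.25 Hz (ID29-style SSX), 100 Hz (XFEL fixed target).
#' @param fast_axis `"x"` or `"y"`: laboratory axis of the fast direction
#' @return an object of class `scan_grid`
#' @export
scan_grid <- function(step_fast, step_slow, n_per_line, n_lines,
                      rate, fast_axis = c("x", "y")) {
  fast_axis <- match.arg(fast_axis)
  if (step_fast <= 0 || step_slow <= 0) stop("steps must be > 0")
  if (n_per_line < 1 || n_lines < 1) stop("counts must be >= 1")
  if (rate <= 0) stop("rate must be > 0")
  structure(list(step_fast = step_fast, step_slow = step_slow,
                 n_per_line = as.integer(n_per_line),
                 n_lines = as.integer(n_lines),
                 rate = rate, fast_axis = fast_axis),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("serpentine scan: %d lines x %d exposures, steps %g/%g um (fast=%s), %g Hz\n",
              x$n_lines, x$n_per_line, x$step_fast, x$step_slow, x$fast_axis, x$rate))
  invisible(x)
}

#' Build the serpentine exposure schedule
#'
#' Expands a [scan_grid()] into the ordered list of exposure events. The
#' origin is the first exposure; the first line runs in the +fast direction
#' and the direction alternates on every line. Times are `index / rate`
#' with a zero-based index.
#'
#' @param grid a `scan_grid`
#' @return data.frame with columns `index` (0-based), `x`, `y` (micrometre),
#'   `t` (seconds), `line`, `pos_in_line`
#' @export
build_serpentine_scan <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  n <- grid$n_lines * grid$n_per_line
  if (n < 1) stop("empty scan")
  line <- rep(seq_len(grid$n_lines) - 1L, each = grid$n_per_line)
  pos <- rep(seq_len(grid$n_per_line) - 1L, times = grid$n_lines)
  # reverse fast order on odd lines (0-based): serpentine
  fast_idx <- ifelse(line %% 2L == 0L, pos, grid$n_per_line - 1L - pos)
  fast <- fast_idx * grid$step_fast
  slow <- line * grid$step_slow
  idx <- seq_len(n) - 1L
  if (grid$fast_axis == "x") {
    x <- fast; y <- slow
  } else {
    x <- slow; y <- fast
  }
  data.frame(index = idx, x = x, y = y, t = idx / grid$rate,
             line = line, pos_in_line = pos)
}

#' Pairwise separations between exposures
#'
#' For every exposure, the distance and time lag to each earlier exposure
#' within a cut-off radius. The short end of the lag spectrum is the
#' in-line neighbour (`1/rate`); the long end, among spatial nearest
#' neighbours, links the first exposure of one line to the last exposure of
#' the next line (`(2 n_per_line - 1)/rate`).
#'
#' @param events event table from [build_serpentine_scan()]
#' @param max_radius only report pairs closer than this (micrometre); default Inf
#' @return data.frame with columns `i`, `j` (0-based indices, `j` earlier),
#'   `distance` (micrometre), `dt` (seconds)
#' @export
neighbor_separations <- function(events, max_radius = Inf) {
  n <- nrow(events)
  if (n < 2) return(data.frame(i = integer(), j = integer(),
                               distance = numeric(), dt = numeric()))
  ii <- rep(seq_len(n), times = seq_len(n) - 1L)
  jj <- unlist(lapply(seq_len(n), function(k) seq_len(k - 1L)), use.names = FALSE)
  dist <- sqrt((events$x[ii] - events$x[jj])^2 + (events$y[ii] - events$y[jj])^2)
  keep <- dist <= max_radius
  data.frame(i = events$index[ii][keep], j = events$index[jj][keep],
             distance = dist[keep], dt = events$t[ii][keep] - events$t[jj][keep])
}

#' Summarise time lags by distance class
#'
#' Min/max time lag among pairs, grouped by (rounded) pair distance.
#'
#' @param seps output of [neighbor_separations()]
#' @param digits rounding used to define distance classes
#' @return data.frame with `distance`, `n_pairs`, `min_dt`, `max_dt`
#' @export
separation_summary <- function(seps, digits = 6) {
  if (nrow(seps) == 0) return(data.frame(distance = numeric(), n_pairs = integer(),
                                         min_dt = numeric(), max_dt = numeric()))
  d <- round(seps$distance, digits)
  agg <- do.call(rbind, lapply(split(seps$dt, d), function(v)
    data.frame(n_pairs = length(v), min_dt = min(v), max_dt = max(v))))
  out <- data.frame(distance = as.numeric(rownames(agg)), agg, row.names = NULL)
  out[order(out$distance), ]
}

#' Damage spread model
#'
#' Radial spreading of irradiation products from an exposure site, either at
#' constant speed (`r = v t`) or diffusively (`r = sqrt(4 D t)`, the rms
#' radial scale of a 2-D diffusion kernel).
#'
#' @param mode `"constant_speed"` or `"diffusive"`
#' @param speed radial speed (micrometre/second), for `constant_speed`
#' @param diffusivity diffusion coefficient (micrometre^2/second), for `diffusive`
#' @return an object of class `spread_model`
#' @export
spread_model <- function(mode = c("constant_speed", "diffusive"),
                         speed = NULL, diffusivity = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant_speed") {
    if (is.null(speed) || speed < 0) stop("constant_speed mode needs speed >= 0")
    if (!is.null(diffusivity)) stop("exactly one mode parameter may be set")
  } else {
    if (is.null(diffusivity) || diffusivity < 0) stop("diffusive mode needs diffusivity >= 0")
    if (!is.null(speed)) stop("exactly one mode parameter may be set")
  }
  structure(list(mode = mode, speed = speed, diffusivity = diffusivity),
            class = "spread_model")
}

#' Spread radius after a time lag
#'
#' @param model a [spread_model()]
#' @param t elapsed time (seconds), >= 0; vectorised
#' @return radius (micrometre); monotone non-decreasing in `t`, 0 at `t = 0`
#' @export
spread_radius <- function(model, t) {
  stopifnot(inherits(model, "spread_model"))
  if (any(t < 0)) stop("negative time")
  if (model$mode == "constant_speed") model$speed * t else sqrt(4 * model$diffusivity * t)
}

#' Fraction of exposures reached by spread from earlier exposures
#'
#' An exposure is "affected" if its position lies within
#' `spread_radius(t_now - t_earlier)` of at least one earlier exposure.
#' Evaluated at the exposure instants only (discrete schedule, no
#' continuous-time accumulation).
#'
#' @param events time-ordered event table
#' @param model a [spread_model()]
#' @return fraction in \[0, 1\]
#' @export
affected_fraction <- function(events, model) {
  n <- nrow(events)
  if (n < 2) return(0)
  o <- order(events$t)
  events <- events[o, ]
  hit <- logical(n)
  for (i in 2:n) {
    dt <- events$t[i] - events$t[1:(i - 1)]
    r <- spread_radius(model, dt)
    d2 <- (events$x[i] - events$x[1:(i - 1)])^2 + (events$y[i] - events$y[1:(i - 1)])^2
    if (any(d2 <= r^2)) hit[i] <- TRUE
  }
  mean(hit)
}

#' Crystal size model
#'
#' Size distribution of crystals in the chip plane (modelled as discs).
#'
#' @param mean_diameter mean diameter (micrometre), > 0
#' @param sd standard deviation of the diameter (micrometre), >= 0
#' @param distribution `"lognormal"` (default) or `"normal_truncated"`
#'   (normal truncated at zero)
#' @return an object of class `crystal_size_model`
#' @export
crystal_size_model <- function(mean_diameter = 20, sd = 8,
                               distribution = c("lognormal", "normal_truncated")) {
  distribution <- match.arg(distribution)
  if (mean_diameter <= 0) stop("mean_diameter must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(mean_diameter = mean_diameter, sd = sd,
                 distribution = distribution),
            class = "crystal_size_model")
}

draw_diameters <- function(model, n) {
  if (model$sd == 0) return(rep(model$mean_diameter, n))
  if (model$distribution == "lognormal") {
    # match mean and sd on the natural scale
    cv2 <- (model$sd / model$mean_diameter)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(model$mean_diameter) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  } else {
    d <- stats::rnorm(n, model$mean_diameter, model$sd)
    while (any(d <= 0)) d[d <= 0] <- stats::rnorm(sum(d <= 0), model$mean_diameter, model$sd)
    d
  }
}

#' Monte-Carlo multiple-hit fraction
#'
#' Fraction of illuminated crystals intersected by two or more beam
#' positions. Crystals are discs scattered uniformly over the scanned area
#' (padded by one diameter so edge effects cancel); the beam is a point
#' unless `beam_diameter` is set.
#'
#' @param grid a [scan_grid()]
#' @param crystals a [crystal_size_model()]
#' @param n_sim number of simulated crystals, >= 1
#' @param seed RNG seed
#' @param beam_diameter beam diameter (micrometre), default 0 (point beam)
#' @return fraction in \[0, 1\]; deterministic under a fixed seed
#' @export
multi_hit_fraction <- function(grid, crystals, n_sim = 10000, seed = 1,
                               beam_diameter = 0) {
  stopifnot(n_sim >= 1)
  events <- build_serpentine_scan(grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pad <- crystals$mean_diameter + 4 * crystals$sd + beam_diameter
  xr <- range(events$x) + c(-pad, pad)
  yr <- range(events$y) + c(-pad, pad)
  cx <- stats::runif(n_sim, xr[1], xr[2])
  cy <- stats::runif(n_sim, yr[1], yr[2])
  dia <- draw_diameters(crystals, n_sim)
  r_eff <- dia / 2 + beam_diameter / 2
  hits <- integer(n_sim)
  for (k in seq_len(nrow(events))) {
    d2 <- (cx - events$x[k])^2 + (cy - events$y[k])^2
    hits <- hits + (d2 <= r_eff^2)
  }
  illuminated <- hits >= 1L
  if (!any(illuminated)) return(0)
  mean(hits[illuminated] >= 2L)
}

#' Temperature increment from an instantaneous heat source
#'
#' Conduction kernel for the heat deposited by one exposure, evaluated at
#' distance `r` and delay `t`. The 3-D point-source kernel is
#' `dT = E / (rho c (4 pi kappa t)^{3/2}) exp(-r^2 / (4 kappa t))`;
#' the 2-D variant treats the deposit as a line source through a sheet of
#' the given thickness. This kernel is a documented stand-in for a full
#' heterogeneous-medium heat-transport calculation.
#'
#' @param deposited_energy energy deposited (joule)
#' @param distance distance from the source (micrometre)
#' @param t elapsed time (seconds)
#' @param medium list with `density` (kg/m^3), `heat_capacity` (J/(kg K)),
#'   `diffusivity` (m^2/s). Default: water-like.
#' @param kernel `"point3d"` (default) or `"sheet2d"`
#' @param sheet_thickness sheet thickness (micrometre), used by `"sheet2d"`
#' @return temperature increase (kelvin)
#' @export
thermal_increment <- function(deposited_energy, distance, t,
                              medium = list(density = 1000,
                                            heat_capacity = 4184,
                                            diffusivity = 1.43e-7),
                              kernel = c("point3d", "sheet2d"),
                              sheet_thickness = 10) {
  kernel <- match.arg(kernel)
  if (any(unlist(medium) <= 0)) stop("physical parameters must be > 0")
  if (deposited_energy < 0) stop("energy must be >= 0")
  if (t < 0) stop("negative time")
  r <- distance * 1e-6                     # micrometre -> metre
  if (t == 0) {
    if (any(r == 0)) stop("singular input: t = 0 at the source point")
    return(rep(0, length(r))[seq_along(r)])
  }
  rho <- medium$density; cp <- medium$heat_capacity; kap <- medium$diffusivity
  gauss <- exp(-r^2 / (4 * kap * t))
  if (kernel == "point3d") {
    deposited_energy / (rho * cp * (4 * pi * kap * t)^1.5) * gauss
  } else {
    h <- sheet_thickness * 1e-6
    deposited_energy / (rho * cp * h * (4 * pi * kap * t)) * gauss
  }
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
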