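#' Generation recipe for synthetic snapshot image sets
#'
#' Bundles every knob of the snapshot generator. Defaults describe a
#' well-behaved serial dataset: one cell population, moderate per-image
#' scale spread, 10% relative noise, no detector saturation.
#'
#' @param n_images number of snapshot images
#' @param reflections_per_image fraction of the full HKL list observed on
#'   each image (uniform random subset; partiality is not modelled because
#'   Monte-Carlo merging averages over it identically)
#' @param planted_B extra Wilson-type attenuation planted on intensities
#'   (Angstrom^2), `I ~ exp(-B s^2 / 2)`; on top of the structure's atomic B
#' @param noise_sd additive Gaussian noise, as a fraction of each true
#'   intensity
#' @param scale_sd sigma of the lognormal per-image scale factor
#' @param fraction_large_cell probability that an image comes from the
#'   expanded-cell population
#' @param large_cell diverging cell of the second population (default
#'   [large_cell()])
#' @param large_cell_extra_B additional attenuation (Angstrom^2) applied to
#'   large-cell images, emulating their weaker high-resolution diffraction
#' @param clip_cap saturate intensities at this cap (`NULL` = no clipping)
#' @param resolution_limit high-resolution cutoff of the HKL list (Angstrom)
#' @param intensity_model `"structure"` (default): baseline intensities are
#'   `|F_calc|^2` of the toy structure; `"wilson"`: the crystal's true
#'   intensities are drawn once per unique reflection from the acentric
#'   Wilson (exponential) distribution with mean `sum(f^2)`, giving
#'   `<I> ~ exp(-B s^2/2)` exactly - the right baseline when Wilson-B
#'   recovery itself is under test
#' @param seed RNG seed; generation is a pure function of
#'   (structure, recipe)
#' @return list of class `generation_recipe`
#' @export
generation_recipe <- function(n_images = 100, reflections_per_image = 0.3,
                              planted_B = 0, noise_sd = 0.1, scale_sd = 0.3,
                              fraction_large_cell = 0,
                              large_cell = NULL, large_cell_extra_B = 15,
                              clip_cap = NULL, resolution_limit = 1.8,
                              intensity_model = c("structure", "wilson"),
                              seed = 1) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(n_images >= 1,
            reflections_per_image > 0, reflections_per_image <= 1,
            planted_B >= 0, noise_sd >= 0, scale_sd >= 0,
            fraction_large_cell >= 0, fraction_large_cell <= 1,
            resolution_limit > 0)
  structure(list(n_images = as.integer(n_images),
                 reflections_per_image = reflections_per_image,
                 planted_B = planted_B, noise_sd = noise_sd,
                 scale_sd = scale_sd,
                 fraction_large_cell = fraction_large_cell,
                 large_cell = large_cell,
                 large_cell_extra_B = large_cell_extra_B,
                 clip_cap = clip_cap, resolution_limit = resolution_limit,
                 intensity_model = intensity_model, seed = seed),
            class = "generation_recipe")
}

#' Simulate a set of snapshot images
#'
#' Forward-simulates partial still-diffraction snapshots from a toy
#' structure: each image carries a uniform random subset of the full
#' Friedel-unique HKL list, with
#' `I = scale * |F_calc|^2 * exp(-planted_B s^2 / 2) + noise`,
#' per-image lognormal scale, optional second (expanded) cell population
#' with extra attenuation, and optional saturation clipping. The true
#' per-image scale and population are retained for oracles.
#'
#' @param structure a `toy_structure`
#' @param recipe a [generation_recipe()]
#' @return list of image records, each a list with `image_id`, `cell`
#'   (a `unit_cell`), `obs` (data.frame h, k, l, I, sigma), `true_scale`,
#'   `population` (`"small"` or `"large"`)
#' @export
simulate_image_set <- function(structure, recipe = generation_recipe()) {
  stopifnot(inherits(recipe, "generation_recipe"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(recipe$seed)
  small <- structure$cell
  big <- if (is.null(recipe$large_cell)) {
    if (recipe$fraction_large_cell > 0) scaled_large_cell(small) else small
  } else recipe$large_cell
  hkls <- hkl_sphere(small, recipe$resolution_limit)
  Ic <- if (recipe$intensity_model == "wilson") {
    stats::rexp(nrow(hkls), rate = 1 / sum(form_factor(structure$atoms$element)^2))
  } else {
    Mod(calc_structure_factors(structure, hkls))^2
  }
  s2_small <- 1 / hkls$d^2
  s2_big <- 1 / d_spacing(as.matrix(hkls[, c("h", "k", "l")]), big)^2
  base_small <- Ic * exp(-recipe$planted_B * s2_small / 2)
  base_big <- Ic * exp(-(recipe$planted_B + recipe$large_cell_extra_B) * s2_big / 2)
  sig_floor <- 1e-6 * stats::median(base_small[base_small > 0])
  n_refl <- nrow(hkls)
  lapply(seq_len(recipe$n_images), function(i) {
    is_large <- stats::runif(1) < recipe$fraction_large_cell
    keep <- which(stats::runif(n_refl) < recipe$reflections_per_image)
    if (!length(keep)) keep <- sample.int(n_refl, 1)
    sc <- if (recipe$scale_sd > 0) stats::rlnorm(1, 0, recipe$scale_sd) else 1
    I_true <- sc * (if (is_large) base_big[keep] else base_small[keep])
    sd_noise <- recipe$noise_sd * abs(I_true)
    I <- I_true + if (recipe$noise_sd > 0) stats::rnorm(length(keep), 0, sd_noise) else 0
    if (!is.null(recipe$clip_cap)) I <- pmin(I, recipe$clip_cap)
    list(image_id = sprintf("img%05d", i),
         cell = if (is_large) big else small,
         obs = data.frame(h = hkls$h[keep], k = hkls$k[keep], l = hkls$l[keep],
                          I = I, sigma = pmax(sd_noise, sig_floor)),
         true_scale = sc,
         population = if (is_large) "large" else "small")
  })
}

# expanded-cell population for toy cells: the reference small/large
# monoclinic pair scaled onto this cell's axes
scaled_large_cell <- function(cell) {
  s <- small_cell(); l <- large_cell()
  unit_cell(cell$a * l$a / s$a, cell$b * l$b / s$b, cell$c * l$c / s$c,
            alpha = cell$alpha,
            beta = cell$beta + (l$beta - s$beta),
            gamma = cell$gamma)
}
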