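test_that("mc_merge averages observations per unique reflection", {
  hkl <- cbind(1, 2, 3)
  im1 <- tiny_image("a", hkl, 10)
  im2 <- tiny_image("b", hkl, 20)
  m <- mc_merge(list(im1, im2))
  expect_equal(nrow(m$entries), 1)
  expect_equal(m$entries$mean_I, 15)
  expect_equal(m$entries$redundancy, 2)
  expect_equal(m$entries$sem_I, sd(c(10, 20)) / sqrt(2))
  expect_equal(m$entries$d, d_spacing(hkl, im1$cell))

  # noiseless identical images merge to any single image
  st <- make_toy_structure(n_bystander = 2)
  rec <- generation_recipe(n_images = 4, reflections_per_image = 1,
                           noise_sd = 0, scale_sd = 0,
                           resolution_limit = 2.5, seed = 2)
  ims <- simulate_image_set(st, rec)
  mg <- mc_merge(ims)
  one <- ims[[1]]$obs
  idx <- match(paste(mg$entries$h, mg$entries$k, mg$entries$l),
               paste(one$h, one$k, one$l))
  expect_equal(mg$entries$mean_I, one$I[idx], tolerance = 1e-12)

  # permutation invariance
  mg_perm <- mc_merge(rev(ims))
  expect_equal(mg$entries, mg_perm$entries)
})

test_that("per-shell mean intensity follows the planted exponential decay", {
  st <- make_toy_structure()
  rec <- generation_recipe(n_images = 40, reflections_per_image = 0.5,
                           planted_B = 18, noise_sd = 0, scale_sd = 0,
                           resolution_limit = 1.8,
                           intensity_model = "wilson", seed = 8)
  mg <- mc_merge(simulate_image_set(st, rec))
  sh <- shell_statistics(mg, n_shells = 12)
  x <- (1 / sh$d_max^2 + 1 / sh$d_min^2) / 2
  fit <- lm(log(sh$mean_I) ~ x)
  expect_equal(-2 * unname(coef(fit)[2]), 18, tolerance = 0.15)
})

test_that("sem shrinks as 1/sqrt(redundancy) on homogeneous data", {
  # hand-built images: reflection class r observed in the first r images
  set.seed(42)
  reds <- c(2, 4, 8, 16, 32, 64)
  n_per <- 30
  cell <- unit_cell(30, 30, 30)
  hkl_all <- hkl_sphere(cell, 2)[seq_len(length(reds) * n_per), c("h", "k", "l")]
  cls <- rep(reds, each = n_per)
  images <- lapply(1:64, function(i) {
    sel <- which(cls >= i)
    tiny_image(paste0("im", i), as.matrix(hkl_all[sel, ]),
               I = 100 + rnorm(length(sel), 0, 10), cell = cell)
  })
  m <- mc_merge(images)
  ent <- as.data.frame(m$entries)
  agg <- aggregate(sem_I ~ redundancy, ent, mean)
  fit <- lm(log(agg$sem_I) ~ log(agg$redundancy))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("symmetry folding merges equivalents and never adds uniques", {
  cell <- unit_cell(10, 12, 14, beta = 100)
  im <- tiny_image("a", rbind(c(1, 2, 3), c(-1, 2, -3), c(-1, -2, -3), c(2, 0, 1)),
                   I = c(10, 14, 18, 5), cell = cell)
  p1 <- mc_merge(list(im), symmetry = "P1")
  m2 <- mc_merge(list(im), symmetry = "monoclinic_2")
  expect_equal(nrow(p1$entries), 4)
  expect_equal(nrow(m2$entries), 2)
  expect_lte(nrow(m2$entries), nrow(p1$entries))
  folded <- m2$entries[m2$entries$redundancy == 3, ]
  expect_equal(folded$mean_I, mean(c(10, 14, 18)))
})

test_that("inconsistent cells abort the merge with a clustering hint", {
  imA <- tiny_image("a", cbind(1, 0, 0), 10, cell = small_cell())
  imB <- tiny_image("b", cbind(1, 0, 0), 12, cell = large_cell())
  expect_error(mc_merge(list(imA, imB)), "cluster_cells")
})

test_that("shell statistics partition reflections and track completeness", {
  st <- make_toy_structure(n_bystander = 2)
  rec <- generation_recipe(n_images = 4, reflections_per_image = 1,
                           noise_sd = 0, scale_sd = 0,
                           resolution_limit = 2.2, seed = 2)
  mg <- mc_merge(simulate_image_set(st, rec))
  sh <- shell_statistics(mg, n_shells = 8)
  expect_equal(sum(sh$n_refl), nrow(mg$entries))
  # a complete synthetic sphere is complete in every shell
  expect_true(all(sh$completeness > 0.999))
  # single shell reproduces global means
  g <- shell_statistics(mg, n_shells = 1)
  expect_equal(g$mean_I, mean(mg$entries$mean_I))
  expect_equal(g$n_refl, nrow(mg$entries))
  expect_error(shell_statistics(mg, n_shells = nrow(mg$entries) + 1), "shells")
})

test_that("snr_resolution interpolates the threshold crossing", {
  sh <- data.frame(d_max = c(20, 3, 2.4, 2.1), d_min = c(3, 2.4, 2.1, 1.9),
                   mean_I = c(100, 50, 20, 8),
                   mean_I_over_sigma = c(10, 5, 2, 0.8),
                   n_refl = 100, completeness = 1)
  class(sh) <- c("shell_table", "data.frame")
  res <- snr_resolution(sh, 1.0)
  expect_false(res$geometry_limited)
  expect_gt(res$d, 1.9); expect_lt(res$d, 2.25)
  # never crossed: geometry-limited at the best edge
  res4 <- snr_resolution(sh, 0.5)
  expect_true(res4$geometry_limited)
  expect_equal(res4$d, 1.9)
  # analytic crossing of a planted linear decay in 1/d^2
  x <- seq(0.05, 0.45, length.out = 9)
  y <- 12 - 25 * x                       # crosses 1 at x = 11/25
  shl <- data.frame(d_max = 1 / sqrt(x - 0.024), d_min = 1 / sqrt(x + 0.026),
                    mean_I = 1, mean_I_over_sigma = y, n_refl = 10,
                    completeness = 1)
  # shell centres in 1/d^2 equal x by construction up to rounding; rebuild
  shl$d_max <- 1 / sqrt(x - 0.025); shl$d_min <- 1 / sqrt(x + 0.025)
  class(shl) <- c("shell_table", "data.frame")
  out <- snr_resolution(shl, 1.0)
  expect_equal(1 / out$d^2, 11 / 25, tolerance = 1e-6)
})

test_that("clipping_report counts saturated observations", {
  st <- make_toy_structure(n_bystander = 2)
  rec <- generation_recipe(n_images = 10, reflections_per_image = 0.8,
                           noise_sd = 0, scale_sd = 0,
                           resolution_limit = 2.2, seed = 6)
  ims <- simulate_image_set(st, rec)
  allI <- unlist(lapply(ims, function(im) im$obs$I))
  expect_equal(clipping_report(ims, max(allI) * 2)$clipped_fraction, 0)
  cap <- unname(quantile(allI, 0.5))
  rec_c <- generation_recipe(n_images = 10, reflections_per_image = 0.8,
                             noise_sd = 0, scale_sd = 0, clip_cap = cap,
                             resolution_limit = 2.2, seed = 6)
  ims_c <- simulate_image_set(st, rec_c)
  rep <- clipping_report(ims_c, cap)
  expect_equal(rep$clipped_fraction, 0.5, tolerance = 0.02)
  expect_true(all(rep$per_shell$clipped_fraction >= 0, na.rm = TRUE))
})

test_that("clipping flattens the low-resolution end of the Wilson plot", {
  st <- make_toy_structure()
  base <- list(n_images = 40, reflections_per_image = 0.4, planted_B = 25,
               noise_sd = 0.05, scale_sd = 0, resolution_limit = 1.8,
               intensity_model = "wilson", seed = 31)
  mg_u <- mc_merge(simulate_image_set(st, do.call(generation_recipe, base)))
  allI <- unlist(lapply(simulate_image_set(st, do.call(generation_recipe, base)),
                        function(im) im$obs$I))
  base$clip_cap <- unname(quantile(allI, 0.7))
  mg_c <- mc_merge(simulate_image_set(st, do.call(generation_recipe, base)))
  B_u <- wilson_observed(mg_u, n_bins = 25)$B
  B_c <- suppressWarnings(wilson_observed(mg_c, n_bins = 25)$B)
  expect_lt(B_c, B_u)   # clipping biases the fitted B downward
})
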