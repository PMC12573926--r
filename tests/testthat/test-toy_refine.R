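test_that("structure factors reproduce closed-form special cases", {
  cell <- unit_cell(10, 10, 10)
  one <- toy_structure(data.frame(role = "BYSTANDER", element = "C", name = "CA",
                                  resname = "GLY", resno = 1L, chain = "A",
                                  x = 0, y = 0, z = 0, b = 0, occ = 1),
                       cell)
  hkls <- hkl_sphere(cell, 2)
  F1 <- calc_structure_factors(one, hkls)
  expect_equal(Mod(F1), rep(6, nrow(hkls)), tolerance = 1e-12)

  # two identical atoms at x = 0 and x = 1/2: systematic absence for odd h00
  two <- toy_structure(data.frame(role = "BYSTANDER", element = "C",
                                  name = c("C1", "C2"), resname = "GLY",
                                  resno = 1:2, chain = "A",
                                  x = c(0, 5), y = 0, z = 0, b = 0, occ = 1),
                       cell)
  h00 <- data.frame(h = 1:5, k = 0, l = 0)
  F2 <- calc_structure_factors(two, h00)
  expect_equal(Mod(F2)[c(1, 3, 5)], rep(0, 3), tolerance = 1e-10)
  expect_equal(Mod(F2)[c(2, 4)], rep(12, 2), tolerance = 1e-10)

  # B attenuation ratio between two reflections: exp(-B (s1^2 - s2^2)/4)
  oneB <- one; oneB$atoms$b <- 37
  q <- data.frame(h = c(1, 3), k = 0, l = 0)
  s2 <- 1 / d_spacing(as.matrix(q), cell)^2
  FB <- calc_structure_factors(oneB, q)
  expect_equal(Mod(FB)[1] / Mod(FB)[2], exp(-37 * (s2[1] - s2[2]) / 4),
               tolerance = 1e-12)

  far <- one; far$atoms$x <- 1e4
  expect_error(calc_structure_factors(far, hkls), "sanity")
})

test_that("scramble displaces coordinates by the Maxwell-distributed amount", {
  st <- random_uniform_structure(n_atoms = 600, seed = 2)
  expect_identical(scramble(st, 0), st)
  expect_identical(scramble(st, 0.3, seed = 7), scramble(st, 0.3, seed = 7))
  sc <- scramble(st, 0.3, seed = 7)
  disp <- sqrt(rowSums((atom_xyz_test(sc) - atom_xyz_test(st))^2))
  # oracle: mean of |N(0, 0.3^2 I_3)| by direct Monte Carlo
  set.seed(99)
  oracle <- mean(sqrt(rowSums(matrix(rnorm(3e5, 0, 0.3), ncol = 3)^2)))
  expect_equal(mean(disp), oracle, tolerance = 0.05)
  # and the closed form sd * sqrt(8/pi)
  expect_equal(oracle, 0.3 * sqrt(8 / pi), tolerance = 0.01)
})

test_that("analytic Jacobian matches finite differences", {
  st <- random_uniform_structure(n_atoms = 5, cell = unit_cell(12, 13, 14),
                                 b = 8, seed = 3)
  st$atoms$occ <- runif(5, 0.5, 1)
  cell <- st$cell
  hkls <- hkl_sphere(cell, 3)[1:40, ]
  H <- as.matrix(hkls[, c("h", "k", "l")])
  Minv <- solve(cell_orth_matrix(cell))
  s2 <- 1 / d_spacing(H, cell)^2
  active <- list(positions = TRUE, b = TRUE, occ = TRUE)
  pack <- sosdamage:::.pack_parameters(st, 1.3, active)
  ev <- sosdamage:::.refine_model(pack, st, H, Minv, s2, active)
  eps <- 1e-6
  for (j in sample(seq_along(pack), 12)) {
    up <- pack; up[j] <- up[j] + eps
    dn <- pack; dn[j] <- dn[j] - eps
    num <- (sosdamage:::.refine_model(up, st, H, Minv, s2, active)$model -
            sosdamage:::.refine_model(dn, st, H, Minv, s2, active)$model) / (2 * eps)
    scale_ref <- max(abs(num), abs(ev$J[, j]), 1e-8)
    expect_lt(max(abs(num - ev$J[, j])) / scale_ref, 1e-5)
  }
})

test_that("refinement recovers the truth and never increases the residual", {
  st <- make_toy_structure(n_bystander = 6)
  rec <- generation_recipe(n_images = 6, reflections_per_image = 1,
                           noise_sd = 0, scale_sd = 0,
                           resolution_limit = 2.0, seed = 13)
  merged <- mc_merge(simulate_image_set(st, rec))

  # start at truth: immediate convergence, essentially zero shift
  r0 <- refine(st, merged, refinement_options(max_iter = 5))
  expect_true(r0$converged)
  expect_lte(r0$n_iter, 2)
  expect_lt(max_coord_error(r0$structure, st), 1e-9)

  # scrambled start (0.3 A), noiseless data: recovery to < 1e-3 A
  r1 <- refine(st, merged, refinement_options(scramble_sd = 0.3, seed = 5,
                                              max_iter = 80,
                                              convergence_tol = 1e-10))
  expect_true(r1$converged)
  expect_lt(max_coord_error(r1$structure, st), 1e-3)
  # residual non-increasing over accepted steps
  expect_true(all(diff(r1$trace$residual) <= 1e-12))

  # underdetermined system is refused
  few <- merged
  few$entries <- merged$entries[1:10, ]
  expect_error(refine(st, few), "underdetermined")
})

test_that("positional spread shrinks with image count under noise", {
  st <- make_toy_structure(n_bystander = 2)
  fe_wat_for <- function(n_images, seed) {
    rec <- generation_recipe(n_images = n_images, reflections_per_image = 0.6,
                             noise_sd = 0.15, scale_sd = 0.1,
                             resolution_limit = 2.2, seed = seed)
    merged <- mc_merge(simulate_image_set(st, rec))
    r <- refine(st, merged, refinement_options(scramble_sd = 0.1, seed = seed,
                                               max_iter = 40,
                                               convergence_tol = 1e-8))
    heme_report(r$structure)$fe_wat
  }
  v_small <- vapply(1:8, function(s) fe_wat_for(5, 100 + s), 0)
  v_large <- vapply(1:8, function(s) fe_wat_for(40, 200 + s), 0)
  expect_lt(sd(v_large), sd(v_small))
  # median refined error stays well below the scramble it started from
  truth <- heme_report(st)$fe_wat
  expect_lt(median(abs(v_large - truth)), 0.1)
})

test_that("two-state water occupancies are recovered and track dose monotonically", {
  simulate_for_occ <- function(q, seed = 50) {
    truth <- two_state_structure(occ_pos1 = q)
    rec <- generation_recipe(n_images = 6, reflections_per_image = 1,
                             noise_sd = 0, scale_sd = 0,
                             resolution_limit = 2.0, seed = seed)
    mc_merge(simulate_image_set(truth, rec))
  }
  start <- two_state_structure(occ_pos1 = 0.5)

  r1 <- refine_two_state_water(start, simulate_for_occ(1))
  expect_equal(r1$occ_pos1, 1, tolerance = 1e-3)
  expect_equal(r1$occ_pos2, 0, tolerance = 1e-3)
  expect_equal(r1$occ_watx, 1, tolerance = 1e-3)

  r7 <- refine_two_state_water(start, simulate_for_occ(0.7))
  expect_equal(r7$occ_pos1, 0.7, tolerance = 0.05)

  # independent mode agrees at this noiseless fixture
  ri <- refine_two_state_water(start, simulate_for_occ(0.7), mode = "independent")
  expect_equal(ri$occ_pos1, 0.7, tolerance = 0.05)

  # monotone planted dose schedule -> monotone recovered occupancies
  sched <- c(0.95, 0.8, 0.6, 0.4, 0.2)
  rec_occ <- vapply(seq_along(sched), function(i)
    refine_two_state_water(start, simulate_for_occ(sched[i], seed = 60 + i))$occ_pos1,
    0)
  expect_true(all(diff(rec_occ) < 0))

  bad <- make_toy_structure()
  rec <- generation_recipe(n_images = 2, resolution_limit = 2.5, seed = 1)
  expect_error(refine_two_state_water(bad, mc_merge(simulate_image_set(bad, rec))),
               "WAT_POS1")
})
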