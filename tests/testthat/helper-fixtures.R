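# Shared fixtures, all generated in code at test time.

# structure with atoms placed i.i.d. uniform over the whole cell: the
# expected |F|^2 is then flat in resolution (no molecular-transform
# structure), the right baseline for Wilson-fit checks
random_uniform_structure <- function(n_atoms = 40, cell = unit_cell(22, 24, 26),
                                     b = 0, seed = 1, element = "C") {
  set.seed(seed)
  O <- cell_orth_matrix(cell)
  frac <- matrix(runif(3 * n_atoms), ncol = 3)
  xyz <- t(O %*% t(frac))
  toy_structure(data.frame(
    role = "BYSTANDER", element = element, name = "CA", resname = "GLY",
    resno = seq_len(n_atoms), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b, occ = 1,
    stringsAsFactors = FALSE), cell)
}

# minimal hand-built image: one cell, explicit observations
tiny_image <- function(id, hkl, I, sigma = 1, cell = unit_cell(10, 10, 10)) {
  list(image_id = id, cell = cell,
       obs = data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                        I = I, sigma = sigma),
       true_scale = 1, population = "small")
}

# place a point at given distances from two anchors (in the plane spanned
# by the anchors and an out-of-plane direction); used to build H-bond
# partners with exact distances
point_at_distances <- function(p1, p2, d1, d2) {
  u <- p2 - p1
  L <- sqrt(sum(u^2))
  u <- u / L
  x <- (L^2 + d1^2 - d2^2) / (2 * L)
  h2 <- d1^2 - x^2
  stopifnot(h2 >= 0)
  # any perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  p1 + x * u + sqrt(h2) * v
}

# SYNTHETIC stand-in for a deposited heme-site neighbourhood (the real
# deposited entries are not redistributable here): water-ligated heme with
# WatX, an Arg NH1 hydrogen-bonded to the heme water and an Asp carboxylate
# bridging both waters, every distance planted exactly
synthetic_site_structure <- function(fe_wat = 2.45, wat_watx = 2.7,
                                     wat_arg = 2.7, wat_asp = 2.9,
                                     watx_asp = 2.6, chain = "A",
                                     fe_wat_watx_angle = 117) {
  st <- make_toy_structure(fe_wat = fe_wat, wat_watx = wat_watx,
                           fe_wat_watx_angle = fe_wat_watx_angle,
                           n_bystander = 0)
  a <- st$atoms
  wat <- as.numeric(a[a$role == "WAT_O", c("x", "y", "z")])
  watx <- as.numeric(a[a$role == "WATX_O", c("x", "y", "z")])
  fe <- as.numeric(a[a$role == "FE", c("x", "y", "z")])
  # Arg NH1 at wat_arg from the heme water, off to the side
  dir <- c(-0.5, 0.8, 0.34); dir <- dir / sqrt(sum(dir^2))
  arg <- wat + wat_arg * dir
  asp <- point_at_distances(wat, watx, wat_asp, watx_asp)
  extra <- data.frame(
    role = "UNASSIGNED",
    element = c("N", "O"),
    name = c("NH1", "OD1"),
    resname = c("ARG", "ASP"),
    resno = c(342L, 239L),
    chain = chain,
    x = c(arg[1], asp[1]), y = c(arg[2], asp[2]), z = c(arg[3], asp[3]),
    b = 10, occ = 1, stringsAsFactors = FALSE)
  a$chain <- chain
  toy_structure(rbind(a, extra), st$cell)
}

# two-conformer water fixture: the distal water in two alternative
# positions plus WatX, occupancies to be refined
two_state_structure <- function(occ_pos1 = 1, pos2_offset = c(0.5, 0.4, 0.9)) {
  st <- make_toy_structure(n_bystander = 4)
  a <- st$atoms
  iw <- which(a$role == "WAT_O")
  a$role[iw] <- "WAT_POS1"
  a$occ[iw] <- occ_pos1
  pos2 <- as.numeric(a[iw, c("x", "y", "z")]) + pos2_offset
  a <- rbind(a, data.frame(role = "WAT_POS2", element = "O", name = "O",
                           resname = "HOH", resno = 503L, chain = "A",
                           x = pos2[1], y = pos2[2], z = pos2[3],
                           b = a$b[iw], occ = 1 - occ_pos1,
                           stringsAsFactors = FALSE))
  a$occ[a$role == "WATX_O"] <- occ_pos1
  toy_structure(a, st$cell)
}

# independent brute-force oracle for affected_fraction: literal double loop
oracle_affected_fraction <- function(events, radius_fun) {
  n <- nrow(events)
  hit <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (events$t[j] < events$t[i]) {
        d <- sqrt((events$x[i] - events$x[j])^2 + (events$y[i] - events$y[j])^2)
        if (d <= radius_fun(events$t[i] - events$t[j])) { hit <- hit + 1L; break }
      }
    }
  }
  hit / n
}

atom_xyz_test <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

max_coord_error <- function(s1, s2) {
  max(abs(as.matrix(s1$atoms[, c("x", "y", "z")]) -
          as.matrix(s2$atoms[, c("x", "y", "z")])))
}
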