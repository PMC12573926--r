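#' Toy heme-site structure with known ground-truth geometry
#'
#' Builds a small atomic model of a heme-like active site in which every
#' geometric parameter reported by [heme_report()] takes a requested value
#' exactly: iron-to-distal-ligand distance (Fe-Wat), iron-to-proximal-
#' histidine distance (Fe-His), the signed iron-out-of-plane displacement
#' (FeOOP, positive toward the distal side), and optionally a diatomic
#' distal ligand with a given O-O separation and Fe-O-O angle. When the
#' distal ligand is a single water, a second water (WatX) is placed at the
#' requested hydrogen-bond distance and Fe-Wat-WatX angle.
#'
#' The porphyrin plane is represented by four pyrrole-type nitrogens placed
#' exactly coplanar at `plane_radius` from the heme axis. `n_bystander`
#' carbon atoms are scattered around the site (seeded) to give the
#' refinement engine a realistic number of parameters.
#'
#' @param fe_wat Fe to distal ligand O distance (Angstrom)
#' @param fe_his Fe to proximal His N distance (Angstrom); must exceed `feoop`
#' @param feoop signed iron-out-of-plane displacement (Angstrom), positive
#'   toward the distal ligand
#' @param o_o O-O distance of a diatomic distal ligand (Angstrom), or `NULL`
#'   for a single water + WatX
#' @param cell a [unit_cell()]; default a compact triclinic box
#' @param seed RNG seed for bystander placement
#' @param fe_o_o_angle Fe-O-O angle (degrees), diatomic mode only
#' @param fe_wat_watx_angle Fe-Wat-WatX angle (degrees), water mode only
#' @param wat_watx Wat to WatX distance (Angstrom), water mode only
#' @param n_bystander number of bystander C atoms
#' @param b_factor isotropic B assigned to every atom (Angstrom^2)
#' @param plane_radius Fe-axis to pyrrole N distance (Angstrom)
#' @return an object of class `toy_structure`: list with `atoms`
#'   (data.frame: role, element, name, resname, resno, chain, x, y, z, b, occ)
#'   and `cell`
#' @export
make_toy_structure <- function(fe_wat = 2.45, fe_his = 2.1, feoop = 0.3,
                               o_o = NULL, cell = unit_cell(18, 20, 22),
                               seed = 1,
                               fe_o_o_angle = 160, fe_wat_watx_angle = 117,
                               wat_watx = 2.7,
                               n_bystander = 8, b_factor = 10,
                               plane_radius = 2.0) {
  if (fe_wat <= 0 || fe_his <= 0) stop("distances must be > 0")
  if (!is.null(o_o) && o_o <= 0) stop("o_o must be > 0")
  if (feoop >= fe_his)
    stop("inconsistent geometry: feoop must be smaller than fe_his")
  th <- deg2rad(fe_wat_watx_angle)
  ang <- deg2rad(fe_o_o_angle)

  # site built around the heme axis (z), plane at z = 0, distal side = +z
  atoms <- list(
    list("PLANE", "N", "NA", "HEM", 401L, c(plane_radius, 0, 0)),
    list("PLANE", "N", "NB", "HEM", 401L, c(0, plane_radius, 0)),
    list("PLANE", "N", "NC", "HEM", 401L, c(-plane_radius, 0, 0)),
    list("PLANE", "N", "ND", "HEM", 401L, c(0, -plane_radius, 0)),
    list("FE", "FE", "FE", "HEM", 401L, c(0, 0, feoop)),
    list("HIS_N", "N", "NE2", "HIS", 326L, c(0, 0, feoop - fe_his))
  )
  if (is.null(o_o)) {
    wat <- c(0, 0, feoop + fe_wat)
    watx <- wat + wat_watx * c(sin(th), 0, -cos(th))
    atoms <- c(atoms, list(
      list("WAT_O", "O", "O", "HOH", 501L, wat),
      list("WATX_O", "O", "O", "HOH", 502L, watx)
    ))
  } else {
    o1 <- c(0, 0, feoop + fe_wat)
    o2 <- o1 + o_o * c(sin(ang), 0, -cos(ang))
    atoms <- c(atoms, list(
      list("DISTAL_O1", "O", "O1", "OOH", 502L, o1),
      list("DISTAL_O2", "O", "O2", "OOH", 502L, o2)
    ))
  }
  if (n_bystander > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    placed <- do.call(rbind, lapply(atoms, function(a) a[[6]]))
    i <- 0L
    while (i < n_bystander) {
      p <- stats::runif(3, -4.5, 4.5)
      if (min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 1.8) {
        i <- i + 1L
        atoms <- c(atoms, list(list("BYSTANDER", "C", "CA", "GLY", i, p)))
        placed <- rbind(placed, p)
      }
    }
  }
  xyz <- do.call(rbind, lapply(atoms, function(a) a[[6]]))
  # centre the site in the cell so every atom has sane fractional coordinates
  centre <- as.numeric(cell_orth_matrix(cell) %*% c(0.5, 0.5, 0.5))
  xyz <- sweep(xyz, 2, centre - colMeans(xyz), "+")
  df <- data.frame(
    role = vapply(atoms, function(a) a[[1]], ""),
    element = vapply(atoms, function(a) a[[2]], ""),
    name = vapply(atoms, function(a) a[[3]], ""),
    resname = vapply(atoms, function(a) a[[4]], ""),
    resno = vapply(atoms, function(a) as.integer(a[[5]]), 1L),
    chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = b_factor, occ = 1,
    stringsAsFactors = FALSE
  )
  toy_structure(df, cell)
}

#' Construct a toy_structure from an atom table
#'
#' @param atoms data.frame with columns role, element, name, resname, resno,
#'   chain, x, y, z, b, occ
#' @param cell a [unit_cell()]
#' @return object of class `toy_structure`
#' @export
toy_structure <- function(atoms, cell) {
  req <- c("role", "element", "name", "resname", "resno", "chain",
           "x", "y", "z", "b", "occ")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must be in [0, 1]")
  structure(list(atoms = atoms, cell = cell), class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("toy_structure: %d atoms (%s)\n", nrow(x$atoms),
              paste(unique(x$atoms$element), collapse = ", ")))
  print(x$cell)
  invisible(x)
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Ensemble of randomly displaced structures
#'
#' `n` copies of a structure with i.i.d. Gaussian displacement of every
#' Cartesian coordinate. Used to validate bootstrap standard deviations
#' against a known displacement model.
#'
#' @param structure a `toy_structure`
#' @param coord_sd per-coordinate displacement SD (Angstrom), >= 0
#' @param n number of copies
#' @param seed RNG seed; fixed seed gives bit-identical ensembles
#' @return list of `toy_structure`
#' @export
simulate_geometry_ensemble <- function(structure, coord_sd, n, seed = 1) {
  stopifnot(coord_sd >= 0, n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  na <- nrow(structure$atoms)
  lapply(seq_len(n), function(i) {
    s <- structure
    if (coord_sd > 0) {
      s$atoms$x <- s$atoms$x + stats::rnorm(na, 0, coord_sd)
      s$atoms$y <- s$atoms$y + stats::rnorm(na, 0, coord_sd)
      s$atoms$z <- s$atoms$z + stats::rnorm(na, 0, coord_sd)
    }
    s
  })
}
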