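#' Unit cell
#'
#' Construct a crystallographic unit cell. Lengths are in Angstrom, angles in
#' degrees. The monoclinic cells tracked by [cluster_cells()] have
#' `alpha = gamma = 90`.
#'
#' @param a,b,c cell edge lengths (Angstrom), `> 0`
#' @param alpha,beta,gamma cell angles (degrees), in `(0, 180)`
#' @return an object of class `unit_cell`
#' @examples
#' small_cell()
#' unit_cell(10, 12, 14)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Reference unit-cell populations
#'
#' The two monoclinic cell populations seen in fine-step fixed-target data:
#' a compact "normal" cell and an expanded one associated with lower-resolution
#' diffraction.
#'
#' @return a `unit_cell`
#' @export
small_cell <- function() unit_cell(73.4, 68.8, 75.9, 90, 105.7, 90)

#' @rdname small_cell
#' @export
large_cell <- function() unit_cell(75.0, 68.4, 77.6, 90, 107.6, 90)

deg2rad <- function(x) x * pi / 180

#' Orthogonalization matrix (columns are the cell vectors, Angstrom)
#'
#' Cartesian coordinates are `O %*% fractional`. Standard PDB convention:
#' a along x, b in the xy plane.
#' @param cell a `unit_cell`
#' @return 3x3 numeric matrix
#' @export
cell_orth_matrix <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma)); sg <- sin(deg2rad(cell$gamma))
  v <- sqrt(pmax(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3)
}

#' Cell volume in cubic Angstrom
#' @param cell a `unit_cell`
#' @export
cell_volume <- function(cell) abs(det(cell_orth_matrix(cell)))

#' Resolution of reflections
#'
#' d-spacing (Angstrom) of Miller indices in a given cell, from the
#' reciprocal metric: `1/d = |t(solve(O)) %*% hkl|`.
#'
#' @param hkl integer matrix with columns h, k, l (or a length-3 vector)
#' @param cell a `unit_cell`
#' @return numeric vector of d (Angstrom)
#' @export
d_spacing <- function(hkl, cell) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  astar <- t(solve(cell_orth_matrix(cell)))   # rows of t(): reciprocal vectors
  svec <- hkl %*% t(astar)                    # n x 3, units 1/Angstrom
  s <- sqrt(rowSums(svec^2))
  ifelse(s == 0, Inf, 1 / s)
}

#' Enumerate the full HKL list to a resolution limit
#'
#' All Miller indices (excluding 000) with `d >= d_min`, in the given cell.
#' Only the Friedel-unique half (first nonzero index positive) is returned
#' when `friedel_unique = TRUE`.
#'
#' @param cell a `unit_cell`
#' @param d_min resolution limit (Angstrom)
#' @param friedel_unique drop Friedel mates (default TRUE)
#' @return data.frame with columns h, k, l, d
#' @export
hkl_sphere <- function(cell, d_min, friedel_unique = TRUE) {
  stopifnot(d_min > 0)
  hmax <- ceiling(cell$a / d_min)
  kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  d <- d_spacing(as.matrix(grid), cell)
  keep <- d >= d_min
  grid <- grid[keep, ]; d <- d[keep]
  if (friedel_unique) {
    pos <- grid$h > 0 | (grid$h == 0 & (grid$k > 0 | (grid$k == 0 & grid$l > 0)))
    grid <- grid[pos, ]; d <- d[pos]
  }
  if (nrow(grid) == 0L) stop("empty HKL list: resolution limit too low for this cell")
  out <- data.frame(h = grid$h, k = grid$k, l = grid$l, d = d)
  rownames(out) <- NULL
  out
}

#' Convert 1/d^2 to resolution
#'
#' @param inv_d2 positive value(s) in 1/Angstrom^2
#' @return d in Angstrom, `1/sqrt(inv_d2)`
#' @examples
#' inv_d2_to_resolution(0.3)   # ~1.8 Angstrom
#' @export
inv_d2_to_resolution <- function(inv_d2) {
  if (any(!is.finite(inv_d2)) || any(inv_d2 <= 0))
    stop("inv_d2 must be positive")
  1 / sqrt(inv_d2)
}
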