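#' Read a PDB coordinate file
#'
#' Minimal fixed-column parser for ATOM/HETATM records plus CRYST1.
#' Only the first alternate location of each atom is kept unless
#' `altloc` names another one.
#'
#' @param path PDB file
#' @param altloc alternate-location indicator to keep (default: first seen,
#'   i.e. blank or "A")
#' @return a `toy_structure` whose atoms carry `role = "UNASSIGNED"`; use
#'   [assign_heme_roles()] or [read_coordinates()] for role tables
#' @export
read_pdb <- function(path, altloc = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cryst <- lines[startsWith(lines, "CRYST1")]
  cell <- if (length(cryst)) {
    unit_cell(as.numeric(substr(cryst[1], 7, 15)),
              as.numeric(substr(cryst[1], 16, 24)),
              as.numeric(substr(cryst[1], 25, 33)),
              as.numeric(substr(cryst[1], 34, 40)),
              as.numeric(substr(cryst[1], 41, 47)),
              as.numeric(substr(cryst[1], 48, 54)))
  } else unit_cell(100, 100, 100)
  at <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (!length(at)) stop("no parseable ATOM/HETATM records in ", path)
  num <- function(a, b) as.numeric(substr(at, a, b))
  df <- data.frame(
    role = "UNASSIGNED",
    element = trimws(substr(at, 77, 78)),
    name = trimws(substr(at, 13, 16)),
    altloc = substr(at, 17, 17),
    resname = trimws(substr(at, 18, 20)),
    resno = as.integer(substr(at, 23, 26)),
    chain = substr(at, 22, 22),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occ = num(55, 60), b = num(61, 66),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad))
    stop("malformed coordinates at ATOM/HETATM record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$element[df$element == ""] <- toupper(substr(df$name[df$element == ""], 1, 1))
  if (is.null(altloc)) {
    keep <- df$altloc %in% c(" ", "") |
      !duplicated(df[, c("name", "resname", "resno", "chain")])
  } else {
    keep <- df$altloc %in% c(" ", "", altloc)
  }
  df <- df[keep, ]
  df$altloc <- NULL
  if (any(!is.finite(df$occ))) df$occ[!is.finite(df$occ)] <- 1
  df$occ <- pmin(1, pmax(0, df$occ))
  if (any(!is.finite(df$b))) df$b[!is.finite(df$b)] <- 20
  toy_structure(df, cell)
}

#' Write a toy_structure as a PDB file
#'
#' @param structure a `toy_structure`
#' @param path output file
#' @return the path, invisibly
#' @export
write_pdb <- function(structure, path) {
  cell <- structure$cell
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma),
             con)
  a <- structure$atoms
  rec <- ifelse(a$resname %in% c("HOH", "HEM", "OOH", "WAT"), "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  paste0(" ", formatC(a$name, width = -3)))
  writeLines(sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(a)), name4, a$resname, a$chain, a$resno,
                     a$x, a$y, a$z, a$occ, a$b, toupper(a$element)),
             con)
  writeLines("END", con)
  invisible(path)
}

#' Total-least-squares plane through points
#'
#' The plane minimizing the sum of squared perpendicular distances:
#' normal = smallest principal component of the centred points.
#'
#' @param points numeric matrix (>= 3 rows) of x, y, z
#' @return list of class `plane_fit`: `normal` (unit vector), `centroid`,
#'   `rmsd` (Angstrom)
#' @export
lsq_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  centroid <- colMeans(points)
  cen <- sweep(points, 2, centroid)
  sv <- svd(cen)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("collinear points: plane is undefined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  dist <- cen %*% normal
  structure(list(normal = as.numeric(normal), centroid = centroid,
                 rmsd = sqrt(mean(dist^2))),
            class = "plane_fit")
}

#' Signed distance of a point from a fitted plane
#' @param plane a [lsq_plane()] fit
#' @param point length-3 numeric
#' @export
plane_distance <- function(plane, point) {
  sum((point - plane$centroid) * plane$normal)
}

angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

vdist <- function(a, b) sqrt(sum((a - b)^2))

#' Assign heme-site roles in a parsed structure
#'
#' Identifies, per chain: the heme iron (HEM FE), the four pyrrole
#' nitrogens (HEM NA/NB/NC/ND), the proximal histidine NE2 (nearest His
#' NE2 to the iron), and the distal ligand - either a diatomic ligand
#' (residues OOH/PEO/PER/HOO with atoms O1/O2, or two waters within
#' 2.2 Angstrom of each other) or a single water, with WatX the water
#' nearest to the heme-bound water.
#'
#' @param structure a `toy_structure` (e.g. from [read_pdb()])
#' @param chain chain identifier
#' @return data.frame with columns `atom` (row index into
#'   `structure$atoms`) and `role`
#' @export
assign_heme_roles <- function(structure, chain = "A") {
  a <- structure$atoms
  in_chain <- which(a$chain == chain)
  if (!length(in_chain)) stop("no atoms in chain ", chain)
  sub <- a[in_chain, ]
  fe <- in_chain[sub$resname == "HEM" & toupper(sub$name) == "FE"]
  if (length(fe) != 1) {
    cand <- unique(sub$resname[sub$element == "FE"])
    stop("heme iron not found in chain ", chain,
         if (length(cand)) paste0(" (iron-bearing residues present: ",
                                  paste(cand, collapse = ", "), ")")
         else " (no iron atoms present)")
  }
  roles <- data.frame(atom = fe, role = "FE")
  pn <- in_chain[sub$resname == "HEM" & toupper(sub$name) %in% c("NA", "NB", "NC", "ND")]
  if (length(pn) < 3) stop("fewer than 3 pyrrole N atoms found for the heme plane")
  roles <- rbind(roles, data.frame(atom = pn, role = "PLANE"))
  fepos <- as.numeric(a[fe, c("x", "y", "z")])
  dist_to_fe <- function(idx) {
    m <- as.matrix(a[idx, c("x", "y", "z")])
    sqrt(rowSums(sweep(m, 2, fepos)^2))
  }
  his <- in_chain[sub$resname == "HIS" & toupper(sub$name) == "NE2"]
  if (length(his)) {
    his <- his[which.min(dist_to_fe(his))]
    if (dist_to_fe(his) < 3.5)
      roles <- rbind(roles, data.frame(atom = his, role = "HIS_N"))
  }
  # distal side: away from the proximal histidine (or +normal if absent)
  plane <- lsq_plane(as.matrix(a[pn, c("x", "y", "z")]))
  nrm <- plane$normal
  if (length(his) == 1 && any(roles$role == "HIS_N")) {
    hispos <- as.numeric(a[his, c("x", "y", "z")])
    if (sum((hispos - plane$centroid) * nrm) > 0) nrm <- -nrm
  }
  # diatomic ligand by residue code
  dia <- in_chain[sub$resname %in% c("OOH", "PEO", "PER", "HOO")]
  o1 <- dia[toupper(a$name[dia]) == "O1"]; o2 <- dia[toupper(a$name[dia]) == "O2"]
  wat <- in_chain[sub$resname %in% c("HOH", "WAT") & sub$element == "O"]
  distal_wat <- wat[dist_to_fe(wat) < 3.5 &
                      apply(as.matrix(a[wat, c("x", "y", "z")]), 1, function(p)
                        sum((p - plane$centroid) * nrm)) > 0]
  if (length(o1) == 1 && length(o2) == 1) {
    roles <- rbind(roles, data.frame(atom = c(o1, o2),
                                     role = c("DISTAL_O1", "DISTAL_O2")))
  } else if (length(distal_wat)) {
    w1 <- distal_wat[which.min(dist_to_fe(distal_wat))]
    others <- setdiff(wat, w1)
    if (length(others)) {
      w1pos <- as.numeric(a[w1, c("x", "y", "z")])
      dd <- apply(as.matrix(a[others, c("x", "y", "z")]), 1, vdist, b = w1pos)
      if (min(dd) < 2.2) {
        # two waters close enough to be a candidate diatomic ligand
        roles <- rbind(roles, data.frame(atom = c(w1, others[which.min(dd)]),
                                         role = c("DISTAL_O1", "DISTAL_O2")))
      } else {
        roles <- rbind(roles, data.frame(atom = w1, role = "WAT_O"))
        near <- others[dd < 3.6]
        if (length(near)) {
          watx <- near[which.min(dd[dd < 3.6])]
          roles <- rbind(roles, data.frame(atom = watx, role = "WATX_O"))
        }
      }
    } else {
      roles <- rbind(roles, data.frame(atom = w1, role = "WAT_O"))
    }
  }
  roles
}

#' Heme-site geometry report
#'
#' All scalar active-site measurements from Cartesian coordinates:
#' Fe-Wat and Fe-His distances, the signed iron-out-of-plane displacement
#' (positive toward the distal ligand), the O-O distance and Fe-O-O angle
#' of a diatomic distal ligand, the Fe-Wat-WatX angle, and hydrogen-bond
#' distances from the heme water to WatX, to the nearest Arg NH/NE and
#' the nearest Asp OD. Missing role atoms yield `NA` entries rather than
#' an error.
#'
#' @param structure a `toy_structure`; role assignment is taken from the
#'   `role` column if present, otherwise from [assign_heme_roles()]
#' @param chain chain identifier
#' @param plane_atoms `"4N"` (pyrrole nitrogens, default) or `"core"`
#'   (all heme atoms except Fe) for the reference plane
#' @return list of class `geometry_report` with fields `fe_wat`, `fe_his`,
#'   `feoop`, `o_o`, `fe_o_o_angle`, `fe_wat_watx_angle`, `hbonds`, `chain`
#' @export
heme_report <- function(structure, chain = "A", plane_atoms = c("4N", "core")) {
  plane_atoms <- match.arg(plane_atoms)
  a <- structure$atoms
  if (all(a$role == "UNASSIGNED")) {
    roles <- assign_heme_roles(structure, chain)
    a$role <- "UNASSIGNED"
    a$role[roles$atom] <- roles$role
  }
  sel <- a$chain == chain | a$role != "UNASSIGNED"
  a <- a[a$chain == chain, ]
  pos <- function(role) {
    i <- which(a$role == role)
    if (!length(i)) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  fe <- pos("FE")
  if (is.null(fe)) stop("no FE role in chain ", chain)
  plane_idx <- if (plane_atoms == "4N") which(a$role == "PLANE")
               else which(a$resname == "HEM" & a$role != "FE")
  if (length(plane_idx) < 3) stop("fewer than 3 plane atoms")
  plane <- lsq_plane(as.matrix(a[plane_idx, c("x", "y", "z")]))
  wat <- pos("WAT_O"); o1 <- pos("DISTAL_O1"); o2 <- pos("DISTAL_O2")
  watx <- pos("WATX_O"); his <- pos("HIS_N")
  lig <- if (!is.null(wat)) wat else o1
  nrm <- plane$normal
  ref <- if (!is.null(lig)) lig else if (!is.null(his)) -his + 2 * plane$centroid else NULL
  if (!is.null(lig) && sum((lig - plane$centroid) * nrm) < 0) nrm <- -nrm
  if (is.null(lig) && !is.null(his) && sum((his - plane$centroid) * nrm) > 0) nrm <- -nrm
  feoop <- sum((fe - plane$centroid) * nrm)
  hb <- list()
  if (!is.null(wat) && !is.null(watx)) hb$wat_watx <- vdist(wat, watx)
  arg <- which(a$resname == "ARG" & toupper(a$name) %in% c("NH1", "NH2", "NE"))
  if (!is.null(wat) && length(arg))
    hb$wat_arg <- min(apply(as.matrix(a[arg, c("x", "y", "z")]), 1, vdist, b = wat))
  asp <- which(a$resname == "ASP" & toupper(a$name) %in% c("OD1", "OD2"))
  if (!is.null(wat) && length(asp))
    hb$wat_asp <- min(apply(as.matrix(a[asp, c("x", "y", "z")]), 1, vdist, b = wat))
  if (!is.null(watx) && length(asp))
    hb$watx_asp <- min(apply(as.matrix(a[asp, c("x", "y", "z")]), 1, vdist, b = watx))
  out <- list(
    fe_wat = if (!is.null(lig)) vdist(fe, lig) else NA_real_,
    fe_his = if (!is.null(his)) vdist(fe, his) else NA_real_,
    feoop = feoop,
    o_o = if (!is.null(o1) && !is.null(o2)) vdist(o1, o2) else NA_real_,
    fe_o_o_angle = if (!is.null(o1) && !is.null(o2)) angle_deg(fe, o1, o2) else NA_real_,
    fe_wat_watx_angle = if (!is.null(wat) && !is.null(watx))
      angle_deg(fe, wat, watx) else NA_real_,
    hbonds = hb,
    plane_rmsd = plane$rmsd,
    chain = chain)
  class(out) <- "geometry_report"
  out
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("heme geometry (chain %s):\n", x$chain))
  cat(sprintf("  Fe-Wat  %.3f A   Fe-His %.3f A   FeOOP %+.3f A\n",
              x$fe_wat, x$fe_his, x$feoop))
  if (is.finite(x$o_o))
    cat(sprintf("  O-O %.3f A   Fe-O-O %.1f deg\n", x$o_o, x$fe_o_o_angle))
  if (is.finite(x$fe_wat_watx_angle))
    cat(sprintf("  Fe-Wat-WatX %.1f deg\n", x$fe_wat_watx_angle))
  for (nm in names(x$hbonds))
    cat(sprintf("  %s %.2f A\n", nm, x$hbonds[[nm]]))
  invisible(x)
}

#' Read coordinates and assign heme roles per chain
#'
#' Convenience wrapper: parse a PDB file and return the structure together
#' with one role table per chain that contains a heme.
#'
#' @param path PDB file
#' @param altloc see [read_pdb()]
#' @return list with `structure` and `roles` (named list of role tables,
#'   one per heme-bearing chain)
#' @export
read_coordinates <- function(path, altloc = NULL) {
  st <- read_pdb(path, altloc)
  chains <- unique(st$atoms$chain)
  roles <- list()
  for (ch in chains) {
    r <- tryCatch(assign_heme_roles(st, ch), error = function(e) NULL)
    if (!is.null(r)) roles[[ch]] <- r
  }
  if (!length(roles))
    stop("no heme found in any chain of ", path)
  list(structure = st, roles = roles)
}
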