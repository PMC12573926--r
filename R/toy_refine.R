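# Flat per-element form factors (electron counts). The toy forward model
# targets Wilson statistics and refinement behaviour, not absolute
# intensities, so no multi-Gaussian parameterization is used.
.form_factors <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, FE = 26)

form_factor <- function(element) {
  f <- .form_factors[toupper(element)]
  if (any(is.na(f))) {
    f[is.na(f)] <- 6   # unknown elements treated as carbon-like
  }
  unname(f)
}

#' Structure factors of a toy structure
#'
#' Direct summation `F(hkl) = sum_j occ_j f_j exp(-B_j s^2/4) exp(2 pi i hkl . x_frac,j)`
#' with `s = 1/d` and flat form factors per element.
#'
#' @param structure a `toy_structure`
#' @param hkls data.frame with integer columns h, k, l (a `d` column is
#'   recomputed from the structure's cell if absent)
#' @return complex vector of F, one per row of `hkls`
#' @export
calc_structure_factors <- function(structure, hkls) {
  H <- as.matrix(hkls[, c("h", "k", "l")])
  O <- cell_orth_matrix(structure$cell)
  frac <- t(solve(O) %*% t(atom_xyz(structure)))        # natom x 3
  if (any(abs(frac) > 10)) stop("atom outside sanity bounds (|frac| > 10)")
  d <- d_spacing(H, structure$cell)
  s2 <- 1 / d^2
  phases <- 2 * pi * (H %*% t(frac))                    # nhkl x natom
  f <- form_factor(structure$atoms$element)
  W <- exp(-outer(s2, structure$atoms$b) / 4) *
    matrix(structure$atoms$occ * f, nrow(H), nrow(frac), byrow = TRUE)
  complex(real = rowSums(W * cos(phases)),
          imaginary = rowSums(W * sin(phases)))
}

#' Scramble coordinates by stochastic displacement
#'
#' Adds i.i.d. Gaussian noise of the given standard deviation to every
#' Cartesian coordinate, the standard way to decorrelate replica
#' refinements from a common starting model (expected RMS total
#' displacement per atom is `sqrt(3) * sd`).
#'
#' @param structure a `toy_structure`
#' @param sd per-coordinate displacement SD (Angstrom), >= 0
#' @param seed RNG seed
#' @return displaced `toy_structure`
#' @export
scramble <- function(structure, sd, seed = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(structure)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  na <- nrow(structure$atoms)
  structure$atoms$x <- structure$atoms$x + stats::rnorm(na, 0, sd)
  structure$atoms$y <- structure$atoms$y + stats::rnorm(na, 0, sd)
  structure$atoms$z <- structure$atoms$z + stats::rnorm(na, 0, sd)
  structure
}

#' Refinement options
#'
#' @param refine_positions refine Cartesian coordinates (default TRUE)
#' @param refine_b refine isotropic B factors
#' @param refine_occupancies refine occupancies (clamped to \[0, 1\])
#' @param scramble_sd coordinate scrambling applied before refinement
#'   (Angstrom); 0 disables
#' @param max_iter maximum accepted Levenberg-Marquardt iterations
#' @param convergence_tol parameter-shift norm below which refinement stops
#' @param seed seed for the scrambling step
#' @param weighted use `1/sigma^2` weights from the merged data (default
#'   FALSE: unweighted, matching the unweighted Monte-Carlo merge)
#' @return list of class `refinement_options`
#' @export
refinement_options <- function(refine_positions = TRUE, refine_b = FALSE,
                               refine_occupancies = FALSE, scramble_sd = 0,
                               max_iter = 50, convergence_tol = 1e-8,
                               seed = NULL, weighted = FALSE) {
  stopifnot(scramble_sd >= 0, max_iter >= 1, convergence_tol > 0)
  structure(list(refine_positions = refine_positions, refine_b = refine_b,
                 refine_occupancies = refine_occupancies,
                 scramble_sd = scramble_sd, max_iter = max_iter,
                 convergence_tol = convergence_tol, seed = seed,
                 weighted = weighted),
            class = "refinement_options")
}

# model intensities and Jacobian wrt the active parameter vector
# parameters: [log_k, coords..., b..., occ...]
.refine_model <- function(par, template, H, Minv, s2, active) {
  st <- template
  k <- exp(par[1])
  ofs <- 1L
  if (active$positions) {
    n <- nrow(st$atoms)
    xyz <- matrix(par[ofs + seq_len(3 * n)], ncol = 3)
    st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
    ofs <- ofs + 3L * n
  }
  if (active$b) {
    st$atoms$b <- par[ofs + seq_len(nrow(st$atoms))]
    ofs <- ofs + nrow(st$atoms)
  }
  if (active$occ) {
    st$atoms$occ <- pmin(1, pmax(0, par[ofs + seq_len(nrow(st$atoms))]))
  }
  frac <- t(Minv %*% t(atom_xyz(st)))
  phases <- 2 * pi * (H %*% t(frac))
  f <- form_factor(st$atoms$element)
  amp <- exp(-outer(s2, st$atoms$b) / 4) *
    matrix(f, nrow(H), nrow(frac), byrow = TRUE)
  Wocc <- amp * matrix(st$atoms$occ, nrow(H), nrow(frac), byrow = TRUE)
  Fre <- rowSums(Wocc * cos(phases)); Fim <- rowSums(Wocc * sin(phases))
  I_calc <- Fre^2 + Fim^2
  model <- k * I_calc

  # Jacobian of model wrt parameters
  P <- 2 * pi * (H %*% Minv)                     # nhkl x 3, dphase/dcart
  cols <- list(model)                            # d model / d log_k
  if (active$positions) {
    # dF/dcart_{j,a} = i * P[,a] * Wocc[,j] * exp(i phase[,j])
    # d|F|^2 = 2 Re(conj(F) dF) = 2 P[,a] Wocc[,j] (Fre*(-sin) + Fim*cos)...
    # Re(conj(F) * i e^{i p}) = Fim cos(p) - Fre sin(p)
    base <- Wocc * (matrix(Fim, nrow(H), ncol(phases)) * cos(phases) -
                    matrix(Fre, nrow(H), ncol(phases)) * sin(phases))
    for (a in 1:3) {
      cols[[length(cols) + 1L]] <- k * 2 * base * P[, a]
    }
  }
  if (active$b) {
    dI <- 2 * (matrix(Fre, nrow(H), ncol(phases)) * cos(phases) +
               matrix(Fim, nrow(H), ncol(phases)) * sin(phases)) *
      Wocc * (-s2 / 4)
    cols[[length(cols) + 1L]] <- k * dI
  }
  if (active$occ) {
    dI <- 2 * (matrix(Fre, nrow(H), ncol(phases)) * cos(phases) +
               matrix(Fim, nrow(H), ncol(phases)) * sin(phases)) * amp
    cols[[length(cols) + 1L]] <- k * dI
  }
  # assemble: position block interleaves atoms within each axis column set
  J <- matrix(0, nrow(H), length(par))
  J[, 1] <- cols[[1]]
  ofs <- 1L; ci <- 2L
  if (active$positions) {
    n <- ncol(phases)
    for (a in 1:3) {
      J[, ofs + (a - 1L) * n + seq_len(n)] <- cols[[ci]]
      ci <- ci + 1L
    }
    ofs <- ofs + 3L * n
  }
  if (active$b) {
    J[, ofs + seq_len(ncol(phases))] <- cols[[ci]]; ci <- ci + 1L
    ofs <- ofs + ncol(phases)
  }
  if (active$occ) {
    J[, ofs + seq_len(ncol(phases))] <- cols[[ci]]
  }
  list(model = model, J = J, structure = st, k = k)
}

.pack_parameters <- function(st, k, active) {
  par <- log(k)
  if (active$positions) par <- c(par, st$atoms$x, st$atoms$y, st$atoms$z)
  if (active$b) par <- c(par, st$atoms$b)
  if (active$occ) par <- c(par, st$atoms$occ)
  par
}

#' Least-squares refinement of a toy structure against merged intensities
#'
#' Levenberg-Marquardt minimization of
#' `sum w (I_obs - k |F_calc|^2)^2` over an overall scale `k` and the
#' parameter classes selected in `opts`. The damping factor is multiplied
#' by 10 on step rejection and divided by 10 on acceptance; steps with
#' equal residual are accepted. No geometric restraints are applied: the
#' customary 0.3 Angstrom scramble is small enough for unrestrained
#' convergence on toy data.
#'
#' @param start starting `toy_structure` (scrambled internally if
#'   `opts$scramble_sd > 0`)
#' @param merged a `merged_dataset` from [mc_merge()]
#' @param opts a [refinement_options()]
#' @return list of class `refinement_result`: `structure`, `scale`,
#'   `n_iter`, `converged`, `residual`, `trace` (per-iteration log)
#' @export
refine <- function(start, merged, opts = refinement_options()) {
  stopifnot(inherits(start, "toy_structure"))
  # |F|^2 is invariant under a rigid translation of the whole model (in P1),
  # so the origin is a null direction of the target. The orbit representative
  # whose centroid matches the reference (pre-scramble) start model is
  # returned; LM damping keeps the null direction harmless during iteration.
  ref_centroid <- colMeans(atom_xyz(start))
  if (opts$scramble_sd > 0)
    start <- scramble(start, opts$scramble_sd, opts$seed)
  ent <- as.data.frame(merged$entries)
  H <- as.matrix(ent[, c("h", "k", "l")])
  I_obs <- ent$mean_I
  w <- if (opts$weighted) {
    sem <- ent$sem_I
    sem[!is.finite(sem) | sem <= 0] <- stats::median(sem[is.finite(sem) & sem > 0])
    1 / sem^2
  } else rep(1, length(I_obs))
  O <- cell_orth_matrix(start$cell)
  Minv <- solve(O)
  s2 <- 1 / d_spacing(H, start$cell)^2
  active <- list(positions = opts$refine_positions, b = opts$refine_b,
                 occ = opts$refine_occupancies)
  n_par <- 1L + 3L * nrow(start$atoms) * active$positions +
    nrow(start$atoms) * active$b + nrow(start$atoms) * active$occ
  if (length(I_obs) <= n_par)
    stop("underdetermined system: ", length(I_obs), " observations for ",
         n_par, " parameters")

  # initial scale by linear least squares on |F|^2
  I0 <- Mod(calc_structure_factors(start, ent))^2
  k <- sum(w * I_obs * I0) / sum(w * I0^2)
  if (!is.finite(k) || k <= 0) k <- 1
  par <- .pack_parameters(start, k, active)

  ev <- .refine_model(par, start, H, Minv, s2, active)
  res <- I_obs - ev$model
  rss <- sum(w * res^2)
  lambda <- 1e-3
  trace <- data.frame(iter = 0L, residual = rss, max_shift = NA_real_)
  converged <- FALSE
  n_iter <- 0L
  plateau <- 0L
  for (it in seq_len(opts$max_iter)) {
    Jw <- ev$J * w
    g <- crossprod(ev$J, w * res)
    A <- crossprod(ev$J, Jw)
    accepted <- FALSE
    for (try in 1:12) {
      Ad <- A + lambda * diag(diag(A) + 1e-12, nrow(A))
      delta <- tryCatch(solve(Ad, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- par + as.numeric(delta)
      ev2 <- .refine_model(cand, start, H, Minv, s2, active)
      rss2 <- sum(w * (I_obs - ev2$model)^2)
      if (rss2 <= rss) {                       # accept equal residuals
        par <- cand; ev <- ev2
        res <- I_obs - ev$model
        shift <- sqrt(sum(delta^2))
        # residual plateau: several accepted steps without real improvement
        plateau <- if (rss - rss2 <= 1e-9 * max(rss2, 1e-300)) plateau + 1L else 0L
        rss <- rss2
        lambda <- lambda / 10
        accepted <- TRUE
        n_iter <- it
        trace <- rbind(trace, data.frame(iter = it, residual = rss,
                                         max_shift = max(abs(delta))))
        if (shift < opts$convergence_tol || plateau >= 5L) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }  # no downhill step left
    if (converged) break
  }
  if (!converged && n_iter >= opts$max_iter)
    warning("refinement did not converge in ", opts$max_iter, " iterations")
  if (active$positions) {
    shift <- ref_centroid - colMeans(atom_xyz(ev$structure))
    ev$structure$atoms$x <- ev$structure$atoms$x + shift[1]
    ev$structure$atoms$y <- ev$structure$atoms$y + shift[2]
    ev$structure$atoms$z <- ev$structure$atoms$z + shift[3]
  }
  structure(list(structure = ev$structure, scale = ev$k, n_iter = n_iter,
                 converged = converged, residual = rss, trace = trace),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %s after %d iterations, residual %.6g, scale %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$residual, x$scale))
  invisible(x)
}

#' Two-state water occupancy refinement
#'
#' Refines the occupancy partition of a distal water present in two
#' alternative positions, with the steric anti-correlation of the nearby
#' WatX imposed as a constraint: `occ_pos2 = 1 - occ_pos1` and
#' `occ_watx = 1 - occ_pos2 = occ_pos1` (WatX would clash with the
#' displaced water, so it must leave as pos2 fills). The scale is profiled
#' analytically and the single free occupancy found by 1-D minimization;
#' the `"independent"` mode decouples WatX and optimizes both occupancies.
#'
#' @param start `toy_structure` containing atoms with roles `WAT_POS1`,
#'   `WAT_POS2` and `WATX_O`
#' @param merged a `merged_dataset`
#' @param mode `"constrained"` (default) or `"independent"`
#' @return list with `occ_pos1`, `occ_pos2`, `occ_watx`, `residual`
#' @export
refine_two_state_water <- function(start, merged,
                                   mode = c("constrained", "independent")) {
  mode <- match.arg(mode)
  roles <- start$atoms$role
  i1 <- which(roles == "WAT_POS1"); i2 <- which(roles == "WAT_POS2")
  ix <- which(roles == "WATX_O")
  if (length(i1) != 1 || length(i2) != 1 || length(ix) != 1)
    stop("structure must contain exactly one WAT_POS1, WAT_POS2 and WATX_O atom")
  ent <- as.data.frame(merged$entries)
  I_obs <- ent$mean_I
  objective <- function(q, qx) {
    st <- start
    st$atoms$occ[i1] <- q
    st$atoms$occ[i2] <- 1 - q
    st$atoms$occ[ix] <- qx
    Ic <- Mod(calc_structure_factors(st, ent))^2
    k <- sum(I_obs * Ic) / sum(Ic^2)          # profiled scale
    sum((I_obs - k * Ic)^2)
  }
  if (mode == "constrained") {
    opt <- stats::optimize(function(q) objective(q, q), c(0, 1), tol = 1e-6)
    q <- opt$minimum
    list(occ_pos1 = q, occ_pos2 = 1 - q, occ_watx = q, residual = opt$objective)
  } else {
    opt <- stats::optim(c(0.5, 0.5),
                        function(p) objective(p[1], p[2]),
                        method = "L-BFGS-B", lower = 0, upper = 1)
    list(occ_pos1 = opt$par[1], occ_pos2 = 1 - opt$par[1],
         occ_watx = opt$par[2], residual = opt$value)
  }
}
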