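# Grid-based electrostatic-potential models and RMSE/RRMSE evaluation.
#
# The model potential at a point is the sum over atoms (and, in periodic
# cells, atom images) of the point-charge term q/r, optionally the
# atom-centered dipole term mu . rhat / r^2, and optionally the
# cloud-penetration term of a neutral exponential tail model. For 3-D
# periodic cells the conditionally convergent charge term is evaluated by
# Ewald summation in the tinfoil (zero average) gauge; dipole and cloud
# terms use real-space summation over images within a cutoff.

#' Construct a volumetric grid
#'
#' @param origin grid origin, Angstrom.
#' @param axes 3 x 3 matrix of step vectors (rows), Angstrom.
#' @param shape integer triple of point counts along each axis.
#' @param values numeric array of dim `shape` (potential in a.u. or
#'   density in e/bohr^3), or `NULL` to allocate zeros.
#' @param kind `"esp"` or `"density"`.
#' @param cell optional cell for periodic grids (grid must tile the cell).
#' @return A `potential_grid` (origin/axes stored in bohr).
#' @export
potential_grid <- function(origin, axes, shape, values = NULL,
                           kind = c("esp", "density"), cell = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  axes <- as.matrix(axes)
  if (abs(det(axes)) < 1e-12) stop("grid axes must be linearly independent")
  if (is.null(values)) values <- array(0, shape)
  stopifnot(all(dim(values) == shape))
  structure(list(origin = ang_to_bohr(as.numeric(origin)),
                 axes = ang_to_bohr(axes), shape = shape,
                 values = values, kind = kind,
                 cell = if (is.null(cell)) NULL else normalize_cell(cell)),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid (%s): %d x %d x %d points, value range [%.4g, %.4g]\n",
              x$kind, x$shape[1], x$shape[2], x$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cartesian coordinates of all grid points
#'
#' @param grid a `potential_grid`.
#' @return n x 3 matrix, bohr, in the array's storage order (first index
#'   fastest).
#' @export
grid_points <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$shape[1]) - 1,
                               j = seq_len(grid$shape[2]) - 1,
                               k = seq_len(grid$shape[3]) - 1))
  sweep(idx %*% grid$axes, 2, grid$origin, `+`)
}

#' Select the valid grid points for RMSE evaluation
#'
#' A grid point is valid when all three rules hold: the electron density
#' is below `rho_max`, the point is farther than `inner` from every atom,
#' and it is within `outer` of at least one atom. Distances use the
#' minimum over enumerated periodic images when the partition is periodic.
#'
#' @param density a `potential_grid` with `kind = "density"`.
#' @param p a `stockholder_partition` in the same frame.
#' @param rho_max density threshold, e/bohr^3 (default 1e-4).
#' @param inner inner radius cutoff, Angstrom (default 2).
#' @param outer outer radius cutoff, Angstrom (default 5).
#' @return A `valid_mask`: logical array `mask` aligned with the grid and
#'   `n_valid`; an error if no point survives.
#' @export
valid_grid_mask <- function(density, p, rho_max = 1e-4, inner = 2, outer = 5) {
  stopifnot(inherits(density, "potential_grid"))
  pts <- grid_points(density)
  d <- min_atom_distance(pts, p, reach = ang_to_bohr(outer))
  ok <- as.vector(density$values) < rho_max &
    d > ang_to_bohr(inner) & d <= ang_to_bohr(outer)
  if (!any(ok)) {
    stop("no valid grid points: check that the grid and geometry share a frame")
  }
  structure(list(mask = array(ok, density$shape), n_valid = sum(ok)),
            class = "valid_mask")
}

min_atom_distance <- function(pts, p, reach) {
  trans <- candidate_translations(p$pos, p$cell,
                                  reach + max(sqrt(rowSums(p$pos^2))) + 1)
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(trans))) {
    offset <- if (is.null(p$cell$lattice)) c(0, 0, 0)
              else drop(trans[k, ] %*% p$cell$lattice)
    for (A in seq_len(nrow(p$pos))) {
      v <- sweep(pts, 2, p$pos[A, ] + offset)
      d2 <- pmin(d2, rowSums(v^2))
    }
  }
  sqrt(d2)
}

#' Electrostatic potential of a partition's point-multipole model
#'
#' @param p a `stockholder_partition`.
#' @param points n x 3 matrix of evaluation positions, bohr.
#' @param terms character subset of `"charges"`, `"atomic_dipoles"`,
#'   `"cloud_penetration"`. The cloud term is the closed-form potential of
#'   the neutral exponential tail model (point `+N_cloud` plus diffuse
#'   electron cloud `a exp(-b r)`): \eqn{4\pi a e^{-br}(br+2)/(b^3 r)}.
#' @param units `"au"` (hartree/e, default) or `"kcal"` (kcal/mol/e).
#' @param real_cutoff real-space image cutoff for periodic dipole/cloud
#'   sums, Angstrom (default 12).
#' @param ewald_accuracy target accuracy of the periodic charge term.
#' @return Vector of potential values at the points.
#' @export
model_potential <- function(p, points, terms = "charges",
                            units = c("au", "kcal"),
                            real_cutoff = 12, ewald_accuracy = 1e-8) {
  units <- match.arg(units)
  bad <- setdiff(terms, c("charges", "atomic_dipoles", "cloud_penetration"))
  if (length(bad) > 0) stop("unknown term(s): ", paste(bad, collapse = ", "))
  pts <- as.matrix(points)
  periodic <- any(p$cell$periodic)
  if (periodic && sum(p$cell$periodic) != 3) {
    stop("periodic potentials are implemented for 3-D periodic cells only")
  }
  v <- numeric(nrow(pts))
  if ("charges" %in% terms) {
    v <- v + if (periodic) ewald_potential(p, pts, ewald_accuracy)
             else direct_charge_potential(p, pts)
  }
  if (any(c("atomic_dipoles", "cloud_penetration") %in% terms)) {
    trans <- if (periodic) {
      candidate_translations(p$pos, p$cell, ang_to_bohr(real_cutoff))
    } else matrix(0L, 1, 3)
    for (k in seq_len(nrow(trans))) {
      offset <- if (periodic) drop(trans[k, ] %*% p$cell$lattice) else c(0, 0, 0)
      for (A in seq_len(nrow(p$pos))) {
        rv <- sweep(pts, 2, p$pos[A, ] + offset)
        r <- sqrt(rowSums(rv^2))
        check_clearance(r, A)
        if ("atomic_dipoles" %in% terms) {
          v <- v + drop(rv %*% p$dipole[A, ]) / r^3
        }
        if ("cloud_penetration" %in% terms) {
          a <- p$cloud_a[A]; b <- p$cloud_b[A]
          if (is.na(a) || is.na(b)) {
            stop("atom ", A, ": cloud parameters required for the cloud term")
          }
          v <- v + 4 * pi * a * exp(-b * r) * (b * r + 2) / (b^3 * r)
        }
      }
    }
  }
  if (units == "kcal") v <- v * qdr_constants$hartree_to_kcal else v
}

check_clearance <- function(r, A) {
  if (any(r < 1e-9)) {
    stop("evaluation point coincides with nucleus of atom ", A,
         "; exclude nuclear positions (use a valid-point mask)")
  }
}

direct_charge_potential <- function(p, pts) {
  v <- numeric(nrow(pts))
  for (A in seq_len(nrow(p$pos))) {
    rv <- sweep(pts, 2, p$pos[A, ])
    r <- sqrt(rowSums(rv^2))
    check_clearance(r, A)
    v <- v + p$charge[A] / r
  }
  v
}

# Tinfoil-gauge Ewald sum of the point-charge potential in a 3-D periodic
# cell. Non-neutral cells get the uniform compensating background; the
# resulting potential carries the usual arbitrary constant, which is why
# esp_metrics offers mean-offset alignment for periodic grids.
ewald_potential <- function(p, pts, accuracy = 1e-8) {
  L <- p$cell$lattice
  vol <- abs(det(L))
  # split parameter balancing both sums
  alpha <- (nrow(p$pos) * pi^3 / vol^2)^(1 / 6)
  rcut <- sqrt(-log(accuracy)) / alpha
  kcut <- 2 * alpha * sqrt(-log(accuracy))
  G <- solve(L)                       # columns: reciprocal basis / (2 pi)
  v <- numeric(nrow(pts))

  # real-space part
  nmax <- integer(3)
  span <- sqrt(sum((apply(rbind(p$pos, pts), 2, function(x) diff(range(x))))^2))
  for (i in 1:3) nmax[i] <- ceiling(sqrt(sum(G[, i]^2)) * (rcut + span))
  trans <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2], -nmax[3]:nmax[3]))
  for (k in seq_len(nrow(trans))) {
    offset <- drop(trans[k, ] %*% L)
    for (A in seq_len(nrow(p$pos))) {
      rv <- sweep(pts, 2, p$pos[A, ] + offset)
      r <- sqrt(rowSums(rv^2))
      check_clearance(r, A)
      inside <- r <= rcut
      if (any(inside)) {
        v[inside] <- v[inside] + p$charge[A] * erfc_r(alpha * r[inside]) / r[inside]
      }
    }
  }

  # reciprocal-space part; |m_i| <= kcut |a_i| / 2 pi since b_i . a_j = 2 pi d_ij
  kb <- 2 * pi * t(G)                 # rows: reciprocal lattice vectors
  mmax <- integer(3)
  for (i in 1:3) mmax[i] <- ceiling(kcut * sqrt(sum(L[i, ]^2)) / (2 * pi))
  ms <- as.matrix(expand.grid(-mmax[1]:mmax[1], -mmax[2]:mmax[2], -mmax[3]:mmax[3]))
  ms <- ms[rowSums(abs(ms)) > 0, , drop = FALSE]
  kvec <- ms %*% kb
  k2 <- rowSums(kvec^2)
  keep <- k2 <= kcut^2
  kvec <- kvec[keep, , drop = FALSE]
  k2 <- k2[keep]
  if (length(k2) > 0) {
    pref <- 4 * pi / vol * exp(-k2 / (4 * alpha^2)) / k2
    phase_atoms_c <- cos(p$pos %*% t(kvec))   # n_atoms x n_k
    phase_atoms_s <- sin(p$pos %*% t(kvec))
    Sc <- drop(p$charge %*% phase_atoms_c)    # structure factors
    Ss <- drop(p$charge %*% phase_atoms_s)
    ptc <- cos(pts %*% t(kvec))
    pts_s <- sin(pts %*% t(kvec))
    v <- v + drop(ptc %*% (pref * Sc) + pts_s %*% (pref * Ss))
  }

  # background/compensation term (tinfoil gauge)
  v - pi * sum(p$charge) / (alpha^2 * vol)
}

erfc_r <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' RMSE, RRMSE, and R-squared of a model potential on the valid points
#'
#' The null model sets every atomic charge to zero, so its potential
#' vanishes and its RMSE is the root-mean-square reference potential over
#' the same mask; RRMSE = RMSE / RMSE_null and R-squared = 1 - RRMSE^2.
#'
#' @param model_values model potential at all grid points, a.u.
#' @param qm_values reference potential at all grid points, a.u.
#' @param mask a `valid_mask` or logical vector/array.
#' @param align_offset subtract the mean model-minus-reference offset over
#'   the valid points before computing errors. Periodic potentials carry
#'   an arbitrary constant, so this defaults to `TRUE` for periodic grids
#'   when the caller says so and `FALSE` otherwise.
#' @return An `esp_metrics` list: `rmse` (kcal/mol/e), `rmse_au`,
#'   `rmse_null`, `rrmse`, `r_squared`, `n_valid`.
#' @export
esp_metrics <- function(model_values, qm_values, mask, align_offset = FALSE) {
  ok <- if (inherits(mask, "valid_mask")) as.vector(mask$mask) else as.vector(mask)
  m <- as.vector(model_values)[ok]
  q <- as.vector(qm_values)[ok]
  if (length(q) < 1) stop("mask selects no valid points")
  if (align_offset) m <- m - mean(m - q)
  rmse_null <- sqrt(mean(q^2))
  if (rmse_null == 0) {
    stop("reference potential is identically zero on the mask; RRMSE undefined")
  }
  rmse_au <- sqrt(mean((m - q)^2))
  rrmse <- rmse_au / rmse_null
  structure(list(rmse = rmse_au * qdr_constants$hartree_to_kcal,
                 rmse_au = rmse_au,
                 rmse_null = rmse_null * qdr_constants$hartree_to_kcal,
                 rrmse = rrmse,
                 r_squared = 1 - rrmse^2,
                 n_valid = length(q)),
            class = "esp_metrics")
}

#' @export
print.esp_metrics <- function(x, ...) {
  cat(sprintf("esp_metrics: RMSE %.4f kcal/mol/e, RRMSE %.4f, R^2 %.4f (%d valid points)\n",
              x$rmse, x$rrmse, x$r_squared, x$n_valid))
  invisible(x)
}
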