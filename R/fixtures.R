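# Synthetic fixtures: stockholder partitions with controlled structure,
# oracle potential/density grids, and conformational charge ensembles, so
# every module is exercisable without any external data. Fixtures are
# deterministic: the same kind, size, and seed reproduce the same object
# bit for bit.
#
# The water-like fixture uses the per-atom charge and multipole
# magnitudes of a DDEC6-partitioned water molecule (H charge 0.388,
# |mu_H| 0.042, |Theta_H| 0.053; O charge -0.776, |mu_O| 0.136,
# |Theta_O| 0.384 a.u.); the directions are generator-defined,
# C2v-symmetric choices, so this emulates realistic magnitudes without
# claiming to reproduce any published geometry's tensors.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

axial_tensor <- function(u) tcrossprod(u) - diag(3) / 3

random_traceless <- function(scale) {
  M <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  detrace(M)
}

#' Generate a synthetic stockholder partition
#'
#' @param kind one of `"diatomic"`, `"homodiatomic"`, `"water_like"`,
#'   `"chain"`, `"rocksalt"`, `"ring_tube"`, `"random"`.
#' @param size atom count where meaningful (chain/ring/random; rocksalt
#'   needs `8 m^3` atoms and defaults to 8, giving the conventional cubic
#'   cell or its supercells).
#' @param seed RNG seed controlling every random element.
#' @param op_scale overlap-population magnitude of bonded pairs.
#' @param dipole_scale,quadrupole_scale atomic moment magnitudes, a.u.
#'   (`rocksalt` defaults both to 0, its symmetric ideal).
#' @param bond_length nearest-neighbor distance, Angstrom, where the kind
#'   has one.
#' @return A validated `stockholder_partition`.
#' @export
make_fixture <- function(kind = c("diatomic", "homodiatomic", "water_like",
                                  "chain", "rocksalt", "ring_tube", "random"),
                         size = NULL, seed = 1,
                         op_scale = NULL, dipole_scale = NULL,
                         quadrupole_scale = NULL, bond_length = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    diatomic = fixture_diatomic(op_scale %||% 0.5, dipole_scale %||% 0.3,
                                quadrupole_scale %||% 0.1, bond_length %||% 1.5),
    homodiatomic = fixture_homodiatomic(op_scale %||% 0.5, dipole_scale %||% 0.2,
                                        quadrupole_scale %||% 0.3,
                                        bond_length %||% 1.2),
    water_like = fixture_water(op_scale %||% 0.5),
    chain = fixture_chain(size %||% 6, op_scale %||% 0.4,
                          dipole_scale %||% 0.15, quadrupole_scale %||% 0.15,
                          bond_length %||% 1.5),
    rocksalt = fixture_rocksalt(size %||% 8, op_scale %||% 0.08,
                                dipole_scale %||% 0, quadrupole_scale %||% 0),
    ring_tube = fixture_ring(size %||% 12, op_scale %||% 0.4,
                             dipole_scale %||% 0.15, quadrupole_scale %||% 0,
                             bond_length %||% 1.45),
    random = fixture_random(size %||% 8, op_scale %||% 0.3,
                            dipole_scale %||% 0.15, quadrupole_scale %||% 0.15)
  ))
}

pair_row <- function(a, b, op) {
  data.frame(a = a, b = b, t1 = 0L, t2 = 0L, t3 = 0L, op = op)
}

fixture_diatomic <- function(op, dscale, qscale, bond) {
  u <- c(1, 0, 0)
  quad <- array(0, c(3, 3, 2))
  quad[, , 1] <- qscale * axial_tensor(u)
  quad[, , 2] <- 0.6 * qscale * axial_tensor(u)
  stockholder_partition(
    elements = c(9, 1),
    positions = rbind(c(0, 0, 0), bond * u),
    charges = c(-0.3, 0.3),
    dipoles = rbind(dscale * u, 0.6 * dscale * u),
    quadrupoles = quad,
    op_table = pair_row(1, 2, op),
    method_name = "synthetic diatomic")
}

fixture_homodiatomic <- function(op, dscale, qscale, bond) {
  u <- c(1, 0, 0)
  mu <- dscale * c(0.9, 0.3, 0)          # odd under the exchange inversion
  quad <- array(0, c(3, 3, 2))
  quad[, , 1] <- quad[, , 2] <- qscale * axial_tensor(u)  # even
  stockholder_partition(
    elements = c(7, 7),
    positions = rbind(c(0, 0, 0), bond * u),
    charges = c(0, 0),
    dipoles = rbind(mu, -mu),
    quadrupoles = quad,
    op_table = pair_row(1, 2, op),
    method_name = "synthetic homodiatomic")
}

fixture_water <- function(op_oh) {
  # C2v geometry, symmetry axis +z; atom order H, H, O
  roh <- 0.9584
  half <- 104.45 / 2 * pi / 180
  hx <- roh * sin(half)
  hz <- roh * cos(half)
  pos <- rbind(c(hx, 0, hz), c(-hx, 0, hz), c(0, 0, 0))
  uh1 <- c(sin(half), 0, cos(half))
  uh2 <- c(-sin(half), 0, cos(half))
  dip <- rbind(0.042 * uh1, 0.042 * uh2, 0.136 * c(0, 0, 1))
  quad <- array(0, c(3, 3, 3))
  quad[, , 1] <- 0.053 / sqrt(2 / 3) * axial_tensor(uh1)
  quad[, , 2] <- 0.053 / sqrt(2 / 3) * axial_tensor(uh2)
  quad[, , 3] <- 0.384 / sqrt(6) * diag(c(1, 1, -2))
  stockholder_partition(
    elements = c(1, 1, 8),
    positions = pos,
    charges = c(0.388, 0.388, -0.776),
    dipoles = dip,
    quadrupoles = quad,
    op_table = rbind(pair_row(1, 3, op_oh), pair_row(2, 3, op_oh),
                     pair_row(1, 2, 0.03)),
    method_name = "synthetic water-like")
}

fixture_chain <- function(n, op, dscale, qscale, bond) {
  stopifnot(n >= 2)
  pos <- cbind((seq_len(n) - 1) * bond, 0, 0)
  q <- rep_len(c(0.1, -0.1), n)
  q <- q - mean(q)
  quad <- array(0, c(3, 3, n))
  for (A in seq_len(n)) quad[, , A] <- random_traceless(qscale)
  stockholder_partition(
    elements = rep(6L, n),
    positions = pos,
    charges = q,
    dipoles = matrix(stats::rnorm(3 * n, sd = dscale), n, 3),
    quadrupoles = quad,
    op_table = do.call(rbind, lapply(seq_len(n - 1), function(i)
      pair_row(i, i + 1, op))),
    method_name = "synthetic chain")
}

fixture_rocksalt <- function(n_atoms, op, dscale, qscale) {
  m <- round((n_atoms / 8)^(1 / 3))
  if (8 * m^3 != n_atoms) {
    stop("rocksalt fixture needs 8 m^3 atoms (8, 64, 512, ...), got ", n_atoms)
  }
  a0 <- 5.64
  base <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),   # Na
                c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))   # Cl
  shifts <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
  frac <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    sweep(base, 2, shifts[s, ], `+`) / m))
  pos <- frac * (a0 * m)
  z <- rep(rep(c(11L, 17L), each = 4), nrow(shifts))
  q <- rep(rep(c(0.85, -0.85), each = 4), nrow(shifts))
  cell <- list(lattice = diag(3) * a0 * m, periodic = c(TRUE, TRUE, TRUE))
  # nearest-neighbor OP table from the geometry itself
  geo <- enumerate_pairs(ang_to_bohr(pos), normalize_cell(cell),
                         cutoff_sum = a0 / 2 + 0.3)
  nn <- geo[abs(geo$dist - ang_to_bohr(a0 / 2)) < ang_to_bohr(0.2), ]
  op_table <- data.frame(a = nn$a, b = nn$b, t1 = nn$t1, t2 = nn$t2,
                         t3 = nn$t3, op = op)
  n <- nrow(pos)
  quad <- array(0, c(3, 3, n))
  if (qscale > 0) for (A in seq_len(n)) quad[, , A] <- random_traceless(qscale)
  dip <- if (dscale > 0) matrix(stats::rnorm(3 * n, sd = dscale), n, 3)
         else matrix(0, n, 3)
  stockholder_partition(
    elements = z, positions = pos, charges = q,
    dipoles = dip, quadrupoles = quad,
    op_table = op_table, cell = cell,
    method_name = "synthetic rocksalt")
}

fixture_ring <- function(n, op, dscale, qscale, bond) {
  stopifnot(n %% 2 == 0, n >= 6)
  R <- n * bond / (2 * pi)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(R * cos(ang), R * sin(ang), 0)
  radial <- cbind(cos(ang), sin(ang), 0)
  q <- rep_len(c(0.43, -0.43), n)
  quad <- array(0, c(3, 3, n))
  if (qscale > 0) for (A in seq_len(n)) quad[, , A] <- qscale * axial_tensor(radial[A, ])
  stockholder_partition(
    elements = rep_len(c(5L, 7L), n),
    positions = pos,
    charges = q,
    dipoles = dscale * radial,          # coherent radial dipoles
    quadrupoles = quad,
    op_table = do.call(rbind, lapply(seq_len(n), function(i)
      pair_row(i, if (i == n) 1L else i + 1L, op))),
    method_name = "synthetic ring-tube")
}

fixture_random <- function(n, op_scale, dscale, qscale) {
  stopifnot(n >= 2)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- stats::runif(3, 0, 1)
  box <- max(3, n^(1 / 3) * 2.2)
  for (A in 2:n) {
    repeat {
      cand <- stats::runif(3, 0, box)
      if (min(sqrt(rowSums(sweep(pos[seq_len(A - 1), , drop = FALSE], 2,
                                 cand)^2))) > 1.2) break
    }
    pos[A, ] <- cand
  }
  z <- sample(c(1L, 6L, 7L, 8L), n, replace = TRUE)
  q <- stats::rnorm(n, sd = 0.3)
  q <- q - mean(q)
  q <- pmin(q, z - 0.1)                # keep electron counts positive
  q <- q - mean(q)
  quad <- array(0, c(3, 3, n))
  for (A in seq_len(n)) quad[, , A] <- random_traceless(qscale)
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d < 3.2, arr.ind = TRUE)
  op_table <- if (nrow(idx) > 0) {
    data.frame(a = idx[, 1], b = idx[, 2], t1 = 0L, t2 = 0L, t3 = 0L,
               op = op_scale * exp(-(d[idx] - 1.2)))
  } else NULL
  stockholder_partition(
    elements = z, positions = pos, charges = q,
    dipoles = matrix(stats::rnorm(3 * n, sd = dscale), n, 3),
    quadrupoles = quad, op_table = op_table,
    method_name = "synthetic random")
}

#' Generate oracle ESP and density grids for a partition
#'
#' The ESP grid holds the exact model potential of the requested
#' ground-truth terms (plus optional seeded Gaussian noise), standing in
#' for a quantum-mechanical reference; the density grid is a sum of
#' atom-centered exponential clouds normalized to each atom's electron
#' count, so the density rule of the valid-point selection is exercised.
#'
#' @param p a `stockholder_partition` (nonperiodic or 3-D periodic).
#' @param spacing grid spacing, Angstrom (default 0.5).
#' @param padding box padding beyond the atoms, Angstrom (default 6.5,
#'   comfortably past the 5 Angstrom outer cutoff). Ignored for periodic
#'   cells, whose grids tile the cell exactly.
#' @param terms ground-truth term set for the ESP grid.
#' @param noise_sd Gaussian noise standard deviation, a.u. (default 0).
#' @param cloud_b exponential decay constant of the density model,
#'   1/bohr (default 2.0, placing the 1e-4 e/bohr^3 isosurface between
#'   the 2 and 5 Angstrom cutoffs).
#' @param seed seed for the noise.
#' @return List with `esp` and `density` grids.
#' @export
make_oracle_grids <- function(p, spacing = 0.5, padding = 6.5,
                              terms = "charges", noise_sd = 0,
                              cloud_b = 2.0, seed = 1) {
  if (spacing <= 0) stop("spacing must be positive")
  periodic <- any(p$cell$periodic)
  sp <- ang_to_bohr(spacing)
  if (periodic) {
    L <- p$cell$lattice
    shape <- pmax(2L, as.integer(round(sqrt(rowSums(L^2)) / sp)))
    axes <- L / shape
    origin <- c(0, 0, 0) + 0.5 * colSums(axes)   # stay off the nuclei
  } else {
    lo <- apply(p$pos, 2, min) - ang_to_bohr(padding)
    hi <- apply(p$pos, 2, max) + ang_to_bohr(padding)
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / sp)))
    axes <- diag(sp, 3)
    origin <- lo + 0.26 * sp                     # stay off the nuclei
  }
  mk <- function(values, kind) {
    potential_grid(bohr_to_ang(origin), bohr_to_ang(axes), shape, values,
                   kind, cell = if (periodic)
                     list(lattice = bohr_to_ang(p$cell$lattice),
                          periodic = p$cell$periodic))
  }
  pts <- grid_points(mk(NULL, "esp"))
  esp_vals <- model_potential(p, pts, terms = terms)
  if (noise_sd > 0) {
    esp_vals <- esp_vals + with_seed(seed, stats::rnorm(length(esp_vals), sd = noise_sd))
  }
  dens <- numeric(nrow(pts))
  trans <- if (periodic) candidate_translations(p$pos, p$cell, ang_to_bohr(8))
           else matrix(0L, 1, 3)
  for (k in seq_len(nrow(trans))) {
    offset <- if (periodic) drop(trans[k, ] %*% p$cell$lattice) else c(0, 0, 0)
    for (A in seq_len(nrow(p$pos))) {
      r <- sqrt(rowSums(sweep(pts, 2, p$pos[A, ] + offset)^2))
      aA <- p$n_electrons[A] * cloud_b^3 / (8 * pi)
      dens <- dens + aA * exp(-cloud_b * r)
    }
  }
  list(esp = mk(array(esp_vals, shape), "esp"),
       density = mk(array(dens, shape), "density"))
}

#' Generate a synthetic conformational charge ensemble
#'
#' Builds per-method charge profiles with controlled inter-method
#' correlation and adds per-conformation Gaussian jitter of known rms, so
#' the sensitivity and correlation statistics have known expectations.
#'
#' @param base a `stockholder_partition` whose charges seed the shared
#'   profile, or an integer atom count (profile drawn N(0, 0.4)).
#' @param n_conformations conformations per method (>= 1).
#' @param n_methods number of charge methods.
#' @param perturbation sd of the per-conformation jitter, e.
#' @param method_mix weight of the shared profile in each method (length
#'   `n_methods`, recycled; 1 = identical methods).
#' @param seed RNG seed.
#' @return An `ensemble_charge_table`.
#' @export
make_ensemble <- function(base, n_conformations = 21, n_methods = 3,
                          perturbation = 0.02, method_mix = 0.9, seed = 1) {
  stopifnot(n_conformations >= 1, n_methods >= 1)
  with_seed(seed, {
    q_base <- if (inherits(base, "stockholder_partition")) base$charge
              else stats::rnorm(base, sd = 0.4)
    n_atoms <- length(q_base)
    mix <- rep_len(method_mix, n_methods)
    rows <- lapply(seq_len(n_methods), function(a) {
      prof <- mix[a] * q_base +
        sqrt(max(0, 1 - mix[a]^2)) * stats::rnorm(n_atoms, sd = 0.4)
      do.call(rbind, lapply(seq_len(n_conformations), function(j) {
        data.frame(method = sprintf("method_%02d", a),
                   conformation = j, atom = seq_len(n_atoms),
                   charge = prof + if (perturbation > 0)
                     stats::rnorm(n_atoms, sd = perturbation) else 0)
      }))
    })
    ensemble_charge_table(do.call(rbind, rows))
  })
}
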