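# System multipole moments of a partition's electrostatic model and the
# summary error statistics used to compare models against reference
# (e.g. quantum-mechanical) molecular moments.
#
# Traceless quadrupole convention: the primitive-traceless form
#   Theta = sum q (r r^T - r^2 I / 3)
# is used everywhere internally (the convention printed by Gaussian16);
# the Buckingham convention is 3/2 times this and is available through
# to_buckingham().

# standard atomic weights (natural-abundance averages), Z = 1..86
ATOMIC_WEIGHTS <- c(
  1.008, 4.002602, 6.94, 9.0121831, 10.81, 12.011, 14.007, 15.999,
  18.998403163, 20.1797, 22.98976928, 24.305, 26.9815385, 28.085,
  30.973761998, 32.06, 35.45, 39.948, 39.0983, 40.078, 44.955908, 47.867,
  50.9415, 51.9961, 54.938044, 55.845, 58.933194, 58.6934, 63.546, 65.38,
  69.723, 72.630, 74.921595, 78.971, 79.904, 83.798, 85.4678, 87.62,
  88.90584, 91.224, 92.90637, 95.95, 98, 101.07, 102.9055, 106.42,
  107.8682, 112.414, 114.818, 118.71, 121.76, 127.6, 126.90447, 131.293,
  132.90545196, 137.327, 138.90547, 140.116, 140.90766, 144.242, 145,
  150.36, 151.964, 157.25, 158.92535, 162.5, 164.93033, 167.259,
  168.93422, 173.045, 174.9668, 178.49, 180.94788, 183.84, 186.207,
  190.23, 192.217, 195.084, 196.966569, 200.592, 204.38, 207.2,
  208.9804, 209, 210, 222)

detrace <- function(M) {
  M <- (M + t(M)) / 2
  M - diag(3) * sum(diag(M)) / 3
}

resolve_origin <- function(p, origin) {
  if (is.numeric(origin) && length(origin) == 3) return(as.numeric(origin))
  switch(origin,
    center_of_mass = {
      w <- ATOMIC_WEIGHTS[p$z]
      drop(w %*% p$pos) / sum(w)
    },
    center_of_nuclear_charge = drop(p$z %*% p$pos) / sum(p$z),
    stop("unknown origin spec: ", origin)
  )
}

#' Total multipole moments of a partition's electrostatic model
#'
#' Computes the system dipole vector and traceless quadrupole tensor of
#' the atom-centered model truncated at the requested order: charges only,
#' charges plus atomic dipoles, or charges plus dipoles plus atomic
#' quadrupoles. System multipoles are origin-dependent (and divergent) for
#' periodic cells, so only nonperiodic partitions are accepted.
#'
#' @param p a nonperiodic `stockholder_partition`.
#' @param model one of `"charges_only"`, `"charges_plus_dipoles"`,
#'   `"charges_dipoles_quadrupoles"`.
#' @param origin `"center_of_mass"` (default, standard atomic weights),
#'   `"center_of_nuclear_charge"`, or an explicit 3-vector in bohr.
#' @return List with `origin` (bohr), `model`, `dipole` (a.u.), and
#'   `quadrupole` (traceless, a.u., primitive-traceless convention).
#' @export
system_multipoles <- function(p,
                              model = c("charges_only", "charges_plus_dipoles",
                                        "charges_dipoles_quadrupoles"),
                              origin = "center_of_mass") {
  model <- match.arg(model)
  if (any(p$cell$periodic)) {
    stop("system multipoles are not defined for periodic cells")
  }
  o <- resolve_origin(p, origin)
  r <- sweep(p$pos, 2, o)
  mu <- drop(p$charge %*% r)
  Q <- crossprod(r * p$charge, r)
  if (model != "charges_only") {
    mu <- mu + colSums(p$dipole)
    Q <- Q + crossprod(p$dipole, r) + crossprod(r, p$dipole)
  }
  Q <- detrace(Q)
  if (model == "charges_dipoles_quadrupoles") {
    n <- length(p$charge)
    for (A in seq_len(n)) Q <- Q + p$quad[, , A]
  }
  list(origin = o, model = model, dipole = mu, quadrupole = Q)
}

#' Convert a traceless quadrupole tensor to the Buckingham convention
#'
#' The primitive-traceless tensor \eqn{\sum q (rr^T - r^2 I/3)} and the
#' Buckingham tensor \eqn{\frac12 \sum q (3 rr^T - r^2 I)} differ by a
#' factor 3/2; the map is linear and exactly invertible.
#'
#' @param quadrupole traceless 3 x 3 tensor, primitive-traceless convention.
#' @param inverse if `TRUE`, convert from Buckingham back.
#' @return The tensor in the other convention.
#' @export
to_buckingham <- function(quadrupole, inverse = FALSE) {
  if (inverse) quadrupole * (2 / 3) else quadrupole * (3 / 2)
}

frob <- function(M) sqrt(sum(M^2))

#' Aggregate multipole error statistics over a molecule set
#'
#' Given per-molecule model multipoles and reference multipoles, computes
#' the mean error and relative mean error of the dipole magnitude, the
#' RMSEs of the dipole magnitude, dipole vector, and traceless quadrupole
#' tensor, and their relative (RRMSE) counterparts. The null model sets
#' every atomic charge to zero, so its moments vanish and its RMSEs are
#' the root-mean-square reference moments; by construction the null
#' model's RRMSE equals 1.
#'
#' @param models list of per-molecule model summaries, each with `dipole`
#'   (3-vector) and `quadrupole` (traceless 3 x 3), as returned by
#'   [system_multipoles()].
#' @param references list of per-molecule reference multipoles, same shape
#'   and order.
#' @return List of class `multipole_error_stats`: `me`, `rme`,
#'   `rmse_dipole_mag`, `rmse_dipole_vec`, `rmse_quadrupole`, matching
#'   `rrmse_*` fractions, and the null-model RMSEs.
#' @export
multipole_error_stats <- function(models, references) {
  n <- length(models)
  if (n == 0) stop("empty molecule set")
  if (length(references) != n) stop("models and references differ in length")
  mmag <- vapply(models, function(m) sqrt(sum(m$dipole^2)), numeric(1))
  rmag <- vapply(references, function(m) sqrt(sum(m$dipole^2)), numeric(1))
  dvec <- vapply(seq_len(n), function(i)
    sqrt(sum((models[[i]]$dipole - references[[i]]$dipole)^2)), numeric(1))
  dq <- vapply(seq_len(n), function(i)
    frob(models[[i]]$quadrupole - references[[i]]$quadrupole), numeric(1))
  qref <- vapply(references, function(m) frob(m$quadrupole), numeric(1))

  me <- mean(mmag - rmag)
  avg <- mean(rmag)
  null_mag <- sqrt(mean(rmag^2))
  null_quad <- sqrt(mean(qref^2))
  out <- list(
    me = me,
    rme = me / avg,
    rmse_dipole_mag = sqrt(mean((mmag - rmag)^2)),
    rmse_dipole_vec = sqrt(mean(dvec^2)),
    rmse_quadrupole = sqrt(mean(dq^2)),
    null_rmse_dipole_mag = null_mag,
    null_rmse_dipole_vec = null_mag,
    null_rmse_quadrupole = null_quad
  )
  out$rrmse_dipole_mag <- out$rmse_dipole_mag / null_mag
  out$rrmse_dipole_vec <- out$rmse_dipole_vec / null_mag
  out$rrmse_quadrupole <- out$rmse_quadrupole / null_quad
  class(out) <- "multipole_error_stats"
  out
}

#' @export
print.multipole_error_stats <- function(x, ...) {
  cat("multipole error statistics (a.u.; RRMSE as fractions)\n")
  cat(sprintf("  ME dipole magnitude    %+0.4f   RME %+0.1f%%\n", x$me, 100 * x$rme))
  cat(sprintf("  RMSE |mu| %0.4f (RRMSE %0.3f)  RMSE mu vec %0.4f (RRMSE %0.3f)\n",
              x$rmse_dipole_mag, x$rrmse_dipole_mag,
              x$rmse_dipole_vec, x$rrmse_dipole_vec))
  cat(sprintf("  RMSE quadrupole %0.4f (RRMSE %0.3f)\n",
              x$rmse_quadrupole, x$rrmse_quadrupole))
  invisible(x)
}
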