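# Quadrupole resorption (QR): move charge q_Ab from atom image b to atom A
# and compensate entirely on the receiving atom. The transfer's shift
# dipole is cancelled by a compensating atomic dipole q_Ab R_Ab Rhat_Ab
# placed on atom A, and the quadrupole the shift generates about atom A's
# center is removed from atom A's tensor:
#   Theta'_A = Theta_A + sum_b q_Ab R_Ab^2 (Rhat Rhat^T - I/3).
# Both corrections live on the self atom, so QR confines dipole and
# quadrupole changes to self atoms while charge changes reach the bonded
# neighbors; the conservation triple holds about any origin, pair by pair.
#
# The optimal transfers minimize, per atom block,
#   sum_b (q_Ab R_Ab^2)^2 / w_Ab^2 + || Theta'_A ||_F^2
# giving C^(A) S^(A) = V^(A) with C as in atom_block(kind = "QR"),
# V_b = -w_Ab (Rhat^T Theta_A Rhat) (tracelessness removes the I/3 term),
# and q_Ab = w_Ab S_b / R_Ab^2.

#' Right-hand side of one atom's quadrupole-resorption system
#'
#' @param p a `stockholder_partition`; the atom's quadrupole tensor must be
#'   traceless (validation error beyond 1e-8).
#' @param atom atom index A.
#' @param block optionally a precomputed `atom_block(p, atom, "QR")`.
#' @return Per-slot vector
#'   \eqn{V^{(A)}_b = -w_{Ab}\,\hat R_{Ab}^T \Theta_A \hat R_{Ab}}.
#' @export
build_qr_rhs <- function(p, atom, block = NULL) {
  if (is.null(block)) block <- atom_block(p, atom, "QR")
  Theta <- p$quad[, , atom]
  if (abs(sum(diag(Theta))) > 1e-8) {
    stop(sprintf("atom %d: quadrupole trace %.3e exceeds tolerance; detrace the input",
                 atom, sum(diag(Theta))))
  }
  U <- block$dirs
  unname(-block$weights * rowSums((U %*% Theta) * U))
}

#' Solve the quadrupole-resorption update of a partition
#'
#' One conjugate-gradient block solve per atom, returning the transfers
#' together with the self-atom compensating dipoles and traceless
#' quadrupole deltas they imply. The result is the unique minimizer of the
#' convex QR loss.
#'
#' @param p a `stockholder_partition` with pairs enumerated.
#' @param tol relative residual tolerance passed to [cg_solve()].
#' @return A `qr_update`: `transfers` (a `transfer_set`, kind QR),
#'   `comp_dipoles` (n x 3, exactly cancelling the point-charge dipole
#'   change), and `quad_deltas` (3 x 3 x n traceless tensors added to the
#'   atomic quadrupoles).
#' @export
solve_qr <- function(p, tol = 1e-10) {
  transfers <- solve_resorption(p, "QR", tol)
  pr <- p$pairs
  q <- transfers$q
  n <- length(p$charge)
  amt <- q * pr$dist
  comp <- accumulate_rows(cbind(amt * pr$ux, amt * pr$uy, amt * pr$uz), pr$a, n)
  quad_deltas <- array(0, c(3, 3, n))
  if (nrow(pr) > 0) {
    s <- q * pr$dist^2
    U <- as.matrix(pr[, c("ux", "uy", "uz")])
    comps <- cbind(s * (U[, 1]^2 - 1 / 3), s * (U[, 2]^2 - 1 / 3),
                   s * (U[, 3]^2 - 1 / 3),
                   s * U[, 1] * U[, 2], s * U[, 1] * U[, 3], s * U[, 2] * U[, 3])
    acc <- matrix(0, n, 6)
    rs <- rowsum(comps, pr$a)
    acc[as.integer(rownames(rs)), ] <- rs
    quad_deltas[1, 1, ] <- acc[, 1]; quad_deltas[2, 2, ] <- acc[, 2]
    quad_deltas[3, 3, ] <- acc[, 3]
    quad_deltas[1, 2, ] <- quad_deltas[2, 1, ] <- acc[, 4]
    quad_deltas[1, 3, ] <- quad_deltas[3, 1, ] <- acc[, 5]
    quad_deltas[2, 3, ] <- quad_deltas[3, 2, ] <- acc[, 6]
  }
  structure(list(transfers = transfers, comp_dipoles = comp,
                 quad_deltas = quad_deltas),
            class = "qr_update")
}

#' @export
print.qr_update <- function(x, ...) {
  cat(sprintf("qr_update: %d directed transfers, max |comp dipole| = %.3e a.u.\n",
              length(x$transfers$q),
              if (nrow(x$comp_dipoles)) max(abs(x$comp_dipoles)) else 0))
  invisible(x)
}

#' Apply a quadrupole-resorption update to a partition
#'
#' Moves the transfer charges, adds the compensating dipoles, and removes
#' the resorbed part of each atomic quadrupole. Dipole and quadrupole
#' changes are confined to self atoms; the conservation triple (net
#' charge, total dipole, total traceless quadrupole about any origin) is
#' preserved to rounding, and every quadrupole tensor stays traceless.
#'
#' @param p the partition the update was solved from.
#' @param update a `qr_update` from [solve_qr()].
#' @return The updated `stockholder_partition`.
#' @export
apply_qr <- function(p, update) {
  stopifnot(inherits(update, "qr_update"))
  pr <- p$pairs
  q <- update$transfers$q
  out <- p
  n <- length(p$charge)
  out$charge <- p$charge + tapply_sum(q, pr$a, n) - tapply_sum(q, pr$b, n)
  out$dipole <- p$dipole + update$comp_dipoles
  out$quad <- p$quad + update$quad_deltas
  out$n_electrons <- out$z - out$charge
  out
}
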