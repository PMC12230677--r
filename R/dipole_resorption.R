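# Dipole resorption (DR): move charge q_Ab from atom image b to atom A so
# that part of each atomic dipole is re-expressed as adjusted point
# charges. Each directed transfer generates the shift dipole
# q_Ab (r_A - r_b); half of its negative is assigned to each member of the
# pair, which leaves the system's net charge, total dipole moment, and
# total traceless quadrupole moment about any origin exactly unchanged.
# Atomic quadrupole tensors are untouched by DR.
#
# The optimal transfers minimize, independently for each atom block,
#   sum_b (q_Ab R_Ab)^2 / w_Ab^2  +  || mu_A + sum_b q_Ab R_Ab Rhat_Ab ||^2
# whose normal equations are the block system M^(A) Y^(A) = T^(A) with
# M as in atom_block(kind = "DR"), T_b = -w_Ab (mu_A . Rhat_Ab), and
# q_Ab = w_Ab Y_b / R_Ab. The first term switches transfers off as
# OP -> 0 (q_Ab is proportional to w_Ab^2 for small OP); the second
# credits each transfer's full pair dipole to the owning atom, which is
# what makes the global system block-diagonal across atoms.

#' Right-hand side of one atom's dipole-resorption system
#'
#' @param p a `stockholder_partition`.
#' @param atom atom index A.
#' @param block optionally a precomputed `atom_block(p, atom, "DR")`.
#' @return Per-slot vector \eqn{T^{(A)}_b = -w_{Ab}(\mu_A \cdot \hat R_{Ab})};
#'   zero entries wherever the slot weight vanishes.
#' @export
build_dr_rhs <- function(p, atom, block = NULL) {
  if (is.null(block)) block <- atom_block(p, atom, "DR")
  unname(-drop(block$dirs %*% p$dipole[atom, ]) * block$weights)
}

#' Solve the dipole-resorption transfers of a partition
#'
#' Runs one conjugate-gradient block solve per atom and converts the block
#' solutions into per-pair charge transfers. The result is the unique
#' global minimizer of the convex DR loss (every block matrix is symmetric
#' positive definite with eigenvalues at least 1).
#'
#' @param p a `stockholder_partition` with pairs enumerated.
#' @param tol relative residual tolerance passed to [cg_solve()].
#' @return A `transfer_set`: charge `q` moved from image b to atom A for
#'   every stored directed pair (aligned with `p$pairs` rows), plus one
#'   solver report per atom. Mirrored transfers are solved independently.
#' @export
solve_dr <- function(p, tol = 1e-10) {
  solve_resorption(p, "DR", tol)
}

solve_resorption <- function(p, kind, tol = 1e-10) {
  n <- length(p$charge)
  q <- numeric(nrow(p$pairs))
  reports <- vector("list", n)
  for (A in seq_len(n)) {
    block <- atom_block(p, A, kind)
    if (block_dim(block) == 0) {
      reports[[A]] <- data.frame(atom = A, dim = 0L, matvecs = 0L, residual = 0)
      next
    }
    rhs <- if (kind == "DR") build_dr_rhs(p, A, block) else build_qr_rhs(p, A, block)
    sol <- tryCatch(cg_solve(block, rhs, tol = tol),
                    error = function(e) stop("atom ", A, ": ", conditionMessage(e)))
    rows <- which(p$pairs$a == A)
    scale <- if (kind == "DR") block$slots$dist else block$slots$dist^2
    q[rows] <- block$weights * sol$solution / scale
    reports[[A]] <- data.frame(atom = A, dim = block_dim(block),
                               matvecs = sol$report$matvec_count,
                               residual = sol$report$residual_norm)
  }
  structure(list(q = q, kind = kind, pairs = p$pairs,
                 reports = do.call(rbind, reports)),
            class = "transfer_set")
}

#' @export
print.transfer_set <- function(x, ...) {
  cat(sprintf("transfer_set (%s): %d directed transfers, max |q_ab| = %.3e e\n",
              x$kind, length(x$q), if (length(x$q)) max(abs(x$q)) else 0))
  invisible(x)
}

#' Tabulate a transfer set for audit
#'
#' @param x a `transfer_set`.
#' @param ... unused.
#' @return Data frame with atomA, atomB, translation, and q_ab columns.
#' @export
as.data.frame.transfer_set <- function(x, ...) {
  data.frame(atomA = x$pairs$a, atomB = x$pairs$b,
             t1 = x$pairs$t1, t2 = x$pairs$t2, t3 = x$pairs$t3,
             q_ab = x$q)
}

#' Apply dipole-resorption transfers to a partition
#'
#' Updates charges by the antisymmetric transfer sums and updates atomic
#' dipoles so that half of each pair's shift dipole is assigned to each
#' member. Quadrupole tensors are unchanged. The net charge, total dipole
#' moment (charges plus atomic dipoles), and total traceless quadrupole
#' moment about any fixed origin are preserved to rounding.
#'
#' @param p the partition the transfers were solved from.
#' @param transfers a `transfer_set` with `kind = "DR"`.
#' @return The updated `stockholder_partition`.
#' @export
apply_dr <- function(p, transfers) {
  stopifnot(inherits(transfers, "transfer_set"), transfers$kind == "DR")
  pr <- p$pairs
  q <- transfers$q
  out <- p
  out$charge <- p$charge +
    as.numeric(tapply_sum(q, pr$a, length(p$charge))) -
    as.numeric(tapply_sum(q, pr$b, length(p$charge)))
  # each directed transfer contributes + q R Rhat / 2 to BOTH atoms' dipoles
  half <- 0.5 * q * pr$dist
  contrib <- cbind(half * pr$ux, half * pr$uy, half * pr$uz)
  out$dipole <- p$dipole + accumulate_rows(contrib, pr$a, length(p$charge)) +
    accumulate_rows(contrib, pr$b, length(p$charge))
  out$n_electrons <- out$z - out$charge
  out
}

tapply_sum <- function(x, index, n) {
  out <- numeric(n)
  if (length(x) > 0) {
    s <- rowsum(x, index)
    out[as.integer(rownames(s))] <- s
  }
  out
}

accumulate_rows <- function(mat, index, n) {
  out <- matrix(0, n, 3)
  if (nrow(mat) > 0) {
    s <- rowsum(mat, index)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}
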