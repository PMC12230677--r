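# Independent oracles used across the suite. These are built directly from
# the printed block-matrix formulas and from the written loss functions,
# not from the package's matrix-free solver path.

bohr <- function(x) x / 0.529177210903
bohr_to_ang_mat <- function(x) x * 0.529177210903

# dense DR block matrix: diag 1 + w^2, off-diag w_b w_d (Rhat_b . Rhat_d)
dense_dr_matrix <- function(p, atom) {
  s <- p$pairs[p$pairs$a == atom, , drop = FALSE]
  w <- 2 * tanh(2 * s$op)
  U <- as.matrix(s[, c("ux", "uy", "uz")])
  n <- nrow(s)
  M <- matrix(0, n, n)
  for (b in seq_len(n)) for (d in seq_len(n)) {
    M[b, d] <- (b == d) + w[b] * w[d] * sum(U[b, ] * U[d, ])
  }
  M
}

# dense QR block matrix: diag 1 + (2/3) w^2,
# off-diag w_b w_d ((Rhat_b . Rhat_d)^2 - 1/3)
dense_qr_matrix <- function(p, atom) {
  s <- p$pairs[p$pairs$a == atom, , drop = FALSE]
  w <- 2 * tanh(2 * s$op)
  U <- as.matrix(s[, c("ux", "uy", "uz")])
  n <- nrow(s)
  C <- matrix(0, n, n)
  for (b in seq_len(n)) for (d in seq_len(n)) {
    cth <- sum(U[b, ] * U[d, ])
    C[b, d] <- if (b == d) 1 + (2 / 3) * w[b]^2 else
      w[b] * w[d] * (cth^2 - 1 / 3)
  }
  C
}

# written DR loss over all directed transfers with op > 0
# (slots with op = 0 carry no transfer): first term (q R)^2 / w^2, second
# term the squared residual dipole with each transfer's full pair dipole
# credited to its owning atom
dr_loss <- function(p, q_active, active) {
  pr <- p$pairs
  q <- numeric(nrow(pr))
  q[active] <- q_active
  w <- 2 * tanh(2 * pr$op[active])
  first <- sum((q[active] * pr$dist[active])^2 / w^2)
  second <- 0
  for (A in seq_along(p$charge)) {
    rows <- which(pr$a == A)
    mu <- p$dipole[A, ]
    for (r in rows) {
      mu <- mu + q[r] * pr$dist[r] * c(pr$ux[r], pr$uy[r], pr$uz[r])
    }
    second <- second + sum(mu^2)
  }
  first + second
}

# written QR loss: first term (q R^2)^2 / w^2, second term the squared
# Frobenius norm of the residual quadrupole after removing the
# shift-generated tensor q R^2 (Rhat Rhat^T - I/3) from the self atom
qr_loss <- function(p, q_active, active) {
  pr <- p$pairs
  q <- numeric(nrow(pr))
  q[active] <- q_active
  w <- 2 * tanh(2 * pr$op[active])
  first <- sum((q[active] * pr$dist[active]^2)^2 / w^2)
  second <- 0
  for (A in seq_along(p$charge)) {
    rows <- which(pr$a == A)
    Th <- p$quad[, , A]
    for (r in rows) {
      u <- c(pr$ux[r], pr$uy[r], pr$uz[r])
      Th <- Th + q[r] * pr$dist[r]^2 * (tcrossprod(u) - diag(3) / 3)
    }
    second <- second + sum(Th^2)
  }
  first + second
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ei <- numeric(n); ei[i] <- h
    ej <- numeric(n); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h^2)
  }
  H
}

# generic dense quadratic minimizer of a written loss: x* = -H^{-1} g
minimize_quadratic <- function(f, n) {
  g <- num_grad(f, numeric(n))
  H <- num_hessian(f, numeric(n))
  -solve(H, g)
}

total_moments <- function(p, origin) {
  s <- system_multipoles(p, "charges_dipoles_quadrupoles", origin)
  c(sum(p$charge), s$dipole, as.vector(s$quadrupole))
}

random_partition <- function(seed, n = 6) {
  make_fixture("random", size = n, seed = seed)
}
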