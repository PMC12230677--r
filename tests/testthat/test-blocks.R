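test_that("matrix-free products match the dense block matrices", {
  set.seed(11)
  for (seed in 1:5) {
    p <- random_partition(seed, n = 7)
    for (A in seq_along(p$charge)) {
      nb <- sum(p$pairs$a == A)
      if (nb == 0) next
      y <- rnorm(nb)
      expect_lt(max(abs(dr_matvec(atom_block(p, A, "DR"), y) -
                        dense_dr_matrix(p, A) %*% y)), 1e-12)
      expect_lt(max(abs(qr_matvec(atom_block(p, A, "QR"), y) -
                        dense_qr_matrix(p, A) %*% y)), 1e-12)
    }
  }

  # single-slot DR block with OP = 0.5: diagonal is 1 + (2 tanh 1)^2
  dia <- make_fixture("diatomic", op_scale = 0.5)
  b <- atom_block(dia, 1, "DR")
  expect_equal(dr_matvec(b, 1), 1 + (2 * tanh(1))^2)
  expect_equal(dr_matvec(b, 0), 0)

  # single-slot QR block with OP = 1: diagonal is 1 + (2/3)(2 tanh 2)^2
  dia1 <- make_fixture("diatomic", op_scale = 1)
  expect_equal(qr_matvec(atom_block(dia1, 1, "QR"), 2),
               2 * (1 + (2 / 3) * (2 * tanh(2))^2))
})

test_that("collinear QR slots use the (1 - 1/3) geometric factor", {
  # chain interior atom has two collinear neighbors: Rhat parallel or
  # antiparallel, (Rhat_b . Rhat_d)^2 = 1 either way
  p <- make_fixture("chain", size = 3, seed = 1, quadrupole_scale = 0)
  A <- 2
  s <- p$pairs[p$pairs$a == A, ]
  w <- 2 * tanh(2 * s$op)
  C <- dense_qr_matrix(p, A)
  expect_equal(C[1, 2], w[1] * w[2] * (1 - 1 / 3))
  expect_lt(max(abs(qr_matvec(atom_block(p, A, "QR"), c(1, -1)) -
                    C %*% c(1, -1))), 1e-12)
})

test_that("block operators are symmetric and positive definite", {
  set.seed(22)
  for (seed in 1:10) {
    p <- random_partition(seed)
    for (kind in c("DR", "QR")) {
      A <- sample(seq_along(p$charge), 1)
      b <- atom_block(p, A, kind)
      n <- qdrcharges:::block_dim(b)
      if (n == 0) next
      y <- rnorm(n); z <- rnorm(n)
      mv <- if (kind == "DR") dr_matvec else qr_matvec
      expect_lt(abs(sum(y * mv(b, z)) - sum(z * mv(b, y))), 1e-12)
      expect_gte(sum(y * mv(b, y)), sum(y^2) - 1e-12)
    }
  }
})

test_that("conjugate gradients matches dense solves within the matvec budget", {
  expect_equal(cg_solve(atom_block(make_fixture("diatomic"), 1, "DR"),
                        0)$report$matvec_count, 0)

  set.seed(33)
  for (seed in 1:20) {
    p <- random_partition(seed, n = 8)
    for (A in seq_along(p$charge)) {
      nb <- sum(p$pairs$a == A)
      if (nb == 0) next
      rhs <- rnorm(nb)
      for (kind in c("DR", "QR")) {
        blk <- atom_block(p, A, kind)
        res <- cg_solve(blk, rhs, tol = 1e-10)
        dense <- if (kind == "DR") dense_dr_matrix(p, A) else dense_qr_matrix(p, A)
        expect_lt(max(abs(res$solution - solve(dense, rhs))), 1e-9)
        expect_lte(res$report$matvec_count, if (kind == "DR") 4L else 8L)
        expect_true(res$report$converged)
      }
    }
  }
})

test_that("cg_solve reports dimension mismatches and non-convergence", {
  p <- make_fixture("water_like")
  blk <- atom_block(p, 3, "DR")
  expect_error(cg_solve(blk, rnorm(5)), "dimension")
  expect_error(dr_matvec(blk, rnorm(7)), "dimension")
  expect_error(cg_solve(blk, rnorm(qdrcharges:::block_dim(blk)),
                        tol = 0, max_matvecs = 1), "not converged")
})

test_that("eigen diagnostics reflect the identity-plus-low-rank structure", {
  # all weights zero: the block is the identity
  far <- stockholder_partition(
    c(6, 6, 6), rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
    c(0, 0, 0),
    op_table = data.frame(a = c(1, 1), b = c(2, 3), t1 = 0, t2 = 0, t3 = 0,
                          op = c(0, 0)))
  ed <- eigen_diagnostics(atom_block(far, 1, "DR"))
  expect_equal(ed$eigenvalues, c(1, 1))
  expect_equal(ed$n_distinct, 1L)
  expect_true(ed$bounds_ok)

  set.seed(44)
  for (seed in 1:15) {
    p <- random_partition(seed, n = 9)
    A <- which.max(tabulate(p$pairs$a))   # largest block
    dr <- eigen_diagnostics(atom_block(p, A, "DR"))
    qr <- eigen_diagnostics(atom_block(p, A, "QR"))
    expect_lte(dr$n_distinct, 4L)
    expect_lte(qr$n_distinct, 8L)
    expect_gte(min(dr$eigenvalues), 1 - 1e-12)
    expect_gte(min(qr$eigenvalues), 1 - 1e-12)
    sop <- summed_overlap(p, A)
    expect_lte(max(dr$eigenvalues), 1 + 16 * sop^2 + 1e-9)
    expect_true(dr$bounds_ok)
    expect_true(qr$bounds_ok)
    # condition number bound
    expect_lte(max(dr$eigenvalues) / min(dr$eigenvalues), 1 + 16 * sop^2 + 1e-9)
  }
})
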