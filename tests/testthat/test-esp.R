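test_that("valid-point selection enforces all three rules", {
  # single atom at the origin; density from its exponential cloud
  p <- stockholder_partition(8, rbind(c(0, 0, 0)), 0)
  g <- make_oracle_grids(p, spacing = 0.5, padding = 6.5)
  mask <- valid_grid_mask(g$density, p)
  pts <- grid_points(g$density)
  r_ang <- sqrt(rowSums(pts^2)) * 0.529177210903
  rho <- as.vector(g$density$values)
  ok <- as.vector(mask$mask)
  # the three rules, point by point
  expect_equal(ok, rho < 1e-4 & r_ang > 2 & r_ang <= 5)
  # each rule excludes something on this grid
  expect_true(any(!ok & r_ang <= 2))            # inner cutoff active
  expect_true(any(!ok & r_ang > 5))             # outer cutoff active
  expect_true(any(!ok & r_ang > 2 & rho >= 1e-4))  # density rule active
  expect_equal(mask$n_valid, sum(ok))
  # a geometry placed far outside the grid leaves nothing valid
  p_far <- stockholder_partition(8, rbind(c(500, 0, 0)), 0)
  expect_error(valid_grid_mask(g$density, p_far), "valid")
})

test_that("the point-charge potential obeys Coulomb's law and units", {
  p <- stockholder_partition(8, rbind(c(0, 0, 0)), 1, net_charge = 1)
  expect_equal(model_potential(p, rbind(c(1, 0, 0)), "charges"), 1)
  expect_equal(model_potential(p, rbind(c(0, 2, 0)), "charges"), 0.5)
  expect_equal(model_potential(p, rbind(c(1, 0, 0)), "charges", units = "kcal"),
               627.5094740631)
  expect_error(model_potential(p, rbind(c(0, 0, 0)), "charges"), "nucleus")
})

test_that("a pure dipole gives an antisymmetric potential", {
  p <- stockholder_partition(8, rbind(c(0, 0, 0)), 0,
                             dipoles = rbind(c(0, 0, 0.4)))
  v <- model_potential(p, rbind(c(0, 0, 3), c(0, 0, -3)),
                       c("charges", "atomic_dipoles"))
  expect_equal(v[1], -v[2])
  expect_equal(v[1], 0.4 / 9, tolerance = 1e-12)
})

test_that("the cloud-penetration closed form matches radial integration", {
  a <- 2.5; b <- 2.0
  p <- stockholder_partition(8, rbind(c(0, 0, 0)), 0,
                             cloud_a = a, cloud_b = b)
  # numerical potential of the neutral distribution: +N_cloud point charge
  # plus the electron cloud integrated in shells
  n_cloud <- 8 * pi * a / b^3
  v_num <- function(r) {
    inner <- stats::integrate(function(s) 4 * pi * s^2 * a * exp(-b * s),
                              0, r, rel.tol = 1e-12)$value
    outer <- stats::integrate(function(s) 4 * pi * s * a * exp(-b * s),
                              r, Inf, rel.tol = 1e-12)$value
    n_cloud / r - (inner / r + outer)
  }
  for (r in c(0.3, 1, 2.5, 6)) {
    v <- model_potential(p, rbind(c(r, 0, 0)), "cloud_penetration")
    expect_equal(v, v_num(r), tolerance = 1e-9)
  }
  # exponential decay: negligible far beyond 1/b
  expect_lt(abs(model_potential(p, rbind(c(15, 0, 0)), "cloud_penetration")),
            1e-10)
  expect_error(
    model_potential(stockholder_partition(8, rbind(c(0, 0, 0)), 0),
                    rbind(c(1, 0, 0)), "cloud_penetration"),
    "cloud parameters")
})

test_that("esp_metrics implements RMSE, RRMSE = 1 for the null model, and R^2", {
  p <- make_fixture("water_like")
  g <- make_oracle_grids(p, spacing = 0.7)
  mask <- valid_grid_mask(g$density, p)
  v <- model_potential(p, grid_points(g$esp), "charges")

  perfect <- esp_metrics(v, g$esp$values, mask)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$rrmse, 0)
  expect_equal(perfect$r_squared, 1)

  null <- esp_metrics(rep(0, length(v)), g$esp$values, mask)
  expect_identical(null$rrmse, 1)
  expect_identical(null$r_squared, 0)

  # R^2 = 1 - RRMSE^2; a model at RRMSE 0.3 sits at R^2 = 0.91
  shrunk <- esp_metrics(0.7 * as.vector(g$esp$values), g$esp$values, mask)
  expect_equal(shrunk$rrmse, 0.3, tolerance = 1e-12)
  expect_equal(shrunk$r_squared, 0.91, tolerance = 1e-12)

  expect_error(esp_metrics(v, rep(0, length(v)), mask), "identically zero")
})

test_that("convex shrinkage toward the truth keeps RRMSE at most 1", {
  p <- make_fixture("water_like")
  g <- make_oracle_grids(p, spacing = 0.8)
  mask <- valid_grid_mask(g$density, p)
  truth <- as.vector(g$esp$values)
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_lte(esp_metrics(lam * truth, g$esp$values, mask)$rrmse, 1 + 1e-12)
  }
})

test_that("oracle grids close: each model reproduces its own ground truth", {
  p <- make_fixture("water_like")
  gq <- make_oracle_grids(p, spacing = 0.7, terms = "charges")
  mask <- valid_grid_mask(gq$density, p)
  vq <- model_potential(p, grid_points(gq$esp), "charges")
  expect_lt(esp_metrics(vq, gq$esp$values, mask)$rmse_au, 1e-10)

  gqd <- make_oracle_grids(p, spacing = 0.7,
                           terms = c("charges", "atomic_dipoles"))
  vqd <- model_potential(p, grid_points(gqd$esp),
                         c("charges", "atomic_dipoles"))
  expect_lt(esp_metrics(vqd, gqd$esp$values, mask)$rmse_au, 1e-10)
  # charges-only against the dipole-bearing truth must miss
  expect_gt(esp_metrics(vq, gqd$esp$values, mask)$rmse_au, 0)
})

test_that("coherent radial ring dipoles defeat every point-charge-only model", {
  p <- make_fixture("ring_tube", size = 12)
  R <- sqrt(sum(p$pos[1, 1:2]^2))
  # concentric evaluation circles, offset half an atom spacing in angle
  n_ev <- 24
  ang <- 2 * pi * (seq_len(n_ev) - 0.5) / n_ev
  circle <- function(r) cbind(r * cos(ang), r * sin(ang), 0)
  inside <- circle(0.4 * R)
  outside <- circle(1.8 * R)
  # the alternating ring has a symmetry that forces the angular mean of any
  # point-charge-only potential to vanish on both circles
  v_in_q <- model_potential(p, inside, "charges")
  v_out_q <- model_potential(p, outside, "charges")
  expect_lt(abs(mean(v_in_q) - mean(v_out_q)), 1e-12)
  # the radial-dipole ground truth sustains an inside/outside offset
  v_in <- model_potential(p, inside, c("charges", "atomic_dipoles"))
  v_out <- model_potential(p, outside, c("charges", "atomic_dipoles"))
  expect_gt(abs(mean(v_in) - mean(v_out)), 1e-3)
})

test_that("the Ewald charge sum reproduces the rocksalt Madelung constant", {
  p <- make_fixture("rocksalt")
  delta <- c(1e-3, 0, 0)
  pt <- rbind(p$pos[1, ] + delta)
  v_env <- model_potential(p, pt, "charges") - p$charge[1] / sqrt(sum(delta^2))
  r_nn <- bohr(5.64 / 2)
  madelung <- 1.7475645946
  expect_equal(v_env, -madelung * abs(p$charge[1]) / r_nn, tolerance = 1e-4)
  # accuracy-parameter independence (changes alpha, rcut, kcut)
  v2 <- model_potential(p, pt, "charges", ewald_accuracy = 1e-10)
  expect_lt(abs(model_potential(p, pt, "charges") - v2), 1e-7)
  # 1-D/2-D periodic systems are declined
  p1 <- p; p1$cell$periodic <- c(TRUE, TRUE, FALSE)
  expect_error(model_potential(p1, pt, "charges"), "3-D periodic")
})
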