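make_table <- function(values) {
  # values: method -> conformation x atom matrix
  do.call(rbind, lapply(names(values), function(m) {
    v <- values[[m]]
    do.call(rbind, lapply(seq_len(nrow(v)), function(j) {
      data.frame(method = m, conformation = j,
                 atom = seq_len(ncol(v)), charge = v[j, ])
    }))
  })) |> ensemble_charge_table()
}

test_that("conformation averaging is the arithmetic mean per atom", {
  tab <- make_table(list(a = rbind(c(0.1, -0.1), c(0.3, -0.3))))
  avg <- conformation_average(tab)
  expect_equal(avg$q_avg, c(0.2, -0.2))

  # a single conformation is the identity
  one <- make_table(list(a = rbind(c(0.4, -0.4))))
  expect_equal(conformation_average(one)$q_avg, c(0.4, -0.4))

  # random table against a direct double loop
  set.seed(5)
  v <- matrix(rnorm(40), 8, 5)
  tab <- make_table(list(m = v))
  direct <- vapply(1:5, function(aa) mean(v[, aa]), numeric(1))
  expect_equal(conformation_average(tab)$q_avg, direct)
})

test_that("rms charge transfer magnitude is the population rms about the mean", {
  avg <- data.frame(method = "m", atom = 1:2, q_avg = c(0.5, -0.5))
  expect_equal(rms_charge_transfer(avg, "m"), 0.5)
  # equal charges: zero spread
  avg2 <- data.frame(method = "m", atom = 1:3, q_avg = rep(0.37, 3))
  expect_equal(rms_charge_transfer(avg2, "m"), 0)
  # 50-atom set against the population-sd oracle
  set.seed(6)
  q <- rnorm(50, mean = 0.1)
  avg3 <- data.frame(method = "m", atom = 1:50, q_avg = q)
  expect_equal(rms_charge_transfer(avg3, "m"),
               sqrt(mean((q - mean(q))^2)), tolerance = 1e-14)
})

test_that("conformational sensitivity pools squared deviations and scales", {
  # constant across conformations: zero sensitivity (and an error-free sigma)
  tab0 <- make_table(list(m = rbind(c(0.3, -0.3), c(0.3, -0.3))))
  expect_equal(conformational_sensitivity(tab0, "m")$sensitivity, 0)

  # one atom varying (0.1, 0.3), one constant, 2-atom set: pooled rms
  tab1 <- make_table(list(m = rbind(c(0.1, 0.5), c(0.3, 0.5))))
  direct <- sqrt(mean(c(0.1 - 0.2, 0.3 - 0.2, 0, 0)^2))
  s <- conformational_sensitivity(tab1, "m")
  expect_equal(s$sensitivity, direct)

  # homogeneity: doubling all charges doubles the sensitivity, fixes the ratio
  tab2 <- make_table(list(m = 2 * rbind(c(0.1, 0.5), c(0.3, 0.5))))
  s2 <- conformational_sensitivity(tab2, "m")
  expect_equal(s2$sensitivity, 2 * s$sensitivity)
  expect_equal(s2$normalized_sensitivity, s$normalized_sensitivity)

  expect_error(conformational_sensitivity(
    make_table(list(m = rbind(c(0.1, 0.2)))), "m"), "2 conformations")
})

test_that("sensitivity and average-spread decompose the pooled variance", {
  set.seed(9)
  v <- matrix(rnorm(200, sd = 0.2), 20, 10) +
    matrix(rnorm(10, sd = 0.5), 20, 10, byrow = TRUE)
  tab <- make_table(list(m = v))
  s <- conformational_sensitivity(tab, "m")$sensitivity
  qa <- conformation_average(tab)$q_avg
  pooled <- mean((as.vector(v) - mean(v))^2)
  # law of total variance: within-atom + between-atom parts
  between <- mean((rep(qa, each = nrow(v)) - mean(qa))^2)
  expect_equal(s^2 + between, pooled, tolerance = 1e-12)
})

test_that("method correlations match the Pearson oracle", {
  tab <- make_table(list(a = rbind(c(0.2, -0.1, 0.4)),
                         b = rbind(c(0.2, -0.1, 0.4)),
                         c = rbind(-c(0.2, -0.1, 0.4) + 0.3)))
  mc <- method_correlations(conformation_average(tab))
  expect_equal(unname(mc$omega["a", "b"]), 1)
  expect_equal(unname(mc$omega["a", "c"]), -1)

  set.seed(10)
  Q <- matrix(rnorm(300), 100, 3)
  tab2 <- make_table(list(m1 = t(Q[, 1, drop = FALSE]),
                          m2 = t(Q[, 2, drop = FALSE]),
                          m3 = t(Q[, 3, drop = FALSE])))
  mc2 <- method_correlations(conformation_average(tab2))
  expect_lt(max(abs(mc2$omega - cor(Q))), 1e-12)
  expect_equal(unname(diag(mc2$omega)), rep(1, 3))
  expect_lte(max(abs(mc2$omega)), 1 + 1e-12)
  expect_equal(mc2$s_alpha, rowSums(mc2$omega))

  expect_error(method_correlations(
    data.frame(method = "x", atom = 1:3, q_avg = rep(0.2, 3))), "2 methods")
})

test_that("a shared-profile method is the most confluent (sanity check)", {
  set.seed(12)
  base <- rnorm(60, sd = 0.4)
  mats <- c(list(mean_like = rbind(base)),
            lapply(1:4, function(i) rbind(0.8 * base + rnorm(60, sd = 0.25))))
  names(mats)[2:5] <- paste0("m", 1:4)
  mc <- method_correlations(conformation_average(make_table(mats)))
  expect_equal(names(which.max(mc$s_alpha)), "mean_like")
})

test_that("the Pareto table combines accuracy and sensitivity per method", {
  tab <- make_ensemble(20, n_conformations = 5, n_methods = 3,
                       perturbation = 0.03, seed = 2)
  med <- c(method_01 = 0.3, method_02 = 0.2, method_03 = 0.3)
  pt <- pareto_table(tab, med)
  expect_equal(nrow(pt), 3)
  expect_equal(pt$method[1], "method_02")       # lowest RRMSE first
  # ties on RRMSE break on sensitivity
  expect_lte(pt$sensitivity[2], pt$sensitivity[3])
  # row values equal the individually computed statistics
  s1 <- conformational_sensitivity(tab, "method_01")
  row <- pt[pt$method == "method_01", ]
  expect_equal(row$sensitivity, s1$sensitivity)
  expect_equal(row$normalized_sensitivity, s1$normalized_sensitivity)
  expect_equal(row$sigma, rms_charge_transfer(conformation_average(tab),
                                              "method_01"))
})

test_that("synthetic ensembles hit their designed statistics", {
  # identical methods: perfect correlation
  tab <- make_ensemble(15, n_conformations = 4, n_methods = 2,
                       perturbation = 0, method_mix = 1, seed = 3)
  sub <- tab[tab$method == "method_01", ]
  pooled_dev <- sub$charge - stats::ave(sub$charge, sub$atom)
  expect_equal(sqrt(mean(pooled_dev^2)), 0)   # zero jitter, zero sensitivity
  mc <- method_correlations(conformation_average(tab))
  expect_equal(unname(mc$omega[1, 2]), 1)

  # law of large numbers: measured sensitivity near the designed jitter
  big <- make_ensemble(10, n_conformations = 1000, n_methods = 1,
                       perturbation = 0.05, seed = 4)
  s <- conformational_sensitivity(big, "method_01")$sensitivity
  expect_lt(abs(s - 0.05) / 0.05, 0.05)
})
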