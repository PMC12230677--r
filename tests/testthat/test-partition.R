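test_that("exchange files round-trip through both dialects", {
  p <- make_fixture("random", seed = 9)
  for (dialect in c("qdr-json", "qdr-csv")) {
    path <- withr::local_tempfile(fileext = ".qdr")
    save_partition(p, path, dialect)
    q <- load_partition(path)
    expect_lt(max(abs(q$pos - p$pos)), 1e-12)
    expect_lt(max(abs(q$charge - p$charge)), 1e-12)
    expect_lt(max(abs(q$dipole - p$dipole)), 1e-12)
    expect_lt(max(abs(q$quad - p$quad)), 1e-12)
    expect_equal(q$pairs[, c("a", "b", "t1", "t2", "t3")],
                 p$pairs[, c("a", "b", "t1", "t2", "t3")])
    expect_lt(max(abs(q$pairs$op - p$pairs$op)), 1e-12)
  }
  # periodic cells survive too
  rs <- make_fixture("rocksalt")
  path <- withr::local_tempfile(fileext = ".json")
  save_partition(rs, path)
  q <- load_partition(path)
  expect_equal(nrow(q$pairs), nrow(rs$pairs))
  expect_lt(max(abs(q$cell$lattice - rs$cell$lattice)), 1e-12)
})

test_that("a one-sided pair list is completed by mirror symmetry", {
  p <- stockholder_partition(
    elements = c(8, 1), positions = rbind(c(0, 0, 0), c(1.5, 0, 0)),
    charges = c(-0.2, 0.2),
    op_table = data.frame(a = 1, b = 2, t1 = 0, t2 = 0, t3 = 0, op = 0.5))
  expect_equal(nrow(p$pairs), 2)
  expect_equal(sort(p$pairs$a), c(1, 2))
  expect_equal(p$pairs$op, c(0.5, 0.5))
  # mirrored directions are opposite
  expect_equal(p$pairs$ux[1], -p$pairs$ux[2])
})

test_that("invariant violations are rejected with informative errors", {
  expect_error(
    stockholder_partition(c(8, 1), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                          charges = c(-0.2, 0.2), net_charge = 0.5),
    "net_charge")
  badq <- array(0, c(3, 3, 1)); badq[1, 1, 1] <- 1   # nonzero trace
  expect_error(
    stockholder_partition(8, rbind(c(0, 0, 0)), 0, quadrupoles = badq),
    "trace")
  expect_error(
    stockholder_partition(c(8, 1), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                          charges = c(-0.2, 0.2),
                          op_table = data.frame(a = 1, b = 2, t1 = 0, t2 = 0,
                                                t3 = 0, op = -0.1)),
    "negative")
  # conflicting duplicate of a mirrored pair
  expect_error(
    stockholder_partition(c(8, 1), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                          charges = c(-0.2, 0.2),
                          op_table = data.frame(a = c(1, 2), b = c(2, 1),
                                                t1 = 0, t2 = 0, t3 = 0,
                                                op = c(0.5, 0.4))),
    "conflicting")
})

test_that("pair enumeration matches geometry rules and brute force", {
  # nonperiodic diatomic: exactly two mirrored pairs
  p <- stockholder_partition(
    c(9, 1), rbind(c(0, 0, 0), c(1.5, 0, 0)), c(0, 0),
    op_table = data.frame(a = 1, b = 2, t1 = 0, t2 = 0, t3 = 0, op = 0.5))
  expect_equal(nrow(p$pairs), 2)

  # beyond the 10 A cutoff with zero OP: empty pair set
  far <- stockholder_partition(c(9, 1), rbind(c(0, 0, 0), c(12, 0, 0)), c(0, 0))
  expect_equal(nrow(far$pairs), 0)

  # 1-atom cubic cell, 3 A edge, 10 A cutoff: image count equals the
  # brute-force count over the translation lattice |l|_inf <= 4
  cell <- qdrcharges:::normalize_cell(list(lattice = diag(3) * 3,
                                           periodic = c(TRUE, TRUE, TRUE)))
  pr <- enumerate_pairs(rbind(c(0, 0, 0)), cell, cutoff_sum = 10)
  ls <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  d <- sqrt(rowSums((ls * 3)^2))
  expect_equal(nrow(pr), sum(d <= 10 & d > 0))
  # and every enumerated image is a nontrivially translated self pair
  expect_true(all(pr$a == 1 & pr$b == 1))
  expect_false(any(pr$t1 == 0 & pr$t2 == 0 & pr$t3 == 0))
})

test_that("summed overlap population sums the atom's pairs", {
  iso <- stockholder_partition(8, rbind(c(0, 0, 0)), 0)
  expect_equal(summed_overlap(iso, 1), 0)

  dia <- make_fixture("diatomic", op_scale = 0.5)
  expect_equal(summed_overlap(dia, 1), 0.5)
  expect_equal(summed_overlap(dia, 2), 0.5)

  p <- make_fixture("random", size = 10, seed = 2)
  for (A in seq_along(p$charge)) {
    direct <- sum(p$pairs$op[p$pairs$a == A])
    expect_identical(summed_overlap(p, A), direct)
    expect_gte(direct, 0)
    expect_lt(direct, 2 * p$n_electrons[A])
  }
})

test_that("inputs violating the SOP bound draw a consistency warning", {
  expect_warning(
    stockholder_partition(
      c(1, 1), rbind(c(0, 0, 0), c(0.9, 0, 0)), c(0.9, 0.9),
      net_charge = 1.8,
      op_table = data.frame(a = 1, b = 2, t1 = 0, t2 = 0, t3 = 0, op = 0.5)),
    "summed overlap")
})
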