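# Stockholder-partition container and periodic pair enumeration.
#
# A partition holds, per atom in the reference cell: the atomic number, the
# nuclear position, the net atomic charge q_A, the atom-in-material dipole
# vector mu_A and traceless quadrupole tensor Theta_A, plus the pairwise
# overlap populations OP_Ab with nearby atom images. These are the inputs a
# stockholder electron-density partitioning code (DDEC6, Hirshfeld, MBIS, ...)
# produces; this package never computes them from electron densities.

#' Construct a stockholder partition
#'
#' Builds the central data object from per-atom quantities. Positions and
#' lattice vectors are supplied in Angstrom (the exchange-file convention)
#' and stored internally in bohr; multipoles are atomic units.
#'
#' @param elements integer vector of atomic numbers \eqn{z_A}.
#' @param positions n x 3 matrix of nuclear positions, Angstrom.
#' @param charges net atomic charges \eqn{q_A}, e.
#' @param dipoles n x 3 matrix of atomic dipole vectors, e bohr. Defaults to
#'   zeros.
#' @param quadrupoles 3 x 3 x n array of traceless atomic quadrupole tensors,
#'   e bohr^2, primitive-traceless convention (see [to_buckingham()]).
#'   Defaults to zeros.
#' @param op_table data frame of overlap populations with columns
#'   `a`, `b`, `t1`, `t2`, `t3`, `op`: atom indices, integer translation of
#'   the image of `b`, and OP value. Missing mirrored entries are completed
#'   by symmetry.
#' @param cell optional list with `lattice` (up to 3 rows of lattice vectors,
#'   Angstrom) and `periodic` (logical, length 3). `NULL` means nonperiodic.
#' @param n_electrons optional electron counts \eqn{N_A}; defaults to
#'   `elements - charges`.
#' @param cloud_a,cloud_b optional exponential electron-cloud parameters
#'   (e/bohr^3 and 1/bohr) of the tail model `a_A exp(-b_A r)`.
#' @param cutoff_radius per-atom density cutoff radius, Angstrom (default 5,
#'   so pair sums extend to 10 Angstrom for a pair of atoms).
#' @param method_name free-text label of the parent partitioning method.
#' @param net_charge total system charge; defaults to `sum(charges)`.
#' @param op_threshold overlap-population threshold retained with the object
#'   and used when pairs are enumerated (default 1e-4).
#' @param enumerate if `TRUE` (default) enumerate the pair list immediately.
#'
#' @return An object of class `stockholder_partition`.
#' @export
stockholder_partition <- function(elements, positions, charges,
                                  dipoles = NULL, quadrupoles = NULL,
                                  op_table = NULL, cell = NULL,
                                  n_electrons = NULL,
                                  cloud_a = NULL, cloud_b = NULL,
                                  cutoff_radius = 5,
                                  method_name = "unspecified",
                                  net_charge = NULL,
                                  op_threshold = 1e-4,
                                  enumerate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(elements) == n, length(charges) == n)
  if (is.null(dipoles)) dipoles <- matrix(0, n, 3)
  dipoles <- as.matrix(dipoles)
  if (is.null(quadrupoles)) quadrupoles <- array(0, c(3, 3, n))
  stopifnot(all(dim(dipoles) == c(n, 3)), all(dim(quadrupoles) == c(3, 3, n)))
  if (is.null(n_electrons)) n_electrons <- as.numeric(elements) - charges
  cutoff_radius <- rep_len(cutoff_radius, n)
  cell <- normalize_cell(cell)
  p <- structure(list(
    z = as.integer(elements),
    pos = ang_to_bohr(positions),
    charge = as.numeric(charges),
    dipole = dipoles,
    quad = quadrupoles,
    n_electrons = as.numeric(n_electrons),
    cloud_a = if (is.null(cloud_a)) rep(NA_real_, n) else as.numeric(cloud_a),
    cloud_b = if (is.null(cloud_b)) rep(NA_real_, n) else as.numeric(cloud_b),
    cutoff_radius = cutoff_radius,
    cell = cell,
    pairs = empty_pairs(),
    method_name = method_name,
    net_charge = if (is.null(net_charge)) sum(charges) else net_charge,
    op_threshold = op_threshold
  ), class = "stockholder_partition")
  if (enumerate) {
    p$pairs <- enumerate_pairs(p$pos, p$cell,
                               cutoff_sum = sum_cutoffs(cutoff_radius),
                               op_threshold = op_threshold,
                               op_table = op_table)
  }
  validate_partition(p)
  p
}

sum_cutoffs <- function(cutoff_radius) {
  # pairwise cutoff is r_A + r_B; with per-atom radii we use the largest sum
  2 * max(cutoff_radius)
}

normalize_cell <- function(cell) {
  if (is.null(cell)) return(list(lattice = NULL, periodic = c(FALSE, FALSE, FALSE)))
  periodic <- rep_len(as.logical(cell$periodic %||% c(TRUE, TRUE, TRUE)), 3)
  lattice <- cell$lattice
  if (!any(periodic)) return(list(lattice = NULL, periodic = periodic))
  lattice <- as.matrix(lattice)
  if (nrow(lattice) == sum(periodic) && sum(periodic) < 3) {
    full <- matrix(0, 3, 3)
    full[which(periodic), ] <- lattice
    lattice <- full
  }
  stopifnot(all(dim(lattice) == c(3, 3)))
  if (abs(det(lattice[periodic, , drop = FALSE] %*%
              t(lattice[periodic, , drop = FALSE]))) < 1e-12) {
    stop("lattice vectors of periodic directions must be linearly independent")
  }
  list(lattice = ang_to_bohr(lattice), periodic = periodic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_pairs <- function() {
  data.frame(a = integer(), b = integer(),
             t1 = integer(), t2 = integer(), t3 = integer(),
             op = numeric(), dist = numeric(),
             ux = numeric(), uy = numeric(), uz = numeric())
}

#' Validate a stockholder partition
#'
#' Checks every container invariant: symmetric traceless quadrupoles,
#' non-negative electron counts, charge/electron-count consistency, the
#' charge sum against the declared net charge, non-negative overlap
#' populations, unit pair directions, the absence of self pairs, and the
#' mirror symmetry of the pair list (every stored pair (A,b) has a partner
#' (B,a) with negated translation and equal OP).
#'
#' @param p a `stockholder_partition`.
#' @param tol tolerance for the scalar identities (default 1e-10).
#' @return `p`, invisibly; stops with a message naming the first violation.
#' @export
validate_partition <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "stockholder_partition"))
  n <- length(p$charge)
  for (A in seq_len(n)) {
    Q <- p$quad[, , A]
    if (max(abs(Q - t(Q))) > 1e-10) {
      stop(sprintf("atom %d: quadrupole tensor is not symmetric", A))
    }
    if (abs(sum(diag(Q))) > 1e-10) {
      stop(sprintf("atom %d: quadrupole tensor has |trace| = %.3e > 1e-10",
                   A, abs(sum(diag(Q)))))
    }
  }
  if (any(p$n_electrons < 0)) {
    stop(sprintf("atom %d: negative electron count",
                 which(p$n_electrons < 0)[1]))
  }
  dq <- abs(p$charge - (p$z - p$n_electrons))
  if (any(dq > tol)) {
    stop(sprintf("atom %d: charge inconsistent with z - N by %.3e",
                 which.max(dq), max(dq)))
  }
  if (abs(sum(p$charge) - p$net_charge) > tol) {
    stop(sprintf("atomic charges sum to %.12f but net_charge is %.12f",
                 sum(p$charge), p$net_charge))
  }
  pr <- p$pairs
  if (nrow(pr) > 0) {
    if (any(pr$op < 0)) stop("negative overlap population in pair list")
    if (any(pr$a == pr$b & pr$t1 == 0 & pr$t2 == 0 & pr$t3 == 0)) {
      stop("self pair (A = B, zero translation) in pair list")
    }
    if (!any(p$cell$periodic) && any(pr$t1 != 0 | pr$t2 != 0 | pr$t3 != 0)) {
      stop("nonzero translation in a nonperiodic pair list")
    }
    un <- abs(sqrt(pr$ux^2 + pr$uy^2 + pr$uz^2) - 1)
    if (any(un > 1e-12)) stop("pair direction is not a unit vector")
    key <- pair_key(pr$a, pr$b, pr$t1, pr$t2, pr$t3)
    mkey <- pair_key(pr$b, pr$a, -pr$t1, -pr$t2, -pr$t3)
    idx <- match(mkey, key)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("pair (%d,%d | %d %d %d) has no mirrored partner",
                   pr$a[bad], pr$b[bad], pr$t1[bad], pr$t2[bad], pr$t3[bad]))
    }
    if (any(abs(pr$op - pr$op[idx]) > 1e-12)) {
      stop("mirrored pairs carry unequal overlap populations")
    }
  }
  # Eq-15-type bound 0 <= SOP_A < 2 N_A: data consistency, warn not stop
  sop <- vapply(seq_len(n), function(A) sum(pr$op[pr$a == A]), numeric(1))
  if (any(sop >= 2 * p$n_electrons)) {
    warning(sprintf(
      "atom %d: summed overlap population %.4f >= 2 N_A = %.4f; inputs are inconsistent with a valid stockholder partition",
      which(sop >= 2 * p$n_electrons)[1],
      max(sop), 2 * p$n_electrons[which.max(sop)]))
  }
  invisible(p)
}

pair_key <- function(a, b, t1, t2, t3) {
  paste(a, b, t1, t2, t3, sep = "/")
}

#' @export
print.stockholder_partition <- function(x, ...) {
  cat(sprintf("stockholder_partition: %d atoms, %d directed pairs, %s\n",
              length(x$charge), nrow(x$pairs),
              if (any(x$cell$periodic)) sprintf("%d-D periodic", sum(x$cell$periodic))
              else "nonperiodic"))
  cat(sprintf("  method: %s, net charge %.6f\n", x$method_name, x$net_charge))
  cat(sprintf("  rms |mu_A| = %.4f, rms |Theta_A| = %.4f (a.u.)\n",
              rms_atomic_dipole(x), rms_atomic_quadrupole(x)))
  invisible(x)
}

#' Enumerate atom-image pairs within the overlap cutoff
#'
#' Lists every directed pair (A, image b) whose distance is at most the sum
#' of density cutoff radii (default 10 Angstrom) or whose tabulated overlap
#' population is at least `op_threshold`, including nontrivially translated
#' self-images of an atom in periodic cells. Translation enumeration covers
#' every image whose minimum possible distance fits the cutoff, so cutoffs
#' exceeding half the shortest lattice vector simply produce multiple images
#' of the same parent atom.
#'
#' @param positions n x 3 matrix, bohr (internal storage of a partition).
#' @param cell normalized cell (lattice in bohr, logical `periodic`).
#' @param cutoff_sum pair distance cutoff \eqn{r^{cut}_A + r^{cut}_B},
#'   Angstrom (default 10).
#' @param op_threshold keep tabulated pairs with OP at or above this value
#'   even beyond the distance cutoff (default 1e-4).
#' @param op_table data frame `a, b, t1, t2, t3, op`; missing mirrored rows
#'   are synthesized, conflicting duplicates are an error.
#' @return Pair data frame with columns `a, b, t1, t2, t3, op, dist`
#'   (bohr) and unit direction `ux, uy, uz` pointing from A to image b,
#'   containing both members of every mirrored pair.
#' @export
enumerate_pairs <- function(positions, cell = NULL, cutoff_sum = 10,
                            op_threshold = 1e-4, op_table = NULL) {
  cell <- if (is.null(cell) || is.null(cell$periodic)) normalize_cell(cell) else cell
  pos <- as.matrix(positions)
  n <- nrow(pos)
  cutoff_b <- ang_to_bohr(cutoff_sum)
  op_table <- complete_op_table(op_table)
  if (!is.null(op_table) && any(op_table$op < 0)) {
    stop("negative overlap population in op_table")
  }

  trans <- candidate_translations(pos, cell, cutoff_b)
  out <- vector("list", nrow(trans))
  for (k in seq_len(nrow(trans))) {
    l <- trans[k, ]
    offset <- if (is.null(cell$lattice)) c(0, 0, 0) else drop(l %*% cell$lattice)
    dx <- outer(pos[, 1], pos[, 1] + offset[1], function(a, b) b - a)
    dy <- outer(pos[, 2], pos[, 2] + offset[2], function(a, b) b - a)
    dz <- outer(pos[, 3], pos[, 3] + offset[3], function(a, b) b - a)
    d <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- d <= cutoff_b
    if (all(l == 0)) keep <- keep & (row(d) != col(d))
    if (!any(keep)) next
    ij <- which(keep, arr.ind = TRUE)
    out[[k]] <- data.frame(a = unname(ij[, 1]), b = unname(ij[, 2]),
                           t1 = l[1], t2 = l[2], t3 = l[3],
                           dist = d[keep],
                           ux = dx[keep], uy = dy[keep], uz = dz[keep],
                           row.names = NULL)
  }
  pr <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pr)) pr <- cbind(empty_pairs()[0, c("a", "b", "t1", "t2", "t3", "dist")],
                               data.frame(ux = numeric(), uy = numeric(), uz = numeric()))

  # attach OP values; add tabulated pairs beyond the distance cutoff
  if (!is.null(op_table) && nrow(op_table) > 0) {
    key <- pair_key(pr$a, pr$b, pr$t1, pr$t2, pr$t3)
    tkey <- pair_key(op_table$a, op_table$b, op_table$t1, op_table$t2, op_table$t3)
    pr$op <- op_table$op[match(key, tkey)]
    pr$op[is.na(pr$op)] <- 0
    extra <- op_table[!(tkey %in% key) & op_table$op >= op_threshold, , drop = FALSE]
    if (nrow(extra) > 0) {
      off <- if (is.null(cell$lattice)) matrix(0, nrow(extra), 3) else
        as.matrix(extra[, c("t1", "t2", "t3")]) %*% cell$lattice
      v <- pos[extra$b, , drop = FALSE] + off - pos[extra$a, , drop = FALSE]
      d <- sqrt(rowSums(v^2))
      pr <- rbind(pr, data.frame(a = extra$a, b = extra$b,
                                 t1 = extra$t1, t2 = extra$t2, t3 = extra$t3,
                                 dist = d, ux = v[, 1], uy = v[, 2], uz = v[, 3],
                                 op = extra$op))
    }
  } else {
    pr$op <- rep(0, nrow(pr))
  }

  if (nrow(pr) > 0) {
    pr[, c("ux", "uy", "uz")] <- pr[, c("ux", "uy", "uz")] / pr$dist
    pr <- pr[order(pr$a, pr$b, pr$t1, pr$t2, pr$t3), ]
    rownames(pr) <- NULL
  }
  pr[, c("a", "b", "t1", "t2", "t3", "op", "dist", "ux", "uy", "uz")]
}

candidate_translations <- function(pos, cell, cutoff_b) {
  if (is.null(cell$lattice) || !any(cell$periodic)) {
    return(matrix(0L, 1, 3))
  }
  span <- if (nrow(pos) > 1) {
    rng <- apply(pos, 2, range)
    sqrt(sum((rng[2, ] - rng[1, ])^2))
  } else 0
  reach <- cutoff_b + span
  G <- solve(cell$lattice)          # columns g_i, g_i . v_j = delta_ij
  nmax <- integer(3)
  for (i in 1:3) {
    nmax[i] <- if (cell$periodic[i]) ceiling(sqrt(sum(G[, i]^2)) * reach) else 0L
  }
  as.matrix(expand.grid(t1 = -nmax[1]:nmax[1],
                        t2 = -nmax[2]:nmax[2],
                        t3 = -nmax[3]:nmax[3]))
}

complete_op_table <- function(op_table) {
  if (is.null(op_table) || nrow(op_table) == 0) return(op_table)
  need <- c("a", "b", "t1", "t2", "t3", "op")
  if (!all(need %in% names(op_table))) {
    missing <- setdiff(need, names(op_table))
    stop("op_table lacks column(s): ", paste(missing, collapse = ", "))
  }
  key <- pair_key(op_table$a, op_table$b, op_table$t1, op_table$t2, op_table$t3)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    v <- op_table$op[key == d]
    if (max(v) - min(v) > 1e-12) {
      stop("duplicate pair ", d, " with conflicting OP values")
    }
    op_table <- op_table[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  mkey <- pair_key(op_table$b, op_table$a, -op_table$t1, -op_table$t2, -op_table$t3)
  hit <- match(mkey, key)
  conflict <- !is.na(hit) & abs(op_table$op - op_table$op[hit]) > 1e-12
  if (any(conflict)) {
    stop("mirrored pair listed twice with conflicting OP values: ",
         mkey[conflict][1])
  }
  add <- is.na(hit)
  if (any(add)) {
    op_table <- rbind(op_table[, need],
                      data.frame(a = op_table$b[add], b = op_table$a[add],
                                 t1 = -op_table$t1[add], t2 = -op_table$t2[add],
                                 t3 = -op_table$t3[add], op = op_table$op[add]))
  }
  op_table
}

#' Summed overlap population of an atom
#'
#' \eqn{SOP_A = \sum_b OP_{Ab}} over the atom's stored pairs. A valid
#' stockholder partition satisfies \eqn{0 \le SOP_A < 2 N_A}; violations are
#' reported as a data-consistency warning by [validate_partition()].
#'
#' @param p a `stockholder_partition`.
#' @param atom atom index in the reference cell.
#' @return The summed overlap population (dimensionless).
#' @export
summed_overlap <- function(p, atom) {
  stopifnot(atom >= 1, atom <= length(p$charge))
  sum(p$pairs$op[p$pairs$a == atom])
}

rms_atomic_dipole <- function(p) {
  if (length(p$charge) == 0) return(0)
  sqrt(mean(rowSums(p$dipole^2)))
}

rms_atomic_quadrupole <- function(p) {
  if (length(p$charge) == 0) return(0)
  sqrt(mean(apply(p$quad, 3, function(Q) sum(Q^2))))
}
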