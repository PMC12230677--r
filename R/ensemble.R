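# Conformational-ensemble figures of merit for charge assignment methods:
# rms charge transfer magnitude, conformational sensitivity, and the
# covariance/correlation structure between methods. All rms quantities use
# population (1/N) normalization.

#' Construct an ensemble charge table
#'
#' @param data data frame in long format with columns `method`,
#'   `conformation`, `atom`, `charge`; an optional `material` column is
#'   kept for bookkeeping.
#' @return The data frame, validated (rectangular over method x atom) and
#'   classed `ensemble_charge_table`.
#' @export
ensemble_charge_table <- function(data) {
  need <- c("method", "conformation", "atom", "charge")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("ensemble table lacks column(s): ", paste(missing, collapse = ", "))
  }
  counts <- table(data$method, data$atom)
  if (any(counts == 0)) {
    stop("ensemble table is not rectangular: every atom needs >= 1 conformation per method")
  }
  class(data) <- c("ensemble_charge_table", class(data))
  data
}

#' Conformation-averaged charges
#'
#' Arithmetic mean of each atom's charge over the conformations, per
#' method.
#'
#' @param table an `ensemble_charge_table`.
#' @return Data frame with `method`, `atom`, `q_avg`.
#' @export
conformation_average <- function(table) {
  agg <- stats::aggregate(charge ~ method + atom, data = table, FUN = mean)
  names(agg)[names(agg) == "charge"] <- "q_avg"
  agg[order(agg$method, agg$atom), , drop = FALSE]
}

#' Root-mean-square charge transfer magnitude of one method
#'
#' Population rms deviation of the conformation-averaged charges about the
#' method's overall mean charge (the mean is subtracted because training
#' sets may contain charged molecules, so it need not be zero).
#'
#' @param avg_charges data frame from [conformation_average()].
#' @param method method label.
#' @return \eqn{\sigma_{method}} in e.
#' @export
rms_charge_transfer <- function(avg_charges, method) {
  q <- avg_charges$q_avg[avg_charges$method == method]
  if (length(q) < 2) stop("need at least 2 atoms for a charge-transfer rms")
  sqrt(mean((q - mean(q))^2))
}

#' Conformational sensitivity of one method
#'
#' Pooled rms deviation of the per-conformation charges about each atom's
#' conformation average, over all atoms and conformations, plus the
#' normalized version (divided by the method's rms charge transfer
#' magnitude, making it unitless).
#'
#' @param table an `ensemble_charge_table`.
#' @param method method label.
#' @return List with `sensitivity` (e) and `normalized_sensitivity`.
#' @export
conformational_sensitivity <- function(table, method) {
  sub <- table[table$method == method, , drop = FALSE]
  if (length(unique(sub$conformation)) < 2) {
    stop("need at least 2 conformations to measure sensitivity")
  }
  avg <- stats::ave(sub$charge, sub$atom)
  sens <- sqrt(mean((sub$charge - avg)^2))
  sigma <- rms_charge_transfer(conformation_average(sub), method)
  if (sigma == 0) {
    stop("rms charge transfer magnitude is zero; normalized sensitivity undefined")
  }
  list(sensitivity = sens, normalized_sensitivity = sens / sigma)
}

#' Covariance and correlation structure between charge methods
#'
#' Centered-product covariance \eqn{\Lambda_{\alpha\beta}} and correlation
#' \eqn{\Omega_{\alpha\beta}} matrices over the conformation-averaged
#' charges, the summed correlations \eqn{S_\alpha = \sum_\beta
#' \Omega_{\alpha\beta}}, and the per-method count of strong correlations
#' (\eqn{\Omega \ge 0.9}, the stoplight-green threshold, self included).
#'
#' @param avg_charges data frame from [conformation_average()] covering
#'   at least two methods on a common atom set.
#' @return List with matrices `lambda`, `omega`, vector `s_alpha`, and
#'   integer vector `n_strong`.
#' @export
method_correlations <- function(avg_charges) {
  methods <- sort(unique(avg_charges$method))
  if (length(methods) < 2) stop("need at least 2 methods")
  atoms <- sort(unique(avg_charges$atom))
  Q <- sapply(methods, function(m) {
    sub <- avg_charges[avg_charges$method == m, ]
    q <- sub$q_avg[match(atoms, sub$atom)]
    if (anyNA(q)) stop("method ", m, " does not cover the common atom set")
    q
  })
  Qc <- sweep(Q, 2, colMeans(Q))
  lambda <- crossprod(Qc) / length(atoms)
  sd <- sqrt(diag(lambda))
  if (any(sd == 0)) {
    stop("method ", methods[which(sd == 0)[1]],
         " has zero charge variance; correlation undefined")
  }
  omega <- lambda / tcrossprod(sd)
  dimnames(lambda) <- dimnames(omega) <- list(methods, methods)
  list(lambda = lambda, omega = omega,
       s_alpha = rowSums(omega),
       n_strong = rowSums(omega >= 0.9))
}

#' Pareto table of accuracy versus conformational sensitivity
#'
#' One row per method combining its median ESP RRMSE with its ensemble
#' figures of merit, sorted by (RRMSE, sensitivity) so ties break on the
#' lower sensitivity.
#'
#' @param table an `ensemble_charge_table`.
#' @param rrmse_medians named numeric vector of per-method median RRMSE.
#' @return Data frame with method, median_rrmse, sensitivity,
#'   normalized_sensitivity, sigma, s_alpha, n_strong.
#' @export
pareto_table <- function(table, rrmse_medians) {
  methods <- sort(unique(table$method))
  if (!all(methods %in% names(rrmse_medians))) {
    stop("rrmse_medians must cover every method in the table")
  }
  avg <- conformation_average(table)
  corr <- if (length(methods) >= 2) method_correlations(avg) else NULL
  rows <- lapply(methods, function(m) {
    sens <- conformational_sensitivity(table, m)
    data.frame(method = m,
               median_rrmse = unname(rrmse_medians[m]),
               sensitivity = sens$sensitivity,
               normalized_sensitivity = sens$normalized_sensitivity,
               sigma = rms_charge_transfer(avg, m),
               s_alpha = if (is.null(corr)) NA_real_ else unname(corr$s_alpha[m]),
               n_strong = if (is.null(corr)) NA_integer_ else unname(corr$n_strong[m]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$median_rrmse, out$sensitivity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
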