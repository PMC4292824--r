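# Permutation tests: presence of etiologic heterogeneity and the
# incremental value of an additional subtype.
#
# Permuting the case labels re-pairs the risk-factor rows with the genomic
# rows while leaving the genomic matrix -- and therefore the set of k-means
# local maxima -- unchanged.  Each permutation therefore rescores the same
# candidate partitions against the permuted risk table and takes the
# optimum, which reproduces full re-optimization at a fraction of the cost.

# Optimal D* of an ensemble against risk[perm, ].  Standardization of the
# design is permutation-invariant, so the design matrix is built once and
# row-permuted.
opt_D_star <- function(ensemble, risk, perm = NULL,
                       min_class_fraction = 0.05, ridge = 1e-4) {
  Z <- risk_design_matrix(risk)
  if (qr(Z)$rank < ncol(Z))
    stop("opt_D_star: design matrix is rank deficient")
  if (!is.null(perm)) Z <- Z[perm, , drop = FALSE]
  N <- nrow(Z)
  best <- -Inf
  any_ok <- FALSE
  for (s in ensemble$solutions) {
    if (min(s$class_sizes) < min_class_fraction * N) next
    d <- tryCatch(score_labels_D_star(Z, s$labels, s$m, ridge),
                  error = function(e) NA_real_)
    if (is.finite(d)) { any_ok <- TRUE; if (d > best) best <- d }
  }
  if (!any_ok) stop("opt_D_star: no admissible scored solutions")
  best
}

perm_result <- function(observed, null_draws, seed, config) {
  B <- length(null_draws)
  structure(list(observed = observed,
                 null_draws = null_draws,
                 p_value = (1 + sum(null_draws >= observed)) / (1 + B),
                 B = B, seed = seed, config_echo = config),
            class = "permutation_test_result")
}

#' Permutation test for the presence of etiologic heterogeneity
#'
#' The observed statistic is the optimal (maximal) D* over the admissible
#' k-means local maxima for `m` classes. Each of the `B` null draws
#' randomly re-pairs the risk-factor rows with the genomic rows and
#' recomputes the optimal D* over the same candidate partitions, defining
#' the distribution of the statistic in the absence of any genuine
#' genomic/risk-factor association. The p-value uses the add-one formula
#' (1 + #\{null >= obs\}) / (1 + B), so it is never exactly zero.
#'
#' @param X samples x features genomic matrix.
#' @param risk aligned [risk_factor_table()].
#' @param m number of subtypes tested (default 2).
#' @param B number of permutations (default 1000).
#' @param n_restarts k-means restarts for the candidate ensemble.
#' @param seed master seed; restart seeds and permutations derive from it.
#' @param min_class_fraction admissibility threshold (default 0.05).
#' @param ridge ridge penalty for membership fits.
#' @return a `permutation_test_result` with `observed`, `null_draws`,
#'   `p_value`, `B`, `seed`, `config_echo`.
#' @export
heterogeneity_test <- function(X, risk, m = 2L, B = 1000L, n_restarts = 100L,
                               seed = 1L, min_class_fraction = 0.05,
                               ridge = 1e-4) {
  if (B < 19L) stop("heterogeneity_test: B must be at least 19")
  ens <- run_restarted_kmeans(X, m, n_restarts, seed = seed)
  observed <- opt_D_star(ens, risk, NULL, min_class_fraction, ridge)
  N <- nrow(risk)
  null_draws <- numeric(B)
  for (b in seq_len(B)) {
    set.seed((seed + 7919L * b) %% .Machine$integer.max)
    perm <- sample.int(N)
    null_draws[b] <- tryCatch(
      opt_D_star(ens, risk, perm, min_class_fraction, ridge),
      error = function(e) NA_real_)
  }
  if (anyNA(null_draws))
    stop("heterogeneity_test: ", sum(is.na(null_draws)),
         " null draws failed to score")
  perm_result(observed, null_draws, seed,
              list(m = m, n_restarts = n_restarts,
                   min_class_fraction = min_class_fraction, ridge = ridge))
}

#' Permutation test for an incremental subtype
#'
#' Tests whether `m_small + 1` subtypes reveal significantly more etiologic
#' heterogeneity than `m_small`. The observed statistic is
#' optD*(m_small + 1) - optD*(m_small); each permutation re-pairs the risk
#' rows with the genomic rows and recomputes both optima (over the same two
#' candidate ensembles) before differencing, so the null reflects the
#' increment expected when neither class system is genuinely associated
#' with the risk factors.
#'
#' @inheritParams heterogeneity_test
#' @param m_small the smaller number of subtypes (>= 2).
#' @return a `permutation_test_result`.
#' @export
incremental_test <- function(X, risk, m_small = 2L, B = 1000L,
                             n_restarts = 100L, seed = 1L,
                             min_class_fraction = 0.05, ridge = 1e-4) {
  if (m_small < 2L) stop("incremental_test: m_small must be >= 2")
  if (B < 19L) stop("incremental_test: B must be at least 19")
  ens_lo <- run_restarted_kmeans(X, m_small, n_restarts, seed = seed)
  ens_hi <- run_restarted_kmeans(X, m_small + 1L, n_restarts, seed = seed)
  observed <- opt_D_star(ens_hi, risk, NULL, min_class_fraction, ridge) -
    opt_D_star(ens_lo, risk, NULL, min_class_fraction, ridge)
  N <- nrow(risk)
  null_draws <- numeric(B)
  for (b in seq_len(B)) {
    set.seed((seed + 7919L * b) %% .Machine$integer.max)
    perm <- sample.int(N)
    null_draws[b] <- tryCatch(
      opt_D_star(ens_hi, risk, perm, min_class_fraction, ridge) -
        opt_D_star(ens_lo, risk, perm, min_class_fraction, ridge),
      error = function(e) NA_real_)
  }
  if (anyNA(null_draws))
    stop("incremental_test: ", sum(is.na(null_draws)),
         " null draws failed to score")
  perm_result(observed, null_draws, seed,
              list(m_small = m_small, n_restarts = n_restarts,
                   min_class_fraction = min_class_fraction, ridge = ridge))
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat("Permutation test (B =", x$B, ")\n")
  cat("  observed statistic:", format(x$observed, digits = 4), "\n")
  cat("  null mean:", format(mean(x$null_draws), digits = 4),
      " null 95th pct:",
      format(stats::quantile(x$null_draws, 0.95), digits = 4), "\n")
  cat("  p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
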