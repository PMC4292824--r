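# Heterogeneity statistics (K, K_j, K_jk, D, D*) and the case-only
# subtype-membership model.

#' Construct a risk-factor table
#'
#' Validates and types a per-case covariate table used to predict subtype
#' membership. Categorical columns are converted to factors with their
#' declared level vocabulary; continuous columns must be numeric and finite.
#' Rows with missing values in declared columns are removed (complete-case
#' filtering) and the removal is reported via the `"dropped"` attribute.
#'
#' @param df data.frame with one row per case.
#' @param id_col name of the case-identifier column (default `"case_id"`).
#'   Identifiers must be unique.
#' @param categorical named list mapping column names to their level
#'   vocabulary, e.g. `list(smoking = c("never","former","current"))`.
#'   Defaults cover the standard kidney-cancer risk factors: smoking status,
#'   BMI category, hypertension history and gender.
#' @param continuous character vector of continuous covariate columns
#'   (default `"age"`).
#' @param min_level_count minimum number of cases required in every observed
#'   factor level (default 2).
#' @return A `risk_factor_table`: a data.frame with attributes `id_col`,
#'   `categorical`, `continuous`, `dropped`.
#' @export
risk_factor_table <- function(df,
                              id_col = "case_id",
                              categorical = list(
                                smoking = c("never", "former", "current"),
                                bmi = c("normal", "overweight", "obese"),
                                hypertension = c("no", "yes"),
                                gender = c("male", "female")),
                              continuous = "age",
                              min_level_count = 2L) {
  stopifnot(is.data.frame(df))
  categorical <- categorical[intersect(names(categorical), names(df))]
  continuous <- intersect(continuous, names(df))
  if (!id_col %in% names(df))
    stop("risk_factor_table: missing id column '", id_col, "'")
  if (anyDuplicated(df[[id_col]]))
    stop("risk_factor_table: duplicate case ids")
  used <- c(names(categorical), continuous)
  if (length(used) == 0L)
    stop("risk_factor_table: no declared covariate columns present")

  for (cn in names(categorical)) {
    vals <- as.character(df[[cn]])
    bad <- !is.na(vals) & !(vals %in% categorical[[cn]])
    if (any(bad))
      stop("risk_factor_table: column '", cn, "' has values outside its ",
           "vocabulary: ", paste(unique(vals[bad]), collapse = ", "))
    df[[cn]] <- factor(vals, levels = categorical[[cn]])
  }
  for (cn in continuous) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (any(is.infinite(df[[cn]])))
      stop("risk_factor_table: non-finite values in '", cn, "'")
  }
  complete <- stats::complete.cases(df[used])
  dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) stop("risk_factor_table: no complete cases")
  for (cn in names(categorical)) {
    tab <- table(droplevels(df[[cn]]))
    if (any(tab < min_level_count))
      stop("risk_factor_table: level(s) of '", cn, "' observed fewer than ",
           min_level_count, " times: ",
           paste(names(tab)[tab < min_level_count], collapse = ", "))
  }
  structure(df,
            id_col = id_col,
            categorical = categorical,
            continuous = continuous,
            dropped = dropped,
            class = c("risk_factor_table", "data.frame"))
}

#' Design matrix for a risk-factor table
#'
#' Dummy-codes categorical covariates against their first declared level and
#' standardizes continuous covariates (mean 0, SD 1; a zero-variance column
#' is centered only). An intercept column is prepended.
#'
#' @param risk a [risk_factor_table()].
#' @return numeric matrix, N x (1 + p), first column the intercept.
#' @keywords internal
risk_design_matrix <- function(risk) {
  stopifnot(inherits(risk, "risk_factor_table"))
  cat_cols <- names(attr(risk, "categorical"))
  con_cols <- attr(risk, "continuous")
  cols <- list(`(Intercept)` = rep(1, nrow(risk)))
  for (cn in cat_cols) {
    lev <- levels(droplevels(risk[[cn]]))   # skip unobserved levels
    for (l in lev[-1]) cols[[paste0(cn, l)]] <- as.numeric(risk[[cn]] == l)
  }
  for (cn in con_cols) {
    x <- risk[[cn]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) next            # constant: no information
    cols[[cn]] <- (x - mean(x)) / s
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  Z
}

#' Membership matrix
#'
#' Per-case subtype probabilities u (N x m) together with class proportions
#' pi. Validates the probabilistic invariants.
#'
#' @param u numeric matrix, rows summing to 1, entries in \[0, 1\].
#' @param pi length-m vector of positive class proportions summing to 1.
#' @return a `membership_matrix` (list with elements `u`, `pi`).
#' @export
membership_matrix <- function(u, pi) {
  u <- as.matrix(u)
  pi <- as.numeric(pi)
  if (ncol(u) != length(pi))
    stop("membership_matrix: ncol(u) != length(pi)")
  if (any(!is.finite(u)) || any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("membership_matrix: entries of u must lie in [0, 1]")
  if (any(abs(rowSums(u) - 1) > 1e-9))
    stop("membership_matrix: rows of u must sum to 1")
  if (any(pi <= 0))
    stop("membership_matrix: all class proportions must be positive")
  if (abs(sum(pi) - 1) > 1e-12)
    stop("membership_matrix: class proportions must sum to 1")
  structure(list(u = u, pi = pi), class = "membership_matrix")
}

## Multinomial (polytomous) logistic log-likelihood machinery.  The
## coefficient matrix B is (m-1) x (1+p) relative to reference class 1;
## eta_j = Z %*% B[j-1, ] for j = 2..m, class-1 linear predictor fixed at 0.

multinom_probs <- function(Z, B) {
  eta <- Z %*% t(B)                      # N x (m-1)
  rmax <- if (ncol(eta) == 1L) eta[, 1L]
          else eta[cbind(seq_len(nrow(eta)),
                         max.col(eta, ties.method = "first"))]
  emax <- pmax(0, rmax)                  # stabilized softmax with eta_1 = 0
  ex <- exp(eta - emax)
  denom <- exp(-emax) + rowSums(ex)
  cbind(exp(-emax) / denom, ex / denom)
}

multinom_neg_loglik <- function(Z, Y, B, ridge, slope_idx) {
  P <- multinom_probs(Z, B)
  -sum(log(pmax(rowSums(Y * P), 1e-300))) +
    0.5 * ridge * sum(B[, slope_idx, drop = FALSE]^2)
}

#' Fit the case-only subtype membership model
#'
#' Polytomous (multinomial) logistic regression of candidate subtype labels
#' on the risk factors, by Newton-Raphson with step halving. Slope
#' coefficients (not intercepts) may carry a small ridge penalty, which
#' stabilizes fits under complete or quasi-complete separation; the default
#' penalty 1e-4 is negligible away from separation.
#'
#' @param risk a [risk_factor_table()].
#' @param labels integer vector in `1..m`, one per case, aligned with `risk`.
#' @param ridge non-negative ridge penalty on slope coefficients (default
#'   `1e-4`; `0` gives the unpenalized maximum-likelihood fit).
#' @param min_class_size minimum cases per class (default 2).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8).
#' @return list with components `model` (a `subtype_model`: `coefficients`
#'   ((m-1) x (1+p)), `reference_class`, `ridge_penalty`, `converged`,
#'   `loglik`) and `membership` (a [membership_matrix()] of fitted u with
#'   `pi` = observed class fractions).
#' @export
fit_subtype_model <- function(risk, labels, ridge = 1e-4,
                              min_class_size = 2L, max_iter = 100L,
                              tol = 1e-8) {
  stopifnot(inherits(risk, "risk_factor_table"))
  labels <- as.integer(labels)
  N <- nrow(risk)
  if (length(labels) != N)
    stop("fit_subtype_model: labels and risk table are not aligned")
  m <- max(labels)
  if (m < 2L) stop("fit_subtype_model: need at least 2 classes")
  sizes <- tabulate(labels, nbins = m)
  if (any(sizes == 0L))
    stop("fit_subtype_model: empty class among labels 1..", m)
  if (any(sizes < min_class_size))
    stop("fit_subtype_model: class size below min_class_size (",
         min_class_size, "): ", paste(which(sizes < min_class_size),
                                      collapse = ", "))
  if (ridge < 0) stop("fit_subtype_model: ridge must be non-negative")

  Z <- risk_design_matrix(risk)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z))
    stop("fit_subtype_model: design matrix is rank deficient (rank ",
         qrZ$rank, " < ", ncol(Z), " columns)")
  core <- multinom_fit_core(Z, labels, m, ridge, max_iter, tol)
  if (!core$converged && max_iter > 0L)
    warning("fit_subtype_model: Newton iteration did not converge in ",
            max_iter, " iterations")
  B <- core$B
  colnames(B) <- colnames(Z)
  model <- structure(list(coefficients = B,
                          reference_class = 1L,
                          ridge_penalty = ridge,
                          converged = core$converged,
                          loglik = core$loglik),
                     class = "subtype_model")
  list(model = model,
       membership = membership_matrix(core$u, sizes / N))
}

# Dedicated binary-logit Newton path: the m = 2 permutation tests call the
# fit thousands of times, so generic softmax machinery is bypassed.
binary_fit_core <- function(Z, labels, ridge, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(labels == 2L)
  N <- nrow(Z)
  p1 <- ncol(Z)
  pen <- c(0, rep(ridge, p1 - 1L))
  b <- numeric(p1)
  b[1] <- log(mean(y) / (1 - mean(y)))
  eta <- as.vector(Z %*% b)
  nll_of <- function(eta, b)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      0.5 * ridge * sum(b[-1]^2)
  nll <- nll_of(eta, b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-eta))
    g <- as.vector(crossprod(Z, y - p)) - pen * b
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- crossprod(Z, Z * (p * (1 - p)))
    diag(H) <- diag(H) + pen + 1e-10
    step <- tryCatch(solve(H, g), error = function(e) g)
    lambda <- 1
    repeat {
      bn <- b + lambda * step
      en <- as.vector(Z %*% bn)
      nln <- nll_of(en, bn)
      if (nln <= nll + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    done <- abs(nll - nln) < tol * (abs(nll) + 1) && lambda >= 1e-8
    b <- bn; eta <- en; nll <- nln
    if (done) {
      p <- 1 / (1 + exp(-eta))
      g <- as.vector(crossprod(Z, y - p)) - pen * b
      converged <- max(abs(g)) < max(tol, 1e-6)
      break
    }
  }
  p <- 1 / (1 + exp(-eta))
  u <- cbind(1 - p, p)
  list(B = matrix(b, 1L, p1), u = u, converged = converged,
       loglik = -nll, pi = c(1 - mean(y), mean(y)))
}

# Newton-Raphson core on a prebuilt design matrix.  Kept lean: the
# permutation tests call it thousands of times.
multinom_fit_core <- function(Z, labels, m, ridge, max_iter = 100L,
                              tol = 1e-8) {
  if (m == 2L) return(binary_fit_core(Z, labels, ridge, max_iter, tol))
  N <- nrow(Z)
  p1 <- ncol(Z)
  slope_idx <- seq_len(p1)[-1]
  sizes <- tabulate(labels, nbins = m)
  Y <- matrix(0, N, m)
  Y[cbind(seq_len(N), labels)] <- 1
  B <- matrix(0, m - 1L, p1)
  B[, 1] <- log(sizes[-1] / sizes[1])
  nll <- multinom_neg_loglik(Z, Y, B, ridge, slope_idx)
  converged <- FALSE
  d <- m - 1L
  pen <- rep(0, p1); pen[slope_idx] <- ridge
  for (it in seq_len(max_iter)) {
    P <- multinom_probs(Z, B)
    G <- t(Y[, -1, drop = FALSE] - P[, -1, drop = FALSE]) %*% Z  # (m-1) x p1
    G[, slope_idx] <- G[, slope_idx] - ridge * B[, slope_idx, drop = FALSE]
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    H <- matrix(0, d * p1, d * p1)
    for (j in seq_len(d)) {
      for (k in j:d) {
        w <- if (j == k) P[, j + 1L] * (1 - P[, j + 1L])
             else -P[, j + 1L] * P[, k + 1L]
        blk <- crossprod(Z, Z * w)
        rj <- (j - 1L) * p1 + seq_len(p1)
        rk <- (k - 1L) * p1 + seq_len(p1)
        H[rj, rk] <- blk
        if (j != k) H[rk, rj] <- blk
      }
    }
    diag(H) <- diag(H) + rep(pen, d) + 1e-10
    step <- tryCatch(solve(H, as.vector(t(G))),
                     error = function(e) as.vector(t(G)))
    step <- matrix(step, d, p1, byrow = TRUE)
    lambda <- 1
    repeat {
      Bn <- B + lambda * step
      nln <- multinom_neg_loglik(Z, Y, Bn, ridge, slope_idx)
      if (nln <= nll + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (abs(nll - nln) < tol * (abs(nll) + 1) && lambda >= 1e-8) {
      B <- Bn; nll <- nln
      P <- multinom_probs(Z, B)
      G <- t(Y[, -1, drop = FALSE] - P[, -1, drop = FALSE]) %*% Z
      G[, slope_idx] <- G[, slope_idx] - ridge * B[, slope_idx, drop = FALSE]
      converged <- max(abs(G)) < max(tol, 1e-6)
      break
    }
    B <- Bn; nll <- nln
  }
  u <- multinom_probs(Z, B)
  u <- pmin(pmax(u, 0), 1)
  u <- u / rowSums(u)
  list(B = B, u = u, converged = converged, loglik = -nll,
       pi = sizes / N)
}

# D* of one candidate labeling against a prebuilt design matrix; the fast
# path used when rescoring ensembles across permutations.
score_labels_D_star <- function(Z, labels, m, ridge) {
  core <- multinom_fit_core(Z, labels, m, ridge)
  mem <- list(u = core$u, pi = core$pi)
  dev <- sweep(mem$u, 2, mem$pi, "-")
  mean(rowSums(sweep(dev^2, 2, mem$pi, "/")))
}

#' Case-only heterogeneity statistic D*
#'
#' The case-average chi-square-type deviation of the fitted subtype
#' membership probabilities from the overall class proportions:
#' \deqn{D^* = \frac{1}{N}\sum_i \sum_j \frac{(u_{ji} - \pi_j)^2}{\pi_j}.}
#' D* is 0 when memberships carry no information beyond the class fractions
#' and reaches its maximum m - 1 for hard labels (with pi the class
#' fractions).
#'
#' @param mem a [membership_matrix()].
#' @return non-negative scalar.
#' @export
compute_D_star <- function(mem) {
  if (!inherits(mem, "membership_matrix"))
    mem <- membership_matrix(mem$u, mem$pi)
  dev <- sweep(mem$u, 2, mem$pi, "-")
  mean(rowSums(sweep(dev^2, 2, mem$pi, "/")))
}

#' Coefficient of variation of disease risk
#'
#' K = sqrt(v) / mu with the population variance convention
#' v = mean(r^2) - mean(r)^2. K measures how predictable disease occurrence
#' is from the risk factors: the wider the spread of individual risks, the
#' larger K.
#'
#' @param r vector of strictly positive individual risks.
#' @return non-negative scalar.
#' @export
compute_K <- function(r) {
  r <- as.numeric(r)
  if (length(r) == 0L || any(!is.finite(r)) || any(r <= 0))
    stop("compute_K: risks must be positive and finite")
  mu <- mean(r)
  v <- mean(r^2) - mu^2
  sqrt(max(v, 0)) / mu
}

#' Population heterogeneity decomposition
#'
#' From an n x m matrix of per-individual subtype-specific risks r_ji,
#' computes the full set of moments and heterogeneity coefficients: the
#' overall and per-subtype mean risks (mu, mu_j), variances (v, v_j),
#' covariances c_jk, coefficients of variation K and K_j, coefficients of
#' covariation K_jk = c_jk / (mu_j mu_k), subtype proportions pi_j =
#' mu_j / mu, and the incremental risk-prediction measure
#' \deqn{D = \sum_j \pi_j K_j^2 - K^2.}
#' D is also evaluated through its covariance expansion
#' \eqn{\sum_j \pi_j (1-\pi_j) K_j^2 - 2 \sum_{j<k} \pi_j \pi_k K_{jk}} and
#' the two forms are asserted to agree to 1e-10: D grows as the between-
#' subtype risk covariances shrink, i.e. as the subtypes become
#' etiologically distinct.
#'
#' @param r n x m matrix of non-negative subtype risks with positive row
#'   sums.
#' @return list of class `heterogeneity_components` with fields `mu`,
#'   `mu_j`, `v`, `v_j`, `c_jk`, `K`, `K_j`, `K_jk`, `pi`, `D`, `D_cov`,
#'   `D_star` (the case-only statistic evaluated on the exact memberships
#'   u_ji = r_ji / r_i, weighting each individual equally).
#' @export
compute_components <- function(r) {
  r <- as.matrix(r)
  if (any(!is.finite(r)) || any(r < 0))
    stop("compute_components: risks must be finite and non-negative")
  ri <- rowSums(r)
  if (any(ri <= 0))
    stop("compute_components: every individual needs positive total risk")
  n <- nrow(r); m <- ncol(r)
  mu_j <- colMeans(r)
  if (any(mu_j <= 0))
    stop("compute_components: subtype with zero mean risk")
  mu <- sum(mu_j)
  v <- mean(ri^2) - mu^2
  c_jk <- crossprod(r) / n - tcrossprod(mu_j)
  v_j <- diag(c_jk)
  K <- sqrt(max(v, 0)) / mu
  K_j <- sqrt(pmax(v_j, 0)) / mu_j
  K_jk <- c_jk / tcrossprod(mu_j)
  pi <- mu_j / mu
  D <- sum(pi * K_j^2) - K^2
  D_cov <- sum(pi * (1 - pi) * K_j^2) -
    2 * sum(K_jk[upper.tri(K_jk)] * tcrossprod(pi)[upper.tri(K_jk)])
  if (abs(D - D_cov) > 1e-10 * max(1, abs(D)))
    stop("compute_components: moment and covariance forms of D disagree (",
         D, " vs ", D_cov, ")")
  u <- r / ri
  dev <- sweep(u, 2, pi, "-")
  D_star <- mean(rowSums(sweep(dev^2, 2, pi, "/")))
  structure(list(mu = mu, mu_j = mu_j, v = v, v_j = v_j, c_jk = c_jk,
                 K = K, K_j = K_j, K_jk = K_jk, pi = pi,
                 D = D, D_cov = D_cov, D_star = D_star),
            class = "heterogeneity_components")
}
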