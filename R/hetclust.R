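# Candidate partitions by restarted k-means; G and D* scoring; solution
# selection under the unsupervised (max G) or supervised (max D*) criterion.

#' Canonicalize a label vector
#'
#' Renumbers classes by order of first appearance so that partitions equal
#' up to label permutation map to an identical vector. Idempotent.
#'
#' @param labels integer-like vector of class labels.
#' @return integer vector in `1..m`, first case always labelled 1.
#' @export
canonicalize_labels <- function(labels) {
  labels <- as.integer(as.factor(labels))
  match(labels, unique(labels))
}

#' Between-cluster sum of squares G
#'
#' The weighted Euclidean separation of the clusters,
#' G = sum_j n_j * ||xbar_j - xbar||^2, the quantity k-means maximizes
#' (equivalently total SS minus within-cluster SS).
#'
#' @param X samples x features numeric matrix.
#' @param labels class labels, one per row of `X`.
#' @return non-negative scalar.
#' @export
compute_G <- function(X, labels) {
  X <- as.matrix(X)
  labels <- canonicalize_labels(labels)
  if (length(labels) != nrow(X))
    stop("compute_G: labels and X are not aligned")
  center <- colMeans(X)
  G <- 0
  for (j in unique(labels)) {
    idx <- labels == j
    G <- G + sum(idx) * sum((colMeans(X[idx, , drop = FALSE]) - center)^2)
  }
  G
}

# One k-means run; on an empty-cluster failure re-seeds deterministically
# (seed + 1e6 * attempt) up to 25 attempts.
kmeans_once <- function(X, m, seed, iter_max = 100L) {
  for (attempt in 0:24) {
    s <- (seed + attempt * 1000000) %% .Machine$integer.max
    set.seed(s)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = m, iter.max = iter_max,
                                     nstart = 1L)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == m)
      return(list(labels = canonicalize_labels(fit$cluster), seed = s))
  }
  stop("kmeans_once: could not obtain ", m,
       " non-empty clusters after 25 re-seeds")
}

#' Restarted k-means ensemble
#'
#' Runs k-means `n_restarts` times from different random seeds (derived
#' deterministically from `seed`), canonicalizes each resulting partition
#' and deduplicates, recording every restart seed that produced each unique
#' solution. Empty-cluster collapses are handled by deterministic
#' re-seeding.
#'
#' @param X samples x features numeric matrix (finite entries).
#' @param m number of clusters, `2 <= m < nrow(X)`.
#' @param n_restarts number of random restarts.
#' @param seed master seed; restart r uses seed `seed + r`.
#' @return a `solution_ensemble`: list with `solutions` (each a
#'   `cluster_solution` with `labels`, `m`, `G`, `D_star` (NA until
#'   scored), `admissible` (NA until scored), `seeds`, `class_sizes`),
#'   `n_restarts`, `m`, `X_fingerprint`.
#' @export
run_restarted_kmeans <- function(X, m, n_restarts, seed = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("run_restarted_kmeans: X must be finite")
  m <- as.integer(m)
  if (m < 2L) stop("run_restarted_kmeans: m must be at least 2")
  if (m >= nrow(X)) stop("run_restarted_kmeans: m must be < number of samples")
  if (n_restarts < 1L) stop("run_restarted_kmeans: n_restarts must be >= 1")

  sols <- list()
  keys <- character(0)
  for (r in seq_len(n_restarts)) {
    run <- kmeans_once(X, m, seed + r)
    key <- paste(run$labels, collapse = ",")
    hit <- match(key, keys)
    if (is.na(hit)) {
      keys <- c(keys, key)
      sols[[length(sols) + 1L]] <- list(
        labels = run$labels, m = m,
        G = compute_G(X, run$labels),
        D_star = NA_real_, admissible = NA,
        seeds = run$seed,
        class_sizes = tabulate(run$labels, nbins = m))
    } else {
      sols[[hit]]$seeds <- c(sols[[hit]]$seeds, run$seed)
    }
  }
  sols <- lapply(sols, function(s) structure(s, class = "cluster_solution"))
  structure(list(solutions = sols, n_restarts = n_restarts, m = m,
                 X_fingerprint = sum(X) + 0.001 * sum(X^2)),
            class = "solution_ensemble")
}

#' Score an ensemble with the case-only heterogeneity statistic
#'
#' For each unique partition whose smallest class holds at least
#' `min_class_fraction` of the cases, fits the polytomous membership model
#' and stores D*. Solutions with a class below the threshold are marked
#' inadmissible and left unscored; a model-fit failure marks the solution
#' unscored with the failure reason and the pipeline continues.
#'
#' @param ensemble a `solution_ensemble`.
#' @param risk a [risk_factor_table()] covering the clustered samples, rows
#'   aligned with the rows of the clustered matrix.
#' @param min_class_fraction admissibility threshold on the smallest class
#'   (default 0.05).
#' @param ridge ridge penalty forwarded to [fit_subtype_model()].
#' @return the ensemble with `D_star` and `admissible` set on each solution.
#' @export
score_ensemble <- function(ensemble, risk, min_class_fraction = 0.05,
                           ridge = 1e-4) {
  stopifnot(inherits(ensemble, "solution_ensemble"))
  N <- length(ensemble$solutions[[1]]$labels)
  if (nrow(risk) != N)
    stop("score_ensemble: risk table does not cover the clustered samples")
  Z <- risk_design_matrix(risk)
  rank_ok <- qr(Z)$rank == ncol(Z)
  for (i in seq_along(ensemble$solutions)) {
    sol <- ensemble$solutions[[i]]
    if (min(sol$class_sizes) < min_class_fraction * N) {
      sol$admissible <- FALSE
      sol$D_star <- NA_real_
    } else {
      sol$admissible <- TRUE
      fit <- if (!rank_ok) {
        simpleError("design matrix is rank deficient")
      } else tryCatch(
        suppressWarnings(score_labels_D_star(Z, sol$labels, sol$m, ridge)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        sol$D_star <- NA_real_
        sol$unscored_reason <- conditionMessage(fit)
      } else {
        sol$D_star <- fit
      }
    }
    ensemble$solutions[[i]] <- sol
  }
  ensemble
}

#' Select the optimal solution from a scored ensemble
#'
#' Under `max_D_star`, picks the admissible scored solution with the
#' largest heterogeneity statistic (the supervised criterion); under
#' `max_G`, the one with the largest between-cluster dissimilarity (the
#' standard unsupervised criterion). Ties are broken by larger G, then by
#' smaller first restart seed.
#'
#' @param ensemble a scored `solution_ensemble`.
#' @param criterion `"max_D_star"` (default) or `"max_G"`.
#' @return the selected `cluster_solution`.
#' @export
select_solution <- function(ensemble, criterion = c("max_D_star", "max_G")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(ensemble, "solution_ensemble"))
  ok <- vapply(ensemble$solutions,
               function(s) isTRUE(s$admissible) && is.finite(s$D_star),
               logical(1))
  cand <- ensemble$solutions[ok]
  if (length(cand) == 0L)
    stop("select_solution: no admissible scored solutions")
  key <- vapply(cand, function(s) {
    c(if (criterion == "max_D_star") s$D_star else s$G, s$G, -min(s$seeds))
  }, numeric(3))
  best <- order(key[1, ], key[2, ], key[3, ], decreasing = TRUE)[1]
  cand[[best]]
}

#' Random-assignment benchmark
#'
#' Draws `n_draws` uniformly random m-class labelings (redrawing any with
#' an empty class), computing G and D* for each. These benchmark the G and
#' D* values expected when the subtypes carry no genomic or etiologic
#' signal, for the diagnostic scatter of candidate solutions.
#'
#' @inheritParams score_ensemble
#' @param X samples x features matrix.
#' @param m number of classes.
#' @param n_draws number of random labelings.
#' @param seed RNG seed.
#' @return data.frame with columns `draw`, `G`, `D_star`.
#' @export
random_benchmark <- function(X, risk, m, n_draws, seed = 1L,
                             ridge = 1e-4) {
  X <- as.matrix(X)
  N <- nrow(X)
  set.seed(seed)
  G <- D <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    repeat {
      lab <- sample.int(m, N, replace = TRUE)
      if (length(unique(lab)) == m) break
    }
    lab <- canonicalize_labels(lab)
    G[b] <- compute_G(X, lab)
    fit <- tryCatch(
      suppressWarnings(fit_subtype_model(risk, lab, ridge = ridge)),
      error = function(e) NULL)
    D[b] <- if (is.null(fit)) NA_real_ else compute_D_star(fit$membership)
  }
  data.frame(draw = seq_len(n_draws), G = G, D_star = D)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cases:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("adjusted_rand_index: label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Diagnostic table of solutions and random benchmark
#'
#' Combines a scored ensemble with a random benchmark into one long table
#' (`source` is `"kmeans"` or `"random"`), suitable for the G-versus-D*
#' diagnostic scatter that contrasts the supervised and unsupervised
#' selection criteria.
#'
#' @param ensemble a scored `solution_ensemble`.
#' @param benchmark output of [random_benchmark()].
#' @return data.frame with columns `source`, `G`, `D_star`.
#' @export
diagnostic_table <- function(ensemble, benchmark) {
  km <- data.frame(
    source = "kmeans",
    G = vapply(ensemble$solutions, `[[`, numeric(1), "G"),
    D_star = vapply(ensemble$solutions, `[[`, numeric(1), "D_star"))
  rb <- data.frame(source = "random", G = benchmark$G,
                   D_star = benchmark$D_star)
  rbind(km, rb)
}
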