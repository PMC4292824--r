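# Shared fixtures and independent oracles.  Oracles are deliberately
# written as brute force / enumeration, independent of the package code
# paths they check.

# small risk table with one categorical and one continuous covariate
make_risk <- function(n, seed = 1, levels = c("a", "b")) {
  set.seed(seed)
  df <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                   g = sample(levels, n, replace = TRUE),
                   x = rnorm(n))
  risk_factor_table(df, categorical = list(g = levels), continuous = "x")
}

# risk table whose declared covariates are all constant
make_constant_risk <- function(n) {
  df <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                   g = rep("a", n), x = rep(1.5, n))
  risk_factor_table(df, categorical = list(g = c("a", "b")),
                    continuous = "x", min_level_count = 1L)
}

# random valid membership matrix with pi = column means
rand_membership <- function(N, m, seed) {
  set.seed(seed)
  u <- matrix(rgamma(N * m, shape = 0.8), N, m)
  u <- u / rowSums(u)
  membership_matrix(u, colMeans(u))
}

# random positive rate matrix
rand_rates <- function(n, m, seed) {
  set.seed(seed)
  matrix(rexp(n * m, rate = 1 / 0.05) + 1e-4, n, m)
}

# oracle: D via the individual-deviation (u-form) identity
u_form_D <- function(r) {
  ri <- rowSums(r)
  mu <- mean(ri)
  pi <- colMeans(r) / mu
  u <- r / ri
  dev <- sweep(u, 2, pi, "-")
  mean((ri / mu)^2 * rowSums(sweep(dev^2, 2, pi, "/")))
}

# oracle: exhaustive best 2-partition between-cluster SS (n <= 16)
best_2partition_G <- function(X) {
  n <- nrow(X)
  best <- 0
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2L) next
    best <- max(best, compute_G(X, lab))
  }
  best
}

# oracle: exact two-sided rank-sum p by enumeration of all subsets
exact_ranksum_p <- function(in_ranks, n_total) {
  k <- length(in_ranks)
  obs <- sum(in_ranks)
  all_sums <- apply(utils::combn(n_total, k), 2, sum)
  mu <- k * (n_total + 1) / 2
  mean(abs(all_sums - mu) >= abs(obs - mu) - 1e-9)
}

# oracle: best label alignment by independent enumeration (uses a
# different permutation generator and accumulation than the package)
brute_align <- function(confusion) {
  m <- nrow(confusion)
  perms <- as.matrix(expand.grid(rep(list(seq_len(m)), m)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == m), ,
                 drop = FALSE]
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    tr <- 0
    for (j in seq_len(m)) tr <- tr + confusion[j, perms[i, j]]
    if (tr > best) best <- tr
  }
  best
}

# oracle: two-sided Fisher p on a 2x2 table by hypergeometric enumeration
hyper_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# three planted classes with strong, mutually distinct, balanced risk
# profiles (opposite-signed hypertension/gender effects; baselines chosen
# so case class fractions stay near 1/5-2/5-2/5): the "strong effects"
# world for the cluster-number power check
strong3_config <- function(seed, N = 250) {
  covs <- list(
    smoking = list(levels = c("never", "former", "current"),
                   prob = c(0.45, 0.35, 0.20)),
    bmi = list(levels = c("normal", "overweight", "obese"),
               prob = c(0.25, 0.35, 0.40)),
    hypertension = list(levels = c("no", "yes"), prob = c(0.45, 0.55)),
    gender = list(levels = c("male", "female"), prob = c(0.65, 0.35)),
    age = list(mean = 60, sd = 10))
  cols <- etiohet:::design_colnames(covs)
  beta <- matrix(0, 3, length(cols), dimnames = list(NULL, cols))
  beta[2, c("hypertensionyes", "genderfemale")] <- c(3, -2.5)
  beta[3, c("genderfemale", "hypertensionyes")] <- c(3, -2.5)
  scenario_config(n = 20000, N = N, m = 3, covariates = covs, beta = beta,
                  baseline_log_rate = log(0.02) + c(0, -1.2, -0.7),
                  genomic = list(p = 60, effect = 2.5, signal_features = 6),
                  seed = seed)
}

# planted two-class dataset: risk-linked labels plus genomic signal
planted_dataset <- function(N = 120, p = 40, m = 2, effect_scale = 1,
                            genomic_effect = 2, seed = 1, n = 5000) {
  sc <- scenario_config(n = n, N = N, m = m, effect_scale = effect_scale,
                        genomic = list(p = p, effect = genomic_effect,
                                       signal_features = max(4L, p %/% 10)),
                        seed = seed)
  truth <- generate_population(sc)
  cases <- sample_cases(truth, N)
  X <- generate_genomic(cases$labels, sc)
  list(cfg = sc, truth = truth, cases = cases, X = X)
}
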