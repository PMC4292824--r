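# Synthetic populations with planted subtype structure.  Individuals carry
# risk factors drawn from population distributions; per-subtype incidence
# rates follow a multinomial-logit model on the covariates (matching the
# analysis model, so the case-only statistic is consistent for its target);
# cases arise by risk-biased sampling.  Companion generators plant subtype
# signal in genomic matrices, mutation indicators and survival times.

#' Scenario configuration for the synthetic generators
#'
#' Collects every knob of the synthetic world with defaults emulating a
#' case series of a few hundred genomically profiled tumors: kidney-cancer
#' style risk-factor distributions (smoking, BMI category, hypertension,
#' gender, age), a female/hypertension-dominated subtype and a
#' smoking-dominated subtype against a reference subtype, Gaussian genomic
#' signal blocks, Bernoulli mutations, exponential survival with uniform
#' censoring.
#'
#' @param n population size at risk (default 20000).
#' @param N number of sampled cases (default 300).
#' @param m number of subtypes (default 3).
#' @param covariates named list: each categorical covariate is
#'   `list(levels=, prob=)`; a continuous covariate is `list(mean=, sd=)`.
#' @param baseline_log_rate length-m (or scalar) log baseline incidence
#'   rate per subtype (default `log(0.02)`).
#' @param beta m x p matrix of log-rate covariate effects on the
#'   dummy-coded design (reference subtype 1 has the zero row). Default
#'   [default_beta()] with `effect_scale`.
#' @param effect_scale multiplier on the default effect matrix (default 1).
#' @param genomic list: `p` total features (200), `signal_features` per
#'   subtype (10), `effect` mean shift in noise SDs (1.5), `noise_sd` (1),
#'   `effect2` shift for an optional second orthogonal partition (3).
#' @param mutations list: `freq` genes x m matrix of per-subtype mutation
#'   probabilities (default 2 differential + 3 background genes).
#' @param surv list: `base_hazard` (0.1), `hr` per-subtype hazard ratio
#'   step (1.6), `censor_max` uniform censoring horizon (12).
#' @param seed master seed (default 1).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n = 20000L, N = 300L, m = 3L,
                            covariates = NULL,
                            baseline_log_rate = log(0.02),
                            beta = NULL, effect_scale = 1,
                            genomic = list(), mutations = list(),
                            surv = list(), seed = 1L) {
  if (is.null(covariates)) {
    covariates <- list(
      smoking = list(levels = c("never", "former", "current"),
                     prob = c(0.45, 0.35, 0.20)),
      bmi = list(levels = c("normal", "overweight", "obese"),
                 prob = c(0.25, 0.35, 0.40)),
      hypertension = list(levels = c("no", "yes"), prob = c(0.45, 0.55)),
      gender = list(levels = c("male", "female"), prob = c(0.65, 0.35)),
      age = list(mean = 60, sd = 10))
  }
  for (cv in covariates) {
    if (!is.null(cv$prob)) {
      stopifnot(all(cv$prob >= 0), abs(sum(cv$prob) - 1) < 1e-9,
                length(cv$prob) == length(cv$levels))
    }
  }
  stopifnot(m >= 1L, n >= 1L, N >= 1L)
  gen <- utils::modifyList(
    list(p = 200L, signal_features = 10L, effect = 1.5, noise_sd = 1,
         effect2 = 3), genomic)
  mut <- utils::modifyList(list(freq = NULL), mutations)
  srv <- utils::modifyList(
    list(base_hazard = 0.1, hr = 1.6, censor_max = 12), surv)
  cols <- design_colnames(covariates)
  if (is.null(beta)) beta <- default_beta(cols, m, effect_scale)
  beta <- as.matrix(beta)
  if (nrow(beta) != m || ncol(beta) != length(cols))
    stop("scenario_config: beta must be ", m, " x ", length(cols))
  colnames(beta) <- cols
  if (length(baseline_log_rate) == 1L)
    baseline_log_rate <- rep(baseline_log_rate, m)
  structure(list(n = as.integer(n), N = as.integer(N), m = as.integer(m),
                 covariates = covariates,
                 baseline_log_rate = baseline_log_rate,
                 beta = beta, genomic = gen, mutations = mut, surv = srv,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

design_colnames <- function(covariates) {
  cols <- character(0)
  for (cn in names(covariates)) {
    cv <- covariates[[cn]]
    if (!is.null(cv$levels))
      cols <- c(cols, paste0(cn, cv$levels[-1]))
    else cols <- c(cols, cn)
  }
  cols
}

#' Default planted effect matrix
#'
#' Subtype 1 is the reference (zero effects). Subtype 2 is
#' female-predominant with a hypertension excess; subtype 3 is
#' smoking-associated; subtype 4 (when present) is older and heavier.
#' Further subtypes cycle single-covariate effects. Magnitudes are log
#' rate ratios of roughly 0.5-1.4, the order observed for the established
#' kidney-cancer risk factors.
#'
#' @param cols design column names ([design_colnames()]).
#' @param m number of subtypes.
#' @param effect_scale multiplier (default 1).
#' @return m x length(cols) matrix.
#' @export
default_beta <- function(cols, m, effect_scale = 1) {
  beta <- matrix(0, m, length(cols), dimnames = list(NULL, cols))
  assign_eff <- function(j, name, val) {
    if (name %in% cols) beta[j, name] <<- val * effect_scale
  }
  if (m >= 2L) { assign_eff(2, "genderfemale", 1.4)
                 assign_eff(2, "hypertensionyes", 0.6) }
  if (m >= 3L) { assign_eff(3, "smokingcurrent", 1.2)
                 assign_eff(3, "smokingformer", 0.6) }
  if (m >= 4L) { assign_eff(4, "age", 0.5)
                 assign_eff(4, "bmiobese", 0.7) }
  if (m >= 5L) for (j in 5:m)
    beta[j, ((j - 2L) %% length(cols)) + 1L] <-
      effect_scale * ifelse(j %% 2 == 0, 0.9, -0.9)
  beta
}

# Dummy-coded design on the generator's own coding: categorical against
# first level, continuous standardized by its population parameters.
scenario_design <- function(df, covariates) {
  cols <- list()
  for (cn in names(covariates)) {
    cv <- covariates[[cn]]
    if (!is.null(cv$levels)) {
      for (l in cv$levels[-1])
        cols[[paste0(cn, l)]] <- as.numeric(df[[cn]] == l)
    } else {
      cols[[cn]] <- (df[[cn]] - cv$mean) / cv$sd
    }
  }
  do.call(cbind, cols)
}

#' Generate a synthetic population at risk
#'
#' Draws covariates for `cfg$n` individuals and computes the n x m matrix
#' of subtype-specific incidence rates
#' `r_ji = exp(alpha_j + beta_j' x_i)`. The implied membership
#' probabilities `u_ji = r_ji / r_i` follow a multinomial-logit model in
#' the covariates; the exact population heterogeneity D is available via
#' [compute_components()] on the returned rate matrix.
#'
#' @param cfg a [scenario_config()].
#' @return a `synthetic_truth` list: `covariates` (data.frame with
#'   `case_id`), `r` (n x m rates), `u`, `pi` (mu_j/mu), `cfg`.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  df <- data.frame(case_id = sprintf("ID%06d", seq_len(n)))
  for (cn in names(cfg$covariates)) {
    cv <- cfg$covariates[[cn]]
    df[[cn]] <- if (!is.null(cv$levels))
      sample(cv$levels, n, replace = TRUE, prob = cv$prob)
    else stats::rnorm(n, cv$mean, cv$sd)
  }
  Z <- scenario_design(df, cfg$covariates)
  eta <- matrix(cfg$baseline_log_rate, n, cfg$m, byrow = TRUE) +
    Z %*% t(cfg$beta)
  r <- exp(eta)
  if (all(r == 0)) stop("generate_population: degenerate all-zero rates")
  ri <- rowSums(r)
  u <- r / ri
  mu_j <- colMeans(r)
  structure(list(covariates = df, r = r, u = u, pi = mu_j / sum(mu_j),
                 cfg = cfg),
            class = "synthetic_truth")
}

#' Sample cases by risk-biased sampling
#'
#' Individuals become cases with probability proportional to their total
#' risk r_i; each sampled case is assigned a true subtype drawn from its
#' membership probabilities u_ji.
#'
#' @param truth a `synthetic_truth` from [generate_population()].
#' @param N number of cases (default `truth$cfg$N`).
#' @param seed RNG seed (default `truth$cfg$seed + 1`).
#' @param replace sample with replacement (default FALSE, requiring
#'   `N <= n`).
#' @return list with `risk` (a [risk_factor_table()] of the sampled
#'   cases), `labels` (true subtypes), `idx` (population indices).
#' @export
sample_cases <- function(truth, N = truth$cfg$N,
                         seed = truth$cfg$seed + 1L, replace = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- nrow(truth$r)
  if (!replace && N > n)
    stop("sample_cases: N > population size without replacement")
  set.seed(seed)
  ri <- rowSums(truth$r)
  idx <- sample.int(n, N, replace = replace, prob = ri)
  labels <- vapply(idx, function(i)
    sample.int(ncol(truth$u), 1L, prob = truth$u[i, ]), integer(1))
  df <- truth$covariates[idx, , drop = FALSE]
  if (replace) df$case_id <- sprintf("%s_c%04d", df$case_id, seq_len(N))
  rownames(df) <- NULL
  cat_spec <- lapply(Filter(function(cv) !is.null(cv$levels),
                            truth$cfg$covariates), `[[`, "levels")
  con_cols <- names(Filter(function(cv) is.null(cv$levels),
                           truth$cfg$covariates))
  risk <- risk_factor_table(df, categorical = cat_spec,
                            continuous = con_cols, min_level_count = 1L)
  list(risk = risk, labels = labels, idx = idx)
}

#' Generate a genomic matrix with planted subtype signal
#'
#' Gaussian noise with per-subtype mean shifts on disjoint signal-feature
#' blocks: block j (of `cfg$genomic$signal_features` features) is elevated
#' by `cfg$genomic$effect` noise-SDs in cases of subtype j. When a second,
#' orthogonal partition `labels2` is supplied, its classes receive their
#' own signal blocks shifted by `cfg$genomic$effect2`, creating the
#' scenario in which the highest-variance structure and the risk-linked
#' structure disagree.
#'
#' @param labels true subtype labels (length N).
#' @param cfg a [scenario_config()].
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @param labels2 optional second partition.
#' @param platform platform tag (default `"expression"`).
#' @return a `genomic_matrix` (N x `cfg$genomic$p`).
#' @export
generate_genomic <- function(labels, cfg, seed = cfg$seed + 2L,
                             labels2 = NULL, platform = "expression") {
  stopifnot(inherits(cfg, "scenario_config"))
  labels <- as.integer(labels)
  N <- length(labels)
  g <- cfg$genomic
  m1 <- max(labels)
  m2 <- if (is.null(labels2)) 0L else max(as.integer(labels2))
  need <- (m1 + m2) * g$signal_features
  if (g$p < need)
    stop("generate_genomic: p too small for the signal blocks (need >= ",
         need, ")")
  set.seed(seed)
  X <- matrix(stats::rnorm(N * g$p, sd = g$noise_sd), N, g$p)
  for (j in seq_len(m1)) {
    fidx <- (j - 1L) * g$signal_features + seq_len(g$signal_features)
    X[labels == j, fidx] <- X[labels == j, fidx] + g$effect * g$noise_sd
  }
  if (m2 > 0L) {
    labels2 <- as.integer(labels2)
    off <- m1 * g$signal_features
    for (j in seq_len(m2)) {
      fidx <- off + (j - 1L) * g$signal_features + seq_len(g$signal_features)
      X[labels2 == j, fidx] <- X[labels2 == j, fidx] + g$effect2 * g$noise_sd
    }
  }
  genomic_matrix(X, platform,
                 sample_ids = sprintf("S%04d", seq_len(N)),
                 feature_ids = sprintf("feat%04d", seq_len(g$p)))
}

#' Generate per-gene mutation indicators
#'
#' Bernoulli draws with per-subtype mutation frequencies. The default
#' frequency matrix plants two differential genes (one enriched in the
#' last subtype, one in the first) over three background genes at 15
#' percent.
#'
#' @param labels subtype labels.
#' @param cfg a [scenario_config()] (uses `cfg$mutations$freq`, genes x m).
#' @param seed RNG seed (default `cfg$seed + 3`).
#' @return N x genes binary matrix with gene column names.
#' @export
generate_mutations <- function(labels, cfg, seed = cfg$seed + 3L) {
  stopifnot(inherits(cfg, "scenario_config"))
  labels <- as.integer(labels)
  m <- max(labels)
  freq <- cfg$mutations$freq
  if (is.null(freq)) {
    freq <- rbind(gene_up_last = c(rep(0.15, m - 1), 0.55),
                  gene_up_first = c(0.5, rep(0.1, m - 1)),
                  gene_flat1 = rep(0.15, m),
                  gene_flat2 = rep(0.15, m),
                  gene_flat3 = rep(0.15, m))
  }
  freq <- as.matrix(freq)
  if (ncol(freq) != m)
    stop("generate_mutations: freq needs one column per subtype")
  if (any(freq < 0 | freq > 1))
    stop("generate_mutations: frequencies must lie in [0, 1]")
  set.seed(seed)
  N <- length(labels)
  out <- sapply(seq_len(nrow(freq)), function(g)
    stats::rbinom(N, 1L, freq[g, labels]))
  colnames(out) <- rownames(freq)
  out
}

#' Generate subtype-dependent survival data
#'
#' Exponential event times with hazard
#' `base_hazard * hr^(subtype - 1)` and independent uniform censoring on
#' `[0, censor_max]`.
#'
#' @param labels subtype labels.
#' @param cfg a [scenario_config()] (uses `cfg$surv`).
#' @param seed RNG seed (default `cfg$seed + 4`).
#' @return data.frame with columns `time` (> 0) and `event` (0/1).
#' @export
generate_survival <- function(labels, cfg, seed = cfg$seed + 4L) {
  stopifnot(inherits(cfg, "scenario_config"))
  labels <- as.integer(labels)
  s <- cfg$surv
  set.seed(seed)
  hz <- s$base_hazard * s$hr^(labels - 1)
  t_event <- stats::rexp(length(labels), rate = hz)
  t_cens <- stats::runif(length(labels), 0, s$censor_max)
  time <- pmax(pmin(t_event, t_cens), .Machine$double.eps)
  data.frame(time = time, event = as.integer(t_event <= t_cens))
}
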