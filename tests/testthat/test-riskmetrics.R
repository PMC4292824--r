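test_that("compute_K matches hand computation and is scale invariant", {
  expect_equal(compute_K(rep(3.7, 10)), 0)
  expect_equal(compute_K(c(1, 3)), 0.5)
  for (s in 1:5) {
    set.seed(s)
    r <- rexp(50) + 0.01
    expect_equal(compute_K(2.7 * r), compute_K(r), tolerance = 1e-12)
  }
  expect_error(compute_K(c(1, 0)), "positive")
  expect_error(compute_K(c(1, -2)), "positive")
})

test_that("compute_components: worked populations and degenerate cases", {
  # single subtype: no heterogeneity by construction
  expect_equal(compute_components(matrix(rexp(20) + 0.1, 20, 1))$D, 0,
               tolerance = 1e-12)

  # proportional risks r_ji = pi_j * r_i: memberships constant, D = 0
  set.seed(3)
  ri <- rexp(30) + 0.05
  pi <- c(0.2, 0.3, 0.5)
  comp <- compute_components(outer(ri, pi))
  expect_equal(comp$D, 0, tolerance = 1e-12)
  expect_equal(comp$D_star, 0, tolerance = 1e-12)

  # two-individual worked population: rows (0.2, 0.1) and (0.1, 0.2)
  comp <- compute_components(rbind(c(0.2, 0.1), c(0.1, 0.2)))
  expect_equal(comp$K, 0)                    # constant total risk
  expect_equal(comp$pi, c(0.5, 0.5))
  expect_equal(unname(comp$K_j^2), c(1, 1) / 9, tolerance = 1e-12)
  expect_equal(comp$D, 1 / 9, tolerance = 1e-12)
  expect_equal(comp$D_cov, 1 / 9, tolerance = 1e-12)
  expect_equal(comp$D_star, 1 / 9, tolerance = 1e-12)

  expect_error(compute_components(cbind(c(1, 2), c(0, 0))), "zero mean")
  expect_error(compute_components(rbind(c(0, 0), c(1, 1))), "positive")
})

test_that("moment, covariance and u-form expressions of D agree", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(c(10, 100, 1000), 1)
    m <- sample(2:6, 1)
    r <- rand_rates(n, m, seed = 100 + s)
    comp <- compute_components(r)   # internally asserts Eq-form agreement
    expect_equal(comp$D, comp$D_cov, tolerance = 1e-10)
    expect_equal(comp$D, u_form_D(r), tolerance = 1e-10)
    # K identities
    expect_equal(comp$K, sqrt(comp$v) / comp$mu, tolerance = 1e-12)
    expect_equal(unname(diag(comp$K_jk)), unname(comp$K_j^2),
                 tolerance = 1e-12)
  }
})

test_that("constant-total-risk populations equate D and the case-only D*", {
  for (s in 1:10) {
    set.seed(s)
    m <- sample(2:5, 1)
    u <- matrix(rgamma(40 * m, 1), 40, m)
    u <- u / rowSums(u)
    r <- 0.07 * u                   # r_i = 0.07 for everyone
    comp <- compute_components(r)
    expect_equal(comp$D_star, comp$D, tolerance = 1e-12)
  }
})

test_that("compute_D_star: worked values, bounds, permutation invariance", {
  # no deviation
  mem <- membership_matrix(matrix(rep(c(.3, .7), each = 8), 8, 2),
                           c(.3, .7))
  expect_equal(compute_D_star(mem), 0)

  # hard labels, equal sizes: chi-square identity upper bound m - 1
  for (m in 2:5) {
    u <- diag(m)[rep(seq_len(m), each = 6), ]
    expect_equal(compute_D_star(membership_matrix(u, rep(1 / m, m))),
                 m - 1, tolerance = 1e-12)
  }

  # worked 4-case example
  u <- rbind(c(.9, .1), c(.8, .2), c(.2, .8), c(.1, .9))
  expect_equal(compute_D_star(membership_matrix(u, c(.5, .5))), 0.5)

  # zero class proportion rejected
  expect_error(membership_matrix(u, c(1, 0)), "positive")

  # invariance under simultaneous class relabeling
  for (s in 1:10) {
    mem <- rand_membership(25, 4, seed = s)
    perm <- sample(4)
    expect_equal(
      compute_D_star(membership_matrix(mem$u[, perm], mem$pi[perm])),
      compute_D_star(mem), tolerance = 1e-12)
  }
})

test_that("membership_matrix enforces its invariants", {
  expect_error(membership_matrix(matrix(c(.5, .6, .5, .6), 2), c(.5, .5)),
               "sum to 1")
  expect_error(membership_matrix(matrix(c(-.1, .5, 1.1, .5), 2), c(.5, .5)),
               "\\[0, 1\\]")
  expect_error(membership_matrix(matrix(.5, 2, 2), c(.6, .6)), "sum to 1")
})

test_that("fit_subtype_model: intercept-only fit carries no information", {
  risk <- make_constant_risk(30)
  labels <- rep(1:3, each = 10)
  fit <- fit_subtype_model(risk, labels, ridge = 0)
  expect_true(fit$model$converged)
  expect_equal(unname(fit$membership$u),
               matrix(1 / 3, 30, 3), tolerance = 1e-8)
  expect_equal(compute_D_star(fit$membership), 0, tolerance = 1e-8)
})

test_that("fit_subtype_model reproduces the saturated 2x2 crosstab", {
  df <- data.frame(case_id = 1:8,
                   g = c("b", "b", "b", "a", "a", "a", "a", "b"))
  risk <- risk_factor_table(df, categorical = list(g = c("a", "b")),
                            continuous = character(0))
  labels <- c(1, 1, 1, 1, 2, 2, 2, 2)
  fit <- fit_subtype_model(risk, labels, ridge = 0)
  u <- fit$membership$u
  expect_equal(unname(u[df$g == "b", 1]), rep(0.75, 4), tolerance = 1e-7)
  expect_equal(unname(u[df$g == "a", 1]), rep(0.25, 4), tolerance = 1e-7)
})

test_that("ridge handles complete separation; optimum matches 1-D search", {
  n_half <- 20
  df <- data.frame(case_id = seq_len(2 * n_half),
                   g = rep(c("a", "b"), each = n_half))
  risk <- risk_factor_table(df, categorical = list(g = c("a", "b")),
                            continuous = character(0))
  labels <- rep(1:2, each = n_half)
  ridge <- 1e-4
  fit <- fit_subtype_model(risk, labels, ridge = ridge)
  u <- fit$membership$u
  # memberships within 0.01 of the hard labels
  expect_true(all(abs(u[cbind(seq_len(2 * n_half), labels)] - 1) < 0.01))
  # oracle: by symmetry the intercept is -slope/2; profile the slope
  pen_obj <- function(t) 2 * n_half * log1p(exp(-t / 2)) + 0.5 * ridge * t^2
  t_opt <- optimize(pen_obj, c(0, 60))$minimum
  expect_equal(unname(fit$model$coefficients[1, 2]), t_opt,
               tolerance = 1e-3)
  expect_equal(unname(u[1, 1]), plogis(t_opt / 2), tolerance = 1e-4)
})

test_that("mean fitted membership equals the class fractions", {
  set.seed(42)
  risk <- make_risk(90, seed = 7)
  labels <- sample(1:3, 90, replace = TRUE, prob = c(.5, .3, .2))
  fit <- fit_subtype_model(risk, labels, ridge = 0)
  expect_true(fit$model$converged)
  expect_equal(unname(colMeans(fit$membership$u)),
               unname(tabulate(labels, 3) / 90), tolerance = 1e-6)
  expect_equal(fit$membership$pi, tabulate(labels, 3) / 90)
})

test_that("fit_subtype_model rejects degenerate inputs", {
  risk <- make_risk(30, seed = 2)
  expect_error(fit_subtype_model(risk, rep(1L, 30)), "at least 2 classes")
  expect_error(fit_subtype_model(risk, c(rep(1L, 29), 3L)), "empty class")
  expect_error(fit_subtype_model(risk, c(rep(1L, 29), 2L)),
               "min_class_size")
  expect_error(fit_subtype_model(risk, rep(1:2, 15), ridge = -1),
               "non-negative")
  # duplicated covariate column: rank-deficient design
  df <- data.frame(case_id = 1:20, g = rep(c("a", "b"), 10),
                   h = rep(c("a", "b"), 10))
  risk2 <- risk_factor_table(df, categorical = list(g = c("a", "b"),
                                                    h = c("a", "b")),
                             continuous = character(0))
  expect_error(fit_subtype_model(risk2, rep(1:2, each = 10)),
               "rank deficient")
})

test_that("risk_factor_table validates vocabulary and completeness", {
  df <- data.frame(case_id = 1:6,
                   smoking = c("never", "former", "current", "never",
                               "former", "sometimes"),
                   age = c(50, 60, NA, 55, 65, 70))
  expect_error(risk_factor_table(df, categorical = list(
    smoking = c("never", "former", "current")), continuous = "age"),
    "vocabulary")
  df$smoking[6] <- "never"
  rt <- risk_factor_table(df, categorical = list(
    smoking = c("never", "former", "current")), continuous = "age",
    min_level_count = 1L)
  expect_equal(nrow(rt), 5L)          # NA age row dropped
  expect_equal(attr(rt, "dropped"), 1L)
  expect_error(risk_factor_table(df[c(1, 1), ],
                                 categorical = list(smoking = c("never"))),
               "duplicate")
})
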