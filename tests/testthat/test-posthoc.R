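test_that("risk_profile_table reproduces hand counts", {
  df <- data.frame(case_id = 1:6,
                   g = c("m", "m", "f", "m", "f", "f"),
                   age = c(50, 60, 70, 55, 65, 75))
  risk <- risk_factor_table(df, categorical = list(g = c("m", "f")),
                            continuous = "age")
  labels <- c(1, 1, 1, 2, 2, 2)
  tab <- risk_profile_table(labels, risk, digits = NULL)
  # class 1: 2/3 m, 1/3 f; class 2: 1/3 m, 2/3 f
  expect_equal(tab$subtype_1[tab$level == "m"], 200 / 3)
  expect_equal(tab$subtype_2[tab$level == "f"], 200 / 3)
  expect_equal(tab$subtype_1[tab$level == "median"], 60)
  expect_equal(tab$subtype_2[tab$level == "median"], 65)
  # percentages per factor per class sum to 100
  gsum <- colSums(tab[tab$factor == "g", c("subtype_1", "subtype_2")])
  expect_equal(unname(gsum), c(100, 100))
  # single subtype equals the marginal frequencies
  tab1 <- risk_profile_table(rep(1, 6), risk, digits = NULL)
  expect_equal(tab1$subtype_1[tab1$level == "m"], 50)
  expect_equal(attr(tab, "class_sizes"), c(3L, 3L))
})

test_that("mutation_association: exact and chi-square behaviour", {
  labels <- rep(1:2, each = 4)
  # [[2,2],[2,2]]: identical proportions, exact p = 1
  mut_flat <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), ncol = 1,
                     dimnames = list(NULL, "flat"))
  res <- mutation_association(labels, mut_flat, min_mutated = 2)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "fisher")

  # [[5,0],[0,5]]: two-sided exact p = 2/252
  labels2 <- rep(1:2, each = 5)
  mut_sep <- matrix(c(rep(1, 5), rep(0, 5)), ncol = 1,
                    dimnames = list(NULL, "sep"))
  res2 <- mutation_association(labels2, mut_sep, min_mutated = 2)
  expect_equal(res2$p_value, 2 / 252, tolerance = 1e-9)
  expect_equal(res2$p_value,
               hyper_fisher_p(rbind(c(5, 0), c(0, 5))), tolerance = 1e-9)

  # percentages recompute the stored counts
  set.seed(2)
  labels3 <- sample(1:3, 60, replace = TRUE)
  mut3 <- matrix(rbinom(120, 1, 0.3), 60, 2,
                 dimnames = list(NULL, c("g1", "g2")))
  res3 <- mutation_association(labels3, mut3, min_mutated = 1)
  sizes <- tabulate(labels3, 3)
  for (g in 1:2) {
    counts <- round(as.numeric(res3[g, paste0("subtype_", 1:3)]) *
                      sizes / 100)
    expect_equal(counts, as.vector(tapply(mut3[, g], labels3, sum)))
  }

  # all-zero gene untested; non-binary rejected
  res0 <- mutation_association(labels, matrix(0, 8, 1), min_mutated = 1)
  expect_equal(res0$test, "untested")
  expect_true(is.na(res0$p_value))
  expect_error(mutation_association(labels, matrix(2, 8, 1)), "binary")
})

test_that("align_labels matches brute force and handles workouts", {
  lab <- rep(1:3, times = c(4, 3, 5))
  res <- align_labels(lab, lab)
  expect_equal(res$alignment, 1:3)
  expect_equal(res$congruent, 12L)
  expect_equal(res$congruent, sum(diag(res$confusion)))

  # confusion [[5,0],[1,4]] keeps identity alignment, congruent 9
  a <- rep(1:2, times = c(5, 5))
  b <- c(rep(1, 5), 1, rep(2, 4))
  res2 <- align_labels(a, b)
  expect_equal(res2$alignment, 1:2)
  expect_equal(res2$congruent, 9L)

  # exhaustive-oracle agreement on random labelings up to m = 5
  for (s in 1:40) {
    set.seed(s)
    m <- sample(2:5, 1)
    la <- sample(1:m, 40, replace = TRUE)
    lb <- sample(1:m, 40, replace = TRUE)
    conf <- matrix(as.integer(table(factor(la, levels = 1:m),
                                    factor(lb, levels = 1:m))), m, m)
    expect_equal(align_labels(la, lb)$congruent, brute_align(conf))
  }
})

test_that("congruence_test expectation, trivial cases and validity", {
  # aligned marginals a = (5,5), b = (6,4): expectation 5
  a <- rep(1:2, times = c(5, 5))
  b <- rep(1:2, times = c(6, 4))
  res <- congruence_test(a, b, B = 39, seed = 1)
  expect_equal(res$expected_random, 5)

  # labels_B a fixed relabeling of labels_A: perfect congruence, floor p
  lab <- rep(1:3, times = c(6, 7, 7))
  relab <- c(2L, 3L, 1L)[lab]
  res2 <- congruence_test(lab, relab, B = 99, seed = 2)
  expect_equal(res2$congruent, 20L)
  expect_equal(res2$p_value, 1 / 100)

  # independent labelings: p-value valid (not anti-conservative) and
  # centered; ties on the congruence count make exact uniformity
  # unattainable, so the check is an envelope at alpha = 0.05
  set.seed(3)
  ps <- replicate(200, {
    la <- sample(1:2, 40, replace = TRUE)
    lb <- sample(1:2, 40, replace = TRUE)
    congruence_test(la, lb, B = 39,
                    seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(sum(ps <= 0.05), qbinom(0.975, 200, 0.05) + 3)
  expect_gt(mean(ps), 0.35)
})

test_that("gsea_competitive matches exact rank-sum enumeration", {
  set.seed(4)
  N <- 20
  labels <- rep(1:2, each = 10)
  # 5 genes, two strongly up in subtype 1
  X <- cbind(g1 = c(rnorm(10, 3), rnorm(10)),
             g2 = c(rnorm(10, 2.5), rnorm(10)),
             g3 = rnorm(N), g4 = rnorm(N), g5 = rnorm(N))
  rownames(X) <- paste0("s", 1:N)
  sets <- structure(list(top = c("g1", "g2")),
                    class = "gene_set_collection")
  res <- gsea_competitive(X, labels, sets)
  p_sub1 <- res$p_value[res$subtype == 1]
  expect_equal(p_sub1, 0.2)               # ranks {1,2} of 5, C(5,2) = 10
  expect_equal(p_sub1, exact_ranksum_p(c(1, 2), 5))

  # invariant to gene ordering on input
  perm <- c(3, 5, 1, 2, 4)
  res_p <- gsea_competitive(X[, perm], labels, sets)
  expect_equal(res_p$p_value, res$p_value)

  # constant gene: t-statistic 0 by convention (checked via internal)
  expect_equal(etiohet:::welch_t(rep(1, 5), rep(1, 7)), 0)

  # enumeration oracle on random instances with <= 10 genes
  for (s in 1:10) {
    set.seed(100 + s)
    ng <- sample(6:10, 1)
    Xr <- matrix(rnorm(N * ng), N, ng,
                 dimnames = list(NULL, paste0("g", 1:ng)))
    k <- sample(2:(ng - 2), 1)
    set_genes <- sample(colnames(Xr), k)
    rr <- gsea_competitive(Xr, labels,
                           structure(list(s = set_genes),
                                     class = "gene_set_collection"))
    tstat <- apply(Xr, 2, function(col)
      etiohet:::welch_t(col[labels == 1], col[labels == 2]))
    in_ranks <- rank(-tstat)[colnames(Xr) %in% set_genes]
    expect_equal(rr$p_value[rr$subtype == 1],
                 exact_ranksum_p(in_ranks, ng), tolerance = 1e-9)
  }

  # empty complement rejected
  expect_error(gsea_competitive(X, labels,
    structure(list(all = paste0("g", 1:5)),
              class = "gene_set_collection")), "complement")
})

test_that("survival_summary: log-rank, c-index and KM invariants", {
  # identical survival experience in both groups
  tm <- c(1, 2, 3, 4, 5)
  ev <- c(1, 0, 1, 1, 0)
  res <- suppressWarnings(
    survival_summary(rep(1:2, each = 5), c(tm, tm), c(ev, ev)))
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(res$logrank_p, 1, tolerance = 1e-10)
  expect_equal(res$c_index, 0.5, tolerance = 1e-6)

  # perfectly ordered groups: c-index 1
  res2 <- suppressWarnings(
    survival_summary(rep(1:2, each = 6), c(1:6, 101:106), rep(1, 12)))
  expect_equal(res2$c_index, 1.0, tolerance = 1e-8)

  # single group: 0.5 by convention
  res1 <- survival_summary(rep(1, 8), 1:8, rep(1, 8))
  expect_equal(res1$c_index, 0.5)
  expect_equal(res1$logrank_p, 1)

  # KM curves start at 1 and are non-increasing
  set.seed(5)
  labs <- rep(1:3, each = 20)
  sv <- generate_survival(labs, scenario_config(m = 3, seed = 9))
  res3 <- survival_summary(labs, sv$time, sv$event)
  s <- res3$km$surv
  starts <- cumsum(c(1, head(res3$km$strata, -1)))
  for (i in seq_along(starts)) {
    seg <- s[starts[i]:(starts[i] + res3$km$strata[i] - 1)]
    expect_true(all(diff(seg) <= 1e-12))
    expect_lte(seg[1], 1)
  }

  expect_error(survival_summary(rep(1, 3), c(0, 1, 2), c(1, 1, 1)),
               "positive")
  expect_error(survival_summary(rep(1, 3), 1:3, c(0, 0, 0)),
               "at least one event")
  expect_error(survival_summary(c(1, 1, 3), 1:3, c(1, 1, 1)), "empty")
})

test_that("read_gmt parses and filters set sizes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tanother\tg4\tg5",
               "tiny\tdesc\tg9"), path)
  sets <- read_gmt(path, min_size = 2)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  sets2 <- read_gmt(path, min_size = 1, max_size = 2)
  expect_named(sets2, c("setB", "tiny"))
  writeLines("bad\tonly_desc", path)
  expect_error(read_gmt(path), "malformed")
})
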