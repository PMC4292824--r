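# Post-hoc characterization of selected subtypes: risk-profile tables,
# mutation associations, cross-platform congruence, competitive gene-set
# enrichment, survival summaries.

#' Within-subtype risk-factor profile table
#'
#' For each subtype, the relative frequency (percent) of every level of
#' every categorical risk factor, and the median of every continuous
#' covariate. Percentages within one factor and one subtype sum to 100 up
#' to rounding.
#'
#' @param labels subtype labels in `1..m`, aligned with `risk`.
#' @param risk a [risk_factor_table()].
#' @param digits rounding for percentages (default 0; use NULL for none).
#' @return data.frame with columns `factor`, `level`, then one column per
#'   subtype (`subtype_1`, ...). Continuous covariates appear with level
#'   `"median"` and unrounded medians. Attribute `"class_sizes"` holds n_j.
#' @export
risk_profile_table <- function(labels, risk, digits = 0) {
  stopifnot(inherits(risk, "risk_factor_table"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(risk))
    stop("risk_profile_table: labels and risk are not aligned")
  m <- max(labels)
  sizes <- tabulate(labels, nbins = m)
  rows <- list()
  for (cn in names(attr(risk, "categorical"))) {
    f <- risk[[cn]]
    for (l in levels(f)) {
      pct <- vapply(seq_len(m), function(j)
        100 * sum(f == l & labels == j) / sizes[j], numeric(1))
      if (!is.null(digits)) pct <- round(pct, digits)
      rows[[length(rows) + 1L]] <-
        data.frame(factor = cn, level = l,
                   t(stats::setNames(pct, paste0("subtype_", seq_len(m)))))
    }
  }
  for (cn in attr(risk, "continuous")) {
    med <- vapply(seq_len(m), function(j)
      stats::median(risk[[cn]][labels == j]), numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(factor = cn, level = "median",
                 t(stats::setNames(med, paste0("subtype_", seq_len(m)))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "class_sizes") <- sizes
  out
}

#' Mutation frequency by subtype with association tests
#'
#' For each gene with at least `min_mutated` mutated cases, tabulates the
#' per-subtype mutation percentage and tests the m x 2 association between
#' subtype and mutation status: Pearson chi-square without continuity
#' correction, falling back to Fisher's exact test whenever any expected
#' cell count is below 5 (`method = "auto"`). Genes below the threshold or
#' with no mutations are reported untested.
#'
#' @param labels subtype labels in `1..m`.
#' @param mutations cases x genes binary (0/1) matrix.
#' @param min_mutated minimum mutated cases for testing (default 5).
#' @param method `"auto"` (default), `"chisq"` or `"fisher"`.
#' @return data.frame, one row per gene: `gene`, `n_mutated`, per-subtype
#'   percentage columns, `p_value` (NA when untested), `test` used.
#' @export
mutation_association <- function(labels, mutations, min_mutated = 5L,
                                 method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  mutations <- as.matrix(mutations)
  if (nrow(mutations) != length(labels))
    stop("mutation_association: labels and mutations are not aligned")
  if (!all(mutations %in% c(0, 1)))
    stop("mutation_association: mutation matrix must be binary 0/1")
  m <- max(labels)
  sizes <- tabulate(labels, nbins = m)
  genes <- colnames(mutations)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(mutations)))
  rows <- lapply(seq_len(ncol(mutations)), function(g) {
    mut <- mutations[, g]
    nmut <- sum(mut)
    pct <- vapply(seq_len(m), function(j)
      100 * sum(mut[labels == j]) / sizes[j], numeric(1))
    res <- data.frame(gene = genes[g], n_mutated = nmut,
                      t(stats::setNames(pct,
                                        paste0("subtype_", seq_len(m)))))
    if (nmut < min_mutated || nmut == length(mut)) {
      res$p_value <- NA_real_
      res$test <- "untested"
      return(res)
    }
    tab <- table(factor(labels, levels = seq_len(m)),
                 factor(mut, levels = c(0, 1)))
    use <- method
    if (use == "auto") {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use <- if (any(expected < 5)) "fisher" else "chisq"
    }
    res$p_value <- if (use == "fisher")
      stats::fisher.test(tab, workspace = 2e6)$p.value
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    res$test <- use
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "class_sizes") <- sizes
  out
}

# Exact maximization of the confusion-matrix trace over label permutations.
# m! search with pruning is unnecessary at the class counts this method
# uses (m <= 8 enforced).
best_alignment <- function(confusion) {
  m <- nrow(confusion)
  if (m > 8L) stop("best_alignment: supports up to 8 classes")
  perms <- perm_enumerate(m)
  traces <- vapply(seq_len(nrow(perms)), function(i)
    sum(confusion[cbind(seq_len(m), perms[i, ])]), numeric(1))
  best <- which.max(traces)
  list(perm = perms[best, ], trace = traces[best])
}

perm_enumerate <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- perm_enumerate(m - 1L)
  out <- do.call(rbind, lapply(seq_len(m), function(first) {
    rest <- setdiff(seq_len(m), first)
    cbind(first, matrix(rest[sub], nrow(sub), m - 1L))
  }))
  dimnames(out) <- NULL
  out
}

#' Align two subtype labelings
#'
#' Finds the permutation of the B labels maximizing the number of cases
#' assigned to matching subtypes (the trace of the permuted confusion
#' matrix), by exact search over all label permutations. Unequal class
#' counts are handled by padding with empty dummy classes.
#'
#' @param labels_A,labels_B subtype labels on the same cases.
#' @return list of class `congruence_result` with `confusion` (A x aligned
#'   B counts), `alignment` (alignment\[j\] = original B label shown in
#'   aligned column j), `congruent` (trace), `n`.
#' @export
align_labels <- function(labels_A, labels_B) {
  labels_A <- as.integer(labels_A)
  labels_B <- as.integer(labels_B)
  if (length(labels_A) != length(labels_B))
    stop("align_labels: label vectors differ in length")
  m <- max(max(labels_A), max(labels_B))
  conf <- table(factor(labels_A, levels = seq_len(m)),
                factor(labels_B, levels = seq_len(m)))
  conf <- matrix(as.integer(conf), m, m)
  al <- best_alignment(conf)
  # permute B columns so that aligned column j pairs with A class j
  aligned <- conf[, al$perm, drop = FALSE]
  structure(list(confusion = aligned,
                 alignment = al$perm,
                 congruent = al$trace,
                 n = length(labels_A)),
            class = "congruence_result")
}

#' Permutation test of cross-platform subtype congruence
#'
#' Quantifies agreement of two subtype systems for the same cases: the
#' observed congruent count after optimal alignment, the count expected
#' under independence of the two labelings with the aligned marginals
#' (sum_j a_j b_j / N), and a permutation p-value obtained by permuting
#' `labels_B` across cases `B` times and re-aligning each permuted
#' labeling.
#'
#' @inheritParams align_labels
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @return `congruence_result` with additional fields `expected_random`,
#'   `p_value`, `B`.
#' @export
congruence_test <- function(labels_A, labels_B, B = 1000L, seed = 1L) {
  obs <- align_labels(labels_A, labels_B)
  marg_A <- rowSums(obs$confusion)
  marg_B <- colSums(obs$confusion)
  obs$expected_random <- sum(marg_A * marg_B) / obs$n
  set.seed(seed)
  null_cong <- vapply(seq_len(B), function(b) {
    align_labels(labels_A, sample(labels_B))$congruent
  }, numeric(1))
  obs$p_value <- (1 + sum(null_cong >= obs$congruent)) / (1 + B)
  obs$B <- B
  obs
}

#' Read a GMT gene-set collection
#'
#' Tab-separated MSigDB-style format: set name, description, then member
#' feature ids. Sets outside the `[min_size, max_size]` band are dropped.
#'
#' @param path GMT file path.
#' @param min_size,max_size retained set-size band (defaults 2 and Inf).
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path, min_size = 2L, max_size = Inf) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("read_gmt: malformed line (need name, description, members): ",
           substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  keep <- vapply(sets, function(s)
    length(s) >= min_size && length(s) <= max_size, logical(1))
  structure(sets[keep], class = "gene_set_collection")
}

welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se <- sqrt(vx / nx + vy / ny)
  if (se == 0) return(0)
  (mean(x) - mean(y)) / se
}

pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) return(0)
  (mean(x) - mean(y)) / se
}

#' Competitive gene-set enrichment by rank-sum test
#'
#' For each subtype k, each gene gets a two-sample t-statistic comparing
#' cases in subtype k against all remaining cases (Welch by default). Genes
#' are ranked by the signed statistic in decreasing order, and for each
#' gene set a two-sided Wilcoxon rank-sum test compares the ranks of in-set
#' genes with the ranks of their complement. This is a competitive test: it
#' asks whether set genes are more differentially expressed than non-set
#' genes, not whether they are differentially expressed at all.
#'
#' @param X expression `genomic_matrix` (or plain samples x genes matrix
#'   with column names).
#' @param labels subtype labels in `1..m`.
#' @param sets a `gene_set_collection` (named list of gene-id vectors).
#' @param statistic `"welch"` (default) or `"pooled"` per-gene t-statistic.
#' @return data.frame with one row per (subtype, set): `subtype`, `set`,
#'   `set_size` (genes present in `X`), `p_value`, `p_bonferroni`
#'   (multiplied by the number of sets tested, capped at 1).
#' @export
gsea_competitive <- function(X, labels, sets,
                             statistic = c("welch", "pooled")) {
  statistic <- match.arg(statistic)
  V <- if (inherits(X, "genomic_matrix")) X$values else as.matrix(X)
  if (is.null(colnames(V))) stop("gsea_competitive: X needs gene names")
  labels <- as.integer(labels)
  if (length(labels) != nrow(V))
    stop("gsea_competitive: labels and X are not aligned")
  m <- max(labels)
  genes <- colnames(V)
  tfun <- if (statistic == "welch") welch_t else pooled_t
  out <- list()
  for (k in seq_len(m)) {
    ink <- labels == k
    tstat <- vapply(seq_along(genes), function(g)
      tfun(V[ink, g], V[!ink, g]), numeric(1))
    rk <- rank(-tstat)          # rank 1 = most up-regulated in subtype k
    for (s in names(sets)) {
      members <- genes %in% sets[[s]]
      if (!any(members) || all(members))
        stop("gsea_competitive: set '", s, "' has empty intersection or ",
             "empty complement among the supplied genes")
      p <- suppressWarnings(
        stats::wilcox.test(rk[members], rk[!members])$p.value)
      out[[length(out) + 1L]] <-
        data.frame(subtype = k, set = s, set_size = sum(members),
                   p_value = p)
    }
  }
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, out$p_value * length(sets))
  rownames(out) <- NULL
  out
}

#' Survival summary of subtypes
#'
#' Kaplan-Meier product-limit curves per subtype, the m-sample log-rank
#' test, and Harrell's c-index of the linear predictor from a Cox
#' proportional-hazards fit on subtype indicator covariates (the standard
#' way to attach a concordance to an unordered categorical grouping). The
#' c-index counts informative pairs only -- pairs whose linear predictors
#' differ: concordant / (concordant + discordant). With a single subtype
#' there is no between-group information and the c-index is 0.5 by
#' convention.
#'
#' @param labels subtype labels in `1..m`.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (at least one event).
#' @return list with `km` ([survival::survfit] object), `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, `c_index`, `n`, `n_events`.
#' @export
survival_summary <- function(labels, time, event) {
  labels <- as.integer(labels)
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(labels) || length(event) != length(labels))
    stop("survival_summary: inputs are not aligned")
  if (any(time <= 0)) stop("survival_summary: times must be positive")
  if (!all(event %in% c(0L, 1L)))
    stop("survival_summary: event must be 0/1")
  if (sum(event) < 1L) stop("survival_summary: need at least one event")
  m <- max(labels)
  if (any(tabulate(labels, nbins = m) == 0L))
    stop("survival_summary: empty subtype")
  grp <- factor(labels, levels = seq_len(m))
  surv <- survival::Surv(time, event)
  km <- survival::survfit(surv ~ grp)
  if (m == 1L) {
    return(list(km = km, logrank_chisq = 0, logrank_df = 0, logrank_p = 1,
                c_index = 0.5, n = length(time), n_events = sum(event)))
  }
  lr <- survival::survdiff(surv ~ grp)
  df <- m - 1L
  cox <- survival::coxph(surv ~ grp)
  cnt <- survival::concordance(cox)$count
  informative <- cnt[["concordant"]] + cnt[["discordant"]]
  ci <- if (informative == 0) 0.5 else cnt[["concordant"]] / informative
  list(km = km,
       logrank_chisq = as.numeric(lr$chisq),
       logrank_df = df,
       logrank_p = stats::pchisq(lr$chisq, df, lower.tail = FALSE),
       c_index = ci,
       n = length(time), n_events = sum(event))
}
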