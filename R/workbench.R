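# I/O, configuration, logging and the command-line surface.

#' Read a genomic matrix from TSV
#'
#' Strict TSV parser: header row with an ID column first, numeric body.
#' Ragged rows, non-numeric cells and duplicate IDs raise errors naming
#' the offending line.
#'
#' @param path TSV file.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @param platform platform tag for the resulting matrix.
#' @param chromosome optional per-feature chromosome vector.
#' @return a [genomic_matrix()], samples in rows.
#' @export
read_genomic_matrix <- function(path,
                                orientation = c("samples_rows",
                                                "features_rows"),
                                platform = "expression",
                                chromosome = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_genomic_matrix: ", path,
                               ": need a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(cells[[1]])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != ncols)
      stop("read_genomic_matrix: ", path, ": line ", i, " has ",
           length(cells[[i]]), " fields, expected ", ncols)
  }
  col_ids <- cells[[1]][-1]
  row_ids <- vapply(cells[-1], `[[`, character(1), 1)
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup))
    stop("read_genomic_matrix: ", path, ": duplicate row ID '", dup[1], "'")
  if (anyDuplicated(col_ids))
    stop("read_genomic_matrix: ", path, ": duplicate column ID '",
         col_ids[duplicated(col_ids)][1], "'")
  vals <- matrix(NA_real_, length(row_ids), length(col_ids))
  for (i in seq_along(row_ids)) {
    x <- suppressWarnings(as.numeric(cells[[i + 1L]][-1]))
    if (anyNA(x))
      stop("read_genomic_matrix: ", path, ": non-numeric cell on line ",
           i + 1L)
    vals[i, ] <- x
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  if (orientation == "features_rows") vals <- t(vals)
  genomic_matrix(vals, platform, chromosome = chromosome)
}

#' Write a genomic matrix to TSV
#'
#' @param M a `genomic_matrix`.
#' @param path output file.
#' @param orientation row entity of the written file.
#' @export
write_genomic_matrix <- function(M, path,
                                 orientation = c("samples_rows",
                                                 "features_rows")) {
  orientation <- match.arg(orientation)
  V <- M$values
  if (orientation == "features_rows") V <- t(V)
  id_name <- if (orientation == "samples_rows") "sample_id" else "feature_id"
  df <- data.frame(rownames(V), V, check.names = FALSE)
  colnames(df) <- c(id_name, colnames(V))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation TSV
#'
#' Two columns, `feature_id` and `chromosome`. Returns the chromosome
#' vector aligned to the features of `M` (NA for unannotated features),
#' for sex-chromosome exclusion in [standardize_and_merge()].
#'
#' @param path TSV with header columns `feature_id`, `chromosome`.
#' @param M a `genomic_matrix` to align against.
#' @return `M` with its `chromosome` field set.
#' @export
annotate_features <- function(path, M) {
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("feature_id", "chromosome") %in% names(ann)))
    stop("annotate_features: need columns feature_id, chromosome")
  chrom <- ann$chromosome[match(M$feature_ids, ann$feature_id)]
  genomic_matrix(M$values, M$platform, M$sample_ids, M$feature_ids,
                 as.character(chrom))
}

#' Read a clinical/risk-factor TSV
#'
#' Header TSV with one row per case; column roles are passed through to
#' [risk_factor_table()].
#'
#' @inheritParams risk_factor_table
#' @param path TSV file.
#' @return a `risk_factor_table`.
#' @export
read_risk_table <- function(path, id_col = "case_id",
                            categorical = list(
                              smoking = c("never", "former", "current"),
                              bmi = c("normal", "overweight", "obese"),
                              hypertension = c("no", "yes"),
                              gender = c("male", "female")),
                            continuous = "age") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  risk_factor_table(df, id_col = id_col, categorical = categorical,
                    continuous = continuous)
}

#' Complete-case intersection of pipeline inputs
#'
#' Aligns a genomic matrix with a clinical table (and optionally mutation
#' and survival tables) on shared case identifiers, applying complete-case
#' filtering to the declared clinical columns. The report accounts for
#' every input case: unmatched per input, incomplete among the matched,
#' and aligned.
#'
#' @param genomic a `genomic_matrix`.
#' @param clinical data.frame with case identifiers (raw; missing values
#'   allowed and counted) or a ready `risk_factor_table`.
#' @param mutations optional cases x genes 0/1 matrix with case-id
#'   rownames.
#' @param survival optional data.frame with `case_id`, `time`, `event`.
#' @param ... column-role declarations forwarded to [risk_factor_table()]
#'   when `clinical` is raw.
#' @return list with aligned `genomic`, `risk`, `mutations`, `survival`
#'   (case order matching `genomic$sample_ids`) and `report`.
#' @export
intersect_cases <- function(genomic, clinical, mutations = NULL,
                            survival = NULL, ...) {
  stopifnot(inherits(genomic, "genomic_matrix"))
  roles <- list(...)
  id_col <- if (!is.null(roles$id_col)) roles$id_col else "case_id"
  ids_g <- genomic$sample_ids
  ids_c <- as.character(clinical[[id_col]])
  keep_ids <- intersect(ids_g, ids_c)
  if (!is.null(mutations))
    keep_ids <- intersect(keep_ids, rownames(mutations))
  if (!is.null(survival))
    keep_ids <- intersect(keep_ids, as.character(survival[[id_col]]))
  if (length(keep_ids) == 0L)
    stop("intersect_cases: empty case intersection")
  matched_clin <- clinical[ids_c %in% keep_ids, , drop = FALSE]
  risk <- if (inherits(clinical, "risk_factor_table")) {
    # already complete-case; just subset
    out <- matched_clin
    attributes(out)[c("id_col", "categorical", "continuous", "dropped")] <-
      attributes(clinical)[c("id_col", "categorical", "continuous",
                             "dropped")]
    class(out) <- class(clinical)
    out
  } else {
    do.call(risk_factor_table, c(list(matched_clin), roles))
  }
  incomplete <- if (inherits(clinical, "risk_factor_table")) 0L
                else attr(risk, "dropped")
  aligned_ids <- intersect(keep_ids, as.character(risk[[id_col]]))
  if (length(aligned_ids) == 0L)
    stop("intersect_cases: empty case intersection")
  # order by genomic sample order
  aligned_ids <- ids_g[ids_g %in% aligned_ids]
  gsub_idx <- match(aligned_ids, ids_g)
  gal <- genomic_matrix(genomic$values[gsub_idx, , drop = FALSE],
                        genomic$platform, aligned_ids,
                        genomic$feature_ids, genomic$chromosome)
  risk <- risk[match(aligned_ids, as.character(risk[[id_col]])), ,
               drop = FALSE]
  class(risk) <- c("risk_factor_table", "data.frame")
  mal <- if (is.null(mutations)) NULL
         else mutations[match(aligned_ids, rownames(mutations)), ,
                        drop = FALSE]
  sal <- if (is.null(survival)) NULL
         else survival[match(aligned_ids,
                             as.character(survival[[id_col]])), ,
                       drop = FALSE]
  report <- list(
    n_genomic = length(ids_g),
    n_clinical = length(ids_c),
    unmatched_genomic = sum(!ids_g %in% keep_ids),
    unmatched_clinical = sum(!ids_c %in% keep_ids),
    incomplete = incomplete,
    aligned = length(aligned_ids))
  list(genomic = gal, risk = risk, mutations = mal, survival = sal,
       report = report)
}

# Polynomial rolling hash over the JSON serialization; embedded in output
# artifacts so reruns can be matched to their configuration.
config_fingerprint <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a scored ensemble to JSON
#'
#' @param ensemble a `solution_ensemble`.
#' @param path output JSON file.
#' @param seed master seed to embed.
#' @param config optional configuration list to fingerprint.
#' @export
write_ensemble_json <- function(ensemble, path, seed = NA_integer_,
                                config = NULL) {
  payload <- list(
    m = ensemble$m,
    n_restarts = ensemble$n_restarts,
    seed = seed,
    config_hash = if (is.null(config)) NA else config_fingerprint(config),
    solutions = lapply(ensemble$solutions, function(s)
      list(labels = s$labels, G = s$G, D_star = s$D_star,
           admissible = s$admissible, seeds = s$seeds,
           class_sizes = s$class_sizes)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

required_keys <- function(cfg, keys, command) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("config for '", command, "' is missing required key(s): ",
         paste(missing, collapse = ", "))
}

known_keys <- function(cfg, keys, command) {
  extra <- setdiff(names(cfg), keys)
  if (length(extra))
    stop("config for '", command, "' has unknown key(s): ",
         paste(extra, collapse = ", "))
}

cli_log <- function(out_dir, command, cfg, seed, extra = list()) {
  log <- c(sprintf("command: %s", command),
           sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           sprintf("package_version: %s",
                   as.character(utils::packageVersion("etiohet"))),
           sprintf("seed: %s", seed),
           sprintf("config_hash: %s", config_fingerprint(cfg)),
           sprintf("config: %s",
                   jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)),
           unlist(extra))
  writeLines(log, file.path(out_dir, paste0(command, ".log")))
}

#' Command-line entry point
#'
#' Dispatches `etiohet <command> <config.json>` with commands `simulate`,
#' `prep`, `cluster`, `test-het`, `test-k` and `posthoc`. Each command
#' reads a JSON configuration, validates its keys before any computation,
#' runs the corresponding module and writes TSV/JSON outputs plus a log
#' capturing the seed, package version and configuration echo into the
#' config's `out_dir`. An installed wrapper script lives at
#' `system.file("cli", "etiohet.R", package = "etiohet")`.
#'
#' @param args character vector, default the process command-line
#'   arguments.
#' @return 0 on success (invisibly); errors propagate (the wrapper maps
#'   them to a non-zero exit status).
#' @export
etiohet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: etiohet <simulate|prep|cluster|test-het|test-k",
                 "|posthoc> <config.json>")
  if (length(args) != 2L) stop(usage, call. = FALSE)
  command <- args[1]
  cfg <- jsonlite::read_json(args[2], simplifyVector = TRUE)
  if (is.null(cfg$out_dir)) stop("config is missing required key: out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  switch(command,
    "simulate" = cli_simulate(cfg, seed),
    "prep" = cli_prep(cfg, seed),
    "cluster" = cli_cluster(cfg, seed),
    "test-het" = cli_test(cfg, seed, incremental = FALSE),
    "test-k" = cli_test(cfg, seed, incremental = TRUE),
    "posthoc" = cli_posthoc(cfg, seed),
    stop(usage, call. = FALSE))
  invisible(0L)
}

cli_simulate <- function(cfg, seed) {
  known_keys(cfg, c("out_dir", "seed", "n", "N", "m", "effect_scale",
                    "genomic_effect", "genomic_p"), "simulate")
  sc <- scenario_config(
    n = if (is.null(cfg$n)) 20000L else cfg$n,
    N = if (is.null(cfg$N)) 300L else cfg$N,
    m = if (is.null(cfg$m)) 3L else cfg$m,
    effect_scale = if (is.null(cfg$effect_scale)) 1 else cfg$effect_scale,
    genomic = Filter(Negate(is.null),
                     list(effect = cfg$genomic_effect, p = cfg$genomic_p)),
    seed = seed)
  truth <- generate_population(sc)
  cases <- sample_cases(truth)
  X <- generate_genomic(cases$labels, sc)
  V <- X$values
  rownames(V) <- cases$risk$case_id
  X <- genomic_matrix(V, X$platform)
  mut <- generate_mutations(cases$labels, sc)
  rownames(mut) <- cases$risk$case_id
  sv <- generate_survival(cases$labels, sc)
  sv <- data.frame(case_id = cases$risk$case_id, sv)
  od <- cfg$out_dir
  write_genomic_matrix(X, file.path(od, "genomic.tsv"))
  utils::write.table(cases$risk, file.path(od, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(case_id = rownames(mut), mut),
                     file.path(od, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sv, file.path(od, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(case_id = cases$risk$case_id,
                                true_label = cases$labels),
                     file.path(od, "true_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cli_log(cfg$out_dir, "simulate", cfg, seed)
}

cli_prep <- function(cfg, seed) {
  known_keys(cfg, c("out_dir", "seed", "genomic", "counts", "orientation",
                    "platform", "median_min", "mad_min", "top_k",
                    "annotation"), "prep")
  required_keys(cfg, "genomic", "prep")
  orientation <- if (is.null(cfg$orientation)) "samples_rows"
                 else cfg$orientation
  platform <- if (is.null(cfg$platform)) "expression" else cfg$platform
  M <- read_genomic_matrix(cfg$genomic, orientation, platform)
  if (!is.null(cfg$annotation)) M <- annotate_features(cfg$annotation, M)
  if (!is.null(cfg$counts)) {
    counts <- read_genomic_matrix(cfg$counts, orientation, platform)
    M <- filter_expression(M, counts$values,
                           median_min = if (is.null(cfg$median_min)) 5
                                        else cfg$median_min,
                           mad_min = if (is.null(cfg$mad_min)) 1.25
                                     else cfg$mad_min)
  }
  M <- standardize_and_merge(list(M))
  if (!is.null(cfg$top_k)) M <- top_variable_features(M, cfg$top_k)
  write_genomic_matrix(M, file.path(cfg$out_dir, "prepped.tsv"))
  cli_log(cfg$out_dir, "prep", cfg, seed)
}

cli_read_pair <- function(cfg) {
  orientation <- if (is.null(cfg$orientation)) "samples_rows"
                 else cfg$orientation
  M <- read_genomic_matrix(cfg$genomic, orientation)
  risk <- read_risk_table(cfg$clinical)
  al <- intersect_cases(M, risk)
  al
}

cli_cluster <- function(cfg, seed) {
  known_keys(cfg, c("out_dir", "seed", "genomic", "clinical", "orientation",
                    "m", "n_restarts", "min_class_fraction", "ridge",
                    "n_benchmark"), "cluster")
  required_keys(cfg, c("genomic", "clinical", "m"), "cluster")
  al <- cli_read_pair(cfg)
  n_restarts <- if (is.null(cfg$n_restarts)) 100L else cfg$n_restarts
  mcf <- if (is.null(cfg$min_class_fraction)) 0.05
         else cfg$min_class_fraction
  ridge <- if (is.null(cfg$ridge)) 1e-4 else cfg$ridge
  ens <- run_restarted_kmeans(al$genomic$values, cfg$m, n_restarts, seed)
  ens <- score_ensemble(ens, al$risk, mcf, ridge)
  best <- select_solution(ens, "max_D_star")
  nb <- if (is.null(cfg$n_benchmark)) 100L else cfg$n_benchmark
  bench <- random_benchmark(al$genomic$values, al$risk, cfg$m, nb,
                            seed + 31L, ridge)
  od <- cfg$out_dir
  write_ensemble_json(ens, file.path(od, "ensemble.json"), seed, cfg)
  utils::write.table(diagnostic_table(ens, bench),
                     file.path(od, "diagnostic.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(case_id = al$genomic$sample_ids,
                                subtype = best$labels),
                     file.path(od, "subtypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cli_log(od, "cluster", cfg, seed,
          list(sprintf("selected_D_star: %.6g", best$D_star),
               sprintf("selected_G: %.6g", best$G),
               sprintf("unique_solutions: %d", length(ens$solutions))))
}

cli_test <- function(cfg, seed, incremental) {
  command <- if (incremental) "test-k" else "test-het"
  known_keys(cfg, c("out_dir", "seed", "genomic", "clinical", "orientation",
                    "m", "B", "n_restarts", "min_class_fraction", "ridge"),
             command)
  required_keys(cfg, c("genomic", "clinical"), command)
  al <- cli_read_pair(cfg)
  m <- if (is.null(cfg$m)) 2L else cfg$m
  B <- if (is.null(cfg$B)) 1000L else cfg$B
  n_restarts <- if (is.null(cfg$n_restarts)) 100L else cfg$n_restarts
  mcf <- if (is.null(cfg$min_class_fraction)) 0.05
         else cfg$min_class_fraction
  ridge <- if (is.null(cfg$ridge)) 1e-4 else cfg$ridge
  res <- if (incremental)
    incremental_test(al$genomic$values, al$risk, m, B, n_restarts, seed,
                     mcf, ridge)
  else
    heterogeneity_test(al$genomic$values, al$risk, m, B, n_restarts, seed,
                       mcf, ridge)
  out <- list(observed = res$observed, p_value = res$p_value, B = res$B,
              seed = seed, config_hash = config_fingerprint(cfg),
              config_echo = res$config_echo)
  jsonlite::write_json(out, file.path(cfg$out_dir,
                                      paste0(command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(data.frame(draw = seq_len(res$B),
                                statistic = res$null_draws),
                     file.path(cfg$out_dir, paste0(command, "-null.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cli_log(cfg$out_dir, command, cfg, seed,
          list(sprintf("observed: %.6g", res$observed),
               sprintf("p_value: %.6g", res$p_value)))
}

cli_posthoc <- function(cfg, seed) {
  known_keys(cfg, c("out_dir", "seed", "subtypes", "clinical", "mutations",
                    "survival", "genomic", "orientation", "gmt"), "posthoc")
  required_keys(cfg, c("subtypes", "clinical"), "posthoc")
  sub <- utils::read.delim(cfg$subtypes, sep = "\t",
                           stringsAsFactors = FALSE)
  risk <- read_risk_table(cfg$clinical)
  idx <- match(sub$case_id, as.character(risk$case_id))
  if (anyNA(idx)) stop("cli_posthoc: subtype case ids missing from clinical")
  risk <- risk[idx, , drop = FALSE]
  class(risk) <- c("risk_factor_table", "data.frame")
  labels <- as.integer(sub$subtype)
  od <- cfg$out_dir
  utils::write.table(risk_profile_table(labels, risk),
                     file.path(od, "risk_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cfg$mutations)) {
    mutdf <- utils::read.delim(cfg$mutations, sep = "\t",
                               stringsAsFactors = FALSE)
    mut <- as.matrix(mutdf[match(sub$case_id, mutdf$case_id), -1,
                           drop = FALSE])
    utils::write.table(mutation_association(labels, mut),
                       file.path(od, "mutation_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$survival)) {
    sv <- utils::read.delim(cfg$survival, sep = "\t",
                            stringsAsFactors = FALSE)
    sv <- sv[match(sub$case_id, sv$case_id), , drop = FALSE]
    ss <- survival_summary(labels, sv$time, sv$event)
    jsonlite::write_json(list(logrank_chisq = ss$logrank_chisq,
                              logrank_df = ss$logrank_df,
                              logrank_p = ss$logrank_p,
                              c_index = ss$c_index, n = ss$n,
                              n_events = ss$n_events),
                         file.path(od, "survival.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(cfg$gmt) && !is.null(cfg$genomic)) {
    orientation <- if (is.null(cfg$orientation)) "samples_rows"
                   else cfg$orientation
    M <- read_genomic_matrix(cfg$genomic, orientation)
    keep <- match(sub$case_id, M$sample_ids)
    Msub <- genomic_matrix(M$values[keep, , drop = FALSE], M$platform,
                           sub$case_id, M$feature_ids)
    sets <- read_gmt(cfg$gmt)
    utils::write.table(gsea_competitive(Msub, labels, sets),
                       file.path(od, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cli_log(od, "posthoc", cfg, seed)
}
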