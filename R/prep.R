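# Genomic matrix preprocessing: expression / methylation / copy-number
# filtering, standardization, merging, top-variance feature selection.

#' Construct a genomic matrix
#'
#' A samples x features real matrix with platform tag and optional per-
#' feature chromosome annotation.
#'
#' @param values numeric matrix, samples in rows.
#' @param platform one of `"expression"`, `"methylation"`, `"copy_number"`.
#' @param sample_ids,feature_ids unique identifiers; default taken from
#'   dimnames.
#' @param chromosome optional character vector (one per feature), used for
#'   sex-chromosome exclusion.
#' @return a `genomic_matrix` (list with `values`, `platform`,
#'   `sample_ids`, `feature_ids`, `chromosome`).
#' @export
genomic_matrix <- function(values,
                           platform = c("expression", "methylation",
                                        "copy_number"),
                           sample_ids = rownames(values),
                           feature_ids = colnames(values),
                           chromosome = NULL) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("genomic_matrix: non-finite entries")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("genomic_matrix: duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("genomic_matrix: duplicate feature ids")
  if (length(sample_ids) != nrow(values) ||
      length(feature_ids) != ncol(values))
    stop("genomic_matrix: id lengths do not match matrix dimensions")
  if (!is.null(chromosome) && length(chromosome) != ncol(values))
    stop("genomic_matrix: chromosome annotation length mismatch")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, platform = platform,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 chromosome = chromosome),
            class = "genomic_matrix")
}

subset_features <- function(M, keep) {
  genomic_matrix(M$values[, keep, drop = FALSE], M$platform,
                 M$sample_ids, M$feature_ids[keep],
                 if (is.null(M$chromosome)) NULL else M$chromosome[keep])
}

#' Expression feature filter
#'
#' Removes genes with low expression (median raw count below `median_min`)
#' or low variability (median absolute deviation of the analysis-scale
#' values below `mad_min`). The median-count rule operates on the count
#' scale, the MAD rule on the supplied analysis (typically normalized log)
#' scale. The MAD is the raw median absolute deviation without the 1.4826
#' normal-consistency factor (set `mad_constant` to change).
#'
#' @param M a `genomic_matrix` on the analysis scale.
#' @param counts matching samples x features matrix on the count scale
#'   (same feature set as `M`).
#' @param median_min minimum median count (default 5).
#' @param mad_min minimum MAD of the analysis values (default 1.25).
#' @param mad_constant scale factor passed to [stats::mad()] (default 1).
#' @return filtered `genomic_matrix`; attribute `"filter_report"` gives the
#'   number of features removed by each rule and retained.
#' @export
filter_expression <- function(M, counts, median_min = 5, mad_min = 1.25,
                              mad_constant = 1) {
  stopifnot(inherits(M, "genomic_matrix"))
  counts <- as.matrix(counts)
  if (ncol(counts) != ncol(M$values))
    stop("filter_expression: counts and M must share features")
  med <- apply(counts, 2, stats::median)
  madv <- apply(M$values, 2, stats::mad, constant = mad_constant)
  low_expr <- med < median_min
  low_var <- madv < mad_min
  keep <- !low_expr & !low_var
  if (!any(keep))
    stop("filter_expression: all features removed")
  out <- subset_features(M, keep)
  attr(out, "filter_report") <- c(
    input = ncol(M$values),
    removed_low_expression = sum(low_expr),
    removed_low_variability_only = sum(low_var & !low_expr),
    retained = sum(keep))
  out
}

#' Standardize panels feature-wise and merge on common features
#'
#' Each panel is standardized feature-wise to mean 0, SD 1 across its own
#' samples; panels are then merged on the intersection of their feature
#' sets (rows stacked). Zero-variance features are dropped with a warning
#' before merging, and sex-chromosome (X/Y) features are dropped whenever
#' chromosome annotation is present.
#'
#' @param panels list of `genomic_matrix` objects sharing a platform.
#' @param drop_sex_chromosomes drop features annotated to chromosomes
#'   X or Y (default TRUE).
#' @return merged standardized `genomic_matrix`.
#' @export
standardize_and_merge <- function(panels, drop_sex_chromosomes = TRUE) {
  if (inherits(panels, "genomic_matrix")) panels <- list(panels)
  stopifnot(length(panels) >= 1L,
            all(vapply(panels, inherits, logical(1), "genomic_matrix")))
  platform <- panels[[1]]$platform
  if (!all(vapply(panels, `[[`, character(1), "platform") == platform))
    stop("standardize_and_merge: panels must share a platform")
  std <- lapply(panels, function(P) {
    V <- P$values
    sds <- apply(V, 2, stats::sd)
    zero <- sds == 0 | is.na(sds)
    if (any(zero)) {
      warning("standardize_and_merge: dropping ", sum(zero),
              " zero-variance feature(s)")
      P <- subset_features(P, !zero)
      V <- P$values
      sds <- sds[!zero]
    }
    if (drop_sex_chromosomes && !is.null(P$chromosome)) {
      sex <- P$chromosome %in% c("X", "Y", "chrX", "chrY")
      if (any(sex)) P <- subset_features(P, !sex)
      V <- P$values
    }
    P$values <- scale(V)[, , drop = FALSE]
    attr(P$values, "scaled:center") <- NULL
    attr(P$values, "scaled:scale") <- NULL
    P
  })
  common <- Reduce(intersect, lapply(std, `[[`, "feature_ids"))
  if (length(common) == 0L)
    stop("standardize_and_merge: no common features across panels")
  mats <- lapply(std, function(P) P$values[, common, drop = FALSE])
  merged <- do.call(rbind, mats)
  sample_ids <- unlist(lapply(std, `[[`, "sample_ids"))
  if (anyDuplicated(sample_ids))
    stop("standardize_and_merge: duplicate sample ids across panels")
  chrom <- std[[1]]$chromosome
  chrom <- if (is.null(chrom)) NULL else
    chrom[match(common, std[[1]]$feature_ids)]
  genomic_matrix(merged, platform, sample_ids, common, chrom)
}

#' Retain the most variable features
#'
#' Keeps the `k` features with the largest variability (standard deviation
#' by default, MAD optionally); ties are broken deterministically by
#' feature-id order of appearance.
#'
#' @param M a `genomic_matrix`.
#' @param k number of features to retain (default 1000).
#' @param measure `"sd"` (default) or `"mad"`.
#' @return `genomic_matrix` with at most `k` features, in original feature
#'   order.
#' @export
top_variable_features <- function(M, k = 1000L, measure = c("sd", "mad")) {
  stopifnot(inherits(M, "genomic_matrix"), k >= 1L)
  measure <- match.arg(measure)
  v <- switch(measure,
              sd = apply(M$values, 2, stats::sd),
              mad = apply(M$values, 2, stats::mad, constant = 1))
  if (k >= length(v)) return(M)
  ord <- order(-v, seq_along(v))   # stable: feature order breaks ties
  keep <- sort(ord[seq_len(k)])
  subset_features(M, keep)
}
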