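# Methylation-to-expression linkage: library-size normalization by
# median-of-ratios, the two-fold tumor/normal filter, TPM from scaled
# estimates, and methylation--expression correlation.

#' Median-of-ratios size factors
#'
#' The standard RNA-seq library-size estimator: per sample, the median over
#' genes (restricted to genes with non-zero counts in every sample) of the
#' ratio of the gene's count to its across-sample geometric mean. The median
#' is taken on the log scale (exponentiated median of log-ratios), matching
#' the reference implementation; for an odd number of retained genes this is
#' identical to the plain ratio median, for an even number the two middle
#' ratios interpolate geometrically instead of arithmetically. The factors
#' are relative depths: multiplying every library by the same constant
#' leaves them unchanged.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param pseudocount Added to every count before the ratio; 0 (default)
#'   reproduces the plain estimator, a positive value rescues matrices where
#'   no gene is expressed everywhere.
#' @return Positive numeric vector of per-sample size factors.
#' @export
median_of_ratios_size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  expressed <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed))
    stop("no gene with non-zero counts in all samples; ",
         "consider pseudocount > 0")
  logc <- log(counts[expressed, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(median(x - loggeo)))
}

#' Select genes upregulated beyond a fold threshold in tumors
#'
#' Counts are first divided by their [median_of_ratios_size_factors()]; a
#' gene is selected when the tumor group mean strictly exceeds `min_fold`
#' times the normal group mean ("more than `min_fold` times"). A zero normal
#' mean with a positive tumor mean counts as an infinite ratio (selected,
#' with a message); an all-zero gene is not selected.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Character vector per sample, `"normal"` / `"tumor"`.
#' @param min_fold Fold-change threshold (default 2, strict).
#' @param size_factors Optional precomputed size factors.
#' @return Character vector of selected gene ids.
#' @export
fold_change_filter <- function(counts, groups, min_fold = 2.0,
                               size_factors = NULL) {
  stopifnot(all(groups %in% c("normal", "tumor")), min_fold > 0)
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  mt <- rowMeans(norm[, groups == "tumor", drop = FALSE])
  mn <- rowMeans(norm[, groups == "normal", drop = FALSE])
  ratio <- mt / mn  # Inf when mn == 0, mt > 0; NaN when both 0
  inf_sel <- is.infinite(ratio)
  if (any(inf_sel))
    message(sum(inf_sel), " gene(s) unexpressed in normals selected with ",
            "infinite ratio")
  rownames(counts)[!is.nan(ratio) & ratio > min_fold]
}

#' Transcripts per million from RNA-seq scaled estimates
#'
#' @param se Scaled-estimate values in `[0, 1]` (per-sample fractions).
#' @return `se * 1e6`.
#' @export
tpm_from_scaled_estimate <- function(se) {
  if (any(se < 0 | se > 1, na.rm = TRUE))
    stop("scaled estimates must lie in [0, 1]")
  se * 1e6
}

#' Correlate CGI methylation with matched gene expression
#'
#' Samples are matched by name; pairs with a missing value in either vector
#' are dropped listwise. Spearman uses midranks for ties. With fewer than 3
#' complete pairs, or zero variance in either vector, the coefficients are
#' `NA` and the result is flagged undefined.
#'
#' @param beta Named numeric vector of per-sample CGI beta values.
#' @param expr Named numeric vector of per-sample expression.
#' @return Tibble `pearson_r`, `spearman_rho`, `n`, `defined`.
#' @export
methylation_expression_correlation <- function(beta, expr) {
  if (is.null(names(beta)) || is.null(names(expr)))
    stop("beta and expr must be named by sample id")
  shared <- intersect(names(beta), names(expr))
  x <- beta[shared]
  y <- expr[shared]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(pearson_r = NA_real_, spearman_rho = NA_real_,
                  n = n, defined = FALSE))
  }
  tibble(pearson_r = stats::cor(x, y, method = "pearson"),
         spearman_rho = stats::cor(x, y, method = "spearman"),
         n = n, defined = TRUE)
}
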