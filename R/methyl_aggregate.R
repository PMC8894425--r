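# CGI-level aggregation of site/probe beta values and the array-style
# prescreen that shortlists candidate CGIs before targeted sequencing.

#' Construct a CGI-by-sample beta matrix
#'
#' @param values Numeric matrix, CGIs in rows and samples in columns; entries
#'   in `[0, 1]` or `NA` (missing).
#' @param samples Sample sheet tibble with columns `sample_id`, `tissue`
#'   (`"normal"`/`"tumor"`), `patient` (pairing key). At most one normal and
#'   one tumor sample per patient.
#' @return The matrix with the sample sheet attached, class `beta_matrix`.
#' @export
beta_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values needs CGI rownames")
  stopifnot(all(c("sample_id", "tissue", "patient") %in% names(samples)))
  if (!identical(colnames(values), samples$sample_id))
    stop("column names must equal samples$sample_id, in order")
  if (!all(samples$tissue %in% c("normal", "tumor")))
    stop("tissue must be 'normal' or 'tumor'")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta values must lie in [0, 1]")
  if (any(table(samples$patient, samples$tissue) > 1))
    stop("at most one normal and one tumor sample per patient")
  structure(values, samples = as_tibble(samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("beta_matrix: %d CGIs x %d samples (%d normal, %d tumor), %.1f%% missing\n",
              nrow(x), ncol(x), sum(s$tissue == "normal"),
              sum(s$tissue == "tumor"), 100 * mean(is.na(x))))
  invisible(x)
}

bm_samples <- function(bm) attr(bm, "samples")

#' Aggregate per-CpG beta values to CGI level
#'
#' For each (CGI, sample), the CGI beta is the unweighted arithmetic mean of
#' the beta values of sites inside the CGI that (i) lie on the CGI's analysis
#' strand, (ii) have read depth at least `min_cov`, and (iii) have a defined
#' beta. The value is missing unless the number of such covered sites is
#' strictly greater than `min_site_fraction` times the CGI's total CpG-site
#' count (the low-quality filter: data present in more than a third of sites
#' by default). The total site count comes from `ref_sites` if supplied, else
#' from the union of site positions observed in any sample within the CGI.
#' Duplicated input records (same sample/position) are deduplicated.
#'
#' @param sites Per-CpG record tibble (see [read_cpg_coverage()]).
#' @param cgis CGI interval tibble; its `strand` column is the analysis
#'   strand per CGI (`"."` accepts both strands, the array-probe case).
#' @param samples Sample sheet (see [beta_matrix()]).
#' @param min_cov Minimum read depth per site; 0 waives the filter (array
#'   probes carry no counts).
#' @param min_site_fraction Completeness threshold as a fraction of the CGI's
#'   total sites; strict inequality.
#' @param ref_sites Optional tibble `chrom`, `pos` of reference CpG sites
#'   used as the per-CGI completeness denominator.
#' @return A [beta_matrix()].
#' @export
aggregate_to_cgi <- function(sites, cgis, samples,
                             min_cov = 10, min_site_fraction = 1 / 3,
                             ref_sites = NULL) {
  stopifnot(min_cov >= 0, min_site_fraction >= 0, min_site_fraction <= 1)
  if (is.null(cgis$name) || anyNA(cgis$name))
    cgis$name <- format_region(cgis)
  sites <- distinct(sites, .data$sample_id, .data$chrom, .data$pos,
                    .keep_all = TRUE)

  assign_cgi <- function(chrom, pos) {
    idx <- rep(NA_integer_, length(pos))
    for (g in seq_len(nrow(cgis))) {
      hit <- chrom == cgis$chrom[g] & pos >= cgis$start[g] & pos < cgis$end[g]
      idx[hit & is.na(idx)] <- g
    }
    idx
  }

  ref <- if (is.null(ref_sites)) {
    distinct(sites, .data$chrom, .data$pos)
  } else {
    distinct(as_tibble(ref_sites), .data$chrom, .data$pos)
  }
  ref_idx <- assign_cgi(ref$chrom, ref$pos)
  total_sites <- tabulate(ref_idx, nbins = nrow(cgis))
  for (g in which(total_sites == 0))
    warning("CGI '", cgis$name[g], "' contains no CpG sites in the reference ",
            "site list; its values are missing", call. = FALSE)

  sites$cgi_idx <- assign_cgi(sites$chrom, sites$pos)
  keep_strand <- cgis$strand[sites$cgi_idx] == "." |
    sites$strand == cgis$strand[sites$cgi_idx]
  depth <- sites$meth_count + sites$unmeth_count
  usable <- !is.na(sites$cgi_idx) & keep_strand & depth >= min_cov &
    !is.na(sites$beta)

  vals <- matrix(NA_real_, nrow(cgis), nrow(samples),
                 dimnames = list(cgis$name, samples$sample_id))
  use <- sites[usable, ]
  if (nrow(use)) {
    key_s <- match(use$sample_id, samples$sample_id)
    grp <- interaction(use$cgi_idx, key_s, drop = TRUE)
    mean_by <- tapply(use$beta, grp, mean)
    cnt_by <- tapply(use$beta, grp, length)
    ids <- strsplit(names(mean_by), ".", fixed = TRUE)
    gi <- as.integer(vapply(ids, `[`, "", 1L))
    si <- as.integer(vapply(ids, `[`, "", 2L))
    ok <- cnt_by > min_site_fraction * total_sites[gi] & total_sites[gi] > 0
    vals[cbind(gi[ok], si[ok])] <- mean_by[ok]
  }
  beta_matrix(vals, samples)
}

#' Array-style prescreen of candidate CGIs
#'
#' Implements the microarray shortlisting rule: per CGI, average the beta
#' values of all normal samples; a tumor sample is discordant when its value
#' differs from that normal mean by at least `d_min` (in either direction);
#' the CGI is selected when discordant tumors exceed fraction `f_min` of the
#' tumor samples with data (strictly more). CGIs with no normal-sample data
#' are excluded.
#'
#' @param bm A [beta_matrix()].
#' @param d_min Minimum absolute beta difference (default 0.20, inclusive).
#' @param f_min Minimum discordant-patient fraction (default 0.20, strict).
#' @return Character vector of selected CGI ids.
#' @export
prescreen_array <- function(bm, d_min = 0.20, f_min = 0.20) {
  stopifnot(inherits(bm, "beta_matrix"),
            d_min > 0, d_min <= 1, f_min > 0, f_min <= 1)
  s <- bm_samples(bm)
  if (!any(s$tissue == "normal") || !any(s$tissue == "tumor"))
    stop("need at least one normal and one tumor sample")
  nv <- unclass(bm)[, s$tissue == "normal", drop = FALSE]
  tv <- unclass(bm)[, s$tissue == "tumor", drop = FALSE]
  nmean <- rowMeans(nv, na.rm = TRUE)
  sel <- character(0)
  for (g in seq_len(nrow(bm))) {
    if (!is.finite(nmean[g])) next  # no normal data: excluded
    tg <- tv[g, ]
    tg <- tg[!is.na(tg)]
    if (!length(tg)) next
    frac <- sum(abs(tg - nmean[g]) >= d_min) / length(tg)
    if (frac > f_min) sel <- c(sel, rownames(bm)[g])
  }
  sel
}
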