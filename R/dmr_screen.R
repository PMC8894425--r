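# Four-criterion cohort screen on CGI-level betas from targeted bisulfite
# sequencing: a paired-difference prevalence rule, low/high methylation bands
# on the cohort means, and a mean-difference rule, yielding the candidate DMR
# table.

#' Screening thresholds for the cohort DMR screen
#'
#' Defaults implement the published decision rule: a per-patient paired beta
#' difference above 0.30 in at least half of the patients, a healthy-tissue
#' cohort mean below 30%, a tumor cohort mean of 50% or more (bands swapped
#' for hypomethylation), a cohort mean difference above 30%, and a minimum
#' per-site read depth of 10.
#'
#' @param paired_diff_min Per-patient absolute difference threshold
#'   (fraction scale, strict `>`).
#' @param paired_fraction_min Minimum fraction of evaluable patients
#'   exceeding it (inclusive `>=`).
#' @param low_band_max Upper bound (fraction) on the lower cohort mean
#'   (strict `<`).
#' @param high_band_min Lower bound (fraction) on the higher cohort mean
#'   (inclusive `>=`).
#' @param mean_diff_min Minimum cohort mean difference (fraction, strict `>`).
#' @param min_cov Minimum read depth per CpG site.
#' @return Named list of class `screen_params`.
#' @export
screen_params <- function(paired_diff_min = 0.30,
                          paired_fraction_min = 0.50,
                          low_band_max = 0.30,
                          high_band_min = 0.50,
                          mean_diff_min = 0.30,
                          min_cov = 10) {
  p <- as.list(environment())
  stopifnot(p$paired_diff_min > 0, p$paired_diff_min < 1,
            p$paired_fraction_min > 0, p$paired_fraction_min <= 1,
            p$low_band_max > 0, p$high_band_min < 1,
            p$low_band_max < p$high_band_min,
            p$mean_diff_min > 0, p$mean_diff_min < 1,
            p$min_cov >= 1)
  structure(p, class = "screen_params")
}

#' Fraction of patients whose paired tumor/normal difference exceeds a delta
#'
#' The denominator counts patients with a non-missing normal and tumor value
#' for the CGI; the numerator those whose absolute tumor-minus-normal
#' difference strictly exceeds `delta`.
#'
#' @param bm A [beta_matrix()] with pairing keys.
#' @param cgi CGI id (rowname of `bm`).
#' @param delta Difference threshold on the fraction scale.
#' @return A list with `numerator`, `denominator`, `fraction` (`NA` when no
#'   patient is evaluable).
#' @export
paired_diff_fraction <- function(bm, cgi, delta = 0.30) {
  stopifnot(inherits(bm, "beta_matrix"), delta > 0, delta < 1)
  if (!cgi %in% rownames(bm)) stop("unknown CGI id: ", cgi)
  s <- bm_samples(bm)
  v <- unclass(bm)[cgi, ]
  norm <- v[s$tissue == "normal"]
  tum <- v[s$tissue == "tumor"]
  names(norm) <- s$patient[s$tissue == "normal"]
  names(tum) <- s$patient[s$tissue == "tumor"]
  shared <- intersect(names(norm), names(tum))
  d <- tum[shared] - norm[shared]
  d <- d[!is.na(d)]
  list(numerator = sum(abs(d) > delta),
       denominator = length(d),
       fraction = if (length(d)) sum(abs(d) > delta) / length(d) else NA_real_)
}

#' Classify a CGI as hyper-, hypomethylated, or neither
#'
#' Band rules on the cohort means (percent scale): hypermethylated when the
#' healthy mean is below `100 * low_band_max`, the tumor mean at least
#' `100 * high_band_min`, the difference above `100 * mean_diff_min`, and the
#' paired-difference patient fraction at least `paired_fraction_min`;
#' hypomethylated with the bands swapped; otherwise none. The two band rules
#' are mutually exclusive by construction.
#'
#' @param mcom Mean control (healthy) methylation, percent scale 0-100.
#' @param mcam Mean case (tumor) methylation, percent scale 0-100.
#' @param frac Paired-difference patient fraction in `[0, 1]`.
#' @param params A [screen_params()] object.
#' @return `"hyper"`, `"hypo"`, or `"none"` (vectorized).
#' @export
classify_dmr <- function(mcom, mcam, frac, params = screen_params()) {
  if (any(mcom < 0 | mcom > 100 | mcam < 0 | mcam > 100, na.rm = TRUE))
    stop("mcom/mcam must be on the percent scale 0-100")
  lo <- 100 * params$low_band_max
  hi <- 100 * params$high_band_min
  dmin <- 100 * params$mean_diff_min
  ok_frac <- !is.na(frac) & frac >= params$paired_fraction_min
  hyper <- ok_frac & mcom < lo & mcam >= hi & (mcam - mcom) > dmin
  hypo <- ok_frac & mcam < lo & mcom >= hi & (mcom - mcam) > dmin
  ifelse(hyper, "hyper", ifelse(hypo, "hypo", "none"))
}

#' Run the full cohort DMR screen
#'
#' Aggregates per-CpG records to CGI level (depth filter and completeness
#' rule from [aggregate_to_cgi()]), computes for every CGI the
#' paired-difference patient fraction and the cohort means over all normal
#' and all tumor samples (unpaired samples included in the means), applies
#' [classify_dmr()], and returns one record per CGI passing all criteria,
#' sorted by patient fraction then absolute mean difference, both descending,
#' then coordinate.
#'
#' @param sites Per-CpG record tibble across samples.
#' @param cgis CGI interval tibble.
#' @param samples Sample sheet (see [beta_matrix()]).
#' @param params A [screen_params()] object.
#' @param min_site_fraction Completeness threshold passed to
#'   [aggregate_to_cgi()].
#' @param gene Optional named character vector mapping CGI id to gene id.
#' @return Tibble of DMR records: `cgi`, `region`, `gene`, `numerator`,
#'   `denominator`, `frac_patients`, `mcom`, `mcam`, `diff` (percent scale),
#'   `call`.
#' @export
screen_cohort <- function(sites, cgis, samples, params = screen_params(),
                          min_site_fraction = 1 / 3, gene = NULL) {
  bm <- aggregate_to_cgi(sites, cgis, samples,
                         min_cov = params$min_cov,
                         min_site_fraction = min_site_fraction)
  dmr_table(bm, params, gene = gene, cgis = cgis)
}

#' Build the DMR table from an aggregated beta matrix
#'
#' The screening core of [screen_cohort()], reusable when CGI-level betas are
#' already in hand (array data, external aggregation).
#'
#' @inheritParams screen_cohort
#' @param bm A [beta_matrix()].
#' @return See [screen_cohort()].
#' @export
dmr_table <- function(bm, params = screen_params(), gene = NULL, cgis = NULL) {
  s <- bm_samples(bm)
  vals <- unclass(bm)
  rows <- lapply(rownames(bm), function(id) {
    pdf <- paired_diff_fraction(bm, id, params$paired_diff_min)
    mcom <- mean(vals[id, s$tissue == "normal"], na.rm = TRUE) * 100
    mcam <- mean(vals[id, s$tissue == "tumor"], na.rm = TRUE) * 100
    if (!is.finite(mcom) || !is.finite(mcam) || !pdf$denominator) return(NULL)
    tibble(cgi = id,
           numerator = pdf$numerator, denominator = pdf$denominator,
           frac_patients = pdf$fraction,
           mcom = mcom, mcam = mcam, diff = mcam - mcom,
           call = classify_dmr(mcom, mcam, pdf$fraction, params))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(cgi = character(), region = character(), gene = character(),
                  numerator = integer(), denominator = integer(),
                  frac_patients = double(), mcom = double(), mcam = double(),
                  diff = double(), call = character()))
  }
  out <- out[out$call != "none", , drop = FALSE]
  out$gene <- if (is.null(gene)) NA_character_ else unname(gene[out$cgi])
  out$region <- if (!is.null(cgis)) {
    format_region(cgis)[match(out$cgi, cgis$name)]
  } else NA_character_
  out <- out[order(-out$frac_patients, -abs(out$diff), out$region, out$cgi), ]
  out[, c("cgi", "region", "gene", "numerator", "denominator",
          "frac_patients", "mcom", "mcam", "diff", "call")]
}
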