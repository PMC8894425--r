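# Relative methylation quantification from qMSP quantification cycles: the
# methylated (or half-methylated) primer signal divided by the unmethylated
# primer signal, and tumor-over-normal relative levels.

#' Methylation level from paired Cq values
#'
#' Under the exponential amplification model the template quantity behind a
#' quantification cycle is `(1 + E)^(-Cq)`; the methylation level is the
#' methylated-primer quantity divided by the unmethylated-primer quantity,
#' i.e. `(1 + E)^(Cq_unmet - Cq_met)`. A missing ("nd", supplied as `NA`)
#' methylated Cq gives level 0 (no methylated template detected); a missing
#' unmethylated Cq with a methylated signal present gives `Inf`; both
#' missing gives `NA` with a warning.
#'
#' @param cq_met,cq_unmet Quantification cycles (positive) or `NA` for no
#'   amplification; vectorized.
#' @param efficiency Amplification efficiency in `(0, 1]`; 1 doubles the
#'   product every cycle.
#' @return Numeric vector of levels in `[0, Inf]`.
#' @export
methylation_level <- function(cq_met, cq_unmet, efficiency = 1.0) {
  stopifnot(efficiency > 0, efficiency <= 1)
  if (any(c(cq_met, cq_unmet) <= 0, na.rm = TRUE))
    stop("Cq values must be positive")
  level <- (1 + efficiency)^(cq_unmet - cq_met)
  level[is.na(cq_met) & !is.na(cq_unmet)] <- 0
  level[!is.na(cq_met) & is.na(cq_unmet)] <- Inf
  undef <- is.na(cq_met) & is.na(cq_unmet)
  if (any(undef)) {
    warning(sum(undef), " call(s) with no amplification by either primer")
    level[undef] <- NA_real_
  }
  level
}

#' Tumor-over-normal relative methylation level
#'
#' @param level_tumor,level_normal Methylation levels (see
#'   [methylation_level()]); vectorized.
#' @return `level_tumor / level_normal`, `Inf` (flagged, not an error) when
#'   the normal level is 0.
#' @export
relative_level <- function(level_tumor, level_normal) {
  if (any(level_normal < 0 | level_tumor < 0, na.rm = TRUE))
    stop("levels must be non-negative")
  out <- ifelse(level_normal == 0 & level_tumor > 0, Inf,
                level_tumor / level_normal)
  if (any(is.infinite(out), na.rm = TRUE))
    message(sum(is.infinite(out), na.rm = TRUE),
            " relative level(s) flagged infinite (unmethylated normal)")
  out
}

#' Summarise a replicate qMSP well table into methylation calls
#'
#' Replicate wells are averaged on the Cq scale (the conventional treatment;
#' set `average = "quantity"` to average `(1+E)^(-Cq)` instead); wells with
#' no amplification are recorded as `NA` Cq and excluded from the replicate
#' mean, and a target whose wells all failed for a primer variant gets the
#' "nd" semantics of [methylation_level()].
#'
#' @param wells Tibble with columns `sample_id`, `target`, `variant`
#'   (`"met"`, `"half"`, `"unmet"`), `cq` (positive or `NA`), and optionally
#'   `replicate`.
#' @param efficiency Amplification efficiency.
#' @param numerator `"met"` (default) or `"half"`: which primer signal forms
#'   the numerator.
#' @param average `"cq"` or `"quantity"`.
#' @return Tibble `sample_id`, `target`, `level`.
#' @export
qmsp_calls <- function(wells, efficiency = 1.0,
                       numerator = c("met", "half"),
                       average = c("cq", "quantity")) {
  numerator <- match.arg(numerator)
  average <- match.arg(average)
  stopifnot(all(c("sample_id", "target", "variant", "cq") %in% names(wells)))
  if (!all(wells$variant %in% c("met", "half", "unmet")))
    stop("variant must be 'met', 'half' or 'unmet'")
  agg <- wells %>%
    group_by(.data$sample_id, .data$target, .data$variant) %>%
    summarise(cq = if (all(is.na(.data$cq))) NA_real_ else if (average == "cq")
      mean(.data$cq, na.rm = TRUE) else
        -log((mean((1 + efficiency)^(-.data$cq), na.rm = TRUE)),
             base = 1 + efficiency),
      .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "variant", values_from = "cq")
  for (v in c("met", "half", "unmet"))
    if (!v %in% names(agg)) agg[[v]] <- NA_real_
  tibble(sample_id = agg$sample_id, target = agg$target,
         level = methylation_level(agg[[numerator]], agg$unmet, efficiency))
}
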