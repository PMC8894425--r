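# Accessors for the published cohort summary tables bundled with the
# package. These transcriptions of printed results serve as screening
# inputs and regression fixtures: the DMR summary carries the per-CGI cohort
# statistics (patient fraction, mean control and case methylation on the
# percent scale), and the clinical table carries the subgroup contingency
# counts.

#' Published colorectal DMR cohort summary
#'
#' The 40 candidate CpG islands from the 90-patient paired targeted
#' bisulfite sequencing cohort, with genomic context, adjacent gene,
#' paired-difference patient fraction (numerator/denominator), mean control
#' methylation (`mcom`), mean case methylation (`mcam`) and their difference,
#' all on the percent scale.
#'
#' @return A tibble with one row per CGI.
#' @export
published_dmr_summary <- function() {
  path <- system.file("extdata", "crc_dmr_summary.csv", package = "methmark",
                      mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   na.strings = "NA")
  as_tibble(df)
}

#' Published subgroup clinical contingency counts
#'
#' Per-covariate category counts of the two methylation-defined patient
#' subgroups (hypermethylated group 1, n = 25; group 2, n = 61;
#' per-covariate denominators differ where clinical data are missing).
#'
#' @param parameter Optional covariate name; when given, returns the counts
#'   as a category x subgroup matrix ready for [chi_square_test()].
#' @return A tibble (all parameters) or a count matrix (one parameter).
#' @export
published_subgroup_clinical <- function(parameter = NULL) {
  path <- system.file("extdata", "crc_subgroup_clinical.csv",
                      package = "methmark", mustWork = TRUE)
  df <- as_tibble(read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE))
  if (is.null(parameter)) return(df)
  sub <- df[df$parameter == parameter, , drop = FALSE]
  if (!nrow(sub)) stop("unknown parameter: ", parameter)
  m <- as.matrix(sub[, c("group1", "group2")])
  rownames(m) <- sub$category
  m
}
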