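#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange bind_rows case_when distinct filter group_by
#'   left_join mutate n pull rename select summarise ungroup
#' @importFrom rlang .data
#' @importFrom stats median na.omit rbinom rbeta rexp rnbinom rnorm rpois
#'   runif setNames
#' @importFrom utils read.table write.table
NULL

# -- genomic intervals -------------------------------------------------------
#
# All internal coordinates are 0-based half-open (BED convention).  Printed
# region strings such as "chr13:28498226-28499046" are 1-based inclusive and
# converted at the boundary by parse_region()/format_region().

#' Construct a validated table of genomic intervals
#'
#' Intervals are 0-based half-open throughout the package. `strand` may be
#' `"+"`, `"-"` or `"."` (unstranded).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, 0-based exclusive ends; must exceed `start`.
#' @param strand Strand per interval, recycled; one of `"+"`, `"-"`, `"."`.
#' @param name Optional interval identifiers.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".", name = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end))) stop("start/end must be integral")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start")
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  tibble(
    chrom = chrom, start = start, end = end, strand = strand,
    name = rep_len(as.character(name), length(chrom))
  )
}

#' Parse printed region strings into 0-based half-open intervals
#'
#' Region strings like `"chr13:28498226-28499046"` (1-based, inclusive, as
#' printed in publications and genome browsers) become 0-based half-open
#' intervals. En dashes and embedded commas are tolerated.
#'
#' @param x Character vector of `chrom:start-end` strings.
#' @return An interval tibble (see [genomic_interval()]).
#' @seealso [format_region()] for the inverse.
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x)  # en dash as printed in tables
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region string: ", x[bad][1])
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(vapply(m, `[`, "", 3L))
  e1 <- as.numeric(vapply(m, `[`, "", 4L))
  genomic_interval(chrom, s1 - 1, e1, name = x)
}

#' Format 0-based half-open intervals as printed 1-based region strings
#'
#' @param intervals An interval tibble.
#' @return Character vector of `chrom:start-end` strings (1-based inclusive).
#' @export
format_region <- function(intervals) {
  sprintf("%s:%d-%d", intervals$chrom, intervals$start + 1L, intervals$end)
}

#' Convert an interval tibble to a `GRanges`
#'
#' @param intervals An interval tibble (0-based half-open).
#' @return A [GenomicRanges::GRanges] (1-based inclusive, as GRanges requires).
#' @export
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = ifelse(intervals$strand == ".", "*", intervals$strand)
  )
}

# -- per-CpG coverage tables -------------------------------------------------

#' Read a per-CpG methylation coverage table
#'
#' Reads a Bismark-coverage-like TSV with columns chromosome, position
#' (1-based), strand, methylated read count, unmethylated read count.
#' Positions are converted to 0-based. The beta value is
#' `meth / (meth + unmeth)`; sites with zero total coverage keep their counts
#' but get a missing (`NA`) beta — they are never dropped, so downstream
#' completeness filters see true missingness.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `sample_id`, `meth_count`, `unmeth_count`, `beta`.
#' @export
read_cpg_coverage <- function(path, sample_id = basename(path)) {
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c("character", "numeric", "character",
                              "numeric", "numeric"),
               col.names = c("chrom", "pos", "strand", "meth_count",
                             "unmeth_count")),
    error = function(e) stop("malformed coverage file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- which(is.na(df$pos) | is.na(df$meth_count) | is.na(df$unmeth_count) |
                 !df$strand %in% c("+", "-", "."))
  if (length(bad)) stop("malformed line ", bad[1], " in '", path, "'")
  neg <- which(df$meth_count < 0 | df$unmeth_count < 0)
  if (length(neg)) stop("negative count at line ", neg[1], " in '", path, "'")
  cpg_records(df$chrom, df$pos - 1, df$strand, sample_id,
              df$meth_count, df$unmeth_count)
}

#' Build per-CpG records from vectors
#'
#' @param chrom,pos,strand Site coordinates (`pos` 0-based).
#' @param sample_id Sample identifier(s), recycled.
#' @param meth_count,unmeth_count Non-negative read counts.
#' @return A per-CpG record tibble; see [read_cpg_coverage()].
#' @export
cpg_records <- function(chrom, pos, strand, sample_id, meth_count, unmeth_count) {
  if (any(meth_count < 0) || any(unmeth_count < 0)) stop("negative counts")
  total <- meth_count + unmeth_count
  tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    strand = rep_len(as.character(strand), length(chrom)),
    sample_id = rep_len(as.character(sample_id), length(chrom)),
    meth_count = as.integer(meth_count),
    unmeth_count = as.integer(unmeth_count),
    beta = ifelse(total > 0, meth_count / total, NA_real_)
  )
}

#' Write per-CpG records back to the coverage TSV dialect
#'
#' Inverse of [read_cpg_coverage()]: positions are written 1-based.
#'
#' @param records A per-CpG record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_coverage <- function(records, path) {
  out <- data.frame(records$chrom, records$pos + 1L, records$strand,
                    records$meth_count, records$unmeth_count)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- BED-like interval files -------------------------------------------------

#' Read CGI or gene intervals from a BED-like file
#'
#' BED is 0-based half-open, matching internal coordinates, so no conversion
#' happens. For `kind = "cgi"` columns are chrom, start, end and optionally
#' name; strand defaults to `"+"` (the analysis strand) unless a 6th column is
#' present. For `kind = "gene"` the 4th column is the gene id and the 6th the
#' gene strand (required). Input order is preserved; overlapping intervals are
#' retained unmerged.
#'
#' @param path Path to the BED file.
#' @param kind `"cgi"` or `"gene"`.
#' @return An interval tibble; for genes with column `gene_id`.
#' @export
read_intervals <- function(path, kind = c("cgi", "gene")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- genomic_interval("chr0", 0, 1)[0, ]
    if (kind == "gene") out$gene_id <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1], " in '", path, "'")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  if (any(is.na(start) | is.na(end)))
    stop("non-numeric coordinates in '", path, "'")
  if (any(end <= start))
    stop("end <= start at line ", which(end <= start)[1], " in '", path, "'")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4], ""), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[6], ""), "+")
  if (!all(strand %in% c("+", "-", ".")))
    stop("unknown strand symbol in '", path, "'")
  out <- genomic_interval(chrom, start, end, strand = strand, name = name)
  if (kind == "gene") {
    if (any(is.na(name))) stop("gene BED requires a gene id in column 4")
    if (any(!strand %in% c("+", "-"))) stop("gene BED requires strand + or -")
    out$gene_id <- out$name
  }
  out
}

#' Export CGI intervals as a BED file of capture targets
#'
#' @param cgis An interval tibble of CGIs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_target_bed <- function(cgis, path) {
  if (!nrow(cgis)) stop("no intervals to export")
  out <- data.frame(cgis$chrom, cgis$start, cgis$end,
                    ifelse(is.na(cgis$name), ".", cgis$name),
                    0L, cgis$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- run configuration -------------------------------------------------------

#' Default run configuration
#'
#' One flat list of every tunable threshold in the pipeline, with defaults
#' equal to the screening rules the pipeline implements, so any stage can be
#' re-run with perturbed thresholds.
#'
#' @return Named list of thresholds plus `seed`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    # array prescreen
    prescreen_d_min = 0.20, prescreen_f_min = 0.20,
    # cohort screen
    min_cov = 10, min_site_fraction = 1 / 3,
    paired_diff_min = 0.30, paired_fraction_min = 0.50,
    low_band_max = 0.30, high_band_min = 0.50, mean_diff_min = 0.30,
    # context annotation
    promoter_up = 1500, promoter_down = 500,
    # expression
    min_fold = 2.0,
    # primer design
    pair_cpg_min = 6, tm_min = 55, tm_max = 60,
    amplicon_min = 100, amplicon_max = 160,
    primer_len_min = 18, primer_len_max = 30,
    # qMSP
    efficiency = 1.0
  )
}

#' Read a `key=value` run-configuration file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A full configuration list (see [default_run_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric config value for ", key)
    cfg[[key]] <- val
  }
  validate_run_config(cfg)
}

#' Write a configuration list as `key=value` lines
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, "", digits = 15)), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  frac_keys <- c("prescreen_d_min", "prescreen_f_min", "min_site_fraction",
                 "paired_diff_min", "paired_fraction_min", "low_band_max",
                 "high_band_min", "mean_diff_min")
  for (k in frac_keys)
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop(k, " must lie in [0, 1]")
  if (cfg$low_band_max >= cfg$high_band_min)
    stop("low_band_max must be below high_band_min")
  if (cfg$min_cov < 0) stop("min_cov must be >= 0")
  if (cfg$tm_min >= cfg$tm_max) stop("tm_min must be below tm_max")
  if (cfg$amplicon_min >= cfg$amplicon_max)
    stop("amplicon_min must be below amplicon_max")
  if (cfg$efficiency <= 0 || cfg$efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  cfg
}

# stage timing to stderr; used by the command-line wrapper
log_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  message(sprintf("[%s] %.2fs", stage, proc.time()[["elapsed"]] - t0))
  res
}
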