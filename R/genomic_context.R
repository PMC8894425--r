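# Promoter / intragenic / intergenic classification of CGIs against gene
# models, with the adjacent gene attached.

#' Annotate CGIs with genomic context relative to gene models
#'
#' A CGI overlapping any strand-aware promoter window (`promoter_up` bp
#' upstream to `promoter_down` bp downstream of the TSS; the TSS of a `-`
#' gene is its body end) is `promoter`; otherwise a CGI overlapping any gene
#' body is `intragenic`; otherwise `intergenic` with no gene. Promoter beats
#' intragenic when both overlap. Among multiple candidate genes of the same
#' context the largest overlap wins, ties going to the smaller gene start, so
#' the result does not depend on gene input order.
#'
#' @param cgis CGI interval tibble.
#' @param genes Gene interval tibble with `gene_id` and strand `+`/`-`
#'   (TSS-to-TES body).
#' @param promoter_up,promoter_down Promoter window in bp upstream /
#'   downstream of the TSS (defaults 1500 / 500).
#' @return Tibble `cgi`, `region`, `context`, `gene` (`NA` iff intergenic).
#' @export
annotate_cgi <- function(cgis, genes, promoter_up = 1500, promoter_down = 500) {
  stopifnot(promoter_up >= 0, promoter_down >= 0)
  if (is.null(cgis$name) || anyNA(cgis$name)) cgis$name <- format_region(cgis)

  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom_start <- ifelse(genes$strand == "+", tss - promoter_up,
                       tss - promoter_down + 1L)
  prom_end <- ifelse(genes$strand == "+", tss + promoter_down,
                     tss + promoter_up + 1L)
  prom_start <- pmax(0L, as.integer(prom_start))
  prom_end <- pmax(prom_start + 1L, as.integer(prom_end))

  best_hit <- function(cs, ce, cchrom, fs, fe, fchrom) {
    # largest-overlap gene among features overlapping [cs, ce)
    ov <- pmin(ce, fe) - pmax(cs, fs)
    ov[fchrom != cchrom] <- 0L
    hit <- which(ov > 0)
    if (!length(hit)) return(NA_integer_)
    hit <- hit[order(-ov[hit], genes$start[hit])]
    hit[1]
  }

  res <- lapply(seq_len(nrow(cgis)), function(i) {
    cs <- cgis$start[i]; ce <- cgis$end[i]; cc <- cgis$chrom[i]
    p <- best_hit(cs, ce, cc, prom_start, prom_end, genes$chrom)
    if (!is.na(p)) {
      return(tibble(context = "promoter", gene = genes$gene_id[p]))
    }
    b <- best_hit(cs, ce, cc, genes$start, genes$end, genes$chrom)
    if (!is.na(b)) {
      return(tibble(context = "intragenic", gene = genes$gene_id[b]))
    }
    tibble(context = "intergenic", gene = NA_character_)
  })
  out <- bind_rows(res)
  tibble(cgi = cgis$name, region = format_region(cgis),
         context = out$context, gene = out$gene)
}

#' Count CGIs per genomic context
#'
#' @param calls Tibble with a `context` column (and optionally a `call`
#'   column from the DMR screen).
#' @param subset `"all"`, `"hyper"`, or `"hypo"`; non-`"all"` values filter
#'   on `calls$call`.
#' @return Named integer vector `promoter`, `intragenic`, `intergenic`.
#' @export
context_counts <- function(calls, subset = c("all", "hyper", "hypo")) {
  subset <- match.arg(subset)
  if (subset != "all") {
    if (is.null(calls$call)) stop("subsetting needs a 'call' column")
    calls <- calls[calls$call == subset, , drop = FALSE]
  }
  lv <- c("promoter", "intragenic", "intergenic")
  out <- table(factor(calls$context, levels = lv))
  setNames(as.integer(out), lv)
}
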