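# qMSP primer design: strand-aware in-silico bisulfite conversion,
# nearest-neighbor melting temperature, exhaustive constraint-based
# enumeration of primer pairs on the converted top strand, and generation of
# the Met / Unmet / Half-Met primer variants.

#' Primer-design constraints
#'
#' Defaults encode the design rule used for the colorectal qMSP markers: the
#' two primers carry at least six CpG sites in total, each primer's melting
#' temperature falls in 55-60 degrees C, and the amplicon is 100-160 bp.
#' Primer length bounds (18-30 nt) are standard practice.
#'
#' @param pair_cpg_min Minimum total CpG sites across both primers.
#' @param tm_min,tm_max Melting-temperature window per primer, degrees C.
#' @param amplicon_min,amplicon_max Amplicon length window, bp.
#' @param primer_len_min,primer_len_max Primer length bounds, nt.
#' @return Named list of class `design_constraints`.
#' @export
design_constraints <- function(pair_cpg_min = 6, tm_min = 55, tm_max = 60,
                               amplicon_min = 100, amplicon_max = 160,
                               primer_len_min = 18, primer_len_max = 30) {
  p <- as.list(environment())
  stopifnot(p$tm_min < p$tm_max, p$amplicon_min < p$amplicon_max,
            p$primer_len_min >= 15, p$primer_len_min <= p$primer_len_max,
            p$pair_cpg_min >= 0)
  structure(p, class = "design_constraints")
}

#' In-silico bisulfite conversion of the analysis (top) strand
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
#' while methylated CpG cytosine resists conversion. Modes:
#' `"unmethylated"` converts every C to T; `"methylated"` converts every C
#' except one immediately followed by G; `"half"` retains/converts CpG
#' cytosines alternately, starting with "retained" at the 5'-most CpG
#' (configurable via `half_selector`), and converts every non-CpG C. Length
#' and non-C characters are preserved exactly. A trailing C (no following
#' base) is treated as non-CpG.
#'
#' @param seq A single DNA string over `A`, `C`, `G`, `T`.
#' @param mode `"methylated"`, `"unmethylated"`, or `"half"`.
#' @param half_selector For `mode = "half"`: logical vector (recycled over
#'   the CpG cytosines in 5'-to-3' order) saying which CpG cytosines remain
#'   methylated. Default alternates starting with `TRUE`.
#' @return The converted sequence.
#' @export
bisulfite_convert <- function(seq, mode = c("methylated", "unmethylated", "half"),
                              half_selector = c(TRUE, FALSE)) {
  mode <- match.arg(mode)
  b <- strsplit(toupper(seq), "")[[1]]
  if (length(b) && !all(b %in% c("A", "C", "G", "T")))
    stop("sequence contains non-ACGT characters")
  is_c <- b == "C"
  cpg_c <- is_c & c(b[-1] == "G", FALSE)
  convert <- switch(mode,
    unmethylated = is_c,
    methylated = is_c & !cpg_c,
    half = {
      keep <- rep(FALSE, length(b))
      idx <- which(cpg_c)
      keep[idx] <- rep_len(half_selector, length(idx))
      is_c & !keep
    })
  b[convert] <- "T"
  paste(b, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `A`, `C`, `G`, `T`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Count CpG sites falling inside a primer footprint
#'
#' A CpG site is counted when its cytosine (the CG start coordinate) lies
#' inside the half-open footprint — including a C at the last base whose G
#' falls outside.
#'
#' @param start,end Footprint, 0-based half-open.
#' @param cpg_pos Integer vector of CG start coordinates (0-based) on the
#'   analysis strand.
#' @return Integer count.
#' @export
count_cpg_sites <- function(start, end, cpg_pos) {
  sum(cpg_pos >= start & cpg_pos < end)
}

# nearest-neighbor parameters: unified oligonucleotide dH (kcal/mol) / dS
# (cal/mol K) of Allawi & SantaLucia (1997), with terminal A.T / G.C
# initiation terms and the symmetry correction
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
            GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
            TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
            GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set
#' (Allawi & SantaLucia 1997): stacking enthalpies/entropies summed over
#' dinucleotides, terminal A.T (dH 2.3, dS 4.1) and G.C (dH 0.1, dS -2.8)
#' initiation terms, a symmetry correction (dS -1.4) for self-complementary
#' oligos, monovalent-salt correction on the entropy
#' (`0.368 (N-1) ln[Na+]`), and `Tm = 1000 dH / (dS + R ln CT) - 273.15`
#' with `CT` the excess single-strand concentration (the full oligo
#' concentration for a self-complementary primer, half otherwise is not
#' needed since the template is in excess during PCR; the conventional
#' `CT = c_oligo` for symmetric, `c_oligo` as supplied otherwise).
#'
#' @param seq DNA string (length >= 8), no ambiguity codes.
#' @param na_mM Monovalent cation concentration, mM (default 50).
#' @param oligo_nM Oligo concentration, nM (default 500).
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 500) {
  seq <- toupper(seq)
  b <- strsplit(seq, "")[[1]]
  if (length(b) < 8) stop("sequence too short for the two-state model")
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("sequence contains ambiguity codes")
  din <- paste0(b[-length(b)], b[-1])
  dh <- sum(.nn_dh[din])
  ds <- sum(.nn_ds[din])
  for (term in b[c(1, length(b))]) {
    if (term %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  selfcomp <- identical(b, rev(chartr("ACGT", "TGCA", b)))
  k <- oligo_nM * 1e-9
  if (selfcomp) ds <- ds - 1.4 else k <- k / 2
  ds <- ds + 0.368 * (length(b) - 1) * log(na_mM / 1000)
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

# vectorized window Tm over substrings of one strand, via cumulative
# nearest-neighbor sums; numerically identical to melting_temperature() on
# each substring (self-complementary windows get the symmetry terms after a
# cheap terminal-base prefilter)
window_tms <- function(strand, starts0, lens, na_mM = 50, oligo_nM = 500) {
  b <- strsplit(strand, "")[[1]]
  n <- length(b)
  din <- paste0(b[-n], b[-1])
  cumH <- c(0, cumsum(.nn_dh[din]))
  cumS <- c(0, cumsum(.nn_ds[din]))
  a <- starts0 + 1L          # 1-based window start
  e <- starts0 + lens        # 1-based window end
  dh <- cumH[e] - cumH[a]
  ds <- cumS[e] - cumS[a]
  term <- function(base) ifelse(base %in% c("A", "T"), 1, 0)
  at_ends <- term(b[a]) + term(b[e])
  dh <- dh + 2.3 * at_ends + 0.1 * (2 - at_ends)
  ds <- ds + 4.1 * at_ends - 2.8 * (2 - at_ends)
  comp <- chartr("ACGT", "TGCA", strand)
  maybe_pal <- lens %% 2 == 0 &
    b[a] == substring(comp, e, e) &
    b[a + 1L] == substring(comp, e - 1L, e - 1L)
  selfcomp <- rep(FALSE, length(a))
  for (i in which(maybe_pal)) {
    s <- substring(strand, a[i], e[i])
    selfcomp[i] <- identical(s, reverse_complement(s))
  }
  k <- rep(oligo_nM * 1e-9 / 2, length(a))
  ds[selfcomp] <- ds[selfcomp] - 1.4
  k[selfcomp] <- oligo_nM * 1e-9
  ds <- ds + 0.368 * (lens - 1) * log(na_mM / 1000)
  1000 * dh / (ds + 1.987 * log(k)) - 273.15
}

#' Exhaustively enumerate qMSP primer pairs on a converted region
#'
#' Scans every forward and reverse primer placement (all starts and lengths
#' within the constraint bounds) on the bisulfite-converted top strand. The
#' primer sequence used for filtering is the fully methylated variant (CpG
#' cytosines retained); the reverse primer is the reverse complement of the
#' converted top-strand footprint, whose duplex — and therefore melting
#' temperature — is that of the footprint itself. A pair is retained when
#' both primer lengths, both melting temperatures, the amplicon length, and
#' the total CpG count satisfy `constraints`. Pairs are ranked by
#' discriminative score — the mean planted/observed tumor-normal beta
#' difference over the CpGs covered by the two primers — descending, ties by
#' smaller forward/reverse Tm difference, amplicon length closest to 120 bp,
#' then leftmost forward start.
#'
#' @param region List with `seq` (top-strand DNA), `cpg_pos` (0-based CG
#'   starts), and optionally `cpg_diff` (named by position; defaults to 0).
#' @param constraints A [design_constraints()] object.
#' @return Tibble of ranked pairs with footprints, met-variant sequences,
#'   CpG counts, Tm values, amplicon length and score; zero rows when no
#'   placement is feasible.
#' @export
enumerate_primer_pairs <- function(region, constraints = design_constraints()) {
  cn <- constraints
  n <- nchar(region$seq)
  if (n < cn$amplicon_min)
    stop("region shorter than the minimum amplicon")
  cpg_pos <- as.integer(region$cpg_pos)
  cpg_diff <- region$cpg_diff
  if (is.null(cpg_diff)) cpg_diff <- setNames(rep(0, length(cpg_pos)),
                                              as.character(cpg_pos))
  conv <- bisulfite_convert(region$seq, "methylated")

  # all windows, shared between the forward and reverse roles
  wins <- do.call(rbind, lapply(cn$primer_len_min:cn$primer_len_max,
    function(L) {
      if (n < L) return(NULL)
      data.frame(start = 0:(n - L), len = L)
    }))
  if (is.null(wins)) return(empty_pair_table())
  wins$end <- wins$start + wins$len
  wins$seq_met <- substring(conv, wins$start + 1, wins$end)
  wins$cpg <- vapply(seq_len(nrow(wins)), function(i)
    count_cpg_sites(wins$start[i], wins$end[i], cpg_pos), 0L)
  wins$tm <- window_tms(conv, wins$start, wins$len)
  wins <- wins[wins$tm >= cn$tm_min & wins$tm <= cn$tm_max, , drop = FALSE]
  if (!nrow(wins)) return(empty_pair_table())
  wins$rc <- .revcomp_many(wins$seq_met)

  # per-window sum of planted differences via prefix sums over the ordered
  # CpG positions; footprints of a valid pair are disjoint, so the
  # union-mean score is (sum_f + sum_r) / (count_f + count_r)
  ord <- order(cpg_pos)
  pos_sorted <- cpg_pos[ord]
  cum_diff <- c(0, cumsum(unname(cpg_diff[as.character(pos_sorted)])))
  win_sum <- cum_diff[findInterval(wins$end - 0.5, pos_sorted) + 1] -
    cum_diff[findInterval(wins$start - 0.5, pos_sorted) + 1]

  fidx <- vector("list", nrow(wins))
  ridx <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    fs <- wins$start[i]; fe <- wins$end[i]
    j <- which(wins$end >= fs + cn$amplicon_min &
                 wins$end <= fs + cn$amplicon_max &
                 wins$start >= fe &
                 wins$cpg + wins$cpg[i] >= cn$pair_cpg_min)
    fidx[[i]] <- rep.int(i, length(j))
    ridx[[i]] <- j
  }
  f <- unlist(fidx); r <- unlist(ridx)
  if (!length(f)) return(empty_pair_table())
  tot_cpg <- wins$cpg[f] + wins$cpg[r]
  out <- tibble(
    fwd_start = wins$start[f], fwd_end = wins$end[f],
    fwd_seq = wins$seq_met[f], fwd_cpg_count = wins$cpg[f],
    tm_met_f = wins$tm[f],
    rev_start = wins$start[r], rev_end = wins$end[r],
    rev_seq = wins$rc[r], rev_cpg_count = wins$cpg[r],
    tm_met_r = wins$tm[r],
    amplicon_len = wins$end[r] - wins$start[f],
    score = ifelse(tot_cpg > 0, (win_sum[f] + win_sum[r]) / tot_cpg,
                   NA_real_)
  )
  out <- out[order(-out$score, abs(out$tm_met_f - out$tm_met_r),
                   abs(out$amplicon_len - 120), out$fwd_start,
                   out$rev_start), ]
  out
}

# bulk reverse complement of plain character windows (hot path; equivalent
# to reverse_complement() element-wise)
.revcomp_many <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(b) paste(rev(b), collapse = ""), "", USE.NAMES = FALSE)
}

empty_pair_table <- function() {
  tibble(fwd_start = integer(), fwd_end = integer(), fwd_seq = character(),
         fwd_cpg_count = integer(), tm_met_f = double(),
         rev_start = integer(), rev_end = integer(), rev_seq = character(),
         rev_cpg_count = integer(), tm_met_r = double(),
         amplicon_len = integer(), score = double())
}

#' Generate the Met / Unmet / Half-Met sequence variants of a primer pair
#'
#' Forward variants apply the bisulfite-conversion modes to the genomic
#' footprint with CpG context taken from the full region sequence (a
#' footprint-terminal C whose G lies just outside the footprint is still a
#' CpG cytosine); reverse variants are reverse complements of the converted
#' footprint. Half-methylation alternates over the CpG cytosines within each
#' primer's footprint, 5'-most (top strand) retained first. A CpG-free
#' primer has identical Met and Unmet sequences and is flagged.
#'
#' @param pair One row of the [enumerate_primer_pairs()] table (or any list
#'   with `fwd_start`, `fwd_end`, `rev_start`, `rev_end`).
#' @param region The design region (list with `seq`).
#' @param half_selector Logical pattern recycled over each footprint's CpG
#'   cytosines; `TRUE` = retained (methylated).
#' @return The pair as a one-row tibble with columns
#'   `{fwd,rev}_{met,unmet,half}` and `degenerate_fwd` / `degenerate_rev`
#'   flags.
#' @export
make_variants <- function(pair, region, half_selector = c(TRUE, FALSE)) {
  conv <- function(start, end, mode)
    convert_footprint(region$seq, start, end, mode, half_selector)
  fwd <- vapply(c(met = "methylated", unmet = "unmethylated", half = "half"),
                function(m) conv(pair$fwd_start, pair$fwd_end, m), "")
  rev_ <- vapply(c(met = "methylated", unmet = "unmethylated", half = "half"),
                 function(m)
                   reverse_complement(conv(pair$rev_start, pair$rev_end, m)),
                 "")
  tibble(
    fwd_met = fwd[["met"]], fwd_unmet = fwd[["unmet"]], fwd_half = fwd[["half"]],
    rev_met = rev_[["met"]], rev_unmet = rev_[["unmet"]],
    rev_half = rev_[["half"]],
    degenerate_fwd = fwd[["met"]] == fwd[["unmet"]],
    degenerate_rev = rev_[["met"]] == rev_[["unmet"]]
  )
}

# convert a genomic footprint with CpG context from the full sequence
convert_footprint <- function(seq_full, start, end, mode, half_selector) {
  b <- strsplit(toupper(seq_full), "")[[1]]
  is_c <- b == "C"
  cpg_c <- is_c & c(b[-1] == "G", FALSE)
  idx <- (start + 1L):end
  bw <- b[idx]
  cw <- is_c[idx]
  gw <- cpg_c[idx]
  convert <- switch(mode,
    unmethylated = cw,
    methylated = cw & !gw,
    half = {
      keep <- rep(FALSE, length(bw))
      keep[which(gw)] <- rep_len(half_selector, sum(gw))
      cw & !keep
    })
  bw[convert] <- "T"
  paste(bw, collapse = "")
}
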