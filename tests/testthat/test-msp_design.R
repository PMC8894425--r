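test_that("bisulfite conversion modes follow the chemistry", {
  s <- "ACGTACCGTTCAC"
  # CpG Cs at 0-based 1 and 6; plain Cs at 5, 10, 12
  expect_equal(bisulfite_convert(s, "unmethylated"), "ATGTATTGTTTAT")
  expect_equal(bisulfite_convert(s, "methylated"), "ACGTATCGTTTAT")
  # half: first CpG retained, second converted
  expect_equal(bisulfite_convert(s, "half"), "ACGTATTGTTTAT")
  expect_equal(bisulfite_convert(s, "half", half_selector = c(FALSE, TRUE)),
               "ATGTATCGTTTAT")
  # trailing C is non-CpG
  expect_equal(bisulfite_convert("AAC", "methylated"), "AAT")
  expect_error(bisulfite_convert("ACGN", "methylated"), "non-ACGT")
})

test_that("conversion invariants hold on random sequences", {
  set.seed(303)
  for (i in 1:200) {
    s <- random_dna(sample(20:80, 1))
    for (mode in c("methylated", "unmethylated", "half")) {
      out <- bisulfite_convert(s, mode)
      expect_equal(nchar(out), nchar(s))
      # non-C characters untouched
      keep <- strsplit(s, "")[[1]] != "C"
      expect_identical(strsplit(out, "")[[1]][keep],
                       strsplit(s, "")[[1]][keep])
    }
    expect_false(grepl("C", bisulfite_convert(s, "unmethylated"), fixed = TRUE))
    # methylated mode retains exactly the CpG cytosines
    met <- strsplit(bisulfite_convert(s, "methylated"), "")[[1]]
    sb <- strsplit(s, "")[[1]]
    cpg <- sb == "C" & c(sb[-1] == "G", FALSE)
    expect_identical(which(met == "C"), which(cpg))
  }
})

test_that("the nearest-neighbor Tm matches an external reference value", {
  # reference computed with an independent implementation of the unified
  # Allawi & SantaLucia table at Na+ 50 mM, 500 nM oligo
  expect_equal(melting_temperature("AGCGTAGCTAGCTAGCTAGC"),
               57.197184099005824, tolerance = 1e-6)
  expect_error(melting_temperature("ACGTACG"), "too short")
  expect_error(melting_temperature("ACGTACGW"), "ambiguity")
})

test_that("Tm responds to composition, salt and symmetry as expected", {
  at <- melting_temperature("ATATATATATATATATATAT")
  gc <- melting_temperature("GCGCGGCCGGCCGGCGCGCG")
  expect_gt(gc, at)
  lo <- melting_temperature("AGCGTAGCTAGCTAGCTAGC", na_mM = 20)
  hi <- melting_temperature("AGCGTAGCTAGCTAGCTAGC", na_mM = 200)
  expect_gt(hi, lo)
  # a self-complementary oligo takes the symmetry branch and still returns
  # a finite, sane value
  pal <- "ACGTACGTACGTACGT"
  expect_identical(pal, reverse_complement(pal))
  expect_true(is.finite(melting_temperature(pal)))
})

test_that("CpG counting uses the half-open footprint on the C base", {
  cpg <- c(5L, 10L, 19L)
  expect_equal(count_cpg_sites(0, 20, cpg), 3)
  expect_equal(count_cpg_sites(5, 10, cpg), 1)   # C at 5 in, C at 10 out
  expect_equal(count_cpg_sites(19, 20, cpg), 1)  # terminal C, G outside
  expect_equal(count_cpg_sites(6, 10, cpg), 0)
})

test_that("pair enumeration equals the brute-force oracle", {
  cons <- design_constraints(pair_cpg_min = 2, tm_min = 52, tm_max = 62,
                             amplicon_min = 80, amplicon_max = 140)
  for (seed in c(401, 402, 403)) {
    reg <- simulate_region_sequence(180, 12, seed = seed)
    got <- enumerate_primer_pairs(reg, cons)
    want <- oracle_primer_pairs(reg, cons)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
      next
    }
    key <- function(d) sort(paste(d$fwd_start, d$fwd_end,
                                  d$rev_start, d$rev_end))
    expect_identical(key(got), key(want))
    m <- match(paste(got$fwd_start, got$fwd_end, got$rev_start, got$rev_end),
               paste(want$fwd_start, want$fwd_end, want$rev_start,
                     want$rev_end))
    expect_equal(got$tm_met_f, want$tm_f[m], tolerance = 1e-9)
    expect_equal(got$tm_met_r, want$tm_r[m], tolerance = 1e-9)
    expect_equal(got$score, want$score[m], tolerance = 1e-12)
  }
})

test_that("every emitted pair satisfies every constraint", {
  cons <- design_constraints(pair_cpg_min = 3, tm_min = 50, tm_max = 65,
                             amplicon_min = 90, amplicon_max = 160)
  reg <- simulate_region_sequence(300, 22, seed = 404)
  got <- enumerate_primer_pairs(reg, cons)
  expect_gt(nrow(got), 0)
  len_f <- got$fwd_end - got$fwd_start
  len_r <- got$rev_end - got$rev_start
  expect_true(all(len_f >= cons$primer_len_min & len_f <= cons$primer_len_max))
  expect_true(all(len_r >= cons$primer_len_min & len_r <= cons$primer_len_max))
  expect_true(all(got$tm_met_f >= cons$tm_min & got$tm_met_f <= cons$tm_max))
  expect_true(all(got$tm_met_r >= cons$tm_min & got$tm_met_r <= cons$tm_max))
  expect_true(all(got$amplicon_len >= cons$amplicon_min &
                    got$amplicon_len <= cons$amplicon_max))
  expect_true(all(got$fwd_cpg_count + got$rev_cpg_count >= cons$pair_cpg_min))
  expect_true(all(got$rev_start >= got$fwd_end))
  # ranked by score, best first
  expect_true(all(diff(got$score) <= 1e-12))
  # sequences are substrings of the converted strand (rev complemented)
  conv <- bisulfite_convert(reg$seq, "methylated")
  i <- 1
  expect_equal(got$fwd_seq[i],
               substr(conv, got$fwd_start[i] + 1, got$fwd_end[i]))
  expect_equal(got$rev_seq[i],
               reverse_complement(substr(conv, got$rev_start[i] + 1,
                                         got$rev_end[i])))
})

test_that("too-short regions and infeasible constraints are handled", {
  reg <- simulate_region_sequence(60, 4, seed = 405)
  expect_error(enumerate_primer_pairs(reg), "shorter")
  impossible <- design_constraints(pair_cpg_min = 50, tm_min = 50, tm_max = 65,
                                   amplicon_min = 80, amplicon_max = 160)
  reg2 <- simulate_region_sequence(200, 6, seed = 406)
  expect_equal(nrow(enumerate_primer_pairs(reg2, impossible)), 0)
})

test_that("variant generation is consistent with the enumerated sequences", {
  cons <- design_constraints(pair_cpg_min = 3, tm_min = 50, tm_max = 65,
                             amplicon_min = 90, amplicon_max = 160)
  reg <- simulate_region_sequence(260, 18, seed = 407)
  got <- enumerate_primer_pairs(reg, cons)
  expect_gt(nrow(got), 0)
  v <- make_variants(got[1, ], reg)
  expect_equal(v$fwd_met, got$fwd_seq[1])
  expect_equal(v$rev_met, got$rev_seq[1])
  # unmet variants contain no C on the converted-forward / G on the reverse
  expect_false(grepl("C", v$fwd_unmet, fixed = TRUE))
  expect_false(grepl("G", v$rev_unmet, fixed = TRUE))
  # half differs from both ends when the footprint has >= 2 CpGs
  if (got$fwd_cpg_count[1] >= 2) {
    expect_false(v$fwd_half == v$fwd_met)
    expect_false(v$fwd_half == v$fwd_unmet)
  }
  expect_false(v$degenerate_fwd)
})

test_that("a CpG-free footprint yields identical Met and Unmet variants", {
  reg <- list(seq = paste0("ATTAGATTGA", strrep("AT", 60), "CGTTAGGATA"),
              cpg_pos = 120L)
  pair <- list(fwd_start = 0L, fwd_end = 20L, rev_start = 100L, rev_end = 120L)
  v <- make_variants(pair, reg)
  expect_true(v$degenerate_fwd)
  expect_equal(v$fwd_met, v$fwd_unmet)
})

test_that("footprint conversion honors CpG context outside the footprint", {
  # C at footprint end whose G lies just outside is still a CpG cytosine
  reg <- list(seq = "AATTAATTACGAATT")  # C at 0-based 9, G at 10
  pair <- list(fwd_start = 0L, fwd_end = 10L, rev_start = 10L, rev_end = 15L)
  v <- make_variants(pair, reg)
  expect_equal(substr(v$fwd_met, 10, 10), "C")   # retained: CpG context
  expect_equal(substr(v$fwd_unmet, 10, 10), "T")
})
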