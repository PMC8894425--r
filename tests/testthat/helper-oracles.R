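# Independent brute-force oracles used across the suite.  Each recomputes a
# quantity from its definition, deliberately avoiding the code paths of the
# implementation it checks.

# sample sheet for a small paired cohort
make_samples <- function(n_pairs, n_unpaired_normal = 0, n_unpaired_tumor = 0) {
  tibble::tibble(
    sample_id = c(sprintf("P%02d_N", seq_len(n_pairs)),
                  sprintf("P%02d_T", seq_len(n_pairs)),
                  if (n_unpaired_normal) sprintf("UN%02d", seq_len(n_unpaired_normal)),
                  if (n_unpaired_tumor) sprintf("UT%02d", seq_len(n_unpaired_tumor))),
    tissue = c(rep("normal", n_pairs), rep("tumor", n_pairs),
               rep("normal", n_unpaired_normal), rep("tumor", n_unpaired_tumor)),
    patient = c(sprintf("P%02d", seq_len(n_pairs)),
                sprintf("P%02d", seq_len(n_pairs)),
                if (n_unpaired_normal) sprintf("UN%02d", seq_len(n_unpaired_normal)),
                if (n_unpaired_tumor) sprintf("UT%02d", seq_len(n_unpaired_tumor)))
  )
}

# exhaustive prescreen by the written rule, scalar loops only
oracle_prescreen <- function(values, samples, d_min, f_min) {
  sel <- character(0)
  for (g in rownames(values)) {
    nvals <- c()
    for (j in seq_len(ncol(values)))
      if (samples$tissue[j] == "normal" && !is.na(values[g, j]))
        nvals <- c(nvals, values[g, j])
    if (!length(nvals)) next
    nmean <- sum(nvals) / length(nvals)
    hits <- 0; tot <- 0
    for (j in seq_len(ncol(values))) {
      if (samples$tissue[j] != "tumor" || is.na(values[g, j])) next
      tot <- tot + 1
      if (abs(values[g, j] - nmean) >= d_min) hits <- hits + 1
    }
    if (tot > 0 && hits / tot > f_min) sel <- c(sel, g)
  }
  sel
}

# Pearson chi-square from the definition
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# product-moment and midrank correlation from the summation formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  oracle_pearson(midrank(x), midrank(y))
}

# log-rank: hypergeometric tally at each distinct event time
oracle_logrank <- function(time, event, group) {
  lev <- sort(unique(group))
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- U^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# median-of-ratios from the formula, no vectorized shortcuts
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[keep, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  out <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    out[j] <- median(counts[keep, j] / geo)
  out
}

# brute-force primer-pair enumeration: every index pair, every constraint
# evaluated from scratch via the public single-sequence primitives
oracle_primer_pairs <- function(region, cons) {
  conv <- bisulfite_convert(region$seq, "methylated")
  n <- nchar(conv)
  wins <- list()
  for (L in cons$primer_len_min:cons$primer_len_max) {
    if (n < L) next
    for (s in 0:(n - L)) {
      sq <- substr(conv, s + 1, s + L)
      tm <- melting_temperature(sq)
      if (tm < cons$tm_min || tm > cons$tm_max) next
      wins[[length(wins) + 1]] <- list(
        s = s, e = s + L, seq = sq, tm = tm,
        cpg = sum(region$cpg_pos >= s & region$cpg_pos < s + L))
    }
  }
  if (!length(wins)) return(NULL)
  w <- data.frame(s = sapply(wins, `[[`, "s"), e = sapply(wins, `[[`, "e"),
                  tm = sapply(wins, `[[`, "tm"),
                  cpg = sapply(wins, `[[`, "cpg"))
  ij <- expand.grid(f = seq_len(nrow(w)), r = seq_len(nrow(w)))
  amp <- w$e[ij$r] - w$s[ij$f]
  keep <- amp >= cons$amplicon_min & amp <= cons$amplicon_max &
    w$s[ij$r] >= w$e[ij$f] &
    w$cpg[ij$f] + w$cpg[ij$r] >= cons$pair_cpg_min
  ij <- ij[keep, , drop = FALSE]
  if (!nrow(ij)) return(NULL)
  score <- mapply(function(fi, ri) {
    inside <- (region$cpg_pos >= w$s[fi] & region$cpg_pos < w$e[fi]) |
      (region$cpg_pos >= w$s[ri] & region$cpg_pos < w$e[ri])
    if (any(inside))
      mean(region$cpg_diff[as.character(region$cpg_pos[inside])])
    else NA_real_
  }, ij$f, ij$r)
  data.frame(
    fwd_start = w$s[ij$f], fwd_end = w$e[ij$f],
    rev_start = w$s[ij$r], rev_end = w$e[ij$r],
    amplicon_len = w$e[ij$r] - w$s[ij$f], score = score,
    tm_f = w$tm[ij$f], tm_r = w$tm[ij$r],
    cpg_total = w$cpg[ij$f] + w$cpg[ij$r])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
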