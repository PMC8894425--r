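# Synthetic cohort generator.  Every downstream stage of the pipeline is
# exercised on data produced here, with planted ground truth: labelled
# hyper-/hypomethylated CGIs, methylation-linked expression fold changes, and
# survival times with a known group hazard ratio.

#' Simulation parameters for the synthetic cohort
#'
#' Defaults emulate the targeted-bisulfite study design this pipeline serves:
#' 90 paired tumor/normal patients plus 2 unpaired normals and 12 unpaired
#' tumors, mean read depth 30x, hypermethylation effects that move a CGI from
#' a lowly methylated normal baseline (~0.10) past the screening bands.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(params, seed)`.
#' @param n_cgis Number of simulated CGIs.
#' @param frac_hyper,frac_hypo Fractions of CGIs planted as hyper-/hypo-
#'   methylated in tumors; the rest are null.
#' @param sites_per_cgi Length-2 integer range of CpG sites per CGI.
#' @param normal_center_hyper Normal-tissue mean beta of a planted hyper CGI.
#' @param normal_center_hypo Normal-tissue mean beta of a planted hypo CGI.
#' @param null_center_range Range the normal-tissue mean of a null CGI is
#'   drawn from (tumor center equals it).
#' @param effect Planted mean beta difference (tumor minus normal for hyper;
#'   normal minus tumor for hypo).
#' @param concentration Beta-distribution concentration of per-site beta
#'   values around the CGI-level center (larger = tighter).
#' @param mean_depth Mean per-site read depth (Poisson); sites drawing depth
#'   0 are dropped, creating genuine missingness.
#' @param n_pairs Paired patients; `unpaired_normals`, `unpaired_tumors`
#'   additional single-tissue samples.
#' @param expr_baseline,expr_dispersion Negative-binomial mean and dispersion
#'   of gene expression counts in normal tissue.
#' @param expr_fold Tumor/normal expression fold change of genes linked to
#'   planted hyper CGIs.
#' @param baseline_hazard Exponential event rate for the reference survival
#'   group.
#' @param hazard_ratio Hazard multiplier applied to group 1.
#' @param censoring_rate Target fraction of censored observations.
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_cgis = 50L,
                       frac_hyper = 0.2,
                       frac_hypo = 0.1,
                       sites_per_cgi = c(20L, 80L),
                       normal_center_hyper = 0.10,
                       normal_center_hypo = 0.70,
                       null_center_range = c(0.05, 0.95),
                       effect = 0.45,
                       concentration = 5,
                       mean_depth = 30,
                       n_pairs = 90L,
                       unpaired_normals = 2L,
                       unpaired_tumors = 12L,
                       expr_baseline = 200,
                       expr_dispersion = 0.2,
                       expr_fold = 4,
                       baseline_hazard = 0.02,
                       hazard_ratio = 4,
                       censoring_rate = 0.3) {
  p <- as.list(environment())
  stopifnot(p$n_cgis >= 1, p$n_pairs >= 1,
            p$concentration > 0, p$mean_depth > 0,
            p$expr_dispersion > 0, p$hazard_ratio > 0,
            p$censoring_rate >= 0, p$censoring_rate < 1)
  structure(p, class = "sim_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a paired tumor/normal methylation cohort
#'
#' Per CGI a tissue-level target beta is fixed (normal baseline, tumor =
#' baseline +/- planted effect); per site and sample, a beta value is drawn
#' from a Beta distribution centred on that target with the stated
#' concentration, read depth is Poisson around `mean_depth`, and methylated
#' read counts are Binomial(depth, beta). Sites drawing depth zero are
#' dropped, so the completeness filter downstream is exercised by genuine
#' missingness. Deterministic given the seed in `params`.
#'
#' @param params A [sim_params()] object.
#' @return A list with `sites` (per-CpG record tibble across all samples),
#'   `cgis` (interval tibble), `samples` (sample sheet: `sample_id`,
#'   `tissue`, `patient`), and `truth` (per-CGI label and effect).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  n_hyper <- round(p$n_cgis * p$frac_hyper)
  n_hypo <- round(p$n_cgis * p$frac_hypo)
  labels <- rep(c("hyper", "hypo", "null"),
                c(n_hyper, n_hypo, p$n_cgis - n_hyper - n_hypo))

  n_sites <- sample(p$sites_per_cgi[1]:p$sites_per_cgi[2], p$n_cgis,
                    replace = TRUE)
  # lay CGIs along one synthetic chromosome, 10 bp between CpGs, 1 kb gaps
  widths <- n_sites * 10L
  starts <- cumsum(c(1000L, widths[-p$n_cgis] + 1000L))
  cgis <- genomic_interval("chrS", starts, starts + widths, strand = "+",
                           name = sprintf("CGI_%03d", seq_len(p$n_cgis)))

  normal_center <- numeric(p$n_cgis)
  tumor_center <- numeric(p$n_cgis)
  for (g in seq_len(p$n_cgis)) {
    normal_center[g] <- switch(labels[g],
      hyper = p$normal_center_hyper,
      hypo = p$normal_center_hypo,
      null = runif(1, p$null_center_range[1], p$null_center_range[2]))
    tumor_center[g] <- switch(labels[g],
      hyper = normal_center[g] + p$effect,
      hypo = normal_center[g] - p$effect,
      null = normal_center[g])
  }
  eps <- 1e-3
  if (any(tumor_center <= 0 | tumor_center >= 1))
    stop("planted effect pushes a tumor center outside (0, 1)")
  normal_center <- pmin(pmax(normal_center, eps), 1 - eps)
  tumor_center <- pmin(pmax(tumor_center, eps), 1 - eps)

  samples <- tibble(
    sample_id = c(sprintf("P%03d_N", seq_len(p$n_pairs)),
                  sprintf("P%03d_T", seq_len(p$n_pairs)),
                  sprintf("UN%02d_N", seq_len(p$unpaired_normals)),
                  sprintf("UT%02d_T", seq_len(p$unpaired_tumors))),
    tissue = c(rep("normal", p$n_pairs), rep("tumor", p$n_pairs),
               rep("normal", p$unpaired_normals),
               rep("tumor", p$unpaired_tumors)),
    patient = c(sprintf("P%03d", seq_len(p$n_pairs)),
                sprintf("P%03d", seq_len(p$n_pairs)),
                sprintf("UN%02d", seq_len(p$unpaired_normals)),
                sprintf("UT%02d", seq_len(p$unpaired_tumors)))
  )

  site_pos <- lapply(seq_len(p$n_cgis), function(g) {
    cgis$start[g] + 10L * (seq_len(n_sites[g]) - 1L)
  })
  all_pos <- unlist(site_pos)
  cgi_of_site <- rep(seq_len(p$n_cgis), n_sites)
  n_total_sites <- length(all_pos)

  per_sample <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    center <- if (samples$tissue[s] == "normal") normal_center else tumor_center
    mu <- center[cgi_of_site]
    beta <- rbeta(n_total_sites, mu * p$concentration,
                  (1 - mu) * p$concentration)
    depth <- rpois(n_total_sites, p$mean_depth)
    keep <- depth > 0
    meth <- rbinom(sum(keep), depth[keep], beta[keep])
    per_sample[[s]] <- cpg_records(
      chrom = "chrS", pos = all_pos[keep], strand = "+",
      sample_id = samples$sample_id[s],
      meth_count = meth, unmeth_count = depth[keep] - meth
    )
  }

  list(
    sites = bind_rows(per_sample),
    cgis = cgis,
    samples = samples,
    truth = tibble(
      cgi = cgis$name, label = labels,
      normal_center = normal_center, tumor_center = tumor_center,
      effect = ifelse(labels == "null", 0, p$effect),
      n_sites = n_sites
    )
  )
}

#' Simulate expression counts linked to planted methylation effects
#'
#' One gene is linked to each non-null CGI; genes linked to hyper CGIs have
#' tumor mean expression `expr_fold` times the normal mean, genes linked to
#' hypo CGIs the reciprocal, null genes are unchanged. Counts are negative
#' binomial; scaled estimates are per-sample count fractions (summing to 1).
#'
#' @param truth The `truth` tibble from [simulate_cohort()].
#' @param params A [sim_params()] object.
#' @param n_tumor,n_normal Samples per group (default `n_pairs`).
#' @return A list with `counts` (gene x sample integer matrix),
#'   `scaled_estimates` (same shape, columns summing to 1), `groups`
#'   (tissue label per sample), and `gene_truth`.
#' @export
simulate_expression <- function(truth, params,
                                n_tumor = params$n_pairs,
                                n_normal = params$n_pairs) {
  stopifnot(inherits(params, "sim_params"))
  if (params$expr_dispersion <= 0) stop("dispersion must be positive")
  with_seed(params$seed + 1L, {
    genes <- paste0("GENE_", truth$cgi)
    fold <- ifelse(truth$label == "hyper", params$expr_fold,
                   ifelse(truth$label == "hypo", 1 / params$expr_fold, 1))
    mu_normal <- rep(params$expr_baseline, length(genes))
    mu_tumor <- mu_normal * fold
    size <- 1 / params$expr_dispersion
    draw <- function(mu, n) {
      matrix(rnbinom(length(mu) * n, mu = rep(mu, n), size = size),
             nrow = length(mu))
    }
    counts <- cbind(draw(mu_normal, n_normal), draw(mu_tumor, n_tumor))
    rownames(counts) <- genes
    colnames(counts) <- c(sprintf("N%03d", seq_len(n_normal)),
                          sprintf("T%03d", seq_len(n_tumor)))
    se <- sweep(counts, 2, colSums(counts), "/")
    list(
      counts = counts, scaled_estimates = se,
      groups = c(rep("normal", n_normal), rep("tumor", n_tumor)),
      gene_truth = tibble(gene = genes, cgi = truth$cgi,
                          label = truth$label, fold = fold)
    )
  })
}

#' Simulate survival with a planted group hazard ratio
#'
#' Event times are exponential with rate `baseline_hazard` (group 0) or
#' `baseline_hazard * hazard_ratio` (group 1). Censoring times are uniform on
#' `(0, m)` with `m` solved so the expected censored fraction matches
#' `censoring_rate`; rate 0 observes every event.
#'
#' @param groups Vector of group labels (two distinct values; the higher-risk
#'   group is the one sorting last, conventionally `1`).
#' @param params A [sim_params()] object.
#' @param seed Optional seed override (defaults to `params$seed + 2`).
#' @return A tibble with `patient_id`, `time`, `event`, `group`.
#' @export
simulate_survival <- function(groups, params, seed = params$seed + 2L) {
  stopifnot(inherits(params, "sim_params"))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two non-empty groups required")
  if (!all(table(groups) > 0)) stop("empty group")
  with_seed(seed, {
    rate <- ifelse(groups == lev[2],
                   params$baseline_hazard * params$hazard_ratio,
                   params$baseline_hazard)
    t_event <- rexp(length(groups), rate)
    if (params$censoring_rate == 0) {
      time <- t_event
      event <- rep(1L, length(groups))
    } else {
      # censored fraction for T~Exp(r), C~U(0,m): P(T > C) = (1-exp(-rm))/(rm)
      m <- vapply(rate, function(r) {
        stats::uniroot(function(m) (1 - exp(-r * m)) / (r * m) -
                         params$censoring_rate,
                       interval = c(1e-8, 1e8 / r))$root
      }, 0)
      cens <- runif(length(groups), 0, m)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    tibble(patient_id = sprintf("P%03d", seq_along(groups)),
           time = time, event = event, group = groups)
  })
}

#' Simulate a CpG-dense region sequence for primer design
#'
#' Generates a sequence of the requested length containing exactly
#' `cpg_count` CG dinucleotides at returned (0-based) coordinates and no
#' accidental extra CGs, together with per-CpG tumor-minus-normal beta
#' differences: large (`diff_high` range) inside a centrally planted window
#' covering half the CpGs, small (`diff_low` range) outside — the shape a
#' marker CGI shows in practice.
#'
#' @param length Sequence length in bp.
#' @param cpg_count Number of CG dinucleotides to plant.
#' @param seed Integer seed.
#' @param diff_high,diff_low Ranges of planted beta differences inside /
#'   outside the high-difference window.
#' @return A list with `seq` (character), `cpg_pos` (0-based start of each
#'   CG), and `cpg_diff` (named numeric, planted beta differences).
#' @export
simulate_region_sequence <- function(length, cpg_count, seed = 1L,
                                     diff_high = c(0.5, 0.7),
                                     diff_low = c(0.0, 0.1)) {
  if (cpg_count * 2 > length) stop("cannot pack ", cpg_count, " CpGs into ",
                                   length, " bp")
  with_seed(seed, {
    # draw a CG-free backbone: never emit G directly after C
    bases <- character(length)
    prev <- ""
    for (i in seq_len(length)) {
      alphabet <- if (prev == "C") c("A", "C", "T") else c("A", "C", "G", "T")
      bases[i] <- sample(alphabet, 1)
      prev <- bases[i]
    }
    if (cpg_count > 0) {
      # CpG starts at least 2 apart so planted sites never overlap:
      # sample strictly increasing y, then stretch by the index to force
      # pairwise gaps of >= 2 while staying within [0, length - 2]
      slots <- 0:(length - 2L - (cpg_count - 1L))
      y <- sort(slots[sample.int(length(slots), cpg_count)])
      pos <- y + (seq_len(cpg_count) - 1L)
      for (p0 in pos) {
        bases[p0 + 1L] <- "C"
        bases[p0 + 2L] <- "G"
      }
      # planting a G can create a backbone C..G junction only at p0+3 if the
      # following base is itself G-preceded-by-C; G followed by anything is
      # never CG, and anything followed by the planted C is never CG either.
    } else {
      pos <- integer(0)
    }
    seq <- paste(bases, collapse = "")
    found <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
    found <- if (found[1] == -1) integer(0) else as.integer(found) - 1L
    if (!identical(found, as.integer(pos)))
      stop("internal error: accidental CG created")  # guarded by construction
    if (cpg_count > 0) {
      mid <- stats::quantile(seq_along(pos), c(0.25, 0.75), type = 1)
      in_window <- seq_along(pos) >= mid[1] & seq_along(pos) <= mid[2]
      diff <- ifelse(in_window,
                     runif(cpg_count, diff_high[1], diff_high[2]),
                     runif(cpg_count, diff_low[1], diff_low[2]))
      names(diff) <- as.character(pos)
    } else {
      diff <- setNames(numeric(0), character(0))
    }
    list(seq = seq, cpg_pos = as.integer(pos), cpg_diff = diff)
  })
}

#' Write the full synthetic fixture set to disk
#'
#' Emits everything the pipeline consumes: one coverage TSV per sample, a CGI
#' BED, a gene BED (one gene spanning each non-null CGI), expression count
#' and scaled-estimate CSVs, a clinical/survival CSV, a design-region FASTA,
#' and the ground-truth CSV.
#'
#' @param params A [sim_params()] object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(params)
  cov_dir <- file.path(dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  for (s in cohort$samples$sample_id) {
    write_cpg_coverage(cohort$sites[cohort$sites$sample_id == s, ],
                       file.path(cov_dir, paste0(s, ".cov.tsv")))
  }
  export_target_bed(cohort$cgis, file.path(dir, "cgis.bed"))
  nonnull <- cohort$truth$label != "null"
  genes <- cohort$cgis[nonnull, ]
  if (nrow(genes)) {
    genes$start <- pmax(0L, genes$start - 500L)
    genes$end <- genes$end + 500L
    genes$name <- paste0("GENE_", cohort$truth$cgi[nonnull])
    export_target_bed(genes, file.path(dir, "genes.bed"))
  }
  expr <- simulate_expression(cohort$truth, params)
  write.table(data.frame(gene = rownames(expr$counts), expr$counts,
                         check.names = FALSE),
              file.path(dir, "expression_counts.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(expr$scaled_estimates),
                         expr$scaled_estimates, check.names = FALSE),
              file.path(dir, "scaled_estimates.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  surv <- simulate_survival(rep(c(0, 1), length.out = params$n_pairs), params)
  write.table(surv, file.path(dir, "survival.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  region <- simulate_region_sequence(800, 40, seed = params$seed)
  writeLines(c(">design_region", region$seq), file.path(dir, "region.fa"))
  write.table(data.frame(pos = region$cpg_pos, diff = region$cpg_diff),
              file.path(dir, "cpg_diffs.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
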