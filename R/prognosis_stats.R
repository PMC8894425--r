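# Methylation-based prognostic subgrouping: hierarchical clustering of
# patients on marker-CGI betas, Kaplan-Meier / log-rank survival comparison,
# and the clinical-covariate report (chi-square for categories, two-tailed t
# test for age).

#' Pairwise sample distances on a beta matrix
#'
#' Manhattan: `sum |x_i - y_i|`. Canberra: `sum |x_i - y_i| / (|x_i| + |y_i|)`
#' with zero-denominator terms skipped. Missing entries are handled
#' pairwise-complete (coordinates missing in either sample are dropped for
#' that pair); no rescaling is applied.
#'
#' @param values Numeric matrix, samples in columns (e.g. a [beta_matrix()]
#'   restricted to marker CGIs), or samples in rows with `by = "row"`.
#' @param metric `"manhattan"` or `"canberra"`.
#' @param by Whether observations are columns (default) or rows.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
pairwise_distance <- function(values, metric = c("manhattan", "canberra"),
                              by = c("col", "row")) {
  metric <- match.arg(metric)
  by <- match.arg(by)
  m <- as.matrix(values)
  if (by == "col") m <- t(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      x <- m[i, ]; y <- m[j, ]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      val <- if (metric == "manhattan") {
        sum(abs(x - y))
      } else {
        den <- abs(x) + abs(y)
        keep <- den > 0
        sum(abs(x - y)[keep] / den[keep])
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Hierarchical clustering of patients into k subgroups
#'
#' Agglomerative clustering (complete linkage by default) on a precomputed
#' distance matrix, cut into `k` groups. By the subgroup-labelling
#' convention, group 1 is the cluster with the higher mean value of `values`
#' (the hypermethylated group) when `values` is supplied.
#'
#' @param dist_matrix Symmetric distance matrix (see [pairwise_distance()]).
#' @param k Number of groups (default 2).
#' @param linkage Linkage passed to [stats::hclust()].
#' @param values Optional matrix (markers x samples) used to order group
#'   labels by decreasing mean methylation.
#' @return List with `assignment` (named integer vector), `hclust` (the tree,
#'   merge history included), `metric_linkage`.
#' @export
hierarchical_cluster <- function(dist_matrix, k = 2, linkage = "complete",
                                 values = NULL) {
  n <- nrow(dist_matrix)
  if (k > n) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = linkage)
  cl <- stats::cutree(hc, k = k)
  if (!is.null(values)) {
    means <- vapply(seq_len(k), function(g)
      mean(as.matrix(values)[, cl == g], na.rm = TRUE), 0)
    relabel <- match(cl, order(means, decreasing = TRUE))
    cl <- setNames(relabel, names(cl))
  }
  list(assignment = cl, hclust = hc, metric_linkage = linkage)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()]. The curve starts at 1
#' and only drops at event times; censored observations reduce the risk set
#' without dropping the curve.
#'
#' @param records Tibble with `time` (>= 0) and `event` (1 = event,
#'   0 = censored).
#' @return Tibble `time`, `n_risk`, `n_event`, `surv` (step-function
#'   coordinates at the observed times).
#' @export
kaplan_meier <- function(records) {
  if (any(records$time < 0)) stop("negative follow-up time")
  stopifnot(all(records$event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records))
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         surv = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard log-rank statistic: at each event time the observed minus
#' expected events in group 1 under the hypergeometric null, squared and
#' divided by the summed variance; p from chi-square with 1 df. Invariant to
#' time rescaling and group relabelling.
#'
#' @param records Tibble with `time`, `event`, `group` (two non-empty
#'   groups).
#' @return List `chi2`, `p`.
#' @export
logrank_test <- function(records) {
  if (length(unique(records$group)) != 2) stop("exactly two groups required")
  if (sum(records$event) < 1) stop("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = as.data.frame(records))
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' `sum (O - E)^2 / E` with expectations from the row/column margins,
#' `(r-1)(c-1)` degrees of freedom, upper-tail p. Continuity correction is
#' never applied, including for 2x2 tables.
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @return List `stat`, `df`, `p`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(stat = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-tailed two-sample t test
#'
#' Welch by default (`var_equal = TRUE` for the pooled Student variant).
#' Identical constant samples give p = 1.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances?
#' @return List `t`, `df`, `p`.
#' @export
two_sample_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("zero variance in both samples with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Subgroup clinical report
#'
#' For each clinical covariate, counts and percentages per subgroup with
#' per-covariate denominators reflecting missing data, plus the comparison
#' test: two-tailed t test for numeric covariates (age), Pearson chi-square
#' (no continuity correction) for categorical ones. A covariate with a
#' single observed category is skipped with a message. When survival records
#' are supplied, overall log-rank results are attached; `exclude_stage`
#' removes patients of the given stage(s) from the recurrence analysis (the
#' metastatic-stage exclusion).
#'
#' @param assignment Named vector of subgroup labels per patient id.
#' @param clinical Tibble with `patient_id` and covariate columns.
#' @param survival_records Optional tibble `patient_id`, `time`, `event`
#'   (overall survival) and optionally `recurrence_time`,
#'   `recurrence_event`.
#' @param exclude_stage Stage labels excluded from the recurrence analysis
#'   (requires a `stage` column), default `"IV"`.
#' @return List with `covariates` (one tibble per covariate: per-group
#'   summary and p), and optionally `overall_survival` / `recurrence`
#'   log-rank results.
#' @export
subgroup_report <- function(assignment, clinical, survival_records = NULL,
                            exclude_stage = "IV") {
  ids <- intersect(names(assignment), clinical$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  grp <- assignment[ids]
  groups <- sort(unique(grp))
  covs <- setdiff(names(cl), "patient_id")
  out <- list()
  for (v in covs) {
    x <- cl[[v]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      xs <- split(x[ok], grp[ok])
      if (length(xs) < 2 || any(lengths(xs) < 2)) {
        message("covariate '", v, "' skipped: insufficient data")
        next
      }
      tt <- two_sample_t_test(xs[[1]], xs[[2]])
      out[[v]] <- tibble(
        covariate = v, category = "mean",
        !!!setNames(lapply(xs, mean), paste0("group_", names(xs))),
        p = tt$p, test = "t")
    } else {
      tab <- table(factor(x[ok]), grp[ok])
      if (nrow(tab) < 2) {
        message("covariate '", v, "' skipped: single category")
        next
      }
      ct <- chi_square_test(tab)
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      out[[v]] <- tibble(
        covariate = v, category = rownames(tab),
        !!!setNames(lapply(seq_along(groups), function(g)
          sprintf("%.1f%% (%d)", pct[, g], tab[, g])),
          paste0("group_", groups)),
        p = ct$p, test = "chi-square")
    }
  }
  res <- list(covariates = out)
  if (!is.null(survival_records)) {
    sr <- survival_records[survival_records$patient_id %in% ids, , drop = FALSE]
    sr$group <- assignment[sr$patient_id]
    res$overall_survival <- logrank_test(sr)
    if (all(c("recurrence_time", "recurrence_event") %in% names(sr)) &&
        "stage" %in% names(cl)) {
      keep_ids <- cl$patient_id[!cl$stage %in% exclude_stage]
      rec <- sr[sr$patient_id %in% keep_ids, , drop = FALSE]
      rec <- tibble(patient_id = rec$patient_id, time = rec$recurrence_time,
                    event = rec$recurrence_event, group = rec$group)
      res$recurrence <- logrank_test(rec)
    }
  }
  res
}
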