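test_that("pairwise distances match hand computation and stats::dist", {
  vals <- matrix(c(0.1, 0.4,
                   0.9, 0.2,
                   0.5, 0.5), nrow = 2,
                 dimnames = list(c("m1", "m2"), c("a", "b", "c")))
  d <- pairwise_distance(vals, "manhattan")
  expect_equal(d["a", "b"], abs(0.1 - 0.9) + abs(0.4 - 0.2))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(as.matrix(stats::dist(t(vals), method = "manhattan")), d,
               ignore_attr = TRUE)
  dc <- pairwise_distance(vals, "canberra")
  expect_equal(dc["a", "b"],
               abs(0.1 - 0.9) / (0.1 + 0.9) + abs(0.4 - 0.2) / (0.4 + 0.2))
})

test_that("canberra skips zero denominators and NAs drop pairwise", {
  vals <- matrix(c(0, 0.5, NA,
                   0, 0.1, 0.3), nrow = 3,
                 dimnames = list(c("m1", "m2", "m3"), c("a", "b")))
  dc <- pairwise_distance(vals, "canberra")
  # coordinate 1 has 0/0: skipped; coordinate 3 has an NA: dropped
  expect_equal(dc["a", "b"], abs(0.5 - 0.1) / (0.5 + 0.1))
  dm <- pairwise_distance(vals, "manhattan")
  expect_equal(dm["a", "b"], abs(0.5 - 0.1))
})

test_that("complete linkage reproduces a hand-traced dendrogram", {
  # 1-D points {0, 2, 3, 7}: merge {2,3} at 1, then {0} at max(2,3)=3,
  # then {7} at max(7,5,4)=7
  vals <- matrix(c(0, 2, 3, 7), nrow = 1,
                 dimnames = list("m", c("p1", "p2", "p3", "p4")))
  d <- pairwise_distance(vals, "manhattan")
  hc <- hierarchical_cluster(d, k = 2, values = vals)
  expect_equal(hc$hclust$height, c(1, 3, 7))
  # k = 2 separates {0,2,3} from {7}; group 1 = higher mean = {7}
  expect_equal(unname(hc$assignment), c(2, 2, 2, 1))
  expect_error(hierarchical_cluster(d, k = 10), "exceeds")
})

test_that("clustering separates hyper- from unmethylated patients", {
  set.seed(77)
  lowm <- matrix(runif(5 * 12, 0.05, 0.20), 5, 12)
  highm <- matrix(runif(5 * 8, 0.55, 0.85), 5, 8)
  vals <- cbind(lowm, highm)
  colnames(vals) <- sprintf("P%02d", 1:20)
  rownames(vals) <- sprintf("m%d", 1:5)
  hc <- hierarchical_cluster(pairwise_distance(vals, "manhattan"), k = 2,
                             values = vals)
  expect_equal(unname(hc$assignment), rep(c(2L, 1L), c(12, 8)))
})

test_that("the Kaplan-Meier curve matches the product-limit definition", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$n_risk, c(3, 2, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_error(kaplan_meier(tibble::tibble(time = -1, event = 1)), "negative")
})

test_that("the log-rank test matches the hypergeometric oracle", {
  set.seed(88)
  for (i in 1:20) {
    n <- 40
    rec <- tibble::tibble(
      time = round(rexp(n, 0.2), 2) + 0.01,
      event = rbinom(n, 1, 0.8),
      group = rep(c("A", "B"), each = n / 2))
    got <- logrank_test(rec)
    want <- oracle_logrank(rec$time, rec$event, rec$group)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    # invariances: time rescaling and group relabelling
    resc <- logrank_test(dplyr::mutate(rec, time = time * 3.7))
    expect_equal(resc$chi2, got$chi2, tolerance = 1e-10)
    flip <- logrank_test(dplyr::mutate(
      rec, group = ifelse(group == "A", "B", "A")))
    expect_equal(flip$chi2, got$chi2, tolerance = 1e-10)
  }
  expect_error(logrank_test(tibble::tibble(time = 1:4, event = rep(1, 4),
                                           group = rep("A", 4))), "two groups")
})

test_that("log-rank separates groups simulated under a real hazard ratio", {
  p <- sim_params(seed = 91, hazard_ratio = 4, censoring_rate = 0.2)
  grp <- rep(c(0, 1), c(61, 25))
  sv <- simulate_survival(grp, p)
  res <- logrank_test(tibble::tibble(time = sv$time, event = sv$event,
                                     group = grp))
  expect_lt(res$p, 0.01)
})

test_that("the chi-square kernel equals the definition on random tables", {
  set.seed(99)
  for (i in 1:100) {
    r <- sample(2:4, 1); cc <- sample(2:3, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, r, cc)
    got <- chi_square_test(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$stat, want$stat, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(1:3, 3, 1)), "2x2")
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("the t test matches the Welch formula and degenerate rules", {
  x <- c(61, 70, 55, 68, 72, 59)
  y <- c(64, 66, 71, 75, 69)
  got <- two_sample_t_test(x, y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(got$t, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  dfw <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                   (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(got$df, dfw, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(got$t), dfw), tolerance = 1e-12)

  expect_equal(two_sample_t_test(c(5, 5, 5), c(5, 5))$p, 1)
  expect_error(two_sample_t_test(c(5, 5, 5), c(6, 6)), "zero variance")
  expect_error(two_sample_t_test(1, c(2, 3)), ">= 2")
})

test_that("the subgroup report assembles counts, tests and survival", {
  set.seed(111)
  ids <- sprintf("P%02d", 1:40)
  assignment <- setNames(rep(c(1L, 2L), each = 20), ids)
  clinical <- tibble::tibble(
    patient_id = ids,
    age = c(rnorm(20, 70, 5), rnorm(20, 63, 5)),
    stage = sample(c("II", "III", "IV"), 40, TRUE),
    sex = sample(c("F", "M"), 40, TRUE))
  surv <- tibble::tibble(
    patient_id = ids,
    time = rexp(40, rep(c(0.4, 0.1), each = 20)) + 0.01,
    event = rbinom(40, 1, 0.9),
    recurrence_time = rexp(40, 0.2) + 0.01,
    recurrence_event = rbinom(40, 1, 0.5))
  rep_ <- subgroup_report(assignment, clinical, surv)

  # the categorical p equals the kernel applied to the same table
  tab <- table(clinical$sex, assignment[clinical$patient_id])
  expect_equal(unique(rep_$covariates$sex$p), chi_square_test(tab)$p)
  expect_equal(unique(rep_$covariates$sex$test), "chi-square")
  # the numeric covariate runs the t test
  expect_equal(rep_$covariates$age$test, "t")
  expect_equal(
    rep_$covariates$age$p,
    two_sample_t_test(clinical$age[1:20], clinical$age[21:40])$p)
  # counts printed per group sum to the group sizes
  sex_n <- sum(as.integer(gsub(".*\\((\\d+)\\)", "\\1",
                               rep_$covariates$sex$group_1)))
  expect_equal(sex_n, 20)

  # survival blocks match direct calls on the same records
  os <- logrank_test(tibble::tibble(time = surv$time, event = surv$event,
                                    group = assignment[surv$patient_id]))
  expect_equal(rep_$overall_survival$chi2, os$chi2)
  keep <- clinical$patient_id[clinical$stage != "IV"]
  rc <- surv[surv$patient_id %in% keep, ]
  rec_direct <- logrank_test(tibble::tibble(
    time = rc$recurrence_time, event = rc$recurrence_event,
    group = assignment[rc$patient_id]))
  expect_equal(rep_$recurrence$chi2, rec_direct$chi2)
})

test_that("single-category covariates are skipped with a message", {
  ids <- sprintf("P%02d", 1:10)
  assignment <- setNames(rep(c(1L, 2L), each = 5), ids)
  clinical <- tibble::tibble(patient_id = ids, site = rep("colon", 10))
  expect_message(rep_ <- subgroup_report(assignment, clinical), "skipped")
  expect_length(rep_$covariates, 0)
})
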