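test_that("splits are 75/25, seeded and stratified within one sample", {
  sim <- generate_reports(generator_config(n_reports = 100, seed = 12))
  plan <- make_splits(sim$reports, sim$labels, group_by_patient = FALSE,
                      seed = 5)
  expect_length(plan$splits, 5L)
  for (s in plan$splits) {
    expect_length(s$train, 75L)
    expect_length(s$test, 25L)
    expect_length(intersect(s$train, s$test), 0L)
  }
  plan2 <- make_splits(sim$reports, sim$labels, group_by_patient = FALSE,
                       seed = 5)
  expect_identical(plan, plan2)

  # n = 40 with 10 positives: the 10-sample test side gets 2 or 3
  reports <- tibble::tibble(report_id = sprintf("r%02d", 1:40),
                            patient_id = sprintf("p%02d", 1:40),
                            scan_type = "CT", report_datetime = Sys.time(),
                            text = "x.")
  labels <- tibble::tibble(report_id = reports$report_id,
                           stroke = rep(c(1L, 0L), c(10L, 30L)),
                           mca = 0L, acute = 0L)
  for (seed in 1:10) {
    plan <- make_splits(reports, labels, group_by_patient = FALSE,
                        seed = seed)
    for (s in plan$splits) {
      n_pos <- sum(labels$stroke[match(s$test, labels$report_id)])
      expect_true(n_pos %in% 2:3)
    }
  }
  expect_error(make_splits(reports[1:5, ], labels[1:5, ]), "at least 8")
})

test_that("patient grouping keeps every patient on one side", {
  sim <- generate_reports(generator_config(n_reports = 200, seed = 13))
  plan <- make_splits(sim$reports, sim$labels, group_by_patient = TRUE,
                      seed = 2)
  pat <- function(ids) sim$reports$patient_id[match(ids,
                                                    sim$reports$report_id)]
  for (s in plan$splits) {
    expect_length(intersect(pat(s$train), pat(s$test)), 0L)
    # sizes approximate 75/25 up to patient-group granularity
    expect_lt(abs(length(s$test) - 50), 8)
  }
})

test_that("AUC matches its rank form on canonical cases", {
  expect_equal(roc_and_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  expect_equal(roc_and_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_equal(roc_and_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_error(roc_and_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUC equals brute-force pair counting with ties", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_and_auc(y, p)$auc, auc_bruteforce(y, p),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are monotone and span both corners", {
  set.seed(22)
  y <- rbinom(80, 1, 0.5)
  p <- round(runif(80), 1)
  roc <- roc_and_auc(y, p)$roc
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
})

test_that("the split-level confidence interval is the normal form", {
  expect_equal(auc_ci(rep(0.9, 5)), list(mean = 0.9, lower = 0.9,
                                         upper = 0.9))
  ci <- auc_ci(c(0.9, 0.92, 0.94, 0.96, 0.98))
  expect_equal(ci$mean, 0.94)
  expect_equal(ci$lower, 0.9122814, tolerance = 1e-6)
  expect_equal(ci$upper, 0.9677186, tolerance = 1e-6)
  expect_error(auc_ci(0.9), "at least two")
})

test_that("threshold selection is sensitivity-first", {
  y <- c(1, 1, 1, 0, 0, 0)
  p <- c(0.95, 0.9, 0.8, 0.3, 0.2, 0.1)
  t <- select_threshold(y, p, min_sens = 0.9)
  expect_equal(t, 0.8)
  cm <- confusion_metrics(y, p, t)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  # min_sens = 0 degenerates to maximising specificity alone
  t0 <- select_threshold(y, p, min_sens = 0)
  expect_equal(confusion_metrics(y, p, t0)$specificity, 1)
  # unattainable sensitivity falls back to the maximum, with a message
  expect_message(tf <- select_threshold(c(1, 0), c(0.2, 0.8), min_sens = 2),
                 "falling back")
  expect_equal(tf, 0.2)
})

test_that("threshold selection equals exhaustive enumeration", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(8:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 1)
    expect_identical(suppressMessages(select_threshold(y, p)),
                     suppressMessages(threshold_bruteforce(y, p)))
  }
})

test_that("confusion metrics follow their standard definitions", {
  # TP=9, FN=1, TN=8, FP=2
  y <- rep(c(1, 0), c(10, 10))
  p <- c(rep(0.9, 9), 0.1, rep(0.9, 2), rep(0.1, 8))
  cm <- confusion_metrics(y, p, 0.5)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$accuracy, 0.85)
  expect_equal(cm$precision, 9 / 11)
  cm0 <- confusion_metrics(y, p, 0)
  expect_equal(c(cm0$sensitivity, cm0$specificity), c(1, 0))
  cmh <- confusion_metrics(y, p, 1.1)
  expect_equal(c(cmh$sensitivity, cmh$specificity), c(0, 1))
  expect_true(is.na(cmh$precision))
})

test_that("calibration bins use the fixed closed/open intervals", {
  tab <- calibration_table(c(1, 1, 1, 1, 0), rep(0.95, 5))
  expect_equal(tab$event_rate[10], 0.8)
  expect_equal(tab$n[10], 5L)
  # p = 0 lands in the closed-left first bin
  tab0 <- calibration_table(c(0, 1), c(0, 0.05))
  expect_equal(tab0$n[1], 2L)
  # bins partition: counts sum to n, empty bins carry NA rates
  set.seed(24)
  y <- rbinom(300, 1, 0.3)
  p <- runif(300, 0, 0.5)
  tab2 <- calibration_table(y, p)
  expect_equal(sum(tab2$n), 300L)
  expect_true(all(is.na(tab2$event_rate[tab2$n == 0])))
})

test_that("mcnemar matches the closed form and stats::mcnemar.test", {
  r <- mcnemar_test(rep(1, 14), c(rep(1, 7), rep(0, 7)),
                    c(rep(0, 7), rep(1, 7)))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # b = 15, c = 5
  y <- rep(1, 30)
  predA <- rep(c(1, 0, 1), c(15, 5, 10))
  predB <- rep(c(0, 1, 1), c(15, 5, 10))
  r2 <- mcnemar_test(y, predA, predB)
  expect_equal(r2$b, 15)
  expect_equal(r2$c, 5)
  expect_equal(r2$chi2, 5.0)
  expect_equal(r2$p, 0.02534732, tolerance = 1e-6)
  # symmetric in the two models
  r3 <- mcnemar_test(y, predB, predA)
  expect_equal(r3$chi2, r2$chi2)
  expect_equal(r3$p, r2$p)

  # independent oracle across random prediction pairs
  set.seed(25)
  for (rep in 1:10) {
    yy <- rbinom(40, 1, 0.5)
    pa <- rbinom(40, 1, 0.5)
    pb <- rbinom(40, 1, 0.5)
    ours <- mcnemar_test(yy, pa, pb)
    if (ours$b + ours$c == 0) next
    ref <- stats::mcnemar.test(table(factor(pa == yy, c(FALSE, TRUE)),
                                     factor(pb == yy, c(FALSE, TRUE))),
                               correct = FALSE)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    ref_c <- stats::mcnemar.test(table(factor(pa == yy, c(FALSE, TRUE)),
                                       factor(pb == yy, c(FALSE, TRUE))),
                                 correct = TRUE)
    ours_c <- mcnemar_test(yy, pa, pb, correct = TRUE)
    expect_equal(ours_c$p, ref_c$p.value, tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  y <- rbinom(150, 1, 0.5)
  p <- runif(150)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_and_auc(y, p)$auc, ref, tolerance = 1e-12)
})

test_that("run_benchmark assembles a full grid and skips label-less tasks", {
  sim <- generate_reports(generator_config(n_reports = 160, seed = 31))
  bench <- run_benchmark(sim$reports, sim$labels, featurizers = "bow",
                         classifiers = list(
                           logreg_l1 = list(classifier_spec("logreg_l1"))),
                         tasks = c("stroke", "acute"),
                         n_splits = 2, folds = 4, seed = 9, min_df = 2)
  expect_equal(nrow(bench$summary), 2L)
  expect_true(all(bench$summary$mean_auc >= 0 & bench$summary$mean_auc <= 1))
  cell <- bench$cells[["stroke.bow.logreg_l1"]]
  expect_equal(nrow(cell$per_split), 2L)
  expect_true(all(cell$per_split$sensitivity >= 0.9 |
                    cell$per_split$threshold == min(cell$predictions$p)))
  expect_equal(sum(cell$calibration$n), nrow(cell$predictions))

  lab2 <- sim$labels
  lab2$mca <- NA_integer_
  expect_warning(run_benchmark(sim$reports, lab2, featurizers = "bow",
                               classifiers = list(
                                 logreg_l1 = list(classifier_spec("logreg_l1"))),
                               tasks = "mca", n_splits = 2, folds = 4,
                               seed = 9, min_df = 2),
                 "skipped")
})

test_that("benchmark mcnemar compares cells on pooled predictions", {
  sim <- generate_reports(generator_config(n_reports = 160, seed = 32))
  bench <- run_benchmark(sim$reports, sim$labels,
                         featurizers = c("bow", "tfidf"),
                         classifiers = list(
                           logreg_l1 = list(classifier_spec("logreg_l1"))),
                         tasks = "stroke", n_splits = 2, folds = 4,
                         seed = 9, min_df = 2)
  res <- benchmark_mcnemar(bench, "stroke", "bow/logreg_l1",
                           "tfidf/logreg_l1")
  expect_true(res$p >= 0 && res$p <= 1)
  expect_gte(res$chi2, 0)
  expect_error(benchmark_mcnemar(bench, "stroke", "bow/rf",
                                 "tfidf/logreg_l1"), "no benchmark cell")
})
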