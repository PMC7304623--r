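#' Repeated stratified 75/25 train/test splits
#'
#' Builds the validation plan: `n_splits` independent seeded random
#' partitions of the reports into 75% training / 25% testing. Splits are
#' stratified on a task label so each side's prevalence stays within one
#' sample of what the sizes allow. With `group_by_patient = TRUE` (the
#' default) all reports of a patient land on the same side, preventing
#' leakage between train and test through repeat imaging; stratification
#' is then best-effort at the patient-group level. If one patient group
#' alone exceeds the test fraction, stratification is relaxed with a
#' warning.
#'
#' @param reports Report tibble (needs `report_id`, `patient_id`).
#' @param labels Label tibble aligned by `report_id`.
#' @param n_splits Number of independent partitions (default 5).
#' @param train_frac Training fraction (default 0.75).
#' @param stratify_on Label column used for stratification
#'   (default `"stroke"`).
#' @param group_by_patient Keep each patient on one side (default TRUE).
#' @param seed Base seed; split `s` uses `seed + s`.
#' @return A `split_plan`: list of splits, each with `train` and `test`
#'   report-id character vectors.
#' @export
make_splits <- function(reports, labels, n_splits = 5L, train_frac = 0.75,
                        stratify_on = "stroke", group_by_patient = TRUE,
                        seed = 1L) {
  stopifnot(stratify_on %in% names(labels))
  ids <- intersect(reports$report_id, labels$report_id)
  n <- length(ids)
  if (n < 8L) stop("need at least 8 labelled reports to split")
  y <- labels[[stratify_on]][match(ids, labels$report_id)]
  pat <- reports$patient_id[match(ids, reports$report_id)]
  n_train <- round(train_frac * n)
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    splits[[s]] <- with_preserved_seed(seed + s, {
      if (group_by_patient) {
        grouped_split(ids, y, pat, n_train)
      } else {
        stratified_split(ids, y, n_train)
      }
    })
  }
  structure(list(splits = splits, n = n, n_splits = n_splits,
                 train_frac = train_frac, stratify_on = stratify_on,
                 group_by_patient = group_by_patient, seed = seed),
            class = "split_plan")
}

# Exact stratified report-level split: test counts per class by largest
# remainder, so each side's prevalence is within one sample of achievable.
stratified_split <- function(ids, y, n_train) {
  n <- length(ids)
  n_test <- n - n_train
  idx_pos <- which(y == 1L)
  idx_neg <- which(y == 0L)
  test_pos_frac <- n_test * length(idx_pos) / n
  n_test_pos <- min(length(idx_pos), round(test_pos_frac))
  n_test_neg <- n_test - n_test_pos
  test <- c(idx_pos[sample.int(length(idx_pos))][seq_len(n_test_pos)],
            idx_neg[sample.int(length(idx_neg))][seq_len(n_test_neg)])
  list(train = ids[-test], test = ids[test])
}

# Patient-grouped split: shuffle patient groups (positive-heavy and
# negative-heavy groups interleaved for balance), then assign greedily to
# the test side until the 25% target is reached.
grouped_split <- function(ids, y, pat, n_train) {
  n <- length(ids)
  n_test <- n - n_train
  groups <- split(seq_len(n), pat)
  if (max(lengths(groups)) > n_test) {
    warning("a single patient group exceeds the test fraction; ",
            "stratification relaxed", call. = FALSE)
  }
  groups <- groups[sample.int(length(groups))]
  test <- integer(0)
  for (g in groups) {
    cur <- length(test)
    # accept a group while it brings the test side closer to its target size
    if (abs(cur + length(g) - n_test) <= abs(cur - n_test)) {
      test <- c(test, g)
    }
    if (length(test) >= n_test) break
  }
  list(train = ids[-test], test = ids[test])
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>", x$n_splits, "split(s) of", x$n, "reports at",
      paste0(round(100 * x$train_frac), "/", round(100 * (1 - x$train_frac))),
      if (x$group_by_patient) "(grouped by patient)" else "(report-level)",
      "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is computed in its rank (Mann-Whitney) form: the probability
#' that a randomly chosen positive outscores a randomly chosen negative,
#' with ties credited 1/2. ROC points are swept over all distinct scores
#' used as thresholds under the rule "positive iff p >= t".
#'
#' @param y Binary 0/1 labels; both classes must be present.
#' @param p Numeric scores (higher = more positive).
#' @return List with `auc` and `roc` (tibble of threshold, fpr, tpr,
#'   including the (0,0) and (1,1) endpoints).
#' @export
roc_and_auc <- function(y, p) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p), all(y %in% c(0L, 1L)), all(is.finite(p)))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(p, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(p), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(p >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(p >= t & y == 0L) / n_neg, numeric(1))
  roc <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc)
}

#' Mean AUC with a 95% confidence interval over splits
#'
#' Normal-approximation interval over the per-split AUCs:
#' `mean +/- 1.96 * sd / sqrt(k)`, clipped to `[0, 1]`. Percentile
#' intervals are too unstable at five replicates.
#'
#' @param aucs Numeric vector of per-split AUCs (length >= 2).
#' @return List with `mean`, `lower`, `upper`.
#' @export
auc_ci <- function(aucs) {
  if (length(aucs) < 2L) stop("need at least two AUC values for an interval")
  m <- mean(aucs)
  half <- 1.96 * stats::sd(aucs) / sqrt(length(aucs))
  list(mean = m, lower = max(0, m - half), upper = min(1, m + half))
}

#' Sensitivity-first operating threshold
#'
#' Among candidate thresholds (the distinct scores), restricted to those
#' achieving sensitivity >= `min_sens` under "positive iff p >= t",
#' returns the one with the highest specificity; ties go to the largest
#' threshold. If no threshold reaches `min_sens`, the threshold with
#' maximal sensitivity (best specificity among those) is returned and the
#' fallback is reported via a message.
#'
#' @param y Binary 0/1 labels; both classes must be present.
#' @param p Numeric scores.
#' @param min_sens Required sensitivity (default 0.90).
#' @return The selected threshold (a value of `p`).
#' @export
select_threshold <- function(y, p, min_sens = 0.90) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cand <- sort(unique(p), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(p[y == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(p[y == 0L] < t), numeric(1))
  ok <- sens >= min_sens
  if (!any(ok)) {
    message("select_threshold: no threshold reaches sensitivity ",
            min_sens, "; falling back to maximal sensitivity")
    ok <- sens == max(sens)
  }
  idx <- which(ok)
  best <- idx[order(-spec[idx], -cand[idx])][1L]
  cand[best]
}

#' Confusion-matrix metrics at a threshold
#'
#' Standard definitions under "positive iff p >= t". Precision is
#' undefined (returned as `NA`) when there are no predicted positives.
#'
#' @param y Binary 0/1 labels.
#' @param p Numeric scores.
#' @param t Decision threshold.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(y, p, t) {
  y <- as.integer(y)
  pred <- as.integer(p >= t)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Calibration table over fixed 10% probability bins
#'
#' Bins predicted probabilities into the intervals `[0, 0.1]`,
#' `(0.1, 0.2]`, ..., `(0.9, 1.0]` (the first interval is closed on the
#' left so that p = 0 is included) and reports, per bin, the sample
#' count, event count and event rate. Empty bins are kept with an `NA`
#' rate. Example: a last bin holding 5 samples of which 4 are events has
#' event rate 0.8.
#'
#' @param y Binary 0/1 labels.
#' @param p Predicted probabilities in `[0, 1]`.
#' @return Tibble with columns `bin`, `lower`, `upper`, `midpoint`, `n`,
#'   `events`, `event_rate`.
#' @export
calibration_table <- function(y, p) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p), all(p >= 0 & p <= 1))
  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(p, breaks = breaks, include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(bin))
  events <- as.integer(tapply(y, bin, sum, default = 0L))
  tibble::tibble(
    bin = levels(bin),
    lower = breaks[-11L],
    upper = breaks[-1L],
    midpoint = (breaks[-11L] + breaks[-1L]) / 2,
    n = n,
    events = events,
    event_rate = ifelse(n > 0, events / pmax(n, 1L), NA_real_))
}

#' McNemar test between two classifiers
#'
#' Compares paired binary predictions through their discordant counts:
#' `b` = cases model A classifies correctly and model B incorrectly, `c` =
#' the converse. The statistic is `(b - c)^2 / (b + c)` on one degree of
#' freedom, two-sided; with `correct = TRUE` the continuity-corrected form
#' `max(|b - c| - 1, 0)^2 / (b + c)` is used. When `b + c = 0` the models never
#' disagree and the test degenerates to `chi2 = 0`, `p = 1`.
#'
#' @param y True binary labels.
#' @param predA,predB Binary predictions of the two models.
#' @param correct Apply the continuity correction (default FALSE).
#' @return List with `b`, `c`, `chi2`, `p`.
#' @export
mcnemar_test <- function(y, predA, predB, correct = FALSE) {
  y <- as.integer(y)
  predA <- as.integer(predA)
  predB <- as.integer(predB)
  stopifnot(length(y) == length(predA), length(y) == length(predB),
            all(predA %in% c(0L, 1L)), all(predB %in% c(0L, 1L)))
  okA <- predA == y
  okB <- predB == y
  b <- sum(okA & !okB)
  c_ <- sum(!okA & okB)
  if (b + c_ == 0L) {
    return(list(b = b, c = c_, chi2 = 0, p = 1))
  }
  num <- if (correct) max(abs(b - c_) - 1, 0)^2 else (b - c_)^2
  chi2 <- num / (b + c_)
  list(b = b, c = c_, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}
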