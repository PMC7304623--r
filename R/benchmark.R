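#' Run the full featurizer x classifier benchmark
#'
#' Reproduces the validation protocol end to end for each requested task
#' (stroke presence, MCA location, acuity), featurizer (bag-of-words,
#' tf-idf, document embeddings) and classifier: on every one of the
#' repeated stratified 75/25 splits, the vocabulary is fitted on the
#' training side only, tuning parameters are selected by grid-search
#' cross-validation on the training side, the tuned model is refitted and
#' evaluated on the test side, an operating threshold is chosen
#' sensitivity-first, and confusion metrics are recorded. Results are
#' aggregated across splits (mean AUC with a 95% CI, mean metrics, pooled
#' calibration). With an external cohort supplied, every split's trained
#' model is instead evaluated on the entire external set.
#'
#' @param reports Report tibble ([read_reports()] / [generate_reports()]).
#' @param labels Label tibble.
#' @param featurizers Subset of `c("bow", "tfidf", "glove")`.
#' @param classifiers Named list: names are classifier kinds, values are
#'   spec grids (lists of [classifier_spec()]) or single specs. An `rnn`
#'   entry must be a single spec and is only paired with the `glove`
#'   featurizer (it consumes embedded token sequences directly).
#' @param tasks Subset of `c("stroke", "mca", "acute")`.
#' @param embeddings Embedding matrix; required for `glove` featurization
#'   and the `rnn` classifier.
#' @param lexicon,boilerplate Preprocessing configuration.
#' @param n_splits,min_sens,folds,seed,group_by_patient Protocol settings:
#'   number of 75/25 splits (default 5), sensitivity floor for the
#'   operating threshold (default 0.90), CV folds (default 10), base seed,
#'   and patient-level grouping of splits.
#' @param min_df Minimum document frequency for the per-split vocabulary.
#' @param external_reports,external_labels Optional external validation
#'   cohort; when given, the entire external set is tested across all
#'   splits.
#' @return A `benchmark_result`: list with `summary` (one tibble row per
#'   task x featurizer x classifier) and `cells` (per-cell detail:
#'   per-split metrics, pooled predictions, calibration and ROC tables).
#' @export
run_benchmark <- function(reports, labels,
                          featurizers = c("bow", "tfidf", "glove"),
                          classifiers = list(
                            logreg_l1 = default_spec_grid("logreg_l1")),
                          tasks = c("stroke", "mca", "acute"),
                          embeddings = NULL,
                          lexicon = default_phrase_lexicon(),
                          boilerplate = default_boilerplate_patterns(),
                          n_splits = 5L, min_sens = 0.90, folds = 10L,
                          seed = 1L, group_by_patient = TRUE, min_df = 2L,
                          external_reports = NULL, external_labels = NULL) {
  featurizers <- match.arg(featurizers, several.ok = TRUE)
  stopifnot(length(classifiers) >= 1L, !is.null(names(classifiers)))
  if (any(c("glove") %in% featurizers) && is.null(embeddings)) {
    stop("glove featurization requires an embedding matrix")
  }
  docs <- preprocess_reports(reports, lexicon, boilerplate)
  external <- !is.null(external_reports)
  if (external) {
    ext_docs <- preprocess_reports(external_reports, lexicon, boilerplate)
    ext_labels <- external_labels
  }
  cells <- list()
  summary_rows <- list()
  for (task in tasks) {
    if (!task %in% names(labels) || all(is.na(labels[[task]]))) {
      warning("no labels for task '", task, "'; skipped", call. = FALSE)
      next
    }
    plan <- make_splits(reports, labels, n_splits = n_splits,
                        stratify_on = task,
                        group_by_patient = group_by_patient, seed = seed)
    y_all <- stats::setNames(labels[[task]], labels$report_id)
    for (fz in featurizers) {
      for (cl in names(classifiers)) {
        if (cl == "rnn" && fz != "glove") next
        grid <- classifiers[[cl]]
        if (inherits(grid, "classifier_spec")) grid <- list(grid)
        cell <- evaluate_cell(
          docs = docs, y_all = y_all, plan = plan, featurizer = fz,
          grid = grid, embeddings = embeddings, min_df = min_df,
          folds = folds, min_sens = min_sens, seed = seed,
          ext_docs = if (external) ext_docs else NULL,
          ext_y = if (external) {
            stats::setNames(ext_labels[[task]], ext_labels$report_id)
          } else NULL)
        key <- paste(task, fz, cl, sep = ".")
        cell$task <- task; cell$featurizer <- fz; cell$classifier <- cl
        cells[[key]] <- cell
        summary_rows[[key]] <- tibble::tibble(
          task = task, featurizer = fz, classifier = cl,
          mean_auc = cell$mean_auc,
          ci_lower = cell$ci_lower, ci_upper = cell$ci_upper,
          mean_threshold = mean(cell$per_split$threshold),
          sensitivity = mean(cell$per_split$sensitivity),
          specificity = mean(cell$per_split$specificity),
          accuracy = mean(cell$per_split$accuracy),
          precision = mean(cell$per_split$precision, na.rm = TRUE))
      }
    }
  }
  structure(list(summary = do.call(rbind, summary_rows), cells = cells,
                 settings = list(n_splits = n_splits, min_sens = min_sens,
                                 folds = folds, seed = seed, min_df = min_df,
                                 group_by_patient = group_by_patient,
                                 external = external)),
            class = "benchmark_result")
}

evaluate_cell <- function(docs, y_all, plan, featurizer, grid, embeddings,
                          min_df, folds, min_sens, seed,
                          ext_docs = NULL, ext_y = NULL) {
  per_split <- list()
  preds <- list()
  for (s in seq_along(plan$splits)) {
    tr_ids <- plan$splits[[s]]$train
    te_ids <- if (is.null(ext_docs)) plan$splits[[s]]$test else names(ext_docs)
    tr_docs <- docs[tr_ids]
    te_docs <- if (is.null(ext_docs)) docs[te_ids] else ext_docs
    y_tr <- unname(y_all[tr_ids])
    y_te <- if (is.null(ext_docs)) unname(y_all[te_ids]) else unname(ext_y[te_ids])

    if (grid[[1L]]$kind == "rnn") {
      model <- train_rnn_document_model(tr_docs, embeddings, y_tr,
                                        spec = grid[[1L]])
      p <- predict_proba(model, te_docs)
    } else {
      feat <- featurize_split(tr_docs, te_docs, featurizer, embeddings, min_df)
      best <- if (length(grid) > 1L) {
        grid_search_cv(feat$train, y_tr, grid, folds = folds,
                       seed = seed + s)$best_spec
      } else {
        grid[[1L]]
      }
      model <- train_classifier(feat$train, y_tr, best)
      p <- predict_proba(model, feat$test)
    }
    auc <- roc_and_auc(y_te, p)$auc
    t <- select_threshold(y_te, p, min_sens = min_sens)
    cm <- confusion_metrics(y_te, p, t)
    per_split[[s]] <- tibble::tibble(
      split = s, auc = auc, threshold = t,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      accuracy = cm$accuracy, precision = cm$precision)
    preds[[s]] <- tibble::tibble(report_id = te_ids, split = s,
                                 y = y_te, p = p, pred = as.integer(p >= t))
  }
  per_split <- do.call(rbind, per_split)
  preds <- do.call(rbind, preds)
  ci <- auc_ci(per_split$auc)
  pooled_roc <- roc_and_auc(preds$y, preds$p)
  list(per_split = per_split, predictions = preds,
       mean_auc = ci$mean, ci_lower = ci$lower, ci_upper = ci$upper,
       calibration = calibration_table(preds$y, pmin(1, pmax(0, preds$p))),
       roc = pooled_roc$roc)
}

featurize_split <- function(tr_docs, te_docs, featurizer, embeddings, min_df) {
  if (featurizer == "glove") {
    list(train = docvec_matrix(tr_docs, embeddings),
         test = docvec_matrix(te_docs, embeddings))
  } else {
    vocab <- fit_vocabulary(tr_docs, min_df = min_df)
    fn <- if (featurizer == "bow") bow_matrix else tfidf_matrix
    list(train = fn(tr_docs, vocab), test = fn(te_docs, vocab))
  }
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", nrow(x$summary), "cell(s) over",
      x$settings$n_splits, "split(s)\n")
  print(x$summary)
  invisible(x)
}

#' Serialise a benchmark to a metrics list / JSON file
#'
#' Produces a deterministic, JSON-ready summary: per cell the per-split
#' AUCs, mean AUC with CI, mean confusion metrics and the calibration
#' table. Identical inputs and seeds give byte-identical files.
#'
#' @param bench A [run_benchmark()] result.
#' @param path Optional path; when given the JSON is written there.
#' @return The metrics list, invisibly if `path` is given.
#' @export
benchmark_metrics <- function(bench, path = NULL) {
  stopifnot(inherits(bench, "benchmark_result"))
  out <- list(settings = bench$settings, cells = list())
  for (key in sort(names(bench$cells), method = "radix")) {
    cell <- bench$cells[[key]]
    out$cells[[key]] <- list(
      task = cell$task, featurizer = cell$featurizer,
      classifier = cell$classifier,
      auc_per_split = cell$per_split$auc,
      mean_auc = cell$mean_auc,
      ci = c(cell$ci_lower, cell$ci_upper),
      threshold = cell$per_split$threshold,
      sensitivity = mean(cell$per_split$sensitivity),
      specificity = mean(cell$per_split$specificity),
      accuracy = mean(cell$per_split$accuracy),
      precision = mean(cell$per_split$precision, na.rm = TRUE),
      calibration = list(
        midpoint = cell$calibration$midpoint,
        n = cell$calibration$n,
        event_rate = cell$calibration$event_rate))
  }
  if (!is.null(path)) {
    write_metrics_json(out, path)
    return(invisible(out))
  }
  out
}

#' McNemar comparison of two benchmark cells
#'
#' Pools the test-side predictions of two cells of the same task across
#' splits, binarised at each cell's per-split operating threshold, and
#' runs the paired discordant-count test.
#'
#' @param bench A [run_benchmark()] result.
#' @param task Task name.
#' @param cell_a,cell_b Character `"featurizer/classifier"` pairs, e.g.
#'   `"bow/logreg_l1"`.
#' @param correct Continuity correction flag, see [mcnemar_test()].
#' @return A [mcnemar_test()] result.
#' @export
benchmark_mcnemar <- function(bench, task, cell_a, cell_b, correct = FALSE) {
  stopifnot(inherits(bench, "benchmark_result"))
  get_cell <- function(spec) {
    parts <- strsplit(spec, "/", fixed = TRUE)[[1]]
    key <- paste(task, parts[1], parts[2], sep = ".")
    if (!key %in% names(bench$cells)) stop("no benchmark cell ", key)
    bench$cells[[key]]$predictions
  }
  pa <- get_cell(cell_a)
  pb <- get_cell(cell_b)
  keyed <- merge(pa, pb, by = c("report_id", "split"))
  mcnemar_test(keyed$y.x, keyed$pred.x, keyed$pred.y, correct = correct)
}
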