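#' Classifier specification
#'
#' Describes one binary classifier and its tuning parameters. Supported
#' kinds and their fields:
#' \describe{
#'   \item{`logreg_l1`}{lasso-penalised logistic regression: `lambda`
#'     (l1 penalty weight), `max_iter` (default 1000), `tol` (default
#'     0.01).}
#'   \item{`knn`}{k-nearest neighbours on the standardised feature space,
#'     Euclidean distance, probability = neighbour vote fraction: `k`.}
#'   \item{`cart`}{classification tree: `min_bucket` and `max_depth`
#'     (both in 1..10), `split_criterion` ("gini" or "entropy").}
#'   \item{`rf`}{random forest of `n_trees` (default 200) greedy trees;
#'     `seed` fixes the bootstrap draws.}
#'   \item{`rnn`}{hierarchical LSTM document model: `word_hidden`,
#'     `sent_hidden` (default 64/64), `epochs` (20), `batch` (32), `lr`
#'     (0.01), `seed`. Consumed by [train_rnn_document_model()].}
#' }
#'
#' @param ... The classifier kind (first unnamed argument or `kind =`),
#'   one of `"logreg_l1"`, `"knn"`, `"cart"`, `"rf"`, `"rnn"`, followed by
#'   kind-specific fields, see above. (Arguments are matched exactly, so
#'   the `knn` field `k` cannot collide with `kind`.)
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(...) {
  dots <- list(...)
  nms <- names(dots)
  if (is.null(nms)) nms <- rep("", length(dots))
  if ("kind" %in% nms) {
    kind <- dots[["kind"]]
    dots <- dots[nms != "kind"]
    nms <- nms[nms != "kind"]
  } else if (any(nms == "")) {
    first <- which(nms == "")[1L]
    if (first != 1L || sum(nms == "") > 1L) {
      stop("only the first argument (the kind) may be unnamed")
    }
    kind <- dots[[1L]]
    dots <- dots[-1L]
    nms <- nms[-1L]
  } else {
    stop("classifier kind is required")
  }
  kinds <- c("logreg_l1", "knn", "cart", "rf", "rnn")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  }
  extra <- dots
  defaults <- switch(kind,
    logreg_l1 = list(lambda = 0.001, max_iter = 1000L, tol = 0.01),
    knn = list(k = 5L),
    cart = list(min_bucket = 5L, max_depth = 5L, split_criterion = "gini"),
    rf = list(n_trees = 200L, seed = 1L),
    rnn = list(word_hidden = 64L, sent_hidden = 64L, epochs = 20L,
               batch = 32L, lr = 0.01, seed = 1L))
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) {
    stop("unknown field(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  }
  spec <- modifyList(defaults, extra)
  with(spec, switch(kind,
    logreg_l1 = stopifnot(lambda >= 0, max_iter >= 1, tol > 0),
    knn = stopifnot(k >= 1),
    cart = {
      stopifnot(min_bucket >= 1, min_bucket <= 10,
                max_depth >= 1, max_depth <= 10)
      stopifnot(split_criterion %in% c("gini", "entropy"))
    },
    rf = stopifnot(n_trees >= 1),
    rnn = stopifnot(word_hidden >= 1, sent_hidden >= 1, epochs >= 0,
                    batch >= 1, lr > 0)))
  structure(c(list(kind = kind), spec), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  flds <- x[setdiff(names(x), "kind")]
  cat("<classifier_spec>", x$kind, "|",
      paste(names(flds), unlist(flds), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

as_feature_matrix <- function(X) {
  if (inherits(X, "Matrix") || is.matrix(X)) return(X)
  stop("X must be a matrix or Matrix feature matrix")
}

check_training_inputs <- function(X, y) {
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  xv <- if (inherits(X, "sparseMatrix")) X@x else X
  if (any(!is.finite(xv))) stop("feature matrix contains NaN or infinite values")
  y
}

#' Train a binary classifier on a feature matrix
#'
#' Dispatches on `spec$kind`. Logistic regression is fitted with an l1
#' (lasso) penalty at the spec's fixed `lambda`; features are standardised
#' internally (training statistics only) for logistic regression and
#' k-nearest neighbours, both being scale-sensitive. Random forest and
#' recurrent models are deterministic given `spec$seed`.
#'
#' @param X Feature matrix (dense or sparse), documents in rows.
#' @param y Binary 0/1 labels, one per row; both classes must be present.
#' @param spec A [classifier_spec()] with a matrix-based kind
#'   (`rnn` models are trained with [train_rnn_document_model()]).
#' @return A `trained_model` carrying the spec, the fitted state and the
#'   expected feature width.
#' @export
train_classifier <- function(X, y, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_feature_matrix(X)
  y <- check_training_inputs(X, y)
  fit <- switch(spec$kind,
    logreg_l1 = {
      yf <- factor(y, levels = c(0, 1))
      # coordinate descent needs warm starts from lambda_max (the smallest
      # penalty with an all-zero solution); a short geometric path from
      # there down to the requested lambda keeps each step converged.
      # maxit is in the backend unit (single coordinate-descent passes
      # over the whole path), ~100 per optimizer-level iteration.
      n <- nrow(X)
      r <- y - mean(y)
      sds <- sqrt(Matrix::colMeans(X^2) - Matrix::colMeans(X)^2)
      score <- abs(as.numeric(Matrix::crossprod(X, r)))
      score[sds > 0] <- score[sds > 0] / sds[sds > 0]
      score[sds == 0] <- 0
      lambda_max <- max(score) / n
      lam <- if (spec$lambda >= lambda_max) {
        spec$lambda
      } else {
        exp(seq(log(lambda_max), log(spec$lambda), length.out = 10L))
      }
      glmnet::glmnet(x = X, y = yf, family = "binomial", alpha = 1,
                     lambda = lam, standardize = TRUE,
                     maxit = spec$max_iter * 100L,
                     thresh = min(spec$tol, 1e-7))
    },
    knn = {
      Xd <- as.matrix(X)
      ctr <- colMeans(Xd)
      scl <- apply(Xd, 2L, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      list(X = scale(Xd, center = ctr, scale = scl), y = y, k = spec$k,
           center = ctr, scale = scl)
    },
    cart = {
      df <- cart_frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = if (spec$split_criterion == "gini")
                     "gini" else "information"),
                   control = rpart::rpart.control(
                     minbucket = spec$min_bucket,
                     minsplit = max(2L, 2L * spec$min_bucket),
                     maxdepth = spec$max_depth, cp = 0, xval = 0))
    },
    rf = {
      df <- cart_frame(X)
      with_preserved_seed(spec$seed,
        randomForest::randomForest(x = df, y = factor(y, levels = c(0, 1)),
                                   ntree = spec$n_trees))
    },
    rnn = stop("use train_rnn_document_model() for the rnn kind"))
  structure(list(spec = spec, fit = fit, n_features = ncol(X)),
            class = "trained_model")
}

cart_frame <- function(X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df
}

#' Predict class probabilities
#'
#' @param model A `trained_model` from [train_classifier()] or
#'   [train_rnn_document_model()].
#' @param X Feature matrix matching the model's feature contract; for
#'   `rnn` models, a list of `token_doc` objects instead.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  if (model$spec$kind == "rnn") return(predict_proba_rnn(model, X))
  X <- as_feature_matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature width mismatch: model expects ", model$n_features,
         ", got ", ncol(X))
  }
  p <- switch(model$spec$kind,
    logreg_l1 = as.numeric(predict(model$fit, newx = X, type = "response",
                                   s = model$spec$lambda)),
    knn = knn_predict(model$fit, as.matrix(X)),
    cart = {
      pr <- predict(model$fit, newdata = cart_frame(X), type = "prob")
      as.numeric(pr[, "1"])
    },
    rf = {
      # vote fractions: each of the n_trees trees casts one class vote
      pr <- predict(model$fit, newdata = cart_frame(X), type = "prob")
      as.numeric(pr[, "1"])
    })
  stopifnot(all(p >= 0 & p <= 1))
  p
}

knn_predict <- function(fit, Xnew) {
  Xs <- scale(Xnew, center = fit$center, scale = fit$scale)
  k <- min(fit$k, nrow(fit$X))
  tr <- fit$X
  tr_sq <- rowSums(tr^2)
  apply(Xs, 1L, function(q) {
    d2 <- tr_sq - 2 * as.numeric(tr %*% q) + sum(q^2)
    # ties in distance break deterministically by training-row order
    nn <- order(d2, seq_along(d2), method = "radix")[seq_len(k)]
    mean(fit$y[nn])
  })
}

#' Stratified cross-validation fold assignment
#'
#' @param y Binary labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
make_cv_folds <- function(y, folds = 10L, seed = 1L) {
  y <- as.integer(y)
  if (folds > length(y)) stop("more folds than observations")
  if (folds > min(table(y))) {
    stop("folds exceed the minority-class count (", min(table(y)), ")")
  }
  fold <- integer(length(y))
  with_preserved_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG stream.
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Grid search with stratified k-fold cross-validation
#'
#' Evaluates every candidate spec by mean validation AUC over stratified
#' folds and returns the best. Ties (within `1e-12`) go to the simpler
#' spec: larger `lambda`, smaller `max_depth` (then larger `min_bucket`),
#' or smaller `k`.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param spec_grid Non-empty list of [classifier_spec()] objects.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `best_spec`, `best_score`, and `cv_table` (a tibble
#'   of per-spec mean/sd validation AUC).
#' @export
grid_search_cv <- function(X, y, spec_grid, folds = 10L, seed = 1L) {
  if (!length(spec_grid)) stop("empty specification grid")
  X <- as_feature_matrix(X)
  y <- check_training_inputs(X, y)
  fold <- make_cv_folds(y, folds = folds, seed = seed)
  scores <- matrix(NA_real_, nrow = length(spec_grid), ncol = folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (s in seq_along(spec_grid)) {
      m <- train_classifier(X[tr, , drop = FALSE], y[tr], spec_grid[[s]])
      p <- predict_proba(m, X[!tr, , drop = FALSE])
      scores[s, f] <- roc_and_auc(y[!tr], p)$auc
    }
  }
  mean_auc <- rowMeans(scores)
  simp <- vapply(spec_grid, simplicity_key, numeric(1))
  ord <- order(-round(mean_auc, 12), simp, seq_along(spec_grid))
  best <- ord[1L]
  cv_table <- tibble::tibble(
    spec_id = seq_along(spec_grid),
    kind = vapply(spec_grid, `[[`, character(1), "kind"),
    params = vapply(spec_grid, function(s) {
      flds <- s[setdiff(names(s), "kind")]
      paste(names(flds), unlist(flds), sep = "=", collapse = ",")
    }, character(1)),
    mean_auc = mean_auc,
    sd_auc = apply(scores, 1L, stats::sd))
  list(best_spec = spec_grid[[best]], best_score = mean_auc[best],
       cv_table = cv_table)
}

# Lower = simpler; used only to break CV-score ties within a kind.
simplicity_key <- function(spec) {
  switch(spec$kind,
    logreg_l1 = -spec$lambda,
    knn = spec$k,
    cart = spec$max_depth * 100 - spec$min_bucket,
    rf = spec$n_trees,
    rnn = spec$word_hidden + spec$sent_hidden,
    0)
}

#' Default tuning grids
#'
#' Candidate grids for [grid_search_cv()]: the k-NN neighbour counts
#' \{5, 10, 15, 20\}, tree depth/bucket combinations over 1..10, and a
#' logarithmic lasso-penalty ladder.
#'
#' @param kind Classifier kind.
#' @param seed Seed stored in specs that need one.
#' @return List of [classifier_spec()] objects.
#' @export
default_spec_grid <- function(kind = c("logreg_l1", "knn", "cart", "rf"),
                              seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    logreg_l1 = lapply(10^seq(-4, -1, by = 1),
                       function(l) classifier_spec("logreg_l1", lambda = l)),
    knn = lapply(c(5L, 10L, 15L, 20L),
                 function(k) classifier_spec("knn", k = k)),
    cart = {
      grid <- expand.grid(min_bucket = c(1L, 5L, 10L),
                          max_depth = c(2L, 5L, 10L))
      lapply(seq_len(nrow(grid)), function(i) {
        classifier_spec("cart", min_bucket = grid$min_bucket[i],
                        max_depth = grid$max_depth[i])
      })
    },
    rf = list(classifier_spec("rf", seed = seed)))
}

#' Count nonzero coefficients of a lasso logistic model
#'
#' @param model A trained `logreg_l1` model.
#' @return Number of nonzero (non-intercept) coefficients.
#' @export
n_nonzero_coef <- function(model) {
  stopifnot(inherits(model, "trained_model"), model$spec$kind == "logreg_l1")
  cf <- as.numeric(glmnet::coef.glmnet(model$fit, s = model$spec$lambda))[-1L]
  sum(cf != 0)
}
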