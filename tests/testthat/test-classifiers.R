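simulate_features <- function(n, separation = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- cbind(rnorm(n, mean = separation * y), rnorm(n))
    colnames(X) <- c("signal", "noise")
    list(X = X, y = y)
  })
}

test_that("lasso logistic regression separates planted signal", {
  d <- simulate_features(400, separation = 4, seed = 2)
  tr <- seq_len(200)
  m <- train_classifier(d$X[tr, ], d$y[tr], classifier_spec("logreg_l1"))
  p <- predict_proba(m, d$X[-tr, ])
  expect_gte(roc_and_auc(d$y[-tr], p)$auc, 0.99)
})

test_that("null features give chance-level held-out AUC", {
  withr::with_seed(9, {
    y <- rbinom(1000, 1, 0.5)
    X <- matrix(rnorm(2000), ncol = 2)
  })
  tr <- seq_len(500)
  m <- train_classifier(X[tr, ], y[tr], classifier_spec("logreg_l1",
                                                        lambda = 1e-4))
  auc <- roc_and_auc(y[-tr], predict_proba(m, X[-tr, ]))$auc
  expect_gt(auc, 0.40)
  expect_lt(auc, 0.60)
})

test_that("1-nearest-neighbour reproduces training labels", {
  d <- simulate_features(60, separation = 1, seed = 3)
  m <- train_classifier(d$X, d$y, classifier_spec("knn", k = 1))
  expect_equal(predict_proba(m, d$X), as.numeric(d$y))
})

test_that("knn probability is the neighbour vote fraction", {
  X <- matrix(c(0, 0, 0.1, 10), ncol = 1)
  y <- c(1, 1, 0, 0)
  m <- train_classifier(X, y, classifier_spec("knn", k = 3))
  # neighbours of a point at 0: the three nearby rows with labels 1,1,0
  expect_equal(predict_proba(m, matrix(0.01, 1, 1)), 2 / 3)
})

test_that("cart emits leaf purity as probability", {
  # one binary feature; right branch holds 3 positives and 1 negative
  X <- matrix(c(rep(0, 4), rep(1, 4)), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1, 1, 0)
  m <- train_classifier(X, y, classifier_spec("cart", min_bucket = 1,
                                              max_depth = 1))
  p <- predict_proba(m, X)
  expect_equal(p[5:8], rep(0.75, 4))
  expect_equal(p[1:4], rep(0.25, 4))
})

test_that("cart depth 1 recovers the informative feature across seeds", {
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(s, {
      y <- rep(0:1, each = 30)
      X <- cbind(inf = y + rnorm(60, sd = 0.3),
                 junk1 = rnorm(60), junk2 = rnorm(60))
    })
    m <- train_classifier(X, y, classifier_spec("cart", min_bucket = 5,
                                                max_depth = 1))
    if (as.character(m$fit$frame$var[1]) == "f1") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("random forest probabilities are vote fractions over 200 trees", {
  d <- simulate_features(120, separation = 2, seed = 4)
  spec <- classifier_spec("rf", seed = 11)
  m <- train_classifier(d$X, d$y, spec)
  p <- predict_proba(m, d$X)
  expect_true(all(abs(p * 200 - round(p * 200)) < 1e-9))
  # deterministic under the spec seed
  m2 <- train_classifier(d$X, d$y, spec)
  expect_identical(p, predict_proba(m2, d$X))
})

test_that("an all-shrunk lasso model predicts the intercept alone", {
  d <- simulate_features(100, separation = 1, seed = 5)
  m <- train_classifier(d$X, d$y, classifier_spec("logreg_l1", lambda = 5))
  expect_equal(n_nonzero_coef(m), 0L)
  expect_equal(predict_proba(m, d$X), rep(0.5, 100), tolerance = 1e-6)
})

test_that("lasso sparsity is monotone non-increasing in lambda", {
  d <- simulate_features(200, separation = 1.5, seed = 6)
  nz <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(l) {
    n_nonzero_coef(train_classifier(d$X, d$y,
                                    classifier_spec("logreg_l1", lambda = l)))
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(train_classifier(X, rep(1, 10), classifier_spec("knn")),
               "single class")
  expect_error(train_classifier(X, rep(0:1, 3), classifier_spec("knn")),
               "nrow")
  Xn <- X; Xn[1] <- NaN
  expect_error(train_classifier(Xn, rep(0:1, 5), classifier_spec("knn")),
               "NaN")
  m <- train_classifier(X, rep(0:1, 5), classifier_spec("knn", k = 3))
  expect_error(predict_proba(m, matrix(0, 2, 3)), "width mismatch")
})

test_that("classifier_spec validates fields and ranges", {
  expect_error(classifier_spec("cart", max_depth = 11), "max_depth")
  expect_error(classifier_spec("logreg_l1", k = 3), "unknown field")
  expect_error(classifier_spec("knn", k = 0), "k")
})

test_that("grid search matches brute-force fold recomputation", {
  d <- simulate_features(120, separation = 1, seed = 7)
  grid <- default_spec_grid("knn")
  gs <- grid_search_cv(d$X, d$y, grid, folds = 5, seed = 3)
  # oracle: recompute every spec's mean validation AUC over the same folds
  fold <- make_cv_folds(d$y, folds = 5, seed = 3)
  oracle <- vapply(grid, function(spec) {
    mean(vapply(1:5, function(f) {
      m <- train_classifier(d$X[fold != f, ], d$y[fold != f], spec)
      roc_and_auc(d$y[fold == f],
                  predict_proba(m, d$X[fold == f, ]))$auc
    }, numeric(1)))
  }, numeric(1))
  expect_equal(gs$cv_table$mean_auc, oracle)
  ks <- vapply(grid, `[[`, numeric(1), "k")
  best_oracle <- ks[order(-round(oracle, 12), ks)][1]
  expect_equal(gs$best_spec$k, best_oracle)
})

test_that("grid search handles singleton grids and bad fold counts", {
  d <- simulate_features(40, seed = 8)
  single <- list(classifier_spec("knn", k = 3))
  gs <- grid_search_cv(d$X, d$y, single, folds = 4, seed = 1)
  expect_identical(gs$best_spec, single[[1]])
  expect_true(is.finite(gs$best_score))
  expect_error(grid_search_cv(d$X, d$y, single, folds = 50), "folds")
  expect_error(grid_search_cv(d$X, d$y, list(), folds = 4), "empty")
})
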