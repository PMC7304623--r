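test_that("co-occurrence counts follow harmonic window weighting", {
  docs <- toy_corpus("a b")
  vocab <- fit_vocabulary(docs)
  X <- build_cooccurrence(docs, vocab, window = 10)$X
  expect_equal(X["a", "b"], 1.0)
  expect_equal(X["b", "a"], 1.0)

  docs3 <- toy_corpus("a b c")
  v3 <- fit_vocabulary(docs3)
  X3 <- build_cooccurrence(docs3, v3, window = 10)$X
  expect_equal(X3["a", "b"], 1.0)
  expect_equal(X3["b", "c"], 1.0)
  expect_equal(X3["a", "c"], 0.5)
  expect_true(all(Matrix::diag(X3) == 0))

  # empty corpus against an existing vocabulary: all-zero matrix
  X0 <- build_cooccurrence(list(), v3, window = 10)$X
  expect_equal(Matrix::nnzero(X0), 0L)
})

test_that("sentence boundaries block co-occurrence unless spanned", {
  docs <- list(toy_doc(list(c("a", "b"), c("c", "d"))))
  vocab <- fit_vocabulary(docs)
  X <- build_cooccurrence(docs, vocab, window = 10)$X
  expect_equal(X["b", "c"], 0)
  Xs <- build_cooccurrence(docs, vocab, window = 10, span_sentences = TRUE)$X
  expect_equal(Xs["b", "c"], 1.0)
})

test_that("co-occurrence is symmetric with brute-force total mass", {
  set.seed(31)
  for (rep in 1:5) {
    n_tok <- sample(20:60, 1)
    sents <- split(sample(letters[1:8], n_tok, replace = TRUE),
                   rep(1:4, length.out = n_tok))
    docs <- list(toy_doc(unname(sents)))
    vocab <- fit_vocabulary(docs)
    window <- sample(2:6, 1)
    X <- build_cooccurrence(docs, vocab, window = window)$X
    expect_equal(as.matrix(X), t(as.matrix(X)))
    expect_equal(sum(X), 2 * cooc_mass_bruteforce(docs, vocab, window),
                 tolerance = 1e-12)
  }
})

test_that("glove training is seeded, loss-decreasing and refuses empty mass", {
  docs <- corpus_docs(generate_embedding_corpus(
    synthetic_corpus_spec(n_docs = 40, seed = 2)))
  vocab <- fit_vocabulary(docs)
  cooc <- build_cooccurrence(docs, vocab, window = 10)
  cfg <- glove_config(d = 20, iters = 15, seed = 5)
  m1 <- train_glove(cooc, cfg)
  m2 <- train_glove(cooc, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$W, m2$W)
  expect_length(m1$loss_history, 15L)
  expect_lt(m1$loss_history[15], m1$loss_history[1])
  expect_true(all(is.finite(m1$W)))

  m0 <- train_glove(cooc, glove_config(d = 20, iters = 0, seed = 5))
  expect_length(m0$loss_history, 0L)
  # the no-op schedule leaves the seeded initialisation untouched
  expect_identical(m0$W, train_glove(cooc, glove_config(d = 20, iters = 0,
                                                        seed = 5))$W)
  expect_false(identical(m0$W, m1$W))

  empty <- cooc
  empty$X <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = dim(cooc$X),
                                  dimnames = dimnames(cooc$X))
  expect_error(train_glove(empty, cfg), "no co-occurrence mass")
})

test_that("exported vectors are the sum of main and context vectors", {
  docs <- toy_corpus(c("a b a b", "b a b a"))
  vocab <- fit_vocabulary(docs)
  cooc <- build_cooccurrence(docs, vocab, window = 3)
  model <- train_glove(cooc, glove_config(d = 7, iters = 3, seed = 1))
  emb <- export_embeddings(model)
  expect_equal(unname(emb), unname(model$W + model$W_context))
  expect_equal(ncol(emb), 7L)
  expect_identical(rownames(emb), vocab$tokens)
  # and it round-trips through the embedding file formats
  path <- withr::local_tempfile(fileext = ".csv")
  write_embeddings(emb, path, "csv")
  expect_lt(max(abs(read_embeddings(path, "csv") - emb)), 1e-10)
})

test_that("nearest neighbours rank by cosine with lexicographic ties", {
  emb <- rbind(a = c(1, 0, 0), b = c(0.9, 0.1, 0), c = c(0, 1, 0),
               d = c(0, 0, 1))
  nn <- nearest_neighbors(emb, "a", 3)
  # brute-force cosine ranking against all other tokens
  cs <- apply(emb[c("b", "c", "d"), ], 1,
              function(v) sum(v * emb["a", ]) /
                sqrt(sum(v^2) * sum(emb["a", ]^2)))
  expect_identical(nn$token, names(sort(-cs)))
  expect_equal(nn$cosine, unname(sort(cs, decreasing = TRUE)))
  # ties break lexicographically
  emb2 <- rbind(a = c(1, 0), d = c(2, 0), b = c(3, 0))
  expect_identical(nearest_neighbors(emb2, "a", 2)$token, c("b", "d"))
  expect_error(nearest_neighbors(emb, "zzz", 2), "unknown token")
  expect_error(nearest_neighbors(emb, "a", 4), "smaller")
})

test_that("planted synonyms are recovered with clear cosine separation", {
  spec <- synthetic_corpus_spec(n_docs = 150, seed = 77)
  docs <- corpus_docs(generate_embedding_corpus(spec))
  emb <- train_embeddings(docs, glove_config(seed = 77))
  gap <- synonym_cosine_gap(emb, spec$synonym_pairs)
  expect_gte(gap$gap, 0.2)
  # a pair member's nearest neighbour is its partner
  expect_identical(nearest_neighbors(emb, "stroke", 1)$token, "infarct")
})
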