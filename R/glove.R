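#' GloVe training configuration
#'
#' Defaults follow the settings used to train the package's reference
#' neuroradiology embeddings: 100-dimensional vectors, 50 training epochs,
#' a symmetric window of 10 tokens and an initial learning rate of 0.05.
#' The weighting cap `x_max = 100` and exponent `alpha = 0.75` are the
#' canonical choices for the weighted-least-squares objective.
#'
#' @param d Embedding dimension (>= 1).
#' @param iters Training epochs (>= 0); each epoch visits every nonzero
#'   co-occurrence once in a freshly shuffled order.
#' @param window Context size in tokens on each side of the centre word.
#' @param lr Initial AdaGrad learning rate (> 0).
#' @param x_max Co-occurrence cap of the loss weighting function.
#' @param alpha Weighting exponent, in (0, 1].
#' @param seed Integer seed for initialisation and epoch shuffling.
#' @return A `glove_config` list.
#' @export
glove_config <- function(d = 100L, iters = 50L, window = 10L, lr = 0.05,
                         x_max = 100, alpha = 0.75, seed = 1L) {
  stopifnot(d >= 1L, iters >= 0L, window >= 1L, lr > 0,
            alpha > 0, alpha <= 1, x_max > 0)
  structure(list(d = as.integer(d), iters = as.integer(iters),
                 window = as.integer(window), lr = lr, x_max = x_max,
                 alpha = alpha, seed = as.integer(seed)),
            class = "glove_config")
}

#' Build a co-occurrence matrix
#'
#' Accumulates symmetric, harmonically weighted co-occurrence counts: each
#' ordered pair of distinct in-vocabulary tokens at distance `k <= window`
#' within the same sentence contributes `1/k` to both `X[i, j]` and
#' `X[j, i]`. Out-of-vocabulary tokens still occupy positions (distances
#' are counted on the original token sequence) but contribute no mass, and
#' the diagonal is zero. Sentence boundaries block co-occurrence unless
#' `span_sentences = TRUE`, in which case each document is treated as one
#' uninterrupted sequence.
#'
#' @param corpus List of `token_doc` objects.
#' @param vocab Vocabulary fitted on the corpus.
#' @param window Context size in tokens.
#' @param span_sentences Allow windows to cross sentence ends.
#' @return A `cooccurrence` object: list with `vocab` and `X` (sparse
#'   symmetric `dgCMatrix`, V x V).
#' @export
build_cooccurrence <- function(corpus, vocab, window = 10L,
                               span_sentences = FALSE) {
  stopifnot(inherits(vocab, "vocabulary"), window >= 1L)
  seqs <- list()
  for (doc in corpus) {
    sents <- doc$sentences
    if (span_sentences) sents <- list(unlist(sents, use.names = FALSE))
    for (s in sents) {
      idx <- vocab$index[s]
      idx[is.na(idx)] <- 0L
      seqs[[length(seqs) + 1L]] <- as.integer(idx)
    }
  }
  V <- length(vocab$tokens)
  trip <- cooc_accumulate(seqs, as.integer(window))
  X <- Matrix::sparseMatrix(i = c(trip$i, trip$j), j = c(trip$j, trip$i),
                            x = c(trip$x, trip$x), dims = c(V, V),
                            dimnames = list(vocab$tokens, vocab$tokens))
  structure(list(vocab = vocab, X = X), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("<cooccurrence>", nrow(x$X), "x", ncol(x$X), "tokens,",
      Matrix::nnzero(x$X), "nonzero entries, total mass",
      format(sum(x$X), digits = 6), "\n")
  invisible(x)
}

#' Train GloVe embeddings from a co-occurrence matrix
#'
#' Fits main and context vectors plus biases by AdaGrad stochastic descent
#' on the weighted least-squares objective
#' `sum f(X_ij) (w_i . w~_j + b_i + b~_j - ln X_ij)^2` over nonzero
#' entries, with `f(x) = (x/x_max)^alpha` capped at 1. Parameters are
#' initialised uniformly in `(-0.5/d, 0.5/d)` from `cfg$seed`, and nonzero
#' entries are visited in a reshuffled order each epoch; the total weighted
#' loss per epoch is recorded. Runs with the same seed and corpus are
#' bitwise reproducible.
#'
#' @param cooc A [build_cooccurrence()] result with at least one nonzero.
#' @param cfg A [glove_config()].
#' @return A `glove_model`: list with `W`, `W_context` (V x d, tokens as
#'   rownames), `b`, `b_context`, `loss_history` (length `iters`) and
#'   `config`.
#' @export
train_glove <- function(cooc, cfg = glove_config()) {
  stopifnot(inherits(cooc, "cooccurrence"), inherits(cfg, "glove_config"))
  tr <- Matrix::summary(methods::as(cooc$X, "TsparseMatrix"))
  tr <- tr[tr$x > 0, , drop = FALSE]
  if (!nrow(tr)) stop("no co-occurrence mass")
  V <- nrow(cooc$X)
  fit <- glove_train_cpp(as.integer(tr$i), as.integer(tr$j), as.numeric(tr$x),
                         V, cfg$d, cfg$iters, cfg$lr, cfg$x_max, cfg$alpha,
                         cfg$seed)
  rownames(fit$W) <- rownames(fit$W_context) <- cooc$vocab$tokens
  structure(list(W = fit$W, W_context = fit$W_context, b = fit$b,
                 b_context = fit$b_context,
                 loss_history = as.numeric(fit$loss_history), config = cfg),
            class = "glove_model")
}

#' @export
print.glove_model <- function(x, ...) {
  cat("<glove_model>", nrow(x$W), "tokens x", ncol(x$W), "dims,",
      length(x$loss_history), "epoch(s)")
  if (length(x$loss_history)) {
    cat("; final loss",
        format(x$loss_history[length(x$loss_history)], digits = 6))
  }
  cat("\n")
  invisible(x)
}

#' Export embeddings from a trained model
#'
#' The exported vector for each token is the sum of its main and context
#' vectors, `w_i + w~_i` — the usual choice, which slightly improves
#' downstream quality over either matrix alone.
#'
#' @param model A [train_glove()] result.
#' @return Numeric matrix (tokens x d) with tokens as rownames.
#' @export
export_embeddings <- function(model) {
  stopifnot(inherits(model, "glove_model"))
  out <- model$W + model$W_context
  colnames(out) <- paste0("d", seq_len(ncol(out)))
  out
}

#' Train embeddings from a corpus in one call
#'
#' Convenience wrapper chaining [fit_vocabulary()], [build_cooccurrence()]
#' and [train_glove()], returning the exported embedding matrix.
#'
#' @param corpus List of `token_doc` objects.
#' @param cfg A [glove_config()]; its `window` is used for co-occurrence.
#' @param min_df Minimum document frequency for the vocabulary.
#' @param span_sentences See [build_cooccurrence()].
#' @return Embedding matrix (tokens x d), with the fitted model in
#'   `attr(, "model")`.
#' @export
train_embeddings <- function(corpus, cfg = glove_config(), min_df = 1L,
                             span_sentences = FALSE) {
  vocab <- fit_vocabulary(corpus, min_df = min_df)
  cooc <- build_cooccurrence(corpus, vocab, window = cfg$window,
                             span_sentences = span_sentences)
  model <- train_glove(cooc, cfg)
  emb <- export_embeddings(model)
  attr(emb, "model") <- model
  emb
}

#' Nearest neighbours in embedding space
#'
#' Ranks all other vocabulary tokens by cosine similarity to the query
#' token, ties broken lexicographically; the query itself is excluded.
#'
#' @param emb Embedding matrix (tokens as rownames).
#' @param token Query token; must be in the vocabulary.
#' @param k Number of neighbours, `k < nrow(emb)`.
#' @return Tibble with columns `token` and `cosine`, in descending order.
#' @export
nearest_neighbors <- function(emb, token, k = 5L) {
  stopifnot(is.matrix(emb))
  if (!token %in% rownames(emb)) stop("unknown token: ", token)
  if (k >= nrow(emb)) stop("k must be smaller than the vocabulary size")
  sims <- cosine_to(emb, emb[token, ])
  sims <- sims[setdiff(names(sims), token)]
  ord <- order(-sims, names(sims), method = "radix")
  tibble::tibble(token = names(sims)[ord][seq_len(k)],
                 cosine = unname(sims[ord][seq_len(k)]))
}

cosine_to <- function(emb, v) {
  nv <- sqrt(sum(v^2))
  nr <- sqrt(rowSums(emb^2))
  denom <- nr * nv
  out <- as.numeric(emb %*% v)
  out <- ifelse(denom > 0, out / denom, 0)
  names(out) <- rownames(emb)
  out
}

#' Cosine separation of planted synonym pairs
#'
#' Diagnostic used to judge embedding quality on corpora with known
#' synonym structure: the mean cosine similarity within the given pairs
#' minus the mean cosine across tokens of different pairs. Larger is
#' better; a well-trained embedding on a corpus whose pair members occupy
#' interchangeable contexts should separate clearly.
#'
#' @param emb Embedding matrix.
#' @param pairs List of length-2 character vectors.
#' @return List with `within` (mean within-pair cosine), `across` (mean
#'   across-pair cosine) and `gap` (their difference).
#' @export
synonym_cosine_gap <- function(emb, pairs) {
  stopifnot(length(pairs) >= 2L)
  toks <- unlist(pairs)
  if (!all(toks %in% rownames(emb))) {
    stop("pair token(s) missing from embedding: ",
         paste(setdiff(toks, rownames(emb)), collapse = ", "))
  }
  cos1 <- function(a, b) {
    va <- emb[a, ]; vb <- emb[b, ]
    sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  }
  within <- mean(vapply(pairs, function(p) cos1(p[1], p[2]), numeric(1)))
  across <- c()
  for (i in seq_along(pairs)) {
    for (j in seq_along(pairs)) {
      if (i < j) {
        for (a in pairs[[i]]) for (b in pairs[[j]]) {
          across <- c(across, cos1(a, b))
        }
      }
    }
  }
  list(within = within, across = mean(across), gap = within - mean(across))
}
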