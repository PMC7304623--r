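#' Fit a vocabulary on a training corpus
#'
#' Builds the token-to-column map used by bag-of-words and tf-idf
#' featurization, together with the per-token document frequencies needed
#' for inverse-document-frequency weighting. The vocabulary must be fitted
#' on the training split only; document frequencies at test time always
#' refer back to the training corpus.
#'
#' @param docs List of `token_doc` objects (see [preprocess_reports()]).
#' @param min_df Minimum number of documents a token must appear in
#'   (default 1).
#' @param on_empty What to do when no token satisfies `min_df`:
#'   `"error"` (default) or `"allow"` (empty vocabulary).
#' @return An object of class `vocabulary`: list with `tokens`
#'   (lexicographically sorted), `index` (named integer, dense 1..V),
#'   `df` (named integer document frequencies) and `n_docs`.
#' @export
fit_vocabulary <- function(docs, min_df = 1L, on_empty = c("error", "allow")) {
  on_empty <- match.arg(on_empty)
  if (!length(docs)) stop("cannot fit a vocabulary on an empty corpus")
  stopifnot(min_df >= 1L)
  per_doc <- lapply(docs, function(d) unique(doc_tokens(d)))
  df_tab <- table(unlist(per_doc, use.names = FALSE))
  keep <- names(df_tab)[df_tab >= min_df]
  if (!length(keep) && on_empty == "error") {
    stop("no token reaches min_df = ", min_df,
         " across ", length(docs), " document(s)")
  }
  tokens <- sort(keep, method = "radix")
  df <- as.integer(df_tab[tokens])
  names(df) <- tokens
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens),
                 df = df,
                 n_docs = length(docs)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary>", length(x$tokens), "token(s) over", x$n_docs,
      "training document(s)\n")
  invisible(x)
}

#' Bag-of-words count vector for one document
#'
#' Each entry is the absolute frequency of the corresponding vocabulary
#' token in the document; out-of-vocabulary tokens are ignored.
#'
#' @param doc A `token_doc`.
#' @param vocab A fitted [fit_vocabulary()] object.
#' @return Named integer vector of length `V` in vocabulary column order.
#' @export
bow_vector <- function(doc, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  v <- integer(length(vocab$tokens))
  names(v) <- vocab$tokens
  toks <- doc_tokens(doc)
  toks <- toks[toks %in% vocab$tokens]
  if (length(toks)) {
    tab <- table(toks)
    v[names(tab)] <- as.integer(tab)
  }
  v
}

#' Bag-of-words feature matrix
#'
#' @param docs List of `token_doc` objects.
#' @param vocab A fitted [fit_vocabulary()] object.
#' @return Sparse `dgCMatrix` (documents x vocabulary) of counts, with
#'   report ids as rownames and `attr(, "kind") == "bow"`.
#' @export
bow_matrix <- function(docs, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  V <- length(vocab$tokens)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(docs)) {
    toks <- doc_tokens(docs[[d]])
    idx <- vocab$index[toks]
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- table(idx)
      ii <- c(ii, rep.int(d, length(tab)))
      jj <- c(jj, as.integer(names(tab)))
      xx <- c(xx, as.integer(tab))
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                            dims = c(length(docs), V),
                            dimnames = list(doc_ids(docs), vocab$tokens))
  attr(m, "kind") <- "bow"
  m
}

#' Inverse document frequency weights of a vocabulary
#'
#' Smoothed idf: `ln((1 + N) / (1 + df)) + 1`, where `N` is the number of
#' training documents and `df` the training document frequency. A token
#' present in every training document gets weight exactly 1, so its tf-idf
#' value floors at the raw term frequency; rarer tokens are weighted up.
#'
#' @param vocab A fitted [fit_vocabulary()] object.
#' @return Named numeric vector of idf weights.
#' @export
idf_weights <- function(vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  w <- log((1 + vocab$n_docs) / (1 + vocab$df)) + 1
  names(w) <- vocab$tokens
  w
}

#' tf-idf feature matrix
#'
#' Re-weights bag-of-words counts by the relative importance of each token:
#' `value(d, t) = tf(d, t) * idf(t)` with the smoothed idf of
#' [idf_weights()]. Corpus-ubiquitous words (e.g. "is") are thereby
#' down-weighted relative to equally frequent rare words. No row
#' normalisation is applied unless `l2_normalize = TRUE`.
#'
#' @param docs List of `token_doc` objects to transform.
#' @param vocab Vocabulary fitted on the training corpus (carries `df`, `N`).
#' @param l2_normalize Scale each document row to unit Euclidean norm.
#' @return Sparse matrix with `attr(, "kind") == "tfidf"`.
#' @export
tfidf_matrix <- function(docs, vocab, l2_normalize = FALSE) {
  m <- bow_matrix(docs, vocab)
  m <- m %*% Matrix::Diagonal(x = idf_weights(vocab))
  if (l2_normalize) {
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / nrm) %*% m
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(doc_ids(docs), vocab$tokens)
  attr(m, "kind") <- "tfidf"
  m
}

#' Document embedding: sum of word vectors
#'
#' Summarises a document as the elementwise sum of the embedding vectors of
#' its in-vocabulary tokens. Out-of-vocabulary tokens contribute nothing;
#' an empty or all-OOV document maps to the zero vector. The sum is
#' invariant to token order.
#'
#' @param doc A `token_doc`.
#' @param emb Embedding matrix (tokens as rownames), e.g. from
#'   [read_embeddings()] or [export_embeddings()].
#' @return Numeric vector of length `ncol(emb)`.
#' @export
doc_embedding <- function(doc, emb) {
  stopifnot(is.matrix(emb), nrow(emb) >= 1L)
  toks <- doc_tokens(doc)
  idx <- match(toks, rownames(emb))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(numeric(ncol(emb)))
  colSums(emb[idx, , drop = FALSE])
}

#' Document-embedding feature matrix
#'
#' @param docs List of `token_doc` objects.
#' @param emb Embedding matrix (tokens as rownames).
#' @return Dense matrix (documents x embedding dimension) with
#'   `attr(, "kind") == "docvec"`.
#' @export
docvec_matrix <- function(docs, emb) {
  m <- t(vapply(docs, doc_embedding, numeric(ncol(emb)), emb = emb))
  dimnames(m) <- list(doc_ids(docs), colnames(emb))
  attr(m, "kind") <- "docvec"
  m
}

#' Write a feature matrix as TSV
#'
#' @param m Feature matrix (documents x features, rownames = report ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  dt <- data.table::as.data.table(as.matrix(m))
  dt <- cbind(data.table::data.table(report_id = rownames(m)), dt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

doc_ids <- function(docs) {
  vapply(docs, function(d) as.character(d$report_id %||% NA_character_),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
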