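#' Train the hierarchical LSTM document classifier
#'
#' Two stacked recurrent encoders: a word-level LSTM maps each sentence's
#' embedded token sequence to a sentence vector (its final hidden state),
#' and a sentence-level LSTM maps the sentence-vector sequence to a
#' document vector, which feeds an affine + logistic output head. The
#' model is trained by mini-batch Adam on log-loss with global-norm
#' gradient clipping; embedding rows are frozen throughout. All
#' randomness (weight initialisation, epoch shuffling) is derived from
#' `spec$seed`, so identical inputs give identical fits.
#'
#' @param docs List of `token_doc` objects (training documents).
#' @param emb Embedding matrix (tokens as rownames); tokens absent from it
#'   are dropped from the sequences. A warning is issued if fewer than 90%
#'   of documents retain at least one token.
#' @param y Binary 0/1 labels, one per document.
#' @param spec A [classifier_spec()] of kind `"rnn"`.
#' @return A `trained_model` whose fit holds the network weights, the
#'   embedding matrix and the per-epoch mean log-loss (`loss_history`).
#' @export
train_rnn_document_model <- function(docs, emb, y,
                                     spec = classifier_spec("rnn")) {
  stopifnot(inherits(spec, "classifier_spec"), spec$kind == "rnn",
            is.matrix(emb))
  if (!length(docs)) stop("empty corpus")
  y <- as.integer(y)
  if (length(y) != length(docs)) stop("length(y) must equal length(docs)")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  seqs <- docs_to_sequences(docs, emb)
  covered <- vapply(seqs, function(d) any(lengths(d) > 0L), logical(1))
  if (mean(covered) < 0.9) {
    warning("embedding covers at least one token of only ",
            round(100 * mean(covered)), "% of documents", call. = FALSE)
  }
  fit <- rnn_train_cpp(seqs, emb, as.numeric(y),
                       spec$word_hidden, spec$sent_hidden, spec$epochs,
                       spec$batch, spec$lr, clip = 5.0, seed = spec$seed)
  structure(list(spec = spec,
                 fit = list(params = fit[setdiff(names(fit), "loss_history")],
                            emb = emb,
                            loss_history = as.numeric(fit$loss_history)),
                 n_features = ncol(emb)),
            class = "trained_model")
}

predict_proba_rnn <- function(model, docs) {
  seqs <- docs_to_sequences(docs, model$fit$emb)
  p <- as.numeric(rnn_predict_cpp(seqs, model$fit$emb, model$fit$params))
  stopifnot(all(p >= 0 & p <= 1))
  p
}

# token_docs -> per-sentence integer row indices into emb; OOV dropped,
# sentences emptied by OOV removal dropped.
docs_to_sequences <- function(docs, emb) {
  toks <- rownames(emb)
  lapply(docs, function(d) {
    out <- lapply(d$sentences, function(s) {
      idx <- match(s, toks)
      as.integer(idx[!is.na(idx)])
    })
    out[lengths(out) > 0L]
  })
}
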