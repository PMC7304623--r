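# Shared fixture builders; everything is generated in code at test time.

# A token_doc from a list of sentences (character vectors of tokens).
toy_doc <- function(sentences, id = "doc1") {
  structure(list(report_id = id, sentences = sentences), class = "token_doc")
}

# token_docs straight from raw sentences of whitespace-separated tokens
toy_corpus <- function(texts, ids = sprintf("d%02d", seq_along(texts))) {
  mapply(function(txt, id) {
    toy_doc(lapply(strsplit(txt, "\\. ?")[[1]], function(s) {
      strsplit(trimws(s), "\\s+")[[1]]
    }), id = id)
  }, texts, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# small report/label CSV pair on disk; returns the two paths
write_report_fixture <- function(dir = NULL,
                                 texts = c("No acute infarct.",
                                           "Acute MCA infarct.",
                                           "Chronic infarct.")) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  n <- length(texts)
  reports <- tibble::tibble(
    report_id = sprintf("R%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    scan_type = rep_len(c("CT", "MRI", "CTA"), n),
    report_datetime = rep("2015-06-01 10:00:00", n),
    text = texts)
  labels <- tibble::tibble(report_id = reports$report_id,
                           stroke = rep_len(c(0L, 1L, 1L), n),
                           mca = rep_len(c(0L, 1L, 0L), n),
                           acute = rep_len(c(0L, 1L, 0L), n))
  rp <- file.path(dir, "reports.csv")
  lp <- file.path(dir, "labels.csv")
  data.table::fwrite(reports, rp, quote = TRUE)
  data.table::fwrite(labels, lp, quote = TRUE)
  list(reports = rp, labels = lp, dir = dir)
}

# Brute-force AUC over all positive-negative pairs, ties credited 1/2.
auc_bruteforce <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold search mirroring the sensitivity-first rule.
threshold_bruteforce <- function(y, p, min_sens = 0.9) {
  cand <- sort(unique(p), decreasing = TRUE)
  stats <- t(vapply(cand, function(t) {
    c(sens = mean(p[y == 1] >= t), spec = mean(p[y == 0] < t))
  }, numeric(2)))
  ok <- stats[, "sens"] >= min_sens
  if (!any(ok)) ok <- stats[, "sens"] == max(stats[, "sens"])
  idx <- which(ok)
  best <- idx[order(-stats[idx, "spec"], -cand[idx])][1]
  cand[best]
}

# Brute-force co-occurrence total mass: sum of 1/distance over all
# unordered in-window pairs of distinct in-vocabulary token types,
# counted within sentences.
cooc_mass_bruteforce <- function(docs, vocab, window) {
  total <- 0
  for (doc in docs) {
    for (s in doc$sentences) {
      known <- s %in% vocab$tokens
      n <- length(s)
      if (n < 2) next
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):min(n, i + window)) {
          if (known[i] && known[j] && s[i] != s[j]) {
            total <- total + 1 / (j - i)
          }
        }
      }
    }
  }
  total
}
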