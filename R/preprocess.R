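#' Default boilerplate patterns stripped from raw report text
#'
#' Case-insensitive regular expressions matching non-narrative header and
#' footer material commonly found in radiology reports (signatures,
#' accession lines, dictation stamps). Matched spans are replaced by a
#' space before any other normalisation. Sites with different templates
#' should extend or replace this list.
#'
#' @return Character vector of PCRE patterns.
#' @export
default_boilerplate_patterns <- function() {
  c(
    "electronically signed by[^.\n]*",
    "dictated by[^.\n]*",
    "transcribed by[^.\n]*",
    "accession (number|no)\\.?:?\\s*\\S+",
    "medical record (number|no)\\.?:?\\s*\\S+",
    "report (approved|finalized) (on|at)[^.\n]*"
  )
}

#' Default medical phrase lexicon
#'
#' Multi-word neurovascular phrases merged into single tokens before
#' featurization, so that e.g. "middle cerebral artery" behaves as one
#' vocabulary unit ("middlecerebralartery") rather than three. The set
#' covers arterial anatomy, vascular territories, diffusion/attenuation
#' terminology, and the frequent negation frame "no evidence of". It is a
#' starting point, not a closed list: pass a custom lexicon (two columns,
#' `phrase` and `token`) to extend it.
#'
#' @return A tibble with columns `phrase` (lowercase, space-separated) and
#'   `token` (the merged replacement, no spaces).
#' @export
default_phrase_lexicon <- function() {
  phrase <- c(
    "posterior inferior cerebellar artery",
    "anterior inferior cerebellar artery",
    "superior cerebellar artery",
    "middle cerebral artery",
    "anterior cerebral artery",
    "posterior cerebral artery",
    "internal carotid artery",
    "vertebral artery",
    "basilar artery",
    "mca territory",
    "aca territory",
    "pca territory",
    "apparent diffusion coefficient",
    "diffusion weighted imaging",
    "diffusion restriction",
    "restricted diffusion",
    "t2 prolongation",
    "flair hyperintensity",
    "grey white differentiation",
    "gray white differentiation",
    "grey white matter",
    "gray white matter",
    "no evidence of",
    "midline shift",
    "mass effect",
    "basal ganglia",
    "corona radiata",
    "centrum semiovale",
    "internal capsule",
    "posterior fossa",
    "watershed distribution",
    "hemorrhagic transformation",
    "large vessel occlusion",
    "small vessel disease",
    "low attenuation"
  )
  tibble::tibble(phrase = phrase, token = gsub(" ", "", phrase, fixed = TRUE))
}

#' Clean raw report text
#'
#' Normalises a raw report string: configurable boilerplate patterns are
#' removed, separator runs (three or more repeated punctuation marks such
#' as "= = = = = =") are dropped, the text is lowercased, punctuation is
#' replaced by spaces (sentence terminators `.` `!` `?` are retained so
#' that sentences can still be split downstream), and whitespace is
#' collapsed. Cleaning is idempotent; an empty result is legitimate.
#'
#' @param raw Character vector of raw report texts.
#' @param boilerplate Character vector of case-insensitive PCRE patterns to
#'   blank out first; defaults to [default_boilerplate_patterns()].
#' @return Character vector of cleaned, lowercased text.
#' @examples
#' clean_text("IMPRESSION:  Acute  infarct.")
#' @export
clean_text <- function(raw, boilerplate = default_boilerplate_patterns()) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  for (pat in boilerplate) {
    x <- gsub(pat, " ", x, perl = TRUE, ignore.case = TRUE)
  }
  # separator runs: the same punctuation mark >= 3 times, optionally spaced
  x <- gsub("([=\\-_*#~+])(\\s*\\1){2,}", " ", x, perl = TRUE)
  x <- tolower(x)
  # punctuation -> space, keeping sentence terminators for the splitter;
  # replacement (not deletion) prevents fusing words across artifacts
  x <- gsub("[^a-z0-9.!?]+", " ", x, perl = TRUE)
  # a terminator must end a token: "stroke.impression" -> "stroke. impression"
  x <- gsub("([.!?])(?=[a-z0-9])", "\\1 ", x, perl = TRUE)
  # strip terminators that do not follow a word character (e.g. ". . .")
  x <- gsub("(?<![a-z0-9])[.!?]", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Merge lexicon phrases into single tokens
#'
#' Replaces every occurrence of each lexicon phrase in already-cleaned,
#' lowercased text by its merged token. Matching is longest-phrase-first,
#' left-to-right and non-overlapping, on word boundaries.
#'
#' @param text Character vector of cleaned text (see [clean_text()]).
#' @param lexicon Data frame with columns `phrase` and `token`;
#'   defaults to [default_phrase_lexicon()].
#' @return Character vector with phrases merged.
#' @examples
#' merge_phrases("left middle cerebral artery stroke")
#' @export
merge_phrases <- function(text, lexicon = default_phrase_lexicon()) {
  stopifnot(all(c("phrase", "token") %in% names(lexicon)))
  if (any(grepl("[[:space:]]", lexicon$token))) {
    stop("lexicon merged tokens must not contain whitespace")
  }
  ord <- order(-lengths(strsplit(lexicon$phrase, " ", fixed = TRUE)),
               -nchar(lexicon$phrase))
  for (i in ord) {
    pat <- paste0("\\b", gsub("([][.\\\\+*?^$(){}|-])", "\\\\\\1",
                              lexicon$phrase[i], perl = TRUE), "\\b")
    text <- gsub(pat, lexicon$token[i], text, perl = TRUE)
  }
  text
}

#' Split cleaned text into sentences
#'
#' Splits on `.`, `!` or `?` followed by whitespace or end of string;
#' terminators are removed from the returned sentences and empty sentences
#' are dropped.
#'
#' @param text A single cleaned text string.
#' @return Character vector of sentences (possibly empty).
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  parts <- strsplit(text, "(?<=[.!?])\\s+|(?<=[.!?])$", perl = TRUE)[[1]]
  parts <- gsub("[.!?]+$", "", parts)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize a sentence
#'
#' Whitespace split after punctuation removal; merged n-gram tokens pass
#' through intact. Emitted tokens are lowercase and free of whitespace and
#' punctuation.
#'
#' @param sentence A single sentence string.
#' @return Character vector of tokens.
#' @export
tokenize <- function(sentence) {
  stopifnot(length(sentence) == 1L)
  if (is.na(sentence) || !nzchar(sentence)) return(character(0))
  toks <- strsplit(gsub("[.!?]", " ", sentence), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Preprocess one report text into a token document
#'
#' Runs the full normalisation chain — [clean_text()], [merge_phrases()],
#' [split_sentences()], [tokenize()] — and returns a token document: an
#' ordered list of sentences, each an ordered character vector of tokens.
#'
#' @param text Raw report text (single string).
#' @param report_id Identifier carried on the result.
#' @param lexicon Phrase lexicon, see [merge_phrases()].
#' @param boilerplate Boilerplate patterns, see [clean_text()].
#' @return An object of class `token_doc`: list with `report_id` and
#'   `sentences` (list of character vectors). `sentences` is empty only if
#'   the cleaned text was empty.
#' @export
preprocess_text <- function(text, report_id = NA_character_,
                            lexicon = default_phrase_lexicon(),
                            boilerplate = default_boilerplate_patterns()) {
  cleaned <- merge_phrases(clean_text(text, boilerplate), lexicon)
  sents <- lapply(split_sentences(cleaned), tokenize)
  sents <- sents[lengths(sents) > 0L]
  structure(list(report_id = report_id, sentences = sents),
            class = "token_doc")
}

#' Preprocess a report table into token documents
#'
#' @param reports Report tibble from [read_reports()] (or any data frame
#'   with `report_id` and `text` columns).
#' @inheritParams preprocess_text
#' @return Named list of `token_doc` objects, one per report, in input
#'   order; names are report ids.
#' @export
preprocess_reports <- function(reports,
                               lexicon = default_phrase_lexicon(),
                               boilerplate = default_boilerplate_patterns()) {
  stopifnot(all(c("report_id", "text") %in% names(reports)))
  docs <- mapply(preprocess_text, reports$text, reports$report_id,
                 MoreArgs = list(lexicon = lexicon, boilerplate = boilerplate),
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(docs) <- reports$report_id
  docs
}

#' @export
print.token_doc <- function(x, ...) {
  cat("<token_doc>", x$report_id, "-", length(x$sentences), "sentence(s),",
      sum(lengths(x$sentences)), "token(s)\n")
  invisible(x)
}

doc_tokens <- function(doc) unlist(doc$sentences, use.names = FALSE)
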