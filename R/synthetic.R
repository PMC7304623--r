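#' Synthetic report generator configuration
#'
#' The defaults mirror the derivation cohort the package's protocol was
#' designed around: 1,359 reports with stroke prevalence 925/1359,
#' MCA-territory involvement in 350/925 of strokes, acute findings in
#' 522/925, a scan mix of roughly two-thirds CT/CTA, and about 4.6
#' reports per patient. The remaining dials shape how hard the text is:
#' `negation_rate` controls how many stroke-negative reports carry
#' explicitly negated stroke language ("no evidence of acute infarct"),
#' `distractor_rate` how many reports carry chronic / small-vessel /
#' prior-scan phrasing that shares vocabulary with true strokes,
#' `label_noise` the per-label flip probability emulating imperfect
#' adjudication, and `template_jitter` the synonym-swap probability.
#'
#' @param n_reports Number of reports to generate.
#' @param p_stroke Stroke prevalence.
#' @param p_mca_given_stroke P(MCA territory | stroke).
#' @param p_acute_given_stroke P(acute | stroke).
#' @param negation_rate Fraction of stroke-negative reports with negated
#'   stroke phrases.
#' @param distractor_rate Fraction of reports with chronic/non-specific
#'   distractor phrasing.
#' @param label_noise Probability that each emitted label is flipped.
#' @param template_jitter Synonym-swap probability per sentence.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_reports = 1359L,
                             p_stroke = 925 / 1359,
                             p_mca_given_stroke = 350 / 925,
                             p_acute_given_stroke = 522 / 925,
                             negation_rate = 0.5,
                             distractor_rate = 0.3,
                             label_noise = 0.03,
                             template_jitter = 0.3,
                             seed = 1L) {
  probs <- c(p_stroke, p_mca_given_stroke, p_acute_given_stroke,
             negation_rate, distractor_rate, label_noise, template_jitter)
  stopifnot(n_reports >= 0L, all(probs >= 0), all(probs <= 1))
  structure(list(n_reports = as.integer(n_reports), p_stroke = p_stroke,
                 p_mca_given_stroke = p_mca_given_stroke,
                 p_acute_given_stroke = p_acute_given_stroke,
                 negation_rate = negation_rate,
                 distractor_rate = distractor_rate,
                 label_noise = label_noise,
                 template_jitter = template_jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate labelled synthetic neuroradiology reports
#'
#' Assembles each report from seeded templates — an exam header (with
#' occasional boilerplate and "= = = =" separator lines, so the cleaning
#' stage has something to do), a clinical history line, findings
#' sentences and an impression. Labels derive from the generating
#' template: acute strokes get modality-appropriate acute language
#' (restricted diffusion on MRI, hypodensity with loss of grey-white
#' differentiation on CT), chronic strokes get encephalomalacia /
#' prior-infarct language (stroke = 1, acute = 0), MCA-positive strokes
#' mention the MCA territory, and negatives are neutral or carry negated
#' stroke sentences at `negation_rate`. The pre-noise labels satisfy
#' `mca = 1 => stroke = 1` and `acute = 1 => stroke = 1`; `label_noise`
#' flips are applied afterwards and may break them, as real adjudicated
#' labels can.
#'
#' @param cfg A [generator_config()].
#' @return List with `reports` and `labels` tibbles in the formats of
#'   [read_reports()] and [read_labels()].
#' @export
generate_reports <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_reports
  empty <- list(
    reports = tibble::tibble(report_id = character(0),
                             patient_id = character(0),
                             scan_type = character(0),
                             report_datetime = as.POSIXct(character(0), tz = "UTC"),
                             text = character(0)),
    labels = tibble::tibble(report_id = character(0), stroke = integer(0),
                            mca = integer(0), acute = integer(0)))
  if (n == 0L) return(empty)
  with_preserved_seed(cfg$seed, {
    n_patients <- max(1L, round(n / 4.6))
    patient <- sprintf("P%04d", sample.int(n_patients, n, replace = TRUE))
    scan <- sample(c("CT", "CTA", "MRI", "MRA"), n, replace = TRUE,
                   prob = c(0.46, 0.19, 0.27, 0.08))
    stroke <- rbinom(n, 1L, cfg$p_stroke)
    mca <- ifelse(stroke == 1L, rbinom(n, 1L, cfg$p_mca_given_stroke), 0L)
    acute <- ifelse(stroke == 1L, rbinom(n, 1L, cfg$p_acute_given_stroke), 0L)
    when <- as.POSIXct("2003-01-01", tz = "UTC") +
      runif(n, 0, 16 * 365.25 * 86400)
    text <- character(n)
    for (i in seq_len(n)) {
      text[i] <- build_report_text(scan[i], stroke[i], mca[i], acute[i], cfg)
    }
    noisy <- function(lab) {
      flip <- rbinom(n, 1L, cfg$label_noise) == 1L
      as.integer(ifelse(flip, 1L - lab, lab))
    }
    list(reports = tibble::tibble(report_id = sprintf("R%05d", seq_len(n)),
                                  patient_id = patient, scan_type = scan,
                                  report_datetime = when, text = text),
         labels = tibble::tibble(report_id = sprintf("R%05d", seq_len(n)),
                                 stroke = noisy(stroke), mca = noisy(mca),
                                 acute = noisy(acute)))
  })
}

# --- template machinery ----------------------------------------------------

pick <- function(x) x[sample.int(length(x), 1L)]

jitter_sentence <- function(s, rate) {
  swaps <- c("infarct" = "infarction", "demonstrates" = "shows",
             "hypodensity" = "low attenuation", "unremarkable" = "normal",
             "consistent with" = "compatible with", "noted" = "identified")
  for (k in names(swaps)) {
    if (runif(1) < rate) s <- sub(k, swaps[[k]], s, fixed = TRUE)
  }
  s
}

build_report_text <- function(scan, stroke, mca, acute, cfg) {
  mri <- scan %in% c("MRI", "MRA")
  side <- pick(c("left", "right"))
  terr <- if (mca == 1L) {
    pick(c("MCA territory", "middle cerebral artery territory"))
  } else {
    pick(c("PCA territory", "ACA territory", "cerebellar hemisphere",
           "pons", "thalamus", "watershed distribution"))
  }
  terr <- paste(side, terr)
  neutral <- c(
    "The ventricles and sulci are normal in size and configuration.",
    "No midline shift or mass effect.",
    "The visualized paranasal sinuses are clear.",
    "Major intracranial flow voids are preserved.",
    "No extra axial fluid collection.",
    "The orbits are unremarkable.")
  findings <- sample(neutral, sample(2:3, 1L))
  # "subacute" is a relative term in dictated reports: labelers map it to
  # acute or chronic depending on surrounding context, so both acuity
  # classes use it and the acuity task is intrinsically harder than
  # presence or location
  subacute_wording <- stroke == 1L && runif(1) < 0.5
  if (subacute_wording) {
    # the ambiguous case: "subacute" wording is used identically whether
    # the stroke was adjudicated acute (within 7-10 days) or chronic, so
    # the text alone cannot resolve acuity for these reports
    findings <- c(paste0("There is a subacute appearing infarct in the ",
                         terr, "."), findings)
    impression <- paste0("IMPRESSION: Subacute infarct in the ", terr, ".")
  } else if (stroke == 1L && acute == 1L) {
    findings <- c(if (mri) {
      c(paste0("There is restricted diffusion in the ", terr,
               " consistent with acute infarct."),
        if (runif(1) < 0.5)
          "Apparent diffusion coefficient hypointensity without T2 prolongation is noted.")
    } else {
      c(paste0("There is a hypodensity in the ", terr,
               " with loss of grey white differentiation consistent with acute infarct."),
        if (runif(1) < 0.4) "Early sulcal effacement is noted.")
    }, findings)
    if (runif(1) < cfg$distractor_rate) {
      findings <- c(findings,
                    "There is also encephalomalacia from prior infarct.")
    }
    impression <- paste0("IMPRESSION: Acute infarct in the ", terr, ".")
  } else if (stroke == 1L) {
    # prior-scan re-descriptions keep affirmative acute wording in reports
    # whose findings are no longer acute — a classic adjudication trap
    findings <- c(if (runif(1) < cfg$distractor_rate) {
      paste0("Redemonstration of the acute infarct seen on the prior ",
             "examination in the ", terr, " with interval evolution.")
    } else {
      pick(c(
        paste0("Encephalomalacia in the ", terr,
               " consistent with chronic infarct."),
        paste0("Again seen is a chronic infarct in the ", terr,
               " noted on prior examination."),
        "Chronic lacunar infarct in the basal ganglia."))
    }, findings)
    impression <- paste0("IMPRESSION: Chronic infarct in the ", terr,
                         if (runif(1) < 0.5) " without acute changes." else ".")
  } else {
    if (runif(1) < cfg$distractor_rate) {
      findings <- c(findings, pick(c(
        "Mild chronic microvascular ischemic changes in the periventricular white matter.",
        "Scattered foci of small vessel disease.")))
    }
    if (runif(1) < cfg$negation_rate) {
      findings <- c(findings, if (mri) {
        "No restricted diffusion to suggest acute ischemia."
      } else {
        "No evidence of acute infarct or hemorrhage."
      })
      impression <- "IMPRESSION: No acute intracranial abnormality."
    } else {
      impression <- "IMPRESSION: Unremarkable examination."
    }
  }
  findings <- vapply(findings, jitter_sentence, character(1),
                     rate = cfg$template_jitter, USE.NAMES = FALSE)
  header <- c(
    paste0("EXAM: ", scan, " head. "),
    if (runif(1) < 0.5) "= = = = = = ",
    if (runif(1) < 0.4) paste0("Accession Number: ",
                               sample.int(899999L, 1L) + 100000L, ". "),
    paste0("CLINICAL HISTORY: ", sample(40:95, 1L), " year old with ",
           pick(c("right sided weakness", "left sided weakness", "aphasia",
                  "dizziness", "altered mental status", "headache",
                  "facial droop")), ". "))
  paste0(paste0(header, collapse = ""), paste(findings, collapse = " "),
         " ", impression)
}

#' Synthetic embedding-corpus specification
#'
#' Describes a corpus with planted synonym structure for testing the
#' embedding trainer: each synonym pair's members are generated in
#' identical context slots (shared sentence frames), while all other
#' tokens come from a Zipf-like background distribution. A trainer that
#' captures co-occurrence structure should therefore assign near-parallel
#' vectors within a pair and clearly less similar vectors across pairs.
#'
#' @param n_docs Number of documents.
#' @param vocab_size Total vocabulary size; must exceed twice the number
#'   of pairs.
#' @param synonym_pairs List of length-2 character vectors (disjoint).
#' @param seed Integer seed.
#' @return A `synthetic_corpus_spec` list.
#' @export
synthetic_corpus_spec <- function(n_docs = 200L, vocab_size = 100L,
                                  synonym_pairs = list(
                                    c("stroke", "infarct"),
                                    c("ct", "mri"),
                                    c("hypodensity", "hyperintensity")),
                                  seed = 1L) {
  toks <- unlist(synonym_pairs)
  stopifnot(n_docs >= 0L, length(toks) == length(unique(toks)),
            vocab_size > 2L * length(synonym_pairs),
            all(lengths(synonym_pairs) == 2L))
  structure(list(n_docs = as.integer(n_docs),
                 vocab_size = as.integer(vocab_size),
                 synonym_pairs = synonym_pairs, seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

#' Generate a plain-text corpus with planted synonyms
#'
#' Each document holds 5-10 sentences; roughly 60% are frame sentences in
#' which one synonym pair's slot is filled by either member with equal
#' probability (each pair owns its own context words), the rest are
#' background sentences drawn from a Zipf-like distribution over the
#' remaining vocabulary.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return Character vector of documents (one string each, sentences
#'   terminated by periods).
#' @export
generate_embedding_corpus <- function(spec = synthetic_corpus_spec()) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  if (spec$n_docs == 0L) return(character(0))
  with_preserved_seed(spec$seed, {
    n_pairs <- length(spec$synonym_pairs)
    n_extra <- spec$vocab_size - 2L * n_pairs
    stopifnot(n_extra > 6L * n_pairs)
    all_extra <- sprintf("w%03d", seq_len(n_extra))
    # each pair owns six context words that appear only in its frames;
    # the rest form the Zipf-distributed background
    ctx <- split(all_extra[seq_len(6L * n_pairs)],
                 rep(seq_len(n_pairs), each = 6L))
    bg <- all_extra[-seq_len(6L * n_pairs)]
    zipf <- (1 / seq_along(bg))^1.1
    zipf <- zipf / sum(zipf)
    frame_sentence <- function() {
      k <- sample.int(n_pairs, 1L)
      member <- pick(spec$synonym_pairs[[k]])
      cw <- ctx[[k]]
      paste(cw[1], cw[2], member, cw[3], cw[4], pick(cw[5:6]))
    }
    bg_sentence <- function() {
      paste(sample(bg, 8L, replace = TRUE, prob = zipf), collapse = " ")
    }
    vapply(seq_len(spec$n_docs), function(i) {
      n_sent <- sample(5:10, 1L)
      sents <- vapply(seq_len(n_sent), function(j) {
        if (runif(1) < 0.6) frame_sentence() else bg_sentence()
      }, character(1))
      paste0(paste(sents, collapse = ". "), ".")
    }, character(1))
  })
}

#' Convert plain-text documents to token documents
#'
#' Applies the standard cleaning chain to free text that is not a report
#' table (e.g. an embedding-training corpus, one document per element).
#'
#' @param texts Character vector of documents.
#' @param lexicon Optional phrase lexicon; `NULL` (default) skips phrase
#'   merging.
#' @return List of `token_doc` objects.
#' @export
corpus_docs <- function(texts, lexicon = NULL) {
  if (is.null(lexicon)) {
    lexicon <- tibble::tibble(phrase = character(0), token = character(0))
  }
  lapply(seq_along(texts), function(i) {
    preprocess_text(texts[i], report_id = sprintf("D%05d", i),
                    lexicon = lexicon, boilerplate = character(0))
  })
}

#' Read a plain-text corpus file (one document per line)
#'
#' @param path Path to a text file.
#' @param lexicon Optional phrase lexicon, see [corpus_docs()].
#' @return List of `token_doc` objects.
#' @export
read_text_corpus <- function(path, lexicon = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  corpus_docs(readLines(path, encoding = "UTF-8"), lexicon = lexicon)
}
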