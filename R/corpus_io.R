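#' Read a report table
#'
#' Loads the report CSV (columns `report_id`, `patient_id`, `scan_type`,
#' `report_datetime`, `text`). Rows with empty or whitespace-only text are
#' dropped and the skip count is reported via a message; scan types must be
#' one of CT, CTA, MRI, MRA; duplicated report ids are an error because
#' they would corrupt split bookkeeping downstream. The datetime column is
#' parsed for provenance but never enters any model.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per retained report and an attribute
#'   `n_skipped` (count of empty-text rows dropped).
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character", encoding = "UTF-8")
  required <- c("report_id", "patient_id", "scan_type", "report_datetime", "text")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("report CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(dt)[required]
  bad_scan <- !df$scan_type %in% c("CT", "CTA", "MRI", "MRA")
  if (any(bad_scan)) {
    stop("unknown scan_type value(s) in row(s) ",
         paste(which(bad_scan), collapse = ", "), ": ",
         paste(unique(df$scan_type[bad_scan]), collapse = ", "))
  }
  blank <- is.na(df$text) | !nzchar(trimws(df$text))
  n_skipped <- sum(blank)
  if (n_skipped > 0L) {
    message("read_reports: skipped ", n_skipped, " report(s) with empty text")
  }
  df <- df[!blank, ]
  if (anyDuplicated(df$report_id)) {
    stop("duplicate report_id value(s): ",
         paste(unique(df$report_id[duplicated(df$report_id)]), collapse = ", "))
  }
  parsed <- suppressWarnings(as.POSIXct(
    df$report_datetime, tz = "UTC",
    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d",
                   "%m/%d/%Y %H:%M", "%m/%d/%Y")))
  df$report_datetime <- parsed
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Read a label table
#'
#' Loads the label CSV (columns `report_id`, `stroke`, `mca`, `acute`).
#' Every label must be 0 or 1. Label rows are matched to `reports`;
#' reports without labels are reported as unlabeled via a message. A row
#' with `mca = 1` or `acute = 1` while `stroke = 0` is accepted with a
#' warning (adjudicated labels can carry such inconsistencies).
#'
#' @param path Path to the CSV file.
#' @param reports Report tibble from [read_reports()], used to align and
#'   check coverage. Optional; if `NULL` no coverage check is done.
#' @return A tibble with columns `report_id`, `stroke`, `mca`, `acute`
#'   (integer 0/1), ordered to match `reports` where given.
#' @export
read_labels <- function(path, reports = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character", encoding = "UTF-8")
  required <- c("report_id", "stroke", "mca", "acute")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("label CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(dt)[required]
  for (col in c("stroke", "mca", "acute")) {
    vals <- df[[col]]
    bad <- !vals %in% c("0", "1")
    if (any(bad)) {
      stop("label '", col, "' outside {0,1} in row(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(vals[bad]), collapse = ", "))
    }
    df[[col]] <- as.integer(vals)
  }
  inconsistent <- (df$mca == 1L | df$acute == 1L) & df$stroke == 0L
  if (any(inconsistent)) {
    warning("label rows with mca=1 or acute=1 but stroke=0: ",
            sum(inconsistent), " (accepted)", call. = FALSE)
  }
  if (!is.null(reports)) {
    unlabeled <- setdiff(reports$report_id, df$report_id)
    if (length(unlabeled)) {
      message("read_labels: ", length(unlabeled), " report(s) unlabeled")
    }
    df <- df[match(intersect(reports$report_id, df$report_id), df$report_id), ]
  }
  df
}

#' Write word embeddings to disk
#'
#' Two dialects are supported. `"csv"` writes a self-describing table with
#' header `token,d1,...,d<d>`; tokens containing the delimiter are quoted.
#' `"glove_text"` writes the space-separated, headerless layout used by
#' GloVe tooling; a token containing a space is rejected there. Values are
#' written with 12 significant digits so the file round-trips through
#' [read_embeddings()] to within 1e-10.
#'
#' @param emb Numeric matrix with one row per token; rownames are tokens.
#' @param path Output file path.
#' @param dialect `"csv"` or `"glove_text"`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, dialect = c("csv", "glove_text")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(emb), is.numeric(emb), !is.null(rownames(emb)))
  if (anyDuplicated(rownames(emb))) stop("duplicate tokens in embedding matrix")
  if (!all(is.finite(emb))) stop("embedding matrix contains non-finite values")
  tokens <- rownames(emb)
  vals <- apply(emb, 1L, function(r) paste(sprintf("%.12g", r), collapse =
                                             if (dialect == "csv") "," else " "))
  if (dialect == "csv") {
    quoted <- ifelse(grepl('[,"]', tokens),
                     paste0('"', gsub('"', '""', tokens), '"'), tokens)
    header <- paste(c("token", paste0("d", seq_len(ncol(emb)))), collapse = ",")
    writeLines(c(header, paste(quoted, vals, sep = ",")), path, useBytes = TRUE)
  } else {
    if (any(grepl("[[:space:]]", tokens))) {
      stop("glove_text dialect cannot represent tokens containing whitespace")
    }
    writeLines(paste(tokens, vals, sep = " "), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read word embeddings from disk
#'
#' Mirror of [write_embeddings()]. Rows must all have the same number of
#' fields; a ragged row is a format error reported with its line number.
#' Duplicate tokens keep the first occurrence with a warning.
#'
#' @param path Input file path.
#' @param dialect `"csv"` (header `token,d1..dN`) or `"glove_text"`
#'   (space-separated, no header).
#' @return Numeric matrix with tokens as rownames.
#' @export
read_embeddings <- function(path, dialect = c("csv", "glove_text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "csv") {
    if (!length(lines)) stop("embedding csv is empty")
    body_start <- 2L
    fields <- lapply(lines, function(l) scan(text = l, what = character(),
                                             sep = ",", quote = '"',
                                             quiet = TRUE))
  } else {
    body_start <- 1L
    fields <- strsplit(trimws(lines), "[[:space:]]+")
  }
  fields <- fields[seq(body_start, length.out = length(fields) - body_start + 1L)]
  fields <- Filter(length, fields)
  if (!length(fields)) stop("embedding file has no data rows")
  arity <- lengths(fields)
  if (length(unique(arity)) != 1L) {
    bad <- which(arity != arity[1L])[1L]
    stop("ragged embedding file: line ", bad + body_start - 1L,
         " has ", arity[bad], " fields, expected ", arity[1L])
  }
  tokens <- vapply(fields, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1L])))
  if (anyNA(mat)) stop("non-numeric embedding values in ", path)
  if (anyDuplicated(tokens)) {
    warning("duplicate token(s) in embedding file; keeping first occurrence",
            call. = FALSE)
    keep <- !duplicated(tokens)
    tokens <- tokens[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- tokens
  colnames(mat) <- paste0("d", seq_len(ncol(mat)))
  mat
}

#' Write reports and labels as CSV
#'
#' Convenience writers matching the formats read by [read_reports()] and
#' [read_labels()].
#'
#' @param reports,labels Tibbles as produced by [generate_reports()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- reports
  if (inherits(out$report_datetime, "POSIXct")) {
    out$report_datetime <- format(out$report_datetime, "%Y-%m-%d %H:%M:%S",
                                  tz = "UTC")
  }
  data.table::fwrite(out, path, quote = TRUE)
  invisible(path)
}

#' @rdname write_reports
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels, path, quote = TRUE)
  invisible(path)
}

#' Write a metrics object as JSON
#'
#' @param x A list (e.g. a benchmark summary) to serialise.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
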