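test_that("read_reports returns well-formed rows and skips empty text", {
  fx <- write_report_fixture()
  reports <- read_reports(fx$reports)
  expect_equal(nrow(reports), 3L)
  expect_equal(reports$report_id, c("R001", "R002", "R003"))
  expect_s3_class(reports$report_datetime, "POSIXct")

  # blank-text row among four: skipped and counted
  fx2 <- write_report_fixture(texts = c("A.", "  ", "B.", "C."))
  expect_message(r2 <- read_reports(fx2$reports), "skipped 1")
  expect_equal(nrow(r2), 3L)
  expect_equal(attr(r2, "n_skipped"), 1L)
})

test_that("read_reports enforces schema, scan types and unique ids", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("report_id,patient_id,report_datetime,text",
               "R1,P1,2015-01-01,hello"), p)
  expect_error(read_reports(p), "scan_type")

  writeLines(c("report_id,patient_id,scan_type,report_datetime,text",
               "R1,P1,PET,2015-01-01,hello"), p)
  expect_error(read_reports(p), "PET")

  writeLines(c("report_id,patient_id,scan_type,report_datetime,text",
               "R1,P1,CT,2015-01-01,hello",
               "R1,P2,MRI,2015-01-02,world"), p)
  expect_error(read_reports(p), "duplicate")
})

test_that("read_labels validates values and warns on inconsistent labels", {
  fx <- write_report_fixture()
  reports <- read_reports(fx$reports)
  labels <- read_labels(fx$labels, reports)
  expect_equal(nrow(labels), 3L)
  expect_true(all(unlist(labels[, c("stroke", "mca", "acute")]) %in% 0:1))

  dir <- withr::local_tempdir()
  p <- file.path(dir, "labels.csv")
  writeLines(c("report_id,stroke,mca,acute", "R001,0,1,0"), p)
  expect_warning(read_labels(p), "mca=1")

  writeLines(c("report_id,stroke,mca,acute", "R001,2,0,0"), p)
  expect_error(read_labels(p), "row\\(s\\) 1")

  # reports without labels are reported as unlabeled
  writeLines(c("report_id,stroke,mca,acute", "R001,1,0,0"), p)
  expect_message(read_labels(p, reports), "2 report\\(s\\) unlabeled")
})

test_that("embedding files round-trip losslessly in both dialects", {
  emb <- matrix(rnorm(6 * 5), 6, 5,
                dimnames = list(c("stroke", "infarct", "mca", "acute",
                                  "chronic", "middlecerebralartery"), NULL))
  for (dialect in c("csv", "glove_text")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_embeddings(emb, path, dialect = dialect)
    back <- read_embeddings(path, dialect = dialect)
    expect_identical(rownames(back), rownames(emb))
    expect_lt(max(abs(back - emb)), 1e-10)
  }
})

test_that("embedding csv layout is header plus one row per token", {
  emb <- matrix(seq_len(6) / 7, 2, 3, dimnames = list(c("a", "b"), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embeddings(emb, path, dialect = "csv")
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_equal(lines[1], "token,d1,d2,d3")

  wide <- matrix(rnorm(100), 1, 100,
                 dimnames = list("middlecerebralartery", NULL))
  write_embeddings(wide, path, dialect = "csv")
  expect_length(strsplit(readLines(path)[2], ",")[[1]], 101L)
})

test_that("embedding readers reject ragged rows and dedupe tokens", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a 1 2 3", "b 1 2"), path)
  expect_error(read_embeddings(path, "glove_text"), "line 2")

  writeLines(c("a 1 2 3", "a 4 5 6", "b 7 8 9"), path)
  expect_warning(emb <- read_embeddings(path, "glove_text"), "duplicate")
  expect_equal(nrow(emb), 2L)
  expect_equal(unname(emb["a", ]), c(1, 2, 3))
})

test_that("tokens containing the csv delimiter are quoted, not corrupted", {
  emb <- matrix(1:4 / 3, 2, 2, dimnames = list(c("a,b", "c"), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embeddings(emb, path, dialect = "csv")
  back <- read_embeddings(path, "csv")
  expect_identical(rownames(back), c("a,b", "c"))
  expect_error(write_embeddings(
    matrix(1, 1, 1, dimnames = list("a b", NULL)), path, "glove_text"),
    "whitespace")
})
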