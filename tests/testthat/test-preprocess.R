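# Corpus filtering, sectioning and standardisation with offset maps.

test_that("corpus filters enforce inclusion/exclusion criteria", {
  reports <- data.frame(
    id = c("p1", "p1", "p2", "p3", "p4"),
    text = paste("report", 1:5),
    exam_date = as.Date(c("2018-03-01", "2019-06-01", "2017-01-15",
                          "2019-11-30", NA)),
    age = c(44, 44, 17, 18, 60),
    exam_code = c("UTHYD", "UTHYD", "UNECK", "UTHPY", "UTHYD"),
    stringsAsFactors = FALSE)

  # most recent report per pseudoidentifier survives
  out <- suppressMessages(
    filter_corpus(reports, list(keep_most_recent = TRUE)))
  expect_equal(sum(out$id == "p1"), 1L)
  expect_equal(out$exam_date[out$id == "p1"], as.Date("2019-06-01"))

  # adults only: 17 excluded, 18 kept
  out2 <- filter_corpus(reports[3:5, ], list(min_age = 18))
  expect_setequal(out2$id, c("p3", "p4"))

  # empty criteria: identity
  expect_identical(filter_corpus(reports, list()), reports)

  # missing metadata required by an active criterion: excluded and logged
  expect_message(
    out3 <- filter_corpus(reports, list(date_from = "2018-01-01")),
    "missing metadata")
  expect_false("p4" %in% out3$id)

  out4 <- filter_corpus(reports, list(exam_codes = c("UTHYD", "UTHPY")))
  expect_false("p2" %in% out4$id)
})

test_that("reports split into sections at configured headers", {
  text <- "Clinical history: pain. Findings: normal thyroid."
  segs <- split_sections(text, c("clinical history", "findings"))
  expect_equal(segs$name, c("clinical history", "findings"))
  expect_equal(trimws(segs$text), c("pain.", "normal thyroid."))

  # header text itself belongs to no section; segments tile the raw text
  covered <- sum(segs$end - segs$start + 1L)
  expect_lt(covered, nchar(text))
  expect_equal(substr(text, segs$start[1], segs$end[1]), segs$text[1])

  # headerless report: single body section
  segs2 <- split_sections("just some text", c("findings"))
  expect_equal(segs2$name, "body")
  expect_equal(segs2$text, "just some text")

  # text before the first header goes to body
  segs3 <- split_sections("preamble. Findings: stuff", c("findings"))
  expect_equal(segs3$name, c("body", "findings"))

  # repeated header contributes a second segment of the same section
  segs4 <- split_sections("Findings: one. Findings: two.", c("findings"))
  expect_equal(segs4$name, c("findings", "findings"))
  expect_equal(trimws(segs4$text), c("one.", "two."))
})

test_that("section segments plus headers reconstruct the raw report", {
  corpus <- generate_corpus(25, seed = 11)$reports
  for (i in seq_len(nrow(corpus))) {
    segs <- split_sections(corpus$text[i], c("clinical history", "findings"))
    # segments must be disjoint, ordered, in-bounds
    expect_true(all(segs$start <= segs$end))
    expect_true(all(diff(segs$start) > 0))
    expect_true(all(segs$end <= nchar(corpus$text[i])))
    # every segment reproduces its slice of the raw text
    expect_equal(substring(corpus$text[i], segs$start, segs$end), segs$text)
  }
})

test_that("standardisation lowercases, maps punctuation and splits sentences", {
  out <- standardise("The thyroid  is NORMAL.")
  expect_length(out, 1)
  expect_equal(out[[1]]$text, "the thyroid is normal")

  out2 <- standardise("No nodules. Lymph nodes normal.")
  expect_length(out2, 2)
  expect_equal(out2[[1]]$text, "no nodules")
  expect_equal(out2[[2]]$text, "lymph nodes normal")

  # '/', '-', parentheses become separators; decimal points survive
  out3 <- standardise("post-op u2/u3 (left) 2.5 mm")
  expect_equal(out3[[1]]$text, "post op u2 u3 left 2.5 mm")

  # blank lines split sentences
  out4 <- standardise("first line\n\nsecond line")
  expect_length(out4, 2)
})

test_that("offset maps are strictly increasing, in-bounds, and faithful", {
  texts <- c("The thyroid  is NORMAL.",
             "Query: ?cancer (U3) seen... maybe",
             generate_corpus(10, seed = 3)$reports$text)
  for (text in texts) {
    for (sen in standardise(text)) {
      off <- sen$offsets
      expect_equal(length(off), nchar(sen$text))
      expect_true(all(diff(off) > 0))
      expect_true(all(off >= 1 & off <= nchar(text)))
      # every non-space character maps back to itself (lowercased)
      chars <- strsplit(sen$text, "")[[1]]
      raw_chars <- tolower(strsplit(text, "")[[1]])[off]
      keep <- chars != " "
      expect_equal(chars[keep], raw_chars[keep])
    }
  }
})

test_that("standardisation is idempotent on its own output", {
  texts <- generate_corpus(10, seed = 5)$reports$text
  for (text in texts) {
    once <- vapply(standardise(text), `[[`, character(1), "text")
    again <- unlist(lapply(once, function(s) {
      vapply(standardise(s), `[[`, character(1), "text")
    }))
    expect_equal(again, once)
  }
})

test_that("stopword removal changes proximity distances to surviving tokens", {
  plain <- standardise("the thyroid is normal")[[1]]$text
  reduced <- standardise("the thyroid is normal", remove_stopwords = TRUE)[[1]]$text
  expect_equal(plain, "the thyroid is normal")
  expect_equal(reduced, "thyroid normal")
  # adjacency only holds after removal
  expect_false(evaluate_query("thyroid THEN/0 normal", plain)$present)
  expect_true(evaluate_query("thyroid THEN/0 normal", reduced)$present)
  # oracle agrees on the reduced token stream
  q <- parse_query("thyroid THEN/0 normal")
  expect_true(oracle_presence(q, reduced))
})

test_that("corpus round-trips through CSV and JSONL", {
  corpus <- generate_corpus(5, seed = 2)$reports
  for (ext in c("csv", "jsonl")) {
    path <- file.path(tempdir(), paste0("corpus.", ext))
    write_corpus(corpus, path)
    back <- read_corpus(path)
    expect_equal(back$id, corpus$id)
    expect_equal(back$text, corpus$text)
    expect_equal(as.Date(back$exam_date), corpus$exam_date)
    unlink(path)
  }
})

test_that("process_report keeps absolute offsets into the raw report", {
  rep <- list(id = "r1",
              text = "Clinical history: Neck lump.\n\nFindings: The thyroid is NORMAL.")
  proc <- process_report(rep, c("clinical history", "findings"))
  secs <- vapply(proc$sentences, `[[`, character(1), "section")
  expect_setequal(unique(secs), c("clinical history", "findings"))
  for (sen in proc$sentences) {
    raw_slice <- tolower(substring(rep$text, sen$offsets, sen$offsets))
    chars <- strsplit(sen$text, "")[[1]]
    keep <- chars != " "
    expect_equal(chars[keep], raw_slice[keep])
  }
})
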