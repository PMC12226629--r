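# Classification engine: per-class evaluation, derived classes,
# post-processing rules, highlighting, discrepancy flagging.

with_headers <- c("clinical history", "findings")

classify_text <- function(text, ...) {
  s <- thyroid_strategy()
  classify_report(s, process_report(list(id = "t1", text = text),
                                    s$headers), ...)
}

test_that("a BTA grading forces thyroid nodule presence via post-rules", {
  r <- classify_text("Findings: The thyroid was examined. Graded U3.")
  expect_true(r$labels[["BTA U3"]])
  expect_true(r$labels[["Thyroid nodule(s)"]])
  expect_true("Thyroid nodule(s)" %in% r$forced)
  # and the derived classes are re-evaluated after the forcing
  expect_true(r$labels[["Solitary thyroid nodule"]])
  expect_false(r$labels[["Normal thyroid"]])
})

test_that("derived classes follow boolean logic over earlier labels", {
  r <- classify_text("Findings: A solitary nodule in the thyroid.")
  expect_true(r$labels[["Thyroid nodule(s)"]])
  expect_false(r$labels[["Multiple thyroid nodules"]])
  expect_true(r$labels[["Solitary thyroid nodule"]])

  r2 <- classify_text("Findings: Multiple thyroid nodules are seen.")
  expect_true(r2$labels[["Multiple thyroid nodules"]])
  expect_false(r2$labels[["Solitary thyroid nodule"]])

  r3 <- classify_text("Findings: The thyroid gland is entirely normal.")
  expect_true(r3$labels[["Normal thyroid"]])
})

test_that("an empty report yields all-negative labels", {
  r <- classify_text(" ")
  expect_false(any(r$labels))
  # normal thyroid requires a thyroid examination, not mere absence
  expect_false(r$labels[["Normal thyroid"]])
})

test_that("negated findings never justify a positive label", {
  r <- classify_text("Findings: The thyroid was seen. There are no thyroid nodules.")
  expect_false(r$labels[["Thyroid nodule(s)"]])
  expect_true(r$labels[["Thyroid examination"]])
  expect_true(r$labels[["Normal thyroid"]])
  ev <- r$evidence[["Thyroid nodule(s)"]]
  expect_true(all(ev$negated))
})

test_that("classification is idempotent and deterministic", {
  s <- thyroid_strategy()
  proc <- process_report(
    list(id = "x", text = "Findings: Multiple nodules in the thyroid, BTA U2."),
    s$headers)
  r1 <- classify_report(s, proc)
  r2 <- classify_report(s, proc)
  expect_identical(r1, r2)
})

test_that("classes fall back to the body section when theirs is missing", {
  # headerless report: everything lands in 'body', classes configured for
  # 'findings' still classify
  r <- classify_text("A solitary nodule is seen in the thyroid.")
  expect_true(r$labels[["Thyroid nodule(s)"]])
  expect_true(r$labels[["Thyroid examination"]])
})

test_that("AND scope is configurable between section and sentence", {
  s <- thyroid_strategy()
  # goitre branch 'enlarged~2gland & NOT enlarged~2parathy*' needs both in
  # scope; craft a report where 'surgery' and its excluder sit in different
  # sentences to see section-level AND at work
  txt <- "Findings: The thyroid gland is enlarged. No nodules."
  proc <- process_report(list(id = "a", text = txt), s$headers)
  r_sec <- classify_report(s, proc, and_scope = "section")
  r_sen <- classify_report(s, proc, and_scope = "sentence")
  expect_true(r_sec$labels[["Goitre"]])
  expect_true(r_sen$labels[["Goitre"]])

  # surgery mention excluded by a referral in the same section
  txt2 <- "Findings: Thyroid normal. Referred for surgery."
  expect_false(classify_text(txt2)$labels[["Previous thyroid surgery"]])
})

test_that("classify_corpus preserves order, validates ids and logs counts", {
  s <- thyroid_strategy()
  corpus <- generate_corpus(10, seed = 9)$reports
  res <- classify_corpus(s, corpus)
  expect_length(res, 10)
  expect_equal(vapply(res, `[[`, character(1), "id"), corpus$id)

  expect_error(
    classify_corpus(s, data.frame(id = c("a", "a"), text = c("x", "y"))),
    "duplicate")

  expect_length(classify_corpus(s, corpus[0, ]), 0)

  expect_message(classify_corpus(s, corpus[1:3, ], verbose = TRUE),
                 "positive")
})

test_that("an invalid strategy is rejected before any classification", {
  s <- thyroid_strategy()
  s$classes[[3]]$query_text <- "x (("
  s$classes[[3]]$query <- NULL
  expect_error(classify_corpus(s, generate_corpus(2, seed = 1)$reports),
               "invalid")
})

test_that("every positive search label carries non-negated evidence", {
  s <- thyroid_strategy()
  corpus <- generate_corpus(60, seed = 13)$reports
  res <- classify_corpus(s, corpus)
  derived <- c("Solitary thyroid nodule", "Normal thyroid")
  for (r in res) {
    for (cls in names(r$labels)) {
      if (!r$labels[[cls]] || cls %in% derived) next
      if (cls %in% r$forced) next
      ev <- r$evidence[[cls]]
      expect_true(nrow(ev) > 0 && any(!ev$negated),
                  label = paste(r$id, cls))
    }
  }
})

test_that("post-rule and derived-label identities hold on every output", {
  s <- thyroid_strategy()
  corpus <- generate_corpus(60, seed = 17)$reports
  lm <- labels_matrix(classify_corpus(s, corpus))
  u25 <- lm[["BTA U2"]] | lm[["BTA U3"]] | lm[["BTA U4"]] | lm[["BTA U5"]]
  expect_false(any(u25 & !lm[["Thyroid nodule(s)"]]))
  expect_false(any(lm[["Solitary thyroid nodule"]] &
                     lm[["Multiple thyroid nodules"]]))
  abnormal <- lm[["Thyroid nodule(s)"]] | lm[["Altered thyroid echotexture"]] |
    lm[["Goitre"]] | lm[["Previous thyroid surgery"]]
  expect_false(any(lm[["Normal thyroid"]] & abnormal))
})

test_that("highlighting marks evidence per class and round-trips the text", {
  txt <- paste("Findings: The thyroid is heterogeneous with a goitre.",
               "Multiple nodules are seen. No abnormal lymph nodes.")
  r <- classify_text(txt)
  html <- highlight_report(r)
  expect_match(html, "<mark", fixed = TRUE)
  expect_identical(strip_highlight(html), txt)
  # one legend entry per evidenced class
  for (cls in c("Goitre", "Multiple thyroid nodules")) {
    expect_true(r$labels[[cls]])
  }
  # a report without matches renders unmarked but byte-identical
  r0 <- classify_text("Nothing relevant here & nothing <else>.")
  html0 <- highlight_report(r0)
  expect_false(grepl("<mark", html0, fixed = TRUE))
  expect_identical(strip_highlight(html0),
                   "Nothing relevant here & nothing <else>.")
})

test_that("negation triggers are marked distinctly in highlights", {
  txt <- "Findings: The thyroid was seen. No discrete thyroid lesion is identified."
  r <- classify_text(txt)
  ev <- r$evidence[["Thyroid nodule(s)"]]
  expect_true(any(ev$negated))
  html <- highlight_report(r)
  expect_match(html, "class=\"[^\"]*neg")
  expect_identical(strip_highlight(html), txt)
})

test_that("discrepancy flagging recovers exactly the injected errors", {
  s <- thyroid_strategy()
  gen <- generate_corpus(40, seed = 23)
  res <- classify_corpus(s, gen$reports)
  lm <- labels_matrix(res)
  classes <- thyroid_classes()

  # self-comparison: no discrepancies
  expect_equal(nrow(flag_discrepancies(res, lm)), 0)

  # flip k labels in the reference; exactly those flips are flagged
  ref <- lm
  set.seed(5)
  k <- 7
  flips <- data.frame(row = sample(nrow(ref), k),
                      cls = sample(classes, k, replace = TRUE))
  flips <- unique(flips)
  for (j in seq_len(nrow(flips))) {
    ref[flips$row[j], flips$cls[j]] <- !ref[flips$row[j], flips$cls[j]]
  }
  disc <- flag_discrepancies(res, ref)
  expect_equal(nrow(disc), nrow(flips))
  expect_setequal(paste(disc$id, disc$class),
                  paste(ref$id[flips$row], flips$cls))
  # FP records carry span evidence, FN records the report text
  if (any(disc$kind == "FP")) {
    expect_true(all(nzchar(disc$evidence[disc$kind == "FP"])))
  }

  # a missing reference report is excluded with a message
  expect_message(flag_discrepancies(res, ref[-1, ]), "missing")
})

test_that("results export with one boolean column per class plus evidence", {
  s <- thyroid_strategy()
  res <- classify_corpus(s, generate_corpus(5, seed = 3)$reports)
  path <- tempfile(fileext = ".csv")
  df <- write_labels(res, path)
  expect_true(file.exists(path))
  expect_setequal(setdiff(names(df), c("id", "evidence")), thyroid_classes())
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 5)
  unlink(path)
})
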